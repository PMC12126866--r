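# Greedy extraction of a complete (missing-free) submatrix.
#
# Each pass computes the per-row and per-column missing fractions of the
# current submatrix, then deletes whichever lines the dominant axis rule
# selects: if max p_r >= max p_c, every row with p_r >= max p_c goes;
# otherwise every column with p_c >= max p_r goes. Deleting lines changes the
# opposing fractions, so the rule is re-applied until no missing value
# remains. Each pass removes at least one line (the argmax line always
# qualifies), so the loop terminates in at most rows + columns passes.

#' Greedily extract a complete submatrix
#'
#' Reduces a matrix with missing entries to a submatrix without any, using
#' the iterative dominant-axis deletion rule described above. Fractions are
#' compared exactly via count cross-multiplication (`missing_r * m >=
#' max_missing_c * n`), so ties are decided by arithmetic, not by floating-
#' point luck; an exact tie `max p_r == max p_c` deletes rows.
#'
#' The rule is applied to the matrix as given (rows are typically CpGs,
#' columns samples). `orient_wlog = TRUE` first transposes any matrix with
#' fewer rows than columns, applies the rule, and maps the selection back --
#' the literal "without loss of generality" orientation.
#'
#' @param m Numeric matrix with `NA` for missing entries, or a logical mask
#'   (`TRUE` = missing).
#' @param orient_wlog Transpose-first behaviour for matrices with more
#'   columns than rows (default `FALSE`).
#' @return An object of class `osmi_subset`: list with `kept_rows` and
#'   `kept_cols` (original indices, order-preserving) and `iterations`, a
#'   data frame logging per pass the maximal fractions, the deleted axis and
#'   the number of lines deleted.
#' @export
greedy_complete_subset <- function(m, orient_wlog = FALSE) {
  stopifnot(is.matrix(m), nrow(m) > 0, ncol(m) > 0)
  mask <- if (is.logical(m)) m else is.na(m)
  if (orient_wlog && nrow(mask) < ncol(mask)) {
    res <- greedy_complete_subset(t(mask), orient_wlog = FALSE)
    res$kept_rows2 <- res$kept_rows
    res$kept_rows <- res$kept_cols
    res$kept_cols <- res$kept_rows2
    res$kept_rows2 <- NULL
    res$iterations$axis <- ifelse(res$iterations$axis == "row", "col", "row")
    tmp <- res$iterations$max_p_r
    res$iterations$max_p_r <- res$iterations$max_p_c
    res$iterations$max_p_c <- tmp
    res$transposed <- TRUE
    return(res)
  }
  rows <- seq_len(nrow(mask))
  cols <- seq_len(ncol(mask))
  log <- list()
  it <- 0L
  while (length(rows) > 0 && length(cols) > 0) {
    sub <- mask[rows, cols, drop = FALSE]
    mr <- rowSums(sub)   # missing count per row; p_r = mr / n_cols
    mc <- colSums(sub)   # missing count per col; p_c = mc / n_rows
    if (max(mr) == 0) break
    it <- it + 1L
    m_cur <- length(rows)
    n_cur <- length(cols)
    max_mr <- max(mr)
    max_mc <- max(mc)
    # max p_r >= max p_c  <=>  max_mr / n >= max_mc / m  <=>  max_mr*m >= max_mc*n
    if (max_mr * m_cur >= max_mc * n_cur) {
      del <- mr * m_cur >= max_mc * n_cur
      log[[it]] <- data.frame(iteration = it, max_p_r = max_mr / n_cur,
                              max_p_c = max_mc / m_cur, axis = "row",
                              n_deleted = sum(del))
      rows <- rows[!del]
    } else {
      del <- mc * n_cur >= max_mr * m_cur
      log[[it]] <- data.frame(iteration = it, max_p_r = max_mr / n_cur,
                              max_p_c = max_mc / m_cur, axis = "col",
                              n_deleted = sum(del))
      cols <- cols[!del]
    }
  }
  if (length(rows) == 0 || length(cols) == 0)
    warnf("greedy filtering removed every row or column; selection is empty")
  structure(list(
    kept_rows = rows,
    kept_cols = cols,
    iterations = if (it > 0) do.call(rbind, log) else
      data.frame(iteration = integer(0), max_p_r = numeric(0),
                 max_p_c = numeric(0), axis = character(0),
                 n_deleted = integer(0)),
    transposed = FALSE
  ), class = "osmi_subset")
}

#' @export
print.osmi_subset <- function(x, ...) {
  cat(sprintf("complete-case selection: %d rows x %d cols kept after %d pass(es)\n",
              length(x$kept_rows), length(x$kept_cols), nrow(x$iterations)))
  invisible(x)
}
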