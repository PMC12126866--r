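# MCAR masking and imputation scoring.
#
# The benchmark protocol: take a complete beta-matrix, hide a known fraction
# of entries completely at random inside a random subset of eligible CpG
# rows (keeping the remaining rows fully observed), impute, and score the
# masked entries against the ground truth.

#' Mask entries completely at random
#'
#' Selects `round(eligible_row_fraction * nrow)` CpG rows uniformly at
#' random, then masks entries uniformly at random without replacement inside
#' that eligible block; ineligible rows stay fully observed (some complete-
#' case CpGs are thereby retained, as several multi-sample imputers require).
#' With `mask_basis = "eligible"` (default) the masked count is
#' `round(entry_fraction * eligible_entries)`; `"total"` bases the count on
#' all entries of the matrix while still confining the mask to eligible rows.
#'
#' @param m Complete numeric matrix (no `NA`).
#' @param entry_fraction Fraction of entries to mask (default 0.10).
#' @param eligible_row_fraction Fraction of rows eligible for masking
#'   (default 0.90).
#' @param seed Optional integer seed; the same seed reproduces the same mask
#'   and the caller's RNG stream is left untouched.
#' @param mask_basis `"eligible"` or `"total"` (see above).
#' @return List with `masked` (the matrix with `NA` holes) and `mask` (data
#'   frame of `row`, `col` indices, plus `cpg_id`/`sample_id` when dimnames
#'   exist).
#' @export
mask_mcar <- function(m, entry_fraction = 0.10, eligible_row_fraction = 0.90,
                      seed = NULL, mask_basis = c("eligible", "total")) {
  mask_basis <- match.arg(mask_basis)
  stopifnot(is.matrix(m))
  if (anyNA(m)) stopf("mask_mcar requires a complete matrix")
  if (entry_fraction <= 0 || entry_fraction > 1 ||
      eligible_row_fraction <= 0 || eligible_row_fraction > 1)
    stopf("entry_fraction and eligible_row_fraction must lie in (0, 1]")
  with_seed(seed, {
    n_elig <- round(eligible_row_fraction * nrow(m))
    if (n_elig < 1) stopf("mask too small: no eligible rows")
    elig_rows <- sort(sample.int(nrow(m), n_elig))
    n_entries <- switch(mask_basis,
                        eligible = n_elig * ncol(m),
                        total = nrow(m) * ncol(m))
    n_mask <- round(entry_fraction * n_entries)
    if (n_mask < 1) stopf("mask too small: masked entry count rounds to zero")
    if (n_mask > n_elig * ncol(m))
      stopf("mask too large: %d entries requested but only %d eligible",
            n_mask, n_elig * ncol(m))
    pick <- sample.int(n_elig * ncol(m), n_mask)
    rr <- elig_rows[((pick - 1L) %% n_elig) + 1L]
    cc <- ((pick - 1L) %/% n_elig) + 1L
    masked <- m
    masked[cbind(rr, cc)] <- NA_real_
    mask <- data.frame(row = rr, col = cc)
    if (!is.null(rownames(m))) mask$cpg_id <- rownames(m)[rr]
    if (!is.null(colnames(m))) mask$sample_id <- colnames(m)[cc]
    list(masked = masked, mask = mask)
  })
}

#' Score imputed values on masked entries
#'
#' Computes error metrics between ground truth and imputed values on the
#' masked entries only. Residuals are defined as truth minus imputed, so an
#' imputer that guesses too high produces negative bias.
#'
#' @param truth Complete ground-truth matrix.
#' @param imputed Imputed matrix of the same shape, complete on the mask.
#' @param mask Data frame with `row` and `col` columns (as from
#'   [mask_mcar()]), or a 2-column index matrix.
#' @return An object of class `osmi_eval`: list with `rmse`, `mae`, `bias`
#'   (mean residual), `iqr` (interquartile range of residuals, type-7
#'   linear-interpolation quantiles), `residuals` and `n_masked`.
#' @export
score_imputation <- function(truth, imputed, mask) {
  stopifnot(is.matrix(truth), is.matrix(imputed),
            all(dim(truth) == dim(imputed)))
  idx <- if (is.data.frame(mask)) cbind(mask$row, mask$col) else mask
  stopifnot(is.matrix(idx), ncol(idx) == 2, nrow(idx) >= 1)
  iv <- imputed[idx]
  if (anyNA(iv)) {
    bad <- which(is.na(iv))
    stopf("imputed matrix is missing at %d masked entrie(s), e.g. (%d, %d)",
          length(bad), idx[bad[1], 1], idx[bad[1], 2])
  }
  res <- truth[idx] - iv
  structure(list(
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    bias = mean(res),
    iqr = unname(diff(quantile(res, c(0.25, 0.75), type = 7))),
    residuals = res,
    n_masked = length(res)
  ), class = "osmi_eval")
}

#' @export
print.osmi_eval <- function(x, ...) {
  cat(sprintf("masked-entry evaluation (n = %d): RMSE %.4f, MAE %.4f, bias %+.4f, IQR %.4f\n",
              x$n_masked, x$rmse, x$mae, x$bias, x$iqr))
  invisible(x)
}

#' Paired comparison of residuals
#'
#' Wilcoxon signed-rank test on paired differences `a - b` (zero differences
#' dropped, ties mid-ranked), with rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)` and paired Cohen's d `mean(diff) / sd(diff)`
#' (sample standard deviation, n - 1, over all pairs including zeros).
#'
#' @param a,b Numeric vectors of equal length >= 2, paired entry by entry.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `rank_biserial`, `cohens_d`, `n_nonzero` and `n_total`. When every
#'   difference is zero the test is undefined: `statistic` and `p_value` are
#'   `NA` while both effect sizes are 0.
#' @export
compare_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (anyNA(d)) stopf("paired inputs contain missing values")
  nz <- d != 0
  n_nz <- sum(nz)
  sdd <- sd(d)
  cohens_d <- if (sdd == 0) 0 else mean(d) / sdd
  if (n_nz == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, rank_biserial = 0,
                cohens_d = 0, n_nonzero = 0L, n_total = length(d),
                note = "all paired differences are zero; test undefined"))
  }
  r <- rank(abs(d[nz]))
  w_pos <- sum(r[d[nz] > 0])
  w_neg <- sum(r[d[nz] < 0])
  p <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  )
  list(statistic = w_pos, p_value = p,
       rank_biserial = (w_pos - w_neg) / (w_pos + w_neg),
       cohens_d = cohens_d, n_nonzero = n_nz, n_total = length(d))
}

#' Imputation accuracy as a function of CpG density
#'
#' Repeatedly subsamples a given number of CpG rows from a complete matrix,
#' masks entries at random, imputes every sample with basic OSMI and records
#' the masked-entry RMSE. Because nearest neighbours move closer as more
#' CpGs are available, spatially correlated methylomes show decreasing RMSE
#' with increasing density; spatially uncorrelated ones do not.
#'
#' @param truth Complete matrix.
#' @param annot Matching `cpg_annotation`.
#' @param densities Integer vector of CpG counts (each <= `nrow(truth)`).
#' @param entry_fraction,eligible_row_fraction Masking parameters (see
#'   [mask_mcar()]).
#' @param replicates Replicate subsample/mask draws per density.
#' @param seed Integer seed for the whole procedure.
#' @return Data frame with one row per density: `n_cpgs`, `mean_rmse`, `sem`
#'   (standard error of the mean across replicates; `NA` when
#'   `replicates < 2`).
#' @export
density_accuracy_curve <- function(truth, annot, densities,
                                   entry_fraction = 0.10,
                                   eligible_row_fraction = 0.90,
                                   replicates = 10, seed = NULL) {
  annot <- as_cpg_annotation(annot)
  stopifnot(all(densities >= 2), all(densities <= nrow(truth)))
  with_seed(seed, {
    out <- lapply(densities, function(k) {
      rmses <- vapply(seq_len(replicates), function(r) {
        rows <- sort(sample.int(nrow(truth), k))
        sub <- truth[rows, , drop = FALSE]
        subann <- annot[rows, , drop = FALSE]
        mk <- mask_mcar(sub, entry_fraction, eligible_row_fraction)
        imp <- impute_matrix(mk$masked, subann, mode = "basic")
        score_imputation(sub, imp$values, mk$mask)$rmse
      }, numeric(1))
      data.frame(n_cpgs = k, mean_rmse = mean(rmses),
                 sem = if (replicates >= 2) sd(rmses) / sqrt(replicates) else NA_real_)
    })
    do.call(rbind, out)
  })
}

#' Compare basic and island-aware OSMI on the in-island stratum
#'
#' Masks a complete matrix, runs both OSMI modes, and restricts scoring to
#' the masked entries whose advanced-mode imputation actually came from an
#' in-island neighbour search (provenance `ISLAND_*`). Outside that stratum
#' the two modes coincide by construction, so the stratum is where any
#' island effect can show.
#'
#' @param truth Complete matrix.
#' @param annot `cpg_annotation` carrying island assignments.
#' @param entry_fraction,eligible_row_fraction Masking parameters.
#' @param seed Integer seed for the mask.
#' @param island_strand_filter Passed to [impute_matrix()].
#' @return List with `n_stratum`, per-mode `osmi_eval` reports (`basic`,
#'   `advanced`) on the stratum, and `paired` -- [compare_paired()] of the
#'   absolute residuals, advanced versus basic (negative rank-biserial means
#'   the island-aware mode has the smaller errors). An empty stratum yields
#'   `n_stratum = 0` and no statistics.
#' @export
island_stratified_compare <- function(truth, annot,
                                      entry_fraction = 0.10,
                                      eligible_row_fraction = 0.90,
                                      seed = NULL,
                                      island_strand_filter = FALSE) {
  annot <- as_cpg_annotation(annot)
  mk <- mask_mcar(truth, entry_fraction, eligible_row_fraction, seed = seed)
  imp_b <- impute_matrix(mk$masked, annot, mode = "basic",
                         island_strand_filter = island_strand_filter)
  imp_a <- impute_matrix(mk$masked, annot, mode = "advanced",
                         island_strand_filter = island_strand_filter)
  pa <- imp_a$provenance
  isl <- pa[grepl("^ISLAND_", pa$code), c("cpg_id", "sample_id")]
  mask <- mk$mask
  key <- paste(mask$row, mask$col)
  rid <- match(isl$cpg_id, annot$cpg_id)
  cid <- match(isl$sample_id, colnames(truth) %||% as.character(seq_len(ncol(truth))))
  sel <- match(paste(rid, cid), key)
  sel <- sel[!is.na(sel)]
  if (length(sel) == 0) {
    return(list(n_stratum = 0L, basic = NULL, advanced = NULL, paired = NULL,
                note = "no masked entry used an in-island neighbour search"))
  }
  stratum <- mask[sel, , drop = FALSE]
  sb <- score_imputation(truth, imp_b$values, stratum)
  sa <- score_imputation(truth, imp_a$values, stratum)
  list(
    n_stratum = length(sel),
    basic = sb,
    advanced = sa,
    paired = compare_paired(abs(sa$residuals), abs(sb$residuals)),
    mask = stratum
  )
}
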