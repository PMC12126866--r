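# beta-value matrix input/output.
#
# On-disk layout: first column cpg_id, one column per sample, header row with
# sample identifiers. Missing entries are accepted as empty cells, "NA" or
# "NaN" and written back as "NA".

#' Read a beta-value matrix
#'
#' @param path TSV/CSV file, first column CpG identifiers, remaining columns
#'   one sample each (header row required); gzip supported.
#' @return Numeric matrix with CpG rownames and sample colnames; values in
#'   `[0, 1]` with `NA` for missing entries.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stopf("beta matrix file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, sep = "auto", data.table = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (ncol(dt) < 2) stopf("beta matrix needs a cpg_id column plus >= 1 sample column")
  ids <- as.character(dt[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stopf("duplicate cpg_id in beta matrix: %s", paste(head(dup, 5), collapse = ", "))
  if (anyDuplicated(names(dt)[-1]) > 0) stopf("duplicate sample_id in beta matrix header")
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  rng <- range(m, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stopf("beta values outside [0, 1] (range %.4g..%.4g)", rng[1], rng[2])
  m
}

#' Write a beta-value matrix
#'
#' @param m Numeric matrix with CpG rownames and sample colnames.
#' @param path Output path (tab-separated; `.csv` extension switches to commas).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- data.frame(cpg_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}
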