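# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rbinom rexp rgeom rnorm runif sd quantile plogis
#' @importFrom utils head
NULL

# Normalise strand tokens to the internal {+,-} vocabulary.
# Illumina manifests use F/R, UCSC uses +/-; a unicode minus sign is also
# accepted because it survives some spreadsheet round-trips.
normalize_strand <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "F", "f", "fwd", "forward")] <- "+"
  out[x %in% c("-", "−", "R", "r", "rev", "reverse")] <- "-"
  out
}

# Parse 1-based positions; anything non-integer or < 1 becomes NA.
parse_position <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "NaN", "na", "nan")] <- NA_character_
  pos <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & (is.na(pos) | pos != round(pos) | pos < 1)
  if (any(bad)) {
    warning(sum(bad), " position value(s) unparseable or < 1; set to missing")
  }
  pos[bad] <- NA_real_
  as.integer(round(pos))
}

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
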