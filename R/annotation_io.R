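# CpG annotation and CpG-island track parsing.
#
# All internal coordinates are 1-based inclusive. UCSC island tracks are
# converted from their 0-based half-open convention on read. Strands use the
# {+,-} vocabulary; Illumina F/R codes are mapped F -> +, R -> -.

#' Validate a CpG annotation table
#'
#' Coerces a data frame to the internal annotation layout (`cpg_id`, `chrom`,
#' `pos`, `strand`, `island_id`) and enforces its invariants: unique CpG
#' identifiers, positive 1-based positions, and strands in `{+,-}`. Missing
#' chromosome, position or strand values are permitted (the imputation rules
#' have explicit fallbacks for them).
#'
#' @param df A data frame with at least columns `cpg_id`, `chrom`, `pos`,
#'   `strand`; `island_id` is optional and defaults to `NA`.
#' @return The validated annotation table, of class `cpg_annotation`.
#' @export
as_cpg_annotation <- function(df) {
  req <- c("cpg_id", "chrom", "pos", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stopf("annotation is missing required column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(
    cpg_id = as.character(df$cpg_id),
    chrom = as.character(df$chrom),
    pos = df$pos,
    strand = as.character(df$strand),
    island_id = if ("island_id" %in% names(df)) as.character(df$island_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  out$chrom[!is.na(out$chrom) & out$chrom %in% c("", "NA")] <- NA_character_
  if (!is.integer(out$pos)) out$pos <- parse_position(out$pos)
  out$strand <- normalize_strand(out$strand)
  if (anyNA(out$cpg_id) || any(out$cpg_id == ""))
    stopf("annotation contains empty CpG identifiers")
  dup <- unique(out$cpg_id[duplicated(out$cpg_id)])
  if (length(dup) > 0)
    stopf("duplicate cpg_id in annotation: %s", paste(head(dup, 5), collapse = ", "))
  bad <- !is.na(out$pos) & out$pos < 1
  if (any(bad)) stopf("annotation positions must be >= 1")
  class(out) <- c("cpg_annotation", "data.frame")
  out
}

#' Read a CpG annotation table
#'
#' Parses per-CpG chromosome, position and strand information. Two dialects
#' are supported: `"generic"` (tab-separated, header row with columns
#' `cpg_id`, `chrom`, `pos`, `strand` and optionally `island_id`) and
#' `"illumina450k"` (comma-separated manifest-style table with columns
#' `Name`/`IlmnID`, `CHR`, `MAPINFO`, `Strand`). Rows with unparseable
#' positions or strands keep the row but carry a missing value in that field;
#' they are never dropped.
#'
#' @param path Path to the annotation file (plain or gzip-compressed).
#' @param dialect `"generic"` or `"illumina450k"`.
#' @param col_map Optional named list overriding the dialect's column names,
#'   with any of the entries `cpg_id`, `chrom`, `pos`, `strand`, `island_id`.
#' @param use_island_column For the `"illumina450k"` dialect: if `TRUE` and
#'   the resolved islands-name column is present, it populates the island
#'   assignment directly; otherwise island membership is left empty for
#'   [assign_islands()] to fill from a UCSC track (the default route). The
#'   generic dialect always reads its own optional `island_id` column so
#'   that written tables round-trip.
#' @return A `cpg_annotation` table (see [as_cpg_annotation()]).
#' @export
read_annotation <- function(path,
                            dialect = c("generic", "illumina450k"),
                            col_map = NULL,
                            use_island_column = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  defaults <- switch(dialect,
    generic = list(cpg_id = "cpg_id", chrom = "chrom", pos = "pos",
                   strand = "strand", island_id = "island_id"),
    illumina450k = list(cpg_id = "Name", chrom = "CHR", pos = "MAPINFO",
                        strand = "Strand", island_id = "Islands_Name")
  )
  map <- utils::modifyList(defaults, as.list(col_map %||% list()))
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = "character", data.table = FALSE,
                          na.strings = c("", "NA", "NaN"))
  id_col <- map$cpg_id
  if (!id_col %in% names(dt) && dialect == "illumina450k" && "IlmnID" %in% names(dt))
    id_col <- "IlmnID"
  need <- c(id_col, map$chrom, map$pos, map$strand)
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0)
    stopf("annotation file lacks column(s): %s", paste(miss, collapse = ", "))
  ann <- data.frame(
    cpg_id = dt[[id_col]],
    chrom = dt[[map$chrom]],
    pos = dt[[map$pos]],
    strand = dt[[map$strand]],
    stringsAsFactors = FALSE
  )
  if ((dialect == "generic" || use_island_column) && map$island_id %in% names(dt))
    ann$island_id <- dt[[map$island_id]]
  as_cpg_annotation(ann)
}

#' Write a CpG annotation table
#'
#' Writes the generic tab-separated dialect (missing values as `NA`); reading
#' the file back with [read_annotation()] reproduces the records exactly.
#'
#' @param annot A `cpg_annotation` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  annot <- as_cpg_annotation(annot)
  data.table::fwrite(annot, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Validate a CpG-island interval track
#'
#' @param df Data frame with columns `island_id`, `chrom`, `start`, `end`
#'   (1-based inclusive coordinates).
#' @return The validated track, of class `island_track`.
#' @export
as_island_track <- function(df) {
  req <- c("island_id", "chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stopf("island track is missing required column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(
    island_id = as.character(df$island_id),
    chrom = as.character(df$chrom),
    start = as.integer(df$start),
    end = as.integer(df$end),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end))
    stopf("island track contains non-integer coordinates")
  if (any(out$start < 1)) stopf("island start positions must be >= 1")
  if (any(out$start > out$end)) stopf("island intervals must satisfy start <= end")
  dup <- unique(out$island_id[duplicated(out$island_id)])
  if (length(dup) > 0)
    stopf("duplicate island_id in track: %s", paste(head(dup, 5), collapse = ", "))
  class(out) <- c("island_track", "data.frame")
  out
}

#' Read a UCSC-style CpG island track
#'
#' Parses a tab-separated file in the UCSC `cpgIslandExt` layout
#' (`bin, chrom, chromStart, chromEnd, name, ...`; the leading `bin` column
#' may be absent). UCSC coordinates are 0-based half-open; each record is
#' converted to 1-based inclusive `[chromStart + 1, chromEnd]`. When the name
#' field is not unique across records, identifiers are synthesised as
#' `"chrom:start-end"`.
#'
#' @param path Path to the track file (plain or gzip-compressed).
#' @return An `island_track` table.
#' @export
read_island_track <- function(path) {
  if (!file.exists(path)) stopf("island track file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 4) stopf("island track needs at least 4 tab-separated columns")
  # Detect the optional leading UCSC bin column: with it, columns 3 and 4 are
  # the coordinates; without it they sit in columns 2 and 3.
  first_num <- suppressWarnings(as.numeric(dt[[1]]))
  has_bin <- ncol(dt) >= 5 && !anyNA(first_num) &&
    all(suppressWarnings(!is.na(as.numeric(dt[[3]]))))
  cols <- if (has_bin) 2:5 else 1:4
  chrom <- dt[[cols[1]]]
  s <- suppressWarnings(as.numeric(dt[[cols[2]]]))
  e <- suppressWarnings(as.numeric(dt[[cols[3]]]))
  nm <- dt[[cols[4]]]
  if (anyNA(s) || anyNA(e) || any(s != round(s)) || any(e != round(e)))
    stopf("island track contains non-integer coordinates")
  if (any(s >= e))
    stopf("island track contains records with chromStart >= chromEnd")
  start <- as.integer(s) + 1L
  end <- as.integer(e)
  if (anyNA(nm) || any(nm == "") || anyDuplicated(nm) > 0)
    nm <- sprintf("%s:%d-%d", chrom, start, end)
  as_island_track(data.frame(island_id = nm, chrom = chrom,
                             start = start, end = end,
                             stringsAsFactors = FALSE))
}

#' Write a CpG-island track in UCSC dialect
#'
#' Emits tab-separated `bin, chrom, chromStart, chromEnd, name` records,
#' converting internal 1-based inclusive intervals back to UCSC 0-based
#' half-open coordinates.
#'
#' @param islands An `island_track` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_island_track <- function(islands, path) {
  islands <- as_island_track(islands)
  out <- data.frame(bin = 0L, chrom = islands$chrom,
                    chromStart = islands$start - 1L, chromEnd = islands$end,
                    name = islands$island_id)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign CpGs to CpG islands
#'
#' Sets `island_id` for every CpG whose position lies inside an island
#' interval on the same chromosome (`start <= pos <= end`). CpGs with a
#' missing position or chromosome get no island. A CpG covered by several
#' intervals (possible only in dirty tracks; genuine `cpgIslandExt` tracks do
#' not overlap) is assigned deterministically to the interval with the
#' smallest start (ties: smallest end), with a warning.
#'
#' The operation is idempotent and independent of CpG row order: existing
#' `island_id` values are recomputed from scratch.
#'
#' @param annot A `cpg_annotation` table.
#' @param islands An `island_track` table.
#' @return The annotation with `island_id` filled in.
#' @export
assign_islands <- function(annot, islands) {
  annot <- as_cpg_annotation(annot)
  islands <- as_island_track(islands)
  annot$island_id <- NA_character_
  multi <- 0L
  for (ch in intersect(unique(annot$chrom), unique(islands$chrom))) {
    qi <- which(annot$chrom == ch & !is.na(annot$pos))
    si <- which(islands$chrom == ch)
    if (length(qi) == 0 || length(si) == 0) next
    si <- si[order(islands$start[si], islands$end[si])]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(annot$pos[qi], width = 1L),
      IRanges::IRanges(islands$start[si], islands$end[si])
    )
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) == 0) next
    multi <- multi + sum(duplicated(qh))
    # subjects are pre-sorted by (start, end); the min subject hit per query
    # is the deterministic pick
    first <- tapply(sh, qh, min)
    annot$island_id[qi[as.integer(names(first))]] <-
      islands$island_id[si[as.integer(first)]]
  }
  if (multi > 0)
    warnf("%d CpG(s) overlapped by multiple islands; assigned to the interval with the smallest start", multi)
  annot
}
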