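# Independent brute-force references used to validate the package's
# implementations. These deliberately avoid the data structures and code
# paths of the package: plain loops, all-pairs scans and textbook formulas.

# all-pairs containment scan; multi-overlap resolved by smallest start,
# then smallest end
oracle_assign_islands <- function(annot, islands) {
  out <- rep(NA_character_, nrow(annot))
  for (i in seq_len(nrow(annot))) {
    if (is.na(annot$pos[i]) || is.na(annot$chrom[i])) next
    hits <- which(islands$chrom == annot$chrom[i] &
                    islands$start <= annot$pos[i] &
                    islands$end >= annot$pos[i])
    if (length(hits) == 0) next
    hits <- hits[order(islands$start[hits], islands$end[hits])]
    out[i] <- islands$island_id[hits[1]]
  }
  out
}

# linear scan over all records
oracle_nearest <- function(positions, q) {
  d <- abs(positions - q)
  list(indices = which(d == min(d)), distance = min(d))
}

# naive single-sample imputation: per missing entry, scan all records
oracle_impute_sample <- function(beta, annot, mode = "basic",
                                 neighbor_mode = "tie_average",
                                 island_strand_filter = FALSE) {
  n <- length(beta)
  obs <- !is.na(beta)
  gm <- mean(beta[obs])
  val <- beta
  code <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)

  nn_pick <- function(rec, q) {
    if (neighbor_mode == "flank_average") {
      left <- rec[annot$pos[rec] <= q]
      right <- rec[annot$pos[rec] > q]
      vs <- c()
      nrec <- 0L
      ds <- c()
      if (length(left) > 0) {
        lp <- max(annot$pos[left])
        sel <- left[annot$pos[left] == lp]
        vs <- c(vs, mean(beta[sel])); nrec <- nrec + length(sel); ds <- c(ds, q - lp)
      }
      if (length(right) > 0) {
        rp <- min(annot$pos[right])
        sel <- right[annot$pos[right] == rp]
        vs <- c(vs, mean(beta[sel])); nrec <- nrec + length(sel); ds <- c(ds, rp - q)
      }
      return(list(v = mean(vs), n = nrec, d = min(ds)))
    }
    dd <- abs(annot$pos[rec] - q)
    sel <- rec[dd == min(dd)]
    list(v = mean(beta[sel]), n = length(sel), d = min(dd))
  }

  for (i in which(!obs)) {
    done <- FALSE
    if (mode == "advanced" && !is.na(annot$island_id[i]) && !is.na(annot$pos[i])) {
      rec <- which(obs & !is.na(annot$pos) & !is.na(annot$island_id) &
                     annot$island_id == annot$island_id[i])
      if (island_strand_filter) {
        rec <- if (is.na(annot$strand[i])) integer(0) else
          rec[!is.na(annot$strand[rec]) & annot$strand[rec] == annot$strand[i]]
      }
      if (length(rec) > 0) {
        r <- nn_pick(rec, annot$pos[i])
        val[i] <- r$v
        code[i] <- if (r$n == 1) "ISLAND_NN_UNIQUE" else "ISLAND_NN_TIE_AVG"
        dist[i] <- r$d
        done <- TRUE
      }
    }
    grp_known <- !is.na(annot$chrom[i]) && !is.na(annot$strand[i])
    if (!done && !is.na(annot$pos[i]) && grp_known) {
      rec <- which(obs & !is.na(annot$pos) & !is.na(annot$chrom) & !is.na(annot$strand) &
                     annot$chrom == annot$chrom[i] & annot$strand == annot$strand[i])
      if (length(rec) > 0) {
        r <- nn_pick(rec, annot$pos[i])
        val[i] <- r$v
        code[i] <- if (r$n == 1) "NN_UNIQUE" else "NN_TIE_AVG"
        dist[i] <- r$d
        done <- TRUE
      }
    }
    if (!done && is.na(annot$pos[i]) && grp_known) {
      oid <- which(obs & !is.na(annot$chrom) & !is.na(annot$strand) &
                     annot$chrom == annot$chrom[i] & annot$strand == annot$strand[i])
      if (length(oid) > 0) {
        val[i] <- mean(beta[oid])
        code[i] <- "CHROM_STRAND_MEAN"
        done <- TRUE
      }
    }
    if (!done) {
      val[i] <- gm
      code[i] <- "GENOME_MEAN"
    }
  }
  list(values = val, code = code, nn_distance = dist)
}

# step-by-step simulator of the greedy deletion flowchart, using plain
# floating-point fractions
oracle_greedy <- function(mask) {
  rows <- seq_len(nrow(mask))
  cols <- seq_len(ncol(mask))
  log <- list()
  it <- 0L
  repeat {
    if (length(rows) == 0 || length(cols) == 0) break
    sub <- mask[rows, cols, drop = FALSE]
    pr <- rowMeans(sub)
    pc <- colMeans(sub)
    if (max(pr) == 0) break
    it <- it + 1L
    if (max(pr) >= max(pc)) {
      del <- pr >= max(pc)
      log[[it]] <- list(max_p_r = max(pr), max_p_c = max(pc),
                        axis = "row", n_deleted = sum(del))
      rows <- rows[!del]
    } else {
      del <- pc >= max(pr)
      log[[it]] <- list(max_p_r = max(pr), max_p_c = max(pc),
                        axis = "col", n_deleted = sum(del))
      cols <- cols[!del]
    }
  }
  list(kept_rows = rows, kept_cols = cols, log = log)
}

# textbook signed-rank machinery: midranks of |d| after dropping zeros,
# normal approximation with tie correction and continuity correction
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- w_pos - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(w_pos = w_pos, w_neg = w_neg,
       rank_biserial = (w_pos - w_neg) / (w_pos + w_neg),
       p_value = 2 * stats::pnorm(-abs(z)))
}

oracle_cohens_d <- function(a, b) {
  d <- a - b
  mean(d) / stats::sd(d)
}

# random messy imputation instance: several chromosomes, lattice positions
# (so exact-distance ties actually occur), a sprinkle of missing positions,
# strands and chromosomes, and optional islands
random_instance <- function(n, p_missing = 0.1, n_chrom = 2,
                            with_islands = FALSE, lattice = 10L) {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  pos <- sample.int(max(2L, round(n * lattice / 2)), n, replace = TRUE) * lattice
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom[runif(n) < 0.03] <- NA
  pos[runif(n) < 0.05] <- NA
  strand[runif(n) < 0.03] <- NA
  island_id <- rep(NA_character_, n)
  if (with_islands) {
    # carve islands out of position windows per chromosome
    for (ch in unique(chrom[!is.na(chrom)])) {
      sel <- which(!is.na(chrom) & chrom == ch & !is.na(pos))
      if (length(sel) < 4) next
      cuts <- quantile(pos[sel], c(0.1, 0.3, 0.6, 0.8))
      island_id[sel[pos[sel] >= cuts[1] & pos[sel] <= cuts[2]]] <- paste0(ch, "_islA")
      island_id[sel[pos[sel] >= cuts[3] & pos[sel] <= cuts[4]]] <- paste0(ch, "_islB")
    }
  }
  beta <- round(runif(n), 4)
  beta[sample.int(n, max(1L, round(p_missing * n)))] <- NA
  if (all(is.na(beta))) beta[1] <- 0.5
  list(
    beta = beta,
    annot = as_cpg_annotation(data.frame(
      cpg_id = sprintf("cg%06d", seq_len(n)), chrom = chrom, pos = pos,
      strand = strand, island_id = island_id, stringsAsFactors = FALSE))
  )
}
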