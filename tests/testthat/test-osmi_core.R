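make_annot <- function(chrom, pos, strand = "+", island_id = NA_character_) {
  as_cpg_annotation(data.frame(
    cpg_id = sprintf("cg%03d", seq_along(pos)), chrom = chrom, pos = pos,
    strand = strand, island_id = island_id, stringsAsFactors = FALSE))
}

test_that("nearest-record lookup returns unique minima, both members of a tie, and matches a linear scan", {
  r <- find_nearest_complete(c(100L, 400L), 150L)
  expect_equal(r$indices, 1L)
  expect_equal(r$distance, 50)

  r <- find_nearest_complete(c(100L, 300L), 200L)
  expect_equal(r$indices, c(1L, 2L))
  expect_equal(r$distance, 100)

  expect_error(find_nearest_complete(integer(0), 10L), "no complete record")

  set.seed(11)
  for (rep in 1:5) {
    p <- sort(sample.int(5000, 500, replace = TRUE))  # duplicates included
    for (q in sample.int(5200, 100, replace = TRUE)) {
      got <- find_nearest_complete(p, q)
      expect_equal(got, oracle_nearest(p, q))
    }
  }
})

test_that("single-sample imputation follows the nearest/tie/fallback rules on worked fixtures", {
  # unique nearest neighbour
  a <- make_annot("chr1", c(100L, 150L, 400L))
  r <- impute_sample(c(0.2, NA, 0.9), a)
  expect_equal(r$values[2], 0.2)
  expect_equal(r$code[2], "NN_UNIQUE")
  expect_equal(r$nn_distance[2], 50)

  # exact-distance tie averages both records
  a <- make_annot("chr1", c(100L, 200L, 300L))
  r <- impute_sample(c(0.2, NA, 0.6), a)
  expect_equal(r$values[2], 0.4)
  expect_equal(r$code[2], "NN_TIE_AVG")
  expect_equal(r$nn_distance[2], 100)

  # empty chromosome strand falls back to the genome-wide mean
  a <- make_annot(c("chrA", "chrA", "chrB", "chrB"), c(10L, 20L, 10L, 20L))
  r <- impute_sample(c(NA, NA, 0.3, 0.5), a)
  expect_equal(r$values[1:2], c(0.4, 0.4))
  expect_equal(r$code[1:2], c("GENOME_MEAN", "GENOME_MEAN"))

  # missing position uses the chromosome-strand mean
  a <- make_annot("chr1", c(10L, 50L, NA))
  r <- impute_sample(c(0.1, 0.3, NA), a)
  expect_equal(r$values[3], 0.2)
  expect_equal(r$code[3], "CHROM_STRAND_MEAN")
  expect_true(is.na(r$nn_distance[3]))

  # missing position AND unknown chromosome/strand: genome-wide mean
  a <- make_annot(c("chr1", "chr1", NA), c(10L, 50L, NA))
  r <- impute_sample(c(0.1, 0.5, NA), a)
  expect_equal(r$values[3], 0.3)
  expect_equal(r$code[3], "GENOME_MEAN")

  expect_error(impute_sample(c(NA_real_, NA_real_), make_annot("chr1", c(1L, 2L))),
               "no observed values")
})

test_that("one constructed sample exercises all six provenance codes", {
  annot <- as_cpg_annotation(data.frame(
    cpg_id = sprintf("cg%02d", 1:15),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1",
              "chr2", "chr2", "chr2", "chr2", "chr2",
              "chr3", "chr3", "chr4", "chr4"),
    pos = c(100L, 150L, 400L, 1000L, 1100L, 1200L,
            5000L, 5020L, 6000L, 6100L, 6200L,
            NA, 7000L, 10L, NA),
    strand = "+",
    island_id = c(rep(NA, 6), "I", "I", "J", "J", "J", NA, NA, NA, NA)))
  beta <- c(0.2, NA, 0.9, 0.2, NA, 0.6,
            0.1, NA, 0.3, NA, 0.5,
            NA, NA, 0.15, NA)
  # chr3 carries no observed value at all (genome-mean fallback for both the
  # positioned and the position-less CpG); chr4 has an observed value but the
  # missing CpG lacks a position (chromosome-strand mean)
  r <- impute_sample(beta, annot, mode = "advanced")
  expect_setequal(unique(r$code[!is.na(r$code)]),
                  c("NN_UNIQUE", "NN_TIE_AVG", "ISLAND_NN_UNIQUE",
                    "ISLAND_NN_TIE_AVG", "CHROM_STRAND_MEAN", "GENOME_MEAN"))
  expect_equal(r$code[8], "ISLAND_NN_UNIQUE")
  expect_equal(r$values[8], 0.1)
  expect_equal(r$code[10], "ISLAND_NN_TIE_AVG")
  expect_equal(r$values[10], 0.4)
  gm <- mean(beta, na.rm = TRUE)
  expect_equal(r$values[12], gm)   # no observed value on chr3 +
  expect_equal(r$code[12], "GENOME_MEAN")
  expect_equal(r$values[13], gm)
  expect_equal(r$code[13], "GENOME_MEAN")
  expect_equal(r$values[15], 0.15) # position-less CpG on a strand with data
  expect_equal(r$code[15], "CHROM_STRAND_MEAN")
})

test_that("imputation agrees with the brute-force linear-scan reference on random instances", {
  set.seed(2024)
  for (rep in 1:20) {
    inst <- random_instance(n = sample(c(200, 500, 2000), 1), p_missing = 0.1,
                            with_islands = rep %% 2 == 0)
    for (mode in c("basic", "advanced")) {
      got <- impute_sample(inst$beta, inst$annot, mode = mode)
      ref <- oracle_impute_sample(inst$beta, inst$annot, mode = mode)
      expect_equal(got$values, ref$values, tolerance = 1e-12)
      expect_identical(got$code, ref$code)
      expect_equal(got$nn_distance, ref$nn_distance)
    }
  }
})

test_that("flank-average neighbour mode matches its reference and differs where flanks are asymmetric", {
  set.seed(99)
  inst <- random_instance(n = 800, p_missing = 0.15, with_islands = TRUE)
  for (mode in c("basic", "advanced")) {
    got <- impute_sample(inst$beta, inst$annot, mode = mode,
                         neighbor_mode = "flank_average")
    ref <- oracle_impute_sample(inst$beta, inst$annot, mode = mode,
                                neighbor_mode = "flank_average")
    expect_equal(got$values, ref$values, tolerance = 1e-12)
    expect_identical(got$code, ref$code)
  }
  # asymmetric flanks: tie_average keeps the closer record, flank_average blends
  a <- make_annot("chr1", c(100L, 150L, 400L))
  b <- c(0.2, NA, 0.9)
  expect_equal(impute_sample(b, a)$values[2], 0.2)
  expect_equal(impute_sample(b, a, neighbor_mode = "flank_average")$values[2], 0.55)
})

test_that("method axioms hold on random matrices", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_instance(n = 300, p_missing = 0.2, with_islands = TRUE)
    m <- cbind(inst$beta, round(runif(300), 4), round(runif(300), 4))
    m[sample.int(length(m), 60)] <- NA
    if (all(is.na(m[, 1]))) m[1, 1] <- 0.5
    if (all(is.na(m[, 2]))) m[1, 2] <- 0.5
    if (all(is.na(m[, 3]))) m[1, 3] <- 0.5
    rownames(m) <- inst$annot$cpg_id
    colnames(m) <- c("s1", "s2", "s3")
    r <- impute_matrix(m, inst$annot, mode = "advanced")

    obs <- !is.na(m)
    # observed entries preserved bit-exactly
    expect_identical(r$values[obs], m[obs])
    # no missing entries remain, all within [0, 1]
    expect_false(anyNA(r$values))
    expect_true(all(r$values >= 0 & r$values <= 1))
    # every imputed value lies within the observed range of its own column
    for (j in 1:3) {
      rng <- range(m[, j], na.rm = TRUE)
      expect_true(all(r$values[!obs[, j], j] >= rng[1] &
                        r$values[!obs[, j], j] <= rng[2]))
    }
    # idempotence: re-imputing the completed matrix changes nothing
    r2 <- impute_matrix(r$values, inst$annot, mode = "advanced")
    expect_identical(r2$values, r$values)
    expect_equal(nrow(r2$provenance), 0L)
    # row-permutation invariance
    perm <- sample.int(nrow(m))
    rp <- impute_matrix(m[perm, , drop = FALSE], inst$annot[perm, ], mode = "advanced")
    expect_equal(rp$values, r$values[perm, , drop = FALSE])
    # column independence: a duplicated sample gets identical imputations
    md <- cbind(m, s1bis = m[, 1])
    rd <- impute_matrix(md, inst$annot, mode = "advanced")
    expect_identical(unname(rd$values[, "s1bis"]), unname(rd$values[, "s1"]))
    expect_equal(rd$values[, 1:3], r$values)
  }
})

test_that("advanced OSMI equals basic OSMI wherever the island route is infeasible", {
  set.seed(13)
  inst <- random_instance(n = 1500, p_missing = 0.15, with_islands = TRUE)
  rb <- impute_sample(inst$beta, inst$annot, mode = "basic")
  ra <- impute_sample(inst$beta, inst$annot, mode = "advanced")
  non_island <- !grepl("^ISLAND_", ra$code) | is.na(ra$code)
  expect_equal(ra$values[non_island], rb$values[non_island])
  expect_identical(ra$code[non_island], rb$code[non_island])
})

test_that("a column with no observed values is reported, not fatal", {
  a <- make_annot("chr1", c(10L, 20L))
  m <- matrix(c(0.1, NA, NA, NA), 2, 2,
              dimnames = list(a$cpg_id, c("ok", "empty")))
  r <- impute_matrix(m, a)
  expect_equal(r$failed_samples, "empty")
  expect_false(anyNA(r$values[, "ok"]))
  expect_true(all(is.na(r$values[, "empty"])))
})

test_that("provenance summary counts match a direct recount and are undefined without imputations", {
  a <- make_annot("chr1", c(100L, 110L, 200L, 300L))
  m <- matrix(c(0.2, NA, NA, 0.8,
                0.1, 0.2, 0.3, 0.4), 4, 2,
              dimnames = list(a$cpg_id, c("s1", "s2")))
  r <- impute_matrix(m, a)
  s <- provenance_summary(r, threshold_bp = 50)
  expect_equal(s$pooled$n_imputed, 2L)
  # cg002 imputed from 10 bp away, cg003 from 90/100 bp away
  expect_equal(s$pooled$frac_nn_le_threshold, 0.5)
  expect_equal(s$pooled$frac_mean_fallback, 0)
  expect_true(is.na(s$per_sample$frac_nn_le_threshold[s$per_sample$sample_id == "s2"]))

  set.seed(5)
  inst <- random_instance(n = 400, p_missing = 0.2, with_islands = TRUE)
  mm <- cbind(s1 = inst$beta, s2 = rev(inst$beta))
  rownames(mm) <- inst$annot$cpg_id
  rr <- impute_matrix(mm, inst$annot, mode = "advanced")
  ss <- provenance_summary(rr, threshold_bp = 40)
  p <- rr$provenance
  expect_equal(ss$pooled$n_imputed, nrow(p))
  expect_equal(ss$pooled$frac_nn_le_threshold,
               mean(!is.na(p$nn_distance) & p$nn_distance <= 40))
  expect_equal(ss$pooled$frac_mean_fallback,
               mean(p$code %in% c("CHROM_STRAND_MEAN", "GENOME_MEAN")))
})
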