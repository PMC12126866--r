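# Synthetic methylome generator.
#
# Emulates the three structural features the nearest-neighbour imputation
# exploits: CpG positions clustered into islands (dense inside, sparse in
# the open sea), per-chromosome/strand organisation, and distance-decaying
# co-methylation. The latent field along each chromosome strand is a
# Gaussian AR process with correlation exp(-gap/lambda) between consecutive
# CpGs, which on a line is exactly the exponential covariance kernel
# exp(-d/lambda); region-level logit means (island vs open sea) supply the
# bimodal beta marginals, and the inverse-logit map keeps every value
# strictly inside (0, 1).

#' Build a simulation configuration
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in base pairs.
#' @param n_islands_per_chrom Islands per chromosome.
#' @param island_length_mean Mean island length (bp).
#' @param in_island_gap_mean Mean gap between adjacent in-island CpGs (bp).
#' @param open_sea_gap_mean Mean gap between adjacent open-sea CpGs (bp).
#' @param corr_decay_lambda Correlation length lambda of the latent field
#'   (bp); consecutive CpGs at gap d correlate as `exp(-d / lambda)`.
#' @param island_level_mean_logit Latent (logit-scale) mean inside islands;
#'   the default -2 gives beta ~ 0.12, matching the typically unmethylated
#'   state of island CpGs.
#' @param open_sea_mean_logit Latent mean in the open sea; the default +2
#'   gives beta ~ 0.88 (typically methylated).
#' @param sample_noise_sd Standard deviation of the latent field.
#' @param n_samples Number of independent samples (columns).
#' @param seed Integer seed.
#' @return Validated configuration list of class `osmi_simconfig`.
#' @export
simulation_config <- function(n_chrom = 2L,
                              chrom_length = 1e6,
                              n_islands_per_chrom = 20L,
                              island_length_mean = 600,
                              in_island_gap_mean = 20,
                              open_sea_gap_mean = 1000,
                              corr_decay_lambda = 200,
                              island_level_mean_logit = -2,
                              open_sea_mean_logit = 2,
                              sample_noise_sd = 1,
                              n_samples = 4L,
                              seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
              n_islands_per_chrom = as.integer(n_islands_per_chrom),
              island_length_mean = island_length_mean,
              in_island_gap_mean = in_island_gap_mean,
              open_sea_gap_mean = open_sea_gap_mean,
              corr_decay_lambda = corr_decay_lambda,
              island_level_mean_logit = island_level_mean_logit,
              open_sea_mean_logit = open_sea_mean_logit,
              sample_noise_sd = sample_noise_sd,
              n_samples = as.integer(n_samples), seed = as.integer(seed))
  with(cfg, {
    if (n_chrom < 1 || chrom_length < 1 || n_samples < 1)
      stopf("n_chrom, chrom_length and n_samples must be >= 1")
    if (n_islands_per_chrom < 0) stopf("n_islands_per_chrom must be >= 0")
    if (island_length_mean <= 0 || in_island_gap_mean <= 0 ||
        open_sea_gap_mean <= 0 || corr_decay_lambda <= 0 || sample_noise_sd < 0)
      stopf("lengths, gaps, lambda must be positive; sample_noise_sd >= 0")
  })
  structure(cfg, class = "osmi_simconfig")
}

# mean-g positive integer gaps: 1 + geometric
.rgap <- function(n, mean_gap) {
  if (mean_gap <= 1) return(rep(1L, n))
  1L + rgeom(n, prob = 1 / mean_gap)
}

#' Simulate CpG annotation and island track
#'
#' Places non-overlapping islands uniformly along each chromosome, then lays
#' down CpG positions with geometric gaps whose mean is small inside islands
#' and large outside; strands are assigned at random per CpG. `island_id` is
#' set by construction and is exactly what [assign_islands()] recovers from
#' the emitted track.
#'
#' @param cfg An `osmi_simconfig`.
#' @return List with `annotation` (a `cpg_annotation`) and `islands` (an
#'   `island_track`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "osmi_simconfig"))
  with_seed(cfg$seed, {
    ann <- list()
    isl <- list()
    counter <- 0L
    for (ci in seq_len(cfg$n_chrom)) {
      ch <- paste0("chr", ci)
      k <- cfg$n_islands_per_chrom
      if (k > 0) {
        lens <- pmax(50L, as.integer(round(rexp(k, 1 / cfg$island_length_mean))))
        slack <- cfg$chrom_length - sum(lens) - k  # >= 1 bp between islands
        if (slack < 0)
          stopf("islands do not fit on a %g bp chromosome; reduce n_islands_per_chrom or island_length_mean",
                cfg$chrom_length)
        gaps <- diff(c(0, sort(sample.int(slack + 1, k) - 1L)))
        starts <- cumsum(gaps + 1L) + c(0L, cumsum(lens[-k]))
        ends <- starts + lens - 1L
        isl[[ci]] <- data.frame(
          island_id = sprintf("%s:%d-%d", ch, starts, ends),
          chrom = ch, start = starts, end = ends, stringsAsFactors = FALSE)
      } else {
        starts <- integer(0); ends <- integer(0)
      }
      # walk the chromosome, switching gap regime inside islands
      pos <- integer(0)
      p <- .rgap(1L, cfg$open_sea_gap_mean)
      while (p <= cfg$chrom_length) {
        pos <- c(pos, p)
        inside <- length(starts) > 0 && any(p >= starts & p <= ends)
        p <- p + .rgap(1L, if (inside) cfg$in_island_gap_mean else cfg$open_sea_gap_mean)
      }
      n_cpg <- length(pos)
      iid <- rep(NA_character_, n_cpg)
      if (length(starts) > 0) {
        hit <- findInterval(pos, starts)
        ok <- hit >= 1L & pos <= ends[pmax(hit, 1L)]
        iid[ok] <- isl[[ci]]$island_id[hit[ok]]
      }
      ann[[ci]] <- data.frame(
        cpg_id = sprintf("cg%08d", counter + seq_len(n_cpg)),
        chrom = ch, pos = pos,
        strand = sample(c("+", "-"), n_cpg, replace = TRUE),
        island_id = iid, stringsAsFactors = FALSE)
      counter <- counter + n_cpg
    }
    list(
      annotation = as_cpg_annotation(do.call(rbind, ann)),
      islands = as_island_track(
        if (length(isl) > 0 && cfg$n_islands_per_chrom > 0) do.call(rbind, isl)
        else data.frame(island_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0)))
    )
  })
}

#' Simulate a complete beta-value matrix
#'
#' For every chromosome and every sample independently, draws a
#' standard-normal AR latent field along the sorted CpG positions with
#' step correlation `rho = exp(-gap / lambda)` (the sequential construction
#' `z_i = rho * z_(i-1) + sqrt(1 - rho^2) * eps_i`, which realises the
#' exponential kernel `exp(-d / lambda)` exactly on a line), scales it by
#' `sample_noise_sd`, adds the island or open-sea logit mean, and maps
#' through the inverse logit. All values are strictly inside (0, 1).
#'
#' The field is laid down across both strands of a chromosome because CpG
#' methylation is strand-symmetric; since the exponential kernel restricted
#' to any subset of positions on a line keeps its form, the CpGs of each
#' individual strand also decorrelate as `exp(-d / lambda)`.
#'
#' @param annot `cpg_annotation` from [simulate_annotation()].
#' @param islands Matching `island_track` (only island membership is used,
#'   via `annot$island_id`).
#' @param cfg The `osmi_simconfig` used to build the annotation.
#' @return Complete numeric matrix, CpG rows x sample columns.
#' @export
simulate_beta <- function(annot, islands, cfg) {
  stopifnot(inherits(cfg, "osmi_simconfig"))
  annot <- as_cpg_annotation(annot)
  n <- nrow(annot)
  mu <- ifelse(is.na(annot$island_id),
               cfg$open_sea_mean_logit, cfg$island_level_mean_logit)
  with_seed(cfg$seed + 1L, {
    z <- matrix(0, n, cfg$n_samples)
    for (g in unique(annot$chrom)) {
      idx <- which(annot$chrom == g)
      idx <- idx[order(annot$pos[idx])]
      k <- length(idx)
      rho <- if (k > 1) exp(-diff(annot$pos[idx]) / cfg$corr_decay_lambda) else numeric(0)
      for (s in seq_len(cfg$n_samples)) {
        e <- rnorm(k)
        zz <- numeric(k)
        zz[1] <- e[1]
        if (k > 1) for (i in 2:k) zz[i] <- rho[i - 1] * zz[i - 1] + sqrt(1 - rho[i - 1]^2) * e[i]
        z[idx, s] <- zz
      }
    }
    beta <- plogis(mu + cfg$sample_noise_sd * z)
    dimnames(beta) <- list(annot$cpg_id, sprintf("sample%02d", seq_len(cfg$n_samples)))
    beta
  })
}

#' Simulate a full synthetic methylome
#'
#' Convenience wrapper: [simulate_annotation()] followed by
#' [simulate_beta()].
#'
#' @param cfg An `osmi_simconfig`.
#' @return List with `annotation`, `islands` and `beta`.
#' @export
simulate_methylome <- function(cfg) {
  sim <- simulate_annotation(cfg)
  sim$beta <- simulate_beta(sim$annotation, sim$islands, cfg)
  sim
}
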