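# Synthetic GWAS summary statistics from a known mediation causal diagram
# (exposure -> mediator -> outcome), so every pipeline stage can be
# validated against ground truth.

#' Configuration for the mediation-DAG summary-statistic generator
#'
#' Per SNP j the generator draws a minor-allele frequency, an instrument
#' effect on the exposure `gamma_j` (truncated normal, bounded away from
#' zero so every planted instrument passes genome-wide significance at the
#' configured sample size), and a mediator-specific effect
#' `pi_j ~ N(0, med_effect_sd)` (the mediator's own GWAS signal, without
#' which the mediator's direct effect is not identifiable in
#' multivariable MR). True effects are then
#'
#' * mediator: `alpha * gamma_j + pi_j`
#' * outcome: `direct_true * gamma_j + beta2_true * mediator_j + delta_j`
#'
#' where `delta_j` is horizontal pleiotropy on the outcome (`none`: 0;
#' `balanced`: `N(0, pleiotropy_mag)`; `directional`: constant
#' `pleiotropy_mag`). `n_outliers` randomly chosen SNPs additionally have
#' their outcome effect displaced by `outlier_shift` outcome standard
#' errors. Observed betas add normal noise with per-trait standard error
#' `1/sqrt(2 maf (1-maf) N)` (standardized-trait approximation; binary
#' outcomes are emulated on the log-odds scale with an effective N);
#' `noise_scale = 0` switches sampling noise off while keeping the
#' reported SEs, giving the exact noise-free construction.
#'
#' @param n_snps Number of instruments (>= 4).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param gamma_mean,gamma_sd,gamma_min Instrument-effect distribution:
#'   normal(mean, sd) truncated below at `gamma_min` (all positive).
#' @param alpha True exposure -> mediator effect.
#' @param beta2_true True mediator -> outcome effect.
#' @param direct_true True direct exposure -> outcome effect; the total
#'   effect is `direct_true + alpha * beta2_true`.
#' @param med_effect_sd SD of mediator-specific SNP effects.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mag Pleiotropy magnitude (SD for balanced, constant
#'   shift for directional).
#' @param n_outliers Number of planted outlier SNPs.
#' @param outlier_shift Outlier displacement in outcome-SE units.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param noise_scale Multiplier on the sampling noise (default 1).
#' @param seed RNG seed (required by [simulate_mediation_gwas()]).
#' @return A validated `sim_config`.
#' @export
sim_config <- function(n_snps = 100,
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 1e5,
                       gamma_mean = 0.06, gamma_sd = 0.015, gamma_min = 0.05,
                       alpha = 0.5, beta2_true = -0.8, direct_true = -0.7,
                       med_effect_sd = 0.05,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mag = 0,
                       n_outliers = 0, outlier_shift = 10,
                       maf_range = c(0.1, 0.5),
                       noise_scale = 1, seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snps < 4) {
    ts_error("twostepmr_parameter_error", "n_snps must be at least 4")
  }
  if (any(c(n_exposure, n_mediator, n_outcome) <= 0)) {
    ts_error("twostepmr_parameter_error", "sample sizes must be positive")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    ts_error("twostepmr_parameter_error", "maf_range must lie within (0, 0.5]")
  }
  if (n_outliers > n_snps) {
    ts_error("twostepmr_parameter_error", "n_outliers exceeds n_snps")
  }
  if (gamma_min <= 0 || gamma_sd <= 0) {
    ts_error("twostepmr_parameter_error",
             "gamma_min and gamma_sd must be positive")
  }
  if (noise_scale < 0 || med_effect_sd < 0 || pleiotropy_mag < 0 ||
      outlier_shift < 0) {
    ts_error("twostepmr_parameter_error",
             "noise_scale, med_effect_sd, pleiotropy_mag, outlier_shift must be non-negative")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Truncated normal (lower bound only) by inversion.
rtnorm_lower <- function(n, mean, sd, lower) {
  lo <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1))
}

# Non-palindromic ordered allele pairs for friction-free harmonization.
ALLELE_PAIRS <- rbind(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                      c("C", "T"), c("T", "C"), c("G", "T"), c("T", "G"))

#' Simulate GWAS summary statistics from the mediation DAG
#'
#' @param cfg [sim_config()] with a non-`NULL` seed.
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   ([summary_stat_table()]s sharing SNP ids and alleles) and `truth`, a
#'   `sim_truth` holding the generating parameters: `alpha`, `beta2_true`,
#'   `direct_true`, `total_true = direct_true + alpha * beta2_true`,
#'   `proportion_true = alpha * beta2_true / total_true`, per-SNP true
#'   effects, planted-outlier ids, mafs and per-trait SEs.
#' @export
simulate_mediation_gwas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$seed)) {
    ts_error("twostepmr_parameter_error", "cfg$seed must be set")
  }
  k <- cfg$n_snps
  with_seed(cfg$seed, {
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- rtnorm_lower(k, cfg$gamma_mean, cfg$gamma_sd, cfg$gamma_min)
    med_fx <- stats::rnorm(k, 0, cfg$med_effect_sd)
    delta <- switch(cfg$pleiotropy,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, cfg$pleiotropy_mag),
                    directional = rep(cfg$pleiotropy_mag, k))
    m_true <- cfg$alpha * gamma + med_fx
    o_true <- cfg$direct_true * gamma + cfg$beta2_true * m_true + delta
    het <- 2 * maf * (1 - maf)
    se_x <- 1 / sqrt(het * cfg$n_exposure)
    se_m <- 1 / sqrt(het * cfg$n_mediator)
    se_y <- 1 / sqrt(het * cfg$n_outcome)
    outlier_idx <- if (cfg$n_outliers > 0) sample.int(k, cfg$n_outliers)
                   else integer(0)
    o_true[outlier_idx] <- o_true[outlier_idx] +
      cfg$outlier_shift * se_y[outlier_idx]
    bx <- gamma + cfg$noise_scale * se_x * stats::rnorm(k)
    bm <- m_true + cfg$noise_scale * se_m * stats::rnorm(k)
    bo <- o_true + cfg$noise_scale * se_y * stats::rnorm(k)
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), k, replace = TRUE), ,
                         drop = FALSE]
    snp <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e5 + 2e7 * (seq_len(k) - 1) %/% 22
    base <- data.frame(SNP = snp, CHR = chrom, BP = pos,
                       EA = pair[, 1], OA = pair[, 2], EAF = maf,
                       stringsAsFactors = FALSE)
    mk <- function(beta, se, n, lab) {
      summary_stat_table(cbind(base, data.frame(
        BETA = beta, SE = se, P = pnorm_two(beta / se), N = n)), lab)
    }
    total_true <- cfg$direct_true + cfg$alpha * cfg$beta2_true
    truth <- structure(list(
      alpha = cfg$alpha, beta2_true = cfg$beta2_true,
      direct_true = cfg$direct_true, total_true = total_true,
      proportion_true = cfg$alpha * cfg$beta2_true / total_true,
      gamma = gamma, med_effects = med_fx, pleiotropy = delta,
      mediator_true = m_true, outcome_true = o_true,
      outlier_snps = snp[outlier_idx], maf = maf,
      se_exposure = se_x, se_mediator = se_m, se_outcome = se_y,
      seed = cfg$seed), class = "sim_truth")
    list(exposure = mk(bx, se_x, cfg$n_exposure, "exposure"),
         mediator = mk(bm, se_m, cfg$n_mediator, "mediator"),
         outcome = mk(bo, se_y, cfg$n_outcome, "outcome"),
         truth = truth)
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' Consecutive SNPs are grouped into blocks of `block_size`; within-block
#' squared correlations equal `within_block_r2` (with a small seeded
#' jitter when `seed` is given), between-block correlations are zero.
#'
#' @param positions data.frame with columns `SNP`, `CHR`, `BP` (a
#'   [summary_stat_table()] works).
#' @param block_size SNPs per block (>= 1).
#' @param within_block_r2 Squared correlation within a block, in \[0,1\].
#' @param seed Optional seed for the jitter.
#' @return An [ld_matrix()].
#' @export
simulate_ld_matrix <- function(positions, block_size, within_block_r2,
                               seed = NULL) {
  if (block_size < 1 || block_size != floor(block_size)) {
    ts_error("twostepmr_parameter_error", "block_size must be a positive integer")
  }
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    ts_error("twostepmr_parameter_error", "within_block_r2 must be in [0,1]")
  }
  k <- nrow(positions)
  block <- (seq_len(k) - 1) %/% block_size
  r2 <- outer(block, block, `==`) * within_block_r2
  if (!is.null(seed) && within_block_r2 > 0 && k > 1) {
    jit <- with_seed(seed, matrix(stats::runif(k * k, 0.95, 1), k, k))
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    r2 <- r2 * jit
    r2[r2 > 1] <- 1
  }
  diag(r2) <- 1
  ld_matrix(r2, positions$SNP, chrom = positions$CHR, pos = positions$BP)
}

#' Write a simulated study to disk
#'
#' Writes the three canonical summary-stat TSVs plus the ground truth as
#' JSON.
#'
#' @param sim Result of [simulate_mediation_gwas()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_sim_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.json"))
  write_summary_stats(sim$exposure, paths["exposure"])
  write_summary_stats(sim$mediator, paths["mediator"])
  write_summary_stats(sim$outcome, paths["outcome"])
  jsonlite::write_json(unclass(sim$truth), paths["truth"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
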