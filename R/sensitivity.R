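# Heterogeneity, pleiotropy, outlier and influence diagnostics for a
# univariable MR fit.

heterogeneity_result <- function(statistic, df, flavor) {
  structure(list(statistic = statistic, df = df,
                 pvalue = stats::pchisq(statistic, df, lower.tail = FALSE),
                 flavor = flavor),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("%s: Q=%.4g on %d df, p=%.3g\n",
              x$flavor, x$statistic, x$df, x$pvalue))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_IVW-fixed)^2` with inverse-variance ratio
#' weights `w_j = bx_j^2 / sy_j^2`, on `k - 1` degrees of freedom.
#'
#' @param h [harmonized_set()] with at least 2 SNPs.
#' @return `heterogeneity_result` (flavor `"cochran-ivw"`).
#' @export
cochran_q <- function(h) {
  d <- hs_pair(h)
  if (d$k < 2) {
    ts_error("twostepmr_data_error", "Cochran's Q requires at least 2 SNPs")
  }
  fit <- mr_ivw(h, model = "fixed")
  w <- d$bx^2 / d$sy^2
  q <- sum(w * (d$by / d$bx - fit$beta)^2)
  heterogeneity_result(q, d$k - 1L, "cochran-ivw")
}

#' Rucker's Q heterogeneity statistic
#'
#' Weighted residual sum of squares about the MR-Egger fit on `k - 2`
#' degrees of freedom. Because the Egger fit adds an intercept to the
#' IVW regression, Rucker's Q never exceeds Cochran's Q.
#'
#' @param h [harmonized_set()] with at least 3 SNPs.
#' @return `heterogeneity_result` (flavor `"rucker-egger"`).
#' @export
rucker_q <- function(h) {
  d <- hs_pair(h)
  if (d$k < 3) {
    ts_error("twostepmr_data_error", "Rucker's Q requires at least 3 SNPs")
  }
  f <- egger_fit(h)
  heterogeneity_result(f$rss_w, d$k - 2L, "rucker-egger")
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param h [harmonized_set()] with at least 3 SNPs.
#' @return A `pleiotropy_result`: intercept, SE, two-sided normal p-value.
#' @export
egger_intercept_test <- function(h) {
  f <- egger_fit(h)
  structure(list(intercept = f$intercept, se = f$intercept_se,
                 pvalue = pnorm_two(f$intercept / f$intercept_se)),
            class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept = %.4g (SE %.4g), p = %.3g\n",
              x$intercept, x$se, x$pvalue))
  invisible(x)
}

# Leave-one-out IVW numerators/denominators for a vectorized PRESSO.
loo_ivw_beta <- function(num, den) {
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO outlier detection
#'
#' Global test: the observed inverse-variance weighted residual sum of
#' squares of each SNP against its leave-one-out IVW prediction is
#' compared with an empirical null built by simulating exposure and
#' outcome associations from their stated normal errors under the
#' leave-one-out fits. Outlier test: each SNP's simulated residual
#' distribution yields an empirical tail p-value (`(r+1)/(n_sim+1)`
#' convention); SNPs significant after Bonferroni correction over the
#' tested SNPs are declared outliers. Distortion test: the relative change
#' of the IVW estimate after outlier removal is compared against random
#' removals of the same number of SNPs. SNPs are ordered by identifier
#' internally so results do not depend on input order.
#'
#' @param h [harmonized_set()] with at least 4 SNPs.
#' @param n_sim Number of simulated null datasets (default 1000, minimum
#'   100). Because empirical p-values are floored at `1/(n_sim+1)` and the
#'   outlier test is Bonferroni-corrected over the `k` SNPs, no outlier is
#'   declarable unless `n_sim > k/significance - 1`.
#' @param significance Outlier significance level before Bonferroni
#'   correction (default 0.05).
#' @param seed RNG seed.
#' @return A `presso_result`: `global_rss`, `global_pvalue`,
#'   `outlier_snps` (data.frame of declared outliers with per-SNP
#'   empirical p), `pvalues` (all per-SNP p), `distortion_pvalue` and
#'   `corrected_estimate` (IVW after removal; absent when no outliers).
#' @export
mr_presso <- function(h, n_sim = 1000, significance = 0.05, seed = 42) {
  d <- hs_pair(h)
  if (d$k < 4) {
    ts_error("twostepmr_data_error", "MR-PRESSO requires at least 4 SNPs")
  }
  if (n_sim < 100) {
    ts_error("twostepmr_parameter_error", "n_sim must be at least 100")
  }
  ord <- order(d$snp)
  bx <- d$bx[ord]; sx <- d$sx[ord]; by <- d$by[ord]; sy <- d$sy[ord]
  snp <- d$snp[ord]
  k <- d$k
  w <- 1 / sy^2
  num <- bx * by * w
  den <- bx^2 * w
  b_loo <- loo_ivw_beta(num, den)
  res_obs <- by - b_loo * bx
  rss_j_obs <- w * res_obs^2
  rss_obs <- sum(rss_j_obs)

  sim <- with_seed(seed, {
    BX <- matrix(stats::rnorm(n_sim * k, rep(bx, each = n_sim),
                              rep(sx, each = n_sim)), n_sim, k)
    BY <- matrix(stats::rnorm(n_sim * k, rep(b_loo * bx, each = n_sim),
                              rep(sy, each = n_sim)), n_sim, k)
    W <- matrix(w, n_sim, k, byrow = TRUE)
    NUM <- BX * BY * W
    DEN <- BX^2 * W
    BLOO <- (rowSums(NUM) - NUM) / (rowSums(DEN) - DEN)
    RES2 <- W * (BY - BLOO * BX)^2
    list(rss = rowSums(RES2), res2 = RES2)
  })
  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  p_snp <- (colSums(sim$res2 >= matrix(rss_j_obs, n_sim, k, byrow = TRUE)) + 1) /
    (n_sim + 1)
  p_adj <- pmin(1, p_snp * k)  # Bonferroni over tested SNPs
  is_out <- p_adj < significance
  pvalues <- data.frame(SNP = snp, pvalue = p_snp, pvalue_bonferroni = p_adj,
                        outlier = is_out, stringsAsFactors = FALSE)

  corrected <- NULL
  distortion_p <- NULL
  if (any(is_out)) {
    keep <- !is_out
    h_kept <- harmonized_set(snp[keep], h$traits[c(1, length(h$traits))],
                             cbind(bx[keep], by[keep]),
                             cbind(sx[keep], sy[keep]))
    corrected <- mr_ivw(h_kept, model = "random")
    b_all <- sum(num) / sum(den)
    b_cor <- sum(num[keep]) / sum(den[keep])
    d_obs <- (b_cor - b_all) / abs(b_cor)
    n_out <- sum(is_out)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(k, n_out)
        b_i <- sum(num[-drop]) / sum(den[-drop])
        (b_i - b_all) / abs(b_i)
      }, numeric(1))
    })
    distortion_p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  }
  structure(list(global_rss = rss_obs, global_pvalue = global_p,
                 outlier_snps = pvalues[pvalues$outlier, c("SNP", "pvalue",
                                                           "pvalue_bonferroni")],
                 pvalues = pvalues,
                 distortion_pvalue = distortion_p,
                 corrected_estimate = corrected,
                 n_sim = n_sim, significance = significance, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS=%.4g, global p=%.3g, %d outlier(s)\n",
              x$global_rss, x$global_pvalue, nrow(x$outlier_snps)))
  if (nrow(x$outlier_snps) > 0) {
    cat("  outliers:", paste(x$outlier_snps$SNP, collapse = ", "), "\n")
    cat(sprintf("  distortion p=%.3g; corrected IVW beta=%.4g\n",
                x$distortion_pvalue, x$corrected_estimate$beta))
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn. An exclusion is
#' flagged when it changes the estimate's sign or moves it by more than
#' `flag_multiplier` full-set standard errors.
#'
#' @param h [harmonized_set()].
#' @param flag_multiplier Influence flag threshold in units of the
#'   full-set SE (default 2).
#' @param model IVW model passed through.
#' @return A `loo_result`: data.frame with one row per excluded SNP
#'   (`SNP, beta, se, ci_low, ci_high, pvalue, flag`) plus the full-set
#'   estimate as attribute `full`.
#' @export
leave_one_out <- function(h, flag_multiplier = 2, model = "random") {
  d <- hs_pair(h)
  if (d$k < 3) {
    ts_error("twostepmr_data_error", "leave-one-out requires at least 3 SNPs")
  }
  full <- mr_ivw(h, model = model)
  t_idx <- c(1, length(h$traits))
  rows <- lapply(seq_len(d$k), function(j) {
    hj <- harmonized_set(d$snp[-j], h$traits[t_idx],
                         cbind(d$bx[-j], d$by[-j]),
                         cbind(d$sx[-j], d$sy[-j]))
    e <- mr_ivw(hj, model = model)
    data.frame(SNP = d$snp[j], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               flag = sign(e$beta) != sign(full$beta) ||
                 abs(e$beta - full$beta) > flag_multiplier * full$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  class(out) <- c("loo_result", "data.frame")
  out
}
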