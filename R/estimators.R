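# Univariable two-sample MR estimators. All operate on a harmonized_set
# whose first trait is the exposure and last trait the outcome, and return
# an mr_estimate with a 95% normal-approximation interval (beta +/- 1.96 se)
# and a two-sided normal p-value.

mr_estimate <- function(method, beta, se, n_snp, extras = list()) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pvalue = pnorm_two(beta / se), n_snp = n_snp,
                 extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta=%.4g (SE %.4g), 95%% CI [%.4g, %.4g], p=%.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, n_snp = x$n_snp,
             stringsAsFactors = FALSE)
}

# Exposure/outcome vectors of a pair: first trait vs last trait.
hs_pair <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  t <- length(h$traits)
  if (t < 2) ts_error("twostepmr_data_error", "need exposure and outcome traits")
  list(bx = unname(h$beta[, 1]), sx = unname(h$se[, 1]),
       by = unname(h$beta[, t]), sy = unname(h$se[, t]),
       snp = h$snp_id, k = n_snps(h))
}

#' Per-SNP Wald ratios
#'
#' Ratio estimates `beta_y / beta_x` with first-order standard errors
#' `se_y / |beta_x|` and inverse-variance weights.
#'
#' @param h [harmonized_set()] (exposure first, outcome last).
#' @return data.frame with columns `SNP`, `ratio`, `se`, `weight`.
#' @export
wald_ratios <- function(h) {
  d <- hs_pair(h)
  if (any(d$bx == 0)) {
    ts_error("twostepmr_data_error", "zero exposure beta: Wald ratio undefined")
  }
  data.frame(SNP = d$snp, ratio = d$by / d$bx, se = d$sy / abs(d$bx),
             weight = (d$bx / d$sy)^2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`, the weighted regression
#' of outcome on exposure associations through the origin. The fixed-effect
#' SE is `1/sqrt(sum(bx^2/sy^2))`; the multiplicative random-effects model
#' (default, reflecting heterogeneity) scales it by
#' `sqrt(max(1, Q/(k-1)))` with Q Cochran's statistic about the estimate,
#' so the SE never shrinks below the fixed-effect SE.
#'
#' @param h [harmonized_set()].
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return [`mr_estimate`][wald_ratios] with `extras$Q` and
#'   `extras$dispersion`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- hs_pair(h)
  if (all(d$bx == 0)) {
    ts_error("twostepmr_data_error", "all exposure betas are zero")
  }
  if (d$k == 1) {
    warning("single instrument: IVW degenerates to the Wald ratio",
            call. = FALSE)
    return(mr_estimate("IVW", d$by / d$bx, d$sy / abs(d$bx), 1L,
                       extras = list(model = model, Q = 0, dispersion = 1)))
  }
  w_num <- d$bx * d$by / d$sy^2
  w_den <- d$bx^2 / d$sy^2
  beta <- sum(w_num) / sum(w_den)
  se_fixed <- sqrt(1 / sum(w_den))
  ratio <- d$by / d$bx
  Q <- sum(w_den * (ratio - beta)^2)
  phi <- max(1, Q / (d$k - 1))
  se <- if (model == "random") se_fixed * sqrt(phi) else se_fixed
  mr_estimate("IVW", beta, se, d$k,
              extras = list(model = model, Q = Q, dispersion = phi,
                            se_fixed = se_fixed))
}

# Weighted Egger fit shared by mr_egger, egger_intercept_test, rucker_q.
egger_fit <- function(h) {
  d <- hs_pair(h)
  if (d$k < 3) {
    ts_error("twostepmr_data_error", "MR-Egger requires at least 3 instruments")
  }
  s <- ifelse(d$bx < 0, -1, 1)  # orient so all exposure betas >= 0
  bx <- d$bx * s
  by <- d$by * s
  w <- 1 / d$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  rss_w <- sum(w * stats::residuals(fit)^2)
  sigma2 <- rss_w / (d$k - 2)
  # fixed (known-variance) covariance from the weighted normal equations,
  # then multiplicative dispersion floored at 1: never below the fixed SE
  X <- cbind(1, bx)
  cov_fixed <- solve(crossprod(X, w * X))
  scale <- sqrt(max(1, sigma2))
  cf <- stats::coef(fit)
  list(slope = unname(cf["bx"]),
       slope_se = sqrt(cov_fixed[2, 2]) * scale,
       intercept = unname(cf["(Intercept)"]),
       intercept_se = sqrt(cov_fixed[1, 1]) * scale,
       sigma = sqrt(sigma2), k = d$k,
       rss_w = rss_w,
       bx = bx, by = by, w = w)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations with an
#' intercept (weights `1/sy^2`), after orienting inputs so all exposure
#' betas are non-negative. The slope is the pleiotropy-adjusted causal
#' estimate; the intercept estimates average directional pleiotropy and is
#' stored in `extras` together with its SE and p-value.
#'
#' @param h [harmonized_set()] with at least 3 SNPs.
#' @return [`mr_estimate`][wald_ratios].
#' @export
mr_egger <- function(h) {
  f <- egger_fit(h)
  mr_estimate("Egger", f$slope, f$slope_se, f$k,
              extras = list(intercept = f$intercept,
                            intercept_se = f$intercept_se,
                            intercept_pvalue = pnorm_two(f$intercept / f$intercept_se),
                            dispersion = max(1, f$sigma^2)))
}

# Weighted median of `x` with weights `w`: the value at which the
# normalized cumulative weight crosses 0.5, linearly interpolated between
# the bracketing observations.
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] < 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

#' Weighted median estimator
#'
#' Consistent when at least half the instrument weight comes from valid
#' instruments. The estimate is the inverse-variance weighted median of
#' the per-SNP Wald ratios; the SE comes from a seeded parametric
#' bootstrap resampling the exposure and outcome associations from their
#' stated normal errors.
#'
#' @param h [harmonized_set()] with at least 3 SNPs.
#' @param n_boot Bootstrap resamples (default 1000; fewer than 100 warns).
#' @param seed RNG seed recorded in `extras` (default 42).
#' @return [`mr_estimate`][wald_ratios].
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 42) {
  if (n_boot < 2) {
    ts_error("twostepmr_parameter_error", "n_boot must be at least 2")
  }
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable",
                            call. = FALSE)
  d <- hs_pair(h)
  if (d$k < 3) {
    ts_error("twostepmr_data_error",
             "weighted median requires at least 3 instruments")
  }
  r <- wald_ratios(h)
  beta <- weighted_median_value(r$ratio, r$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(d$k, d$bx, d$sx)
      by <- stats::rnorm(d$k, d$by, d$sy)
      weighted_median_value(by / bx, r$weight)
    }, numeric(1))
  })
  mr_estimate("weighted-median", beta, stats::sd(boots), d$k,
              extras = list(n_boot = n_boot, seed = seed))
}

# Modified Silverman rule-of-thumb bandwidth over the ratio estimates.
mode_bandwidth <- function(ratios) {
  k <- length(ratios)
  s_cand <- c(stats::sd(ratios), stats::mad(ratios))
  s_cand <- s_cand[is.finite(s_cand) & s_cand > 0]
  if (length(s_cand) == 0) return(0)
  0.9 * min(s_cand) / k^(1 / 5)
}

mode_value <- function(ratios, weights, bw, grid_n = 2048) {
  if (length(ratios) == 1 || bw <= 0 || length(unique(ratios)) == 1) {
    return(ratios[which.max(weights)])
  }
  dens <- stats::density(ratios, weights = weights / sum(weights),
                         bw = bw, n = grid_n)
  dens$x[which.max(dens$y)]
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The estimate is the argmax of a normal-kernel smoothed density of the
#' per-SNP Wald ratios: unweighted for the simple mode, inverse-variance
#' weighted for the weighted mode. The bandwidth is `bandwidth_factor`
#' times a modified Silverman rule, `0.9 min(sd, mad) / k^(1/5)`, over the
#' ratio estimates. The SE comes from a seeded parametric bootstrap.
#'
#' @param h [harmonized_set()].
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Positive multiplier of the rule-of-thumb
#'   bandwidth (default 1).
#' @param n_boot,seed Bootstrap settings, as in [mr_weighted_median()].
#' @return [`mr_estimate`][wald_ratios] with `extras$bandwidth`.
#' @export
mr_mode <- function(h, variant = c("simple", "weighted"),
                    bandwidth_factor = 1, n_boot = 1000, seed = 42) {
  variant <- match.arg(variant)
  if (!is.numeric(bandwidth_factor) || bandwidth_factor <= 0) {
    ts_error("twostepmr_parameter_error", "bandwidth_factor must be positive")
  }
  d <- hs_pair(h)
  r <- wald_ratios(h)
  if (d$k == 1) {
    warning("single instrument: mode equals the Wald ratio", call. = FALSE)
    return(mr_estimate(paste0(variant, "-mode"), r$ratio, r$se, 1L,
                       extras = list(bandwidth = 0, seed = seed)))
  }
  wts <- if (variant == "weighted") r$weight else rep(1, d$k)
  bw <- bandwidth_factor * mode_bandwidth(r$ratio)
  beta <- mode_value(r$ratio, wts, bw)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(d$k, d$bx, d$sx)
      by <- stats::rnorm(d$k, d$by, d$sy)
      rb <- by / bx
      mode_value(rb, wts, bandwidth_factor * mode_bandwidth(rb), grid_n = 512)
    }, numeric(1))
  })
  mr_estimate(paste0(variant, "-mode"), beta, stats::sd(boots), d$k,
              extras = list(bandwidth = bw, bandwidth_factor = bandwidth_factor,
                            n_boot = n_boot, seed = seed))
}

# Profile score for RAPS: S(beta) = sum t_j(beta) u_j(beta) with
# t_j = (by - beta bx)/sqrt(sy^2 + beta^2 sx^2) and u_j the derivative
# weight (bx sy^2 + beta by sx^2)/(sy^2 + beta^2 sx^2)^(3/2), i.e. the
# gradient of the profile log-likelihood in beta.
raps_score <- function(beta, bx, sx, by, sy) {
  v <- sy^2 + beta^2 * sx^2
  t_j <- (by - beta * bx) / sqrt(v)
  u_j <- (bx * sy^2 + beta * by * sx^2) / v^1.5
  sum(t_j * u_j)
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Simple (non-robust, no overdispersion) profile-score variant: the
#' estimate solves the profile score equation that accounts for
#' measurement error on both the exposure and outcome associations. The SE
#' comes from the numerical derivative of the score at the root
#' (observed-information approximation); in the limit of vanishing
#' exposure error the estimate and SE coincide with fixed-effect IVW.
#'
#' @param h [harmonized_set()] with at least 3 SNPs and exposure SEs.
#' @return [`mr_estimate`][wald_ratios].
#' @export
mr_raps <- function(h) {
  d <- hs_pair(h)
  if (d$k < 3) {
    ts_error("twostepmr_data_error", "RAPS requires at least 3 instruments")
  }
  score <- function(b) raps_score(b, d$bx, d$sx, d$by, d$sy)
  b0 <- mr_ivw(h, model = "fixed")$beta
  half <- max(1, abs(b0))
  lo <- b0 - half; hi <- b0 + half
  for (i in 1:60) {
    if (sign(score(lo)) != sign(score(hi))) break
    half <- half * 2
    lo <- b0 - half; hi <- b0 + half
  }
  if (sign(score(lo)) == sign(score(hi))) {
    ts_error("twostepmr_convergence_error",
             sprintf("profile score has no sign change on [%.4g, %.4g]", lo, hi))
  }
  root <- stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
  eps <- 1e-6 * max(1, abs(root))
  info <- -(score(root + eps) - score(root - eps)) / (2 * eps)
  if (!is.finite(info) || info <= 0) {
    ts_error("twostepmr_convergence_error",
             "non-positive observed information at the RAPS root")
  }
  mr_estimate("RAPS", root, 1 / sqrt(info), d$k,
              extras = list(robust = FALSE, overdispersion = FALSE))
}

#' Run the full univariable estimator suite
#'
#' @param h [harmonized_set()].
#' @param methods Subset of
#'   `c("IVW","Egger","weighted-median","simple-mode","weighted-mode","RAPS")`.
#' @param ivw_model,n_boot,bandwidth_factor,seed Estimator settings.
#' @return A tidy data.frame, one row per method, with columns
#'   `method, beta, se, ci_low, ci_high, pvalue, n_snp`.
#' @export
mr_all <- function(h, methods = c("IVW", "Egger", "weighted-median",
                                  "simple-mode", "weighted-mode", "RAPS"),
                   ivw_model = "random", n_boot = 1000,
                   bandwidth_factor = 1, seed = 42) {
  run <- list(
    "IVW" = function() mr_ivw(h, model = ivw_model),
    "Egger" = function() mr_egger(h),
    "weighted-median" = function() mr_weighted_median(h, n_boot, seed),
    "simple-mode" = function() mr_mode(h, "simple", bandwidth_factor,
                                       n_boot, seed),
    "weighted-mode" = function() mr_mode(h, "weighted", bandwidth_factor,
                                         n_boot, seed),
    "RAPS" = function() mr_raps(h))
  methods <- match.arg(methods, names(run), several.ok = TRUE)
  do.call(rbind, lapply(methods, function(m) as.data.frame(run[[m]]())))
}
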