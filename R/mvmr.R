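# Multivariable MR: joint weighted regression of outcome associations on
# several exposures' associations, estimating each mediator's direct
# effect adjusted for the primary exposure.

#' Multivariable IVW estimator
#'
#' Weighted regression (weights `1/sy^2`) of the outcome betas on the
#' matrix of exposure betas with no intercept. Under the multiplicative
#' random-effects model (default) coefficient SEs are scaled by
#' `sqrt(max(1, Q/(k - p)))` with `p` predictors and Q the weighted
#' residual sum of squares, so they never shrink below the fixed-effect
#' SEs. Exposure columns with no instrument signal (all-zero betas) get an
#' `NA` coefficient with a warning; near-collinear column pairs raise an
#' error naming the offending traits.
#'
#' @param h [harmonized_set()] whose last trait is the outcome and all
#'   preceding traits are exposures (primary exposure first, mediator(s)
#'   after).
#' @param model `"random"` or `"fixed"`.
#' @param condition_limit Condition-number threshold for the collinearity
#'   check (default 1e8).
#' @return An `mvmr_result`: data.frame with one row per exposure
#'   (`exposure, beta, se, ci_low, ci_high, pvalue`), plus `n_snp`,
#'   `model` and `Q` attributes.
#' @export
mvmr_ivw <- function(h, model = c("random", "fixed"),
                     condition_limit = 1e8) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonized_set"))
  t_n <- length(h$traits)
  if (t_n < 3) {
    ts_error("twostepmr_data_error",
             "multivariable MR needs at least 2 exposures plus an outcome")
  }
  X_full <- h$beta[, -t_n, drop = FALSE]
  y <- h$beta[, t_n]
  w <- 1 / h$se[, t_n]^2
  k <- n_snps(h)
  labels <- h$traits[-t_n]
  active <- colSums(X_full != 0) > 0
  if (any(!active)) {
    warning(sprintf("exposure(s) with no instrument signal dropped from fit: %s",
                    paste(labels[!active], collapse = ", ")), call. = FALSE)
  }
  X <- X_full[, active, drop = FALSE]
  p <- ncol(X)
  if (k < p + 1) {
    ts_error("twostepmr_data_error",
             sprintf("need at least %d SNPs for %d exposures", p + 1, p))
  }
  Xw <- sqrt(w) * X
  if (p > 1) {
    if (kappa(Xw, exact = TRUE) > condition_limit) {
      cors <- abs(stats::cor(X))
      diag(cors) <- 0
      worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      ts_error("twostepmr_data_error",
               sprintf("collinear exposure columns: %s and %s",
                       labels[active][worst[1]], labels[active][worst[2]]))
    }
  }
  fit <- stats::lm(y ~ 0 + X, weights = w)
  Q <- sum(w * stats::residuals(fit)^2)
  sigma2 <- Q / (k - p)
  cov_fixed <- solve(crossprod(X, w * X))
  scale <- if (model == "random") sqrt(max(1, sigma2)) else 1
  beta <- se <- rep(NA_real_, length(labels))
  beta[active] <- unname(stats::coef(fit))
  se[active] <- sqrt(diag(cov_fixed)) * scale
  out <- data.frame(exposure = labels, beta = beta, se = se,
                    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                    pvalue = ifelse(is.na(beta), NA_real_,
                                    pnorm_two(beta / se)),
                    stringsAsFactors = FALSE)
  attr(out, "n_snp") <- k
  attr(out, "model") <- model
  attr(out, "Q") <- Q
  class(out) <- c("mvmr_result", "data.frame")
  out
}

#' Conditional instrument-strength diagnostic
#'
#' For each exposure, regresses its instrument associations on the other
#' exposures' associations (weights from that exposure's SEs) and reports
#' the mean chi-square of the residual instrument signal — an
#' approximation to the conditional F statistic quantifying how much
#' independent instrument strength each exposure retains. Reported as a
#' diagnostic only; nothing is gated on it.
#'
#' @param h [harmonized_set()] as for [mvmr_ivw()].
#' @return data.frame with columns `exposure` and `conditional_f`.
#' @export
mvmr_conditional_f <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  t_n <- length(h$traits)
  if (t_n < 3) {
    ts_error("twostepmr_data_error", "needs at least 2 exposures")
  }
  X <- h$beta[, -t_n, drop = FALSE]
  S <- h$se[, -t_n, drop = FALSE]
  p <- ncol(X)
  f <- vapply(seq_len(p), function(a) {
    others <- X[, -a, drop = FALSE]
    wa <- 1 / S[, a]^2
    r <- stats::residuals(stats::lm(X[, a] ~ 0 + others, weights = wa))
    mean(r^2 * wa)
  }, numeric(1))
  data.frame(exposure = h$traits[-t_n], conditional_f = f,
             stringsAsFactors = FALSE)
}
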