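# Product-of-coefficients mediation decomposition with delta-method CIs.
# beta0: total effect exposure -> outcome; beta1: exposure -> mediator;
# beta2: mediator -> outcome adjusted for the exposure (from MVMR).

#' Two-step mediation decomposition
#'
#' Indirect effect = `beta1 * beta2` (product of coefficients); direct
#' effect = `beta0 - indirect`; proportion mediated
#' `P = (beta1 * beta2) / beta0`. The proportion's standard error uses the
#' first-order delta method for a product over a ratio of independent
#' estimates, `SE(P) = |P| sqrt((se1/beta1)^2 + (se2/beta2)^2 +
#' (se0/beta0)^2)`, and the 95% interval is `P +/- 1.96 SE(P)`. Results
#' are flagged (not truncated) when the indirect and total effects have
#' opposite signs or the proportion falls outside \[0,1\].
#'
#' All arguments are vectorized; `label` carries mediator/outcome
#' identifiers through to the result.
#'
#' @param beta1,se1 Exposure -> mediator effect and SE.
#' @param beta2,se2 Mediator -> outcome effect (exposure-adjusted) and SE.
#' @param beta0,se0 Total exposure -> outcome effect and SE.
#' @param label Optional row labels.
#' @return A `mediation_result` data.frame: input coefficients, `indirect`,
#'   `indirect_se`, `direct`, `proportion`, `proportion_se`, `ci_low`,
#'   `ci_high`, `pvalue` (two-sided normal on P/SE), and logical flags
#'   `flag_sign` (indirect and total effects disagree in sign),
#'   `flag_range` (proportion outside \[0,1\]) and `flag_null_path`
#'   (`beta1` or `beta2` is zero, so P = 0 with the SE from the surviving
#'   terms). The identity `indirect + direct = beta0` holds exactly.
#' @export
mediate <- function(beta1, se1, beta2, se2, beta0, se0, label = NULL) {
  n <- max(lengths(list(beta1, se1, beta2, se2, beta0, se0)))
  args <- lapply(list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                      beta0 = beta0, se0 = se0), rep_len, n)
  if (any(args$se1 <= 0) || any(args$se2 <= 0) || any(args$se0 <= 0)) {
    ts_error("twostepmr_parameter_error", "all SEs must be positive")
  }
  if (any(args$beta0 == 0)) {
    ts_error("twostepmr_parameter_error",
             "beta0 = 0: proportion mediated is undefined")
  }
  with(args, {
    indirect <- beta1 * beta2
    indirect_se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
    direct <- beta0 - indirect
    proportion <- indirect / beta0
    rel1 <- ifelse(beta1 == 0, 0, (se1 / beta1)^2)
    rel2 <- ifelse(beta2 == 0, 0, (se2 / beta2)^2)
    rel0 <- (se0 / beta0)^2
    proportion_se <- ifelse(
      indirect == 0,
      indirect_se / abs(beta0),  # limiting SE from the surviving terms
      abs(proportion) * sqrt(rel1 + rel2 + rel0))
    null_path <- beta1 == 0 | beta2 == 0
    out <- data.frame(
      label = label %||% as.character(seq_len(n)),
      beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
      beta0 = beta0, se0 = se0,
      indirect = indirect, indirect_se = indirect_se, direct = direct,
      proportion = proportion, proportion_se = proportion_se,
      ci_low = proportion - Z95 * proportion_se,
      ci_high = proportion + Z95 * proportion_se,
      pvalue = ifelse(proportion_se > 0,
                      pnorm_two(proportion / proportion_se), 1),
      flag_sign = !null_path & sign(indirect) != sign(beta0),
      flag_range = proportion < 0 | proportion > 1,
      flag_null_path = null_path,
      stringsAsFactors = FALSE)
    class(out) <- c("mediation_result", "data.frame")
    out
  })
}

#' Mediation decomposition from a coefficient-triples table
#'
#' Accepts a data.frame or a tab-separated file with columns
#' `mediator`, `outcome`, `beta1`, `se1`, `beta2`, `se2`, `beta0`, `se0`
#' (one row per mediator-outcome pair) and returns the mediation
#' decomposition with percentage columns rounded to one decimal, shaped
#' like a published mediation summary table.
#'
#' @param x data.frame or path to a TSV of coefficient triples.
#' @return A `mediation_result` with additional columns `mediator`,
#'   `outcome`, `proportion_pct`, `ci_low_pct`, `ci_high_pct` (one-decimal
#'   percentages) and `display` (formatted `"P% (lo%, hi%)"`).
#' @export
mediate_table <- function(x) {
  if (is.character(x)) {
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  }
  need <- c("mediator", "outcome", "beta1", "se1", "beta2", "se2",
            "beta0", "se0")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    ts_error("twostepmr_format_error",
             sprintf("coefficient table lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  res <- mediate(x$beta1, x$se1, x$beta2, x$se2, x$beta0, x$se0,
                 label = paste(x$mediator, x$outcome, sep = " -> "))
  res$mediator <- x$mediator
  res$outcome <- x$outcome
  res$proportion_pct <- round(100 * res$proportion, 1)
  res$ci_low_pct <- round(100 * res$ci_low, 1)
  res$ci_high_pct <- round(100 * res$ci_high, 1)
  res$display <- sprintf("%.1f%% (%.1f%%, %.1f%%)", res$proportion_pct,
                         res$ci_low_pct, res$ci_high_pct)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`); input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in (0,1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    ts_error("twostepmr_parameter_error", "p-values must lie in (0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
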