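# Instrument selection: genome-wide significance filtering, greedy LD
# clumping, and instrument-strength metrics (per-SNP R^2, cumulative R^2,
# F statistic).

#' Construct an LD matrix object
#'
#' @param r2 Square symmetric matrix of squared correlations with unit
#'   diagonal and entries in \[0,1\].
#' @param snp_id SNP identifiers, one per row/column of `r2`.
#' @param chrom,pos Optional per-SNP coordinates.
#' @return An `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_id, chrom = NULL, pos = NULL) {
  r2 <- as.matrix(r2)
  k <- length(snp_id)
  if (nrow(r2) != k || ncol(r2) != k) {
    ts_error("twostepmr_parameter_error", "r2 dimensions must match snp_id")
  }
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE) ||
      max(abs(r2 - t(r2))) > 1e-8 ||
      max(abs(diag(r2) - 1)) > 1e-8) {
    ts_error("twostepmr_parameter_error",
             "r2 must be symmetric with unit diagonal and entries in [0,1]")
  }
  dimnames(r2) <- list(snp_id, snp_id)
  structure(list(snp_id = as.character(snp_id), r2 = r2,
                 chrom = chrom, pos = pos),
            class = "ld_matrix")
}

#' Select instruments by p-value threshold
#'
#' Retains rows with `P` strictly below `threshold` (default the
#' genome-wide significance level 5e-8), preserving input order.
#'
#' @param table [summary_stat_table()]
#' @param threshold Significance level in (0,1).
#' @return Filtered [summary_stat_table()].
#' @export
select_by_pvalue <- function(table, threshold = 5e-8) {
  stopifnot(inherits(table, "summary_stat_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    ts_error("twostepmr_parameter_error", "threshold must be in (0,1)")
  }
  out <- table[table$P < threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_label = trait_label(table),
            class = class(table))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as index
#' (ties broken by chromosome, position, then identifier) and removes all
#' remaining SNPs on the same chromosome within `window_kb` of it whose
#' squared correlation with it exceeds `r2_threshold`. The retained set is
#' the index SNPs, returned in input order. SNP pairs absent from `ld` are
#' treated as independent; such SNPs are listed in the
#' `assumed_independent` attribute.
#'
#' @param table [summary_stat_table()]
#' @param ld Optional [ld_matrix()]; `NULL` treats all SNPs as independent.
#' @param r2_threshold Squared-correlation removal threshold (default
#'   0.001: retain only pairs with r^2 <= 0.001).
#' @param window_kb Two-sided window in kilobases (default 10000).
#' @return Clumped [summary_stat_table()].
#' @export
ld_clump <- function(table, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(table, "summary_stat_table"))
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold > 1) {
    ts_error("twostepmr_parameter_error", "r2_threshold must be in [0,1]")
  }
  if (!is.numeric(window_kb) || window_kb < 0) {
    ts_error("twostepmr_parameter_error", "window_kb must be non-negative")
  }
  k <- nrow(table)
  if (k == 0) return(table)
  in_ld <- if (is.null(ld)) rep(FALSE, k) else table$SNP %in% ld$snp_id
  ord <- order(table$P, table$CHR, table$BP, table$SNP)
  remaining <- ord
  kept <- integer(0)
  window_bp <- window_kb * 1000
  while (length(remaining) > 0) {
    i <- remaining[1]
    kept <- c(kept, i)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- table$CHR[remaining] == table$CHR[i]
    near <- same_chr & abs(table$BP[remaining] - table$BP[i]) <= window_bp
    r2_with_index <- rep(0, length(remaining))
    if (!is.null(ld) && in_ld[i]) {
      j_ld <- in_ld[remaining]
      if (any(j_ld)) {
        r2_with_index[j_ld] <- ld$r2[table$SNP[i], table$SNP[remaining[j_ld]]]
      }
    }
    remove <- near & r2_with_index > r2_threshold
    remaining <- remaining[!remove]
  }
  kept <- sort(kept)  # input order
  out <- table[kept, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, trait_label = trait_label(table),
                   class = class(table))
  attr(out, "assumed_independent") <- table$SNP[kept][!in_ld[kept]]
  out
}

#' Per-SNP explained-variance fraction
#'
#' Computes `R^2 = (2 EAF (1-EAF) beta^2) / (2 EAF (1-EAF) beta^2 +
#' 2 EAF (1-EAF) N SE^2)` per SNP. The frequency factor cancels
#' algebraically, so the value equals `beta^2 / (beta^2 + N SE^2)`; both
#' forms agree to machine precision. SNPs with missing EAF cannot
#' contribute and yield `NA` with a warning.
#'
#' @param eaf,beta,se,n Numeric vectors (recycled to a common length).
#' @return Numeric vector of explained-variance fractions in (0,1).
#' @export
per_snp_r2 <- function(eaf, beta, se, n) {
  if (any(!is.na(se) & se <= 0) || any(!is.na(n) & n <= 0)) {
    ts_error("twostepmr_parameter_error", "se and n must be positive")
  }
  num <- 2 * eaf * (1 - eaf) * beta^2
  den <- num + 2 * eaf * (1 - eaf) * n * se^2
  r2 <- num / den
  if (anyNA(eaf)) {
    warning("cannot compute per-SNP R^2 for record(s) with missing EAF; NA returned",
            call. = FALSE)
    r2[is.na(eaf)] <- NA_real_
  }
  r2
}

#' Instrument-set F statistic
#'
#' `F = R^2 (N - K - 1) / (K (1 - R^2))` where `R^2` is the cumulative
#' explained variance of the `K` selected SNPs and `N` the exposure GWAS
#' sample size. Sets with `F < 10` are conventionally flagged as weak.
#'
#' @param r2 Cumulative explained-variance fraction in \[0,1).
#' @param n Sample size (must exceed `k + 1`).
#' @param k Number of instruments.
#' @return Non-negative F statistic.
#' @export
f_statistic <- function(r2, n, k) {
  if (any(r2 < 0 | r2 >= 1)) {
    ts_error("twostepmr_parameter_error", "r2 must be in [0,1)")
  }
  if (any(n <= k + 1)) {
    ts_error("twostepmr_parameter_error", "need N > K + 1")
  }
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Instrument-strength summary for a selected SNP set
#'
#' @param table [summary_stat_table()] of the selected instruments
#'   (exposure associations).
#' @param f_min Weak-instrument flag threshold (default 10).
#' @return An `instrument_set`: SNP ids, per-SNP R^2, cumulative R^2, F,
#'   K, N, and a `weak` flag (`f_stat < f_min`). SNPs with missing EAF are
#'   excluded from R^2/F and listed in `no_eaf`.
#' @export
instrument_strength <- function(table, f_min = 10) {
  stopifnot(inherits(table, "summary_stat_table"))
  k <- nrow(table)
  if (k == 0) {
    ts_error("twostepmr_data_error", "no instruments to summarize")
  }
  r2 <- suppressWarnings(per_snp_r2(table$EAF, table$BETA, table$SE, table$N))
  cum <- sum(r2, na.rm = TRUE)
  n <- stats::median(table$N)
  f <- f_statistic(cum, n, k)
  # single-SNP F (K = 1) as an optional per-SNP weak-instrument screen
  per_f <- ifelse(is.na(r2), NA_real_, r2 * (table$N - 2) / (1 - r2))
  structure(list(snp_id = table$SNP, per_snp_r2 = r2, per_snp_f = per_f,
                 cumulative_r2 = cum, f_stat = f, k = k, n = n,
                 weak = f < f_min, weak_snps = table$SNP[!is.na(per_f) &
                                                           per_f < f_min],
                 f_min = f_min, no_eaf = table$SNP[is.na(r2)]),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: K=%d, N=%g, cumulative R^2=%.4g, F=%.1f%s\n",
              x$k, x$n, x$cumulative_r2, x$f_stat,
              if (x$weak) sprintf(" [WEAK: F < %g]", x$f_min) else ""))
  invisible(x)
}
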