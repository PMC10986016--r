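# Shared fixture builders and independent oracles.

# Build a two-trait harmonized set directly from effect vectors.
make_pair <- function(bx, by, sx = 0.01, sy = 0.01,
                      snp = sprintf("rs%03d", seq_along(bx))) {
  k <- length(bx)
  harmonized_set(snp, c("exposure", "outcome"),
                 beta = cbind(bx, by),
                 se = cbind(rep_len(sx, k), rep_len(sy, k)))
}

# Build a summary-stat data.frame with sensible defaults.
make_sumstats <- function(n = 5, SNP = sprintf("rs%d", seq_len(n)),
                          CHR = rep("1", n), BP = seq_len(n) * 1000,
                          EA = rep("A", n), OA = rep("G", n),
                          EAF = rep(0.3, n), BETA = rep(0.1, n),
                          SE = rep(0.01, n), P = rep(1e-10, n),
                          N = rep(1e5, n)) {
  data.frame(SNP = SNP, CHR = CHR, BP = BP, EA = EA, OA = OA, EAF = EAF,
             BETA = BETA, SE = SE, P = P, N = N, stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# Weighted least squares through the origin, explicit closed form.
oracle_wls_origin <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  list(beta = beta, se = sqrt(1 / sum(w * x^2)))
}

# Two-parameter weighted least squares via explicit normal equations.
oracle_wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  xtwx <- t(X) %*% (w * X)
  coef <- solve(xtwx, t(X) %*% (w * y))
  list(intercept = coef[1], slope = coef[2],
       cov_fixed = solve(xtwx))
}

# Multi-column weighted least squares without intercept.
oracle_wls_multi <- function(X, y, w) {
  xtwx <- t(X) %*% (w * X)
  coef <- solve(xtwx, t(X) %*% (w * y))
  list(coef = drop(coef), cov_fixed = solve(xtwx))
}

# Brute-force greedy clump reference: independent re-implementation
# working on explicit candidate lists (no early-removal bookkeeping).
oracle_clump <- function(tab, ld, r2_threshold, window_kb) {
  avail <- seq_len(nrow(tab))
  kept <- integer(0)
  while (length(avail) > 0) {
    o <- avail[order(tab$P[avail], tab$CHR[avail], tab$BP[avail],
                     tab$SNP[avail])]
    idx <- o[1]
    kept <- c(kept, idx)
    drop <- vapply(avail, function(j) {
      if (j == idx) return(TRUE)
      if (tab$CHR[j] != tab$CHR[idx]) return(FALSE)
      if (abs(tab$BP[j] - tab$BP[idx]) > window_kb * 1000) return(FALSE)
      r2 <- if (!is.null(ld) && tab$SNP[j] %in% ld$snp_id &&
                tab$SNP[idx] %in% ld$snp_id)
        ld$r2[tab$SNP[idx], tab$SNP[j]] else 0
      r2 > r2_threshold
    }, logical(1))
    avail <- avail[!drop]
  }
  sort(kept)
}

# Exhaustive harmonization oracle for a single SNP: enumerates the action
# by explicit case analysis on allele configuration and frequencies.
oracle_harmonize_one <- function(ea_x, oa_x, eaf_x, ea_o, oa_o, eaf_o,
                                 limit = 0.42) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pal <- oa_x == comp[[ea_x]]
  configs <- list(
    same = c(ea_x, oa_x), swap = c(oa_x, ea_x),
    flip = c(comp[[ea_x]], comp[[oa_x]]),
    flipswap = c(comp[[oa_x]], comp[[ea_x]]))
  match_cfg <- names(Filter(function(cc) cc[1] == ea_o && cc[2] == oa_o,
                            configs))
  if (length(match_cfg) == 0) return(list(action = "dropped-mismatch"))
  if (!pal) {
    if (any(match_cfg %in% c("same", "flip"))) return(list(action = "keep"))
    return(list(action = "flip"))
  }
  # palindromic: label-align, then decide strand from frequencies
  lab_swap <- ea_o == oa_x
  f <- if (lab_swap) 1 - eaf_o else eaf_o
  clear <- function(x) !is.na(x) && (x < limit || x > 1 - limit)
  if (!clear(eaf_x) || !clear(f)) return(list(action = "dropped-palindromic"))
  same_side <- (eaf_x < limit) == (f < limit)
  net_flip <- xor(lab_swap, !same_side)
  list(action = if (net_flip) "flip" else "keep")
}
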