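# Shared internal helpers.

# 95% CI multiplier used throughout (normal approximation).
Z95 <- 1.96

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured errors so callers can distinguish parameter, data and
# convergence failures.
ts_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "twostepmr_error", "error")))
}

pnorm_two <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  # p-values of exactly 0 are avoided (downstream contracts need (0,1])
  pmax(p, .Machine$double.xmin)
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded estimators do not perturb an enclosing
# simulation stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# DNA complement for strand handling.
allele_complement <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic_pair <- function(a1, a2) {
  a2 == allele_complement(a1)
}
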