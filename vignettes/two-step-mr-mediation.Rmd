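---
title: "Two-step two-sample MR mediation: models, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step two-sample MR mediation: models, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepmr)
```

## The problem

Low birth weight is associated with adult type 2 diabetes (T2DM), and
circulating fatty-acid traits are plausible intermediates. With only GWAS
summary statistics available — one GWAS for the exposure (birth weight),
one per mediator (fatty-acid traits), one per outcome (T2DM and glycemic
traits) — a *two-sample* Mendelian randomization design treats genetic
variants as instruments for the exposure, and a *two-step* extension
decomposes the exposure's total effect on the outcome into a part running
through each mediator and a direct remainder.

Three coefficients drive the decomposition:

* $\beta_0$ — total effect of exposure on outcome (univariable MR);
* $\beta_1$ — effect of exposure on the mediator (univariable MR);
* $\beta_2$ — effect of the mediator on the outcome *adjusted for the
  exposure* (multivariable MR).

The indirect (mediated) effect is the product of coefficients
$\beta_1\beta_2$, the direct effect is $\beta_0 - \beta_1\beta_2$, and the
proportion mediated is $P = \beta_1\beta_2/\beta_0$.

## Confidence interval for the proportion mediated

`mediate()` uses the first-order delta method for a product over a ratio
of (assumed independent) estimates:

$$\mathrm{SE}(P) = |P|\sqrt{\left(\frac{s_1}{\beta_1}\right)^2 +
\left(\frac{s_2}{\beta_2}\right)^2 + \left(\frac{s_0}{\beta_0}\right)^2},
\qquad \mathrm{CI} = P \pm 1.96\,\mathrm{SE}(P).$$

This three-term relative-variance form is the unique standard variant
that reproduces the published interval bounds from the published SEs at
one-decimal precision; it was verified against those bounds before any
code was written. Two caveats are inherent and flagged rather than
hidden: $\beta_0$ and $\beta_2$ both involve the outcome GWAS, so the
independence assumption is an approximation; and when the indirect and
total effects disagree in sign, or $P \notin [0,1]$, the result carries
`flag_sign` / `flag_range` instead of being truncated, since the source
analysis reports no truncation rule. A proportion recomputed from
coefficients that were themselves rounded to three decimals can differ
from a published one-decimal percentage by one unit in the last digit;
the tests therefore require agreement within 0.1 percentage points.

```{r}
mediate(0.107, 0.026, -0.819, 0.246, -1.113, 0.235)[,
  c("indirect", "direct", "proportion", "ci_low", "ci_high")]
```

## Instrument selection

Instruments are SNPs with exposure association $p < 5\times10^{-8}$
(strict inequality), pruned by greedy LD clumping: the most significant
remaining SNP indexes a clump and removes all SNPs within 10,000 kb on
the same chromosome with $r^2 > 0.001$; ties on p-value break by
chromosome, position, then identifier so the procedure is deterministic.
Instrument strength uses the explained-variance formula

$$R^2_j = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
 2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,\mathrm{SE}^2}$$

(the frequency factor cancels algebraically; both forms are computed and
tested for agreement), summed over the selected set, and
$F = R^2(N-K-1)/(K(1-R^2))$. Whether a weak-instrument rule of $F<10$
discards individual SNPs or whole sets is ambiguous in common usage; the
package flags the *set* (`instrument_strength()$weak`) and additionally
reports single-SNP F values (`per_snp_f`, the $K=1$ version of the same
formula) so a per-SNP screen is available without being imposed.

## Harmonization

All traits are aligned to the exposure's effect allele (the exposure
defines the instrument direction). Swapped alleles — on either strand —
negate the beta and reflect the allele frequency. Palindromic SNPs (A/T,
G/C) cannot be resolved from allele labels; strand is inferred from
allele frequency when both frequencies are outside
$[0.42, 0.58]$ (the conventional two-sample MR band; the limit is a
parameter), with same-side frequencies read as same-strand and
opposite-side as flipped, and the SNP dropped otherwise. Every input SNP
receives a disposition in the `drop_log`
(`kept`/`flipped`/`dropped-palindromic`/`dropped-missing`/`dropped-mismatch`),
and harmonization is idempotent.

## Estimators

All univariable estimators consume a `harmonized_set` (exposure first,
outcome last) and report a normal-approximation 95% interval
$\beta \pm 1.96\,\mathrm{SE}$ with two-sided normal p-values.

* **IVW** (principal method): $\hat\beta = \sum \beta_{xj}\beta_{yj}/\sigma_{yj}^2
  \big/ \sum \beta_{xj}^2/\sigma_{yj}^2$. The default is the
  multiplicative random-effects model: the fixed-effect SE is scaled by
  $\sqrt{\max(1, Q/(k-1))}$, never shrinking below the fixed SE, which
  matches the heterogeneity observed in the source analysis.
* **MR-Egger**: weighted regression with intercept after orienting all
  exposure betas non-negative; the intercept estimates average
  directional pleiotropy. The same dispersion floor applies.
* **Weighted median**: the Wald-ratio value at which normalized
  cumulative inverse-variance weights cross 0.5, interpolated between
  bracketing SNPs; SE by seeded parametric bootstrap (default 1000
  resamples, seed recorded in the output).
* **Simple/weighted mode**: argmax of a normal-kernel density of the
  ratios (unweighted / inverse-variance weighted), bandwidth =
  `bandwidth_factor` × the modified Silverman rule
  $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$ over the ratio estimates —
  the rule used in the mode-estimator literature; SE by seeded bootstrap.
* **RAPS**: the simple profile-score variant; the estimate solves
  $\sum_j t_j(\beta)u_j(\beta) = 0$ with
  $t_j = (\beta_{yj}-\beta\beta_{xj})/\sqrt{\sigma_{yj}^2+\beta^2\sigma_{xj}^2}$,
  accounting for exposure-side error; the SE comes from the numerical
  derivative of the score at the root. Robust loss and overdispersion are
  deliberately off: the source analysis names the method without variant
  detail, so the simplest member of the family is the default.

Multivariable MR (`mvmr_ivw()`) regresses outcome betas on the matrix of
exposure betas without intercept, weights $1/\sigma_y^2$, SEs scaled by
$\sqrt{\max(1, Q/(k-p))}$. The instrument set is the union of each
exposure's genome-wide-significant clumped SNPs, harmonized jointly — the
dominant convention when the source is silent. A conditional
instrument-strength diagnostic (`mvmr_conditional_f()`) is reported but
nothing is gated on it.

## Diagnostics

Cochran's Q (about the fixed-effect IVW estimate, ratio weights,
$k-1$ df) and Rucker's Q (weighted residual about the Egger fit, $k-2$
df, always $\le$ Cochran's Q) quantify heterogeneity; the Egger intercept
tests directional pleiotropy; leave-one-out flags single-SNP influence.

MR-PRESSO compares each SNP's inverse-variance-weighted residual against
its leave-one-out IVW prediction with an empirical null simulated from
the stated per-SNP errors. Empirical p-values use the $(r+1)/(n_{sim}+1)$
convention, outliers require Bonferroni-corrected significance over the
tested SNPs, and a distortion test compares the corrected estimate
against random removals of the same size. Two numerical consequences are
worth knowing: no outlier is declarable unless
$n_{sim} > k/\alpha - 1$ (the empirical floor meets the Bonferroni
correction), and SNPs are sorted by identifier internally so that the
stochastic test is invariant to input order. The orchestrated pipeline
mirrors the source workflow: when the Egger intercept is significant at
0.05 the PRESSO pass removes outliers, re-estimates and re-tests
(configurable to `always`/`never`), and BH adjustment is applied last,
per outcome family by default.

## The synthetic-data generator

`simulate_mediation_gwas()` draws, per SNP $j$: a minor-allele frequency
(uniform on [0.1, 0.5]); an exposure instrument effect $\gamma_j$ from a
truncated normal (mean 0.06, sd 0.015, lower bound 0.05) — bounded away
from zero so every planted instrument passes genome-wide significance at
the configured sample sizes, decoupling selection behaviour from
estimator behaviour; and a mediator-specific effect
$\pi_j \sim N(0, 0.05)$. True effects are $\alpha\gamma_j + \pi_j$ on the
mediator and
$\delta\gamma_j + \beta_2(\alpha\gamma_j+\pi_j) + \text{pleiotropy}_j$
on the outcome, with observed betas adding noise of SD
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$ (standardized-trait
approximation; binary outcomes are emulated on the log-odds scale with an
effective $N$). Defaults place the truth at the published scale:
$\alpha = 0.5$, $\beta_2 = -0.8$, direct effect $-0.7$, hence total
$-1.1$ and mediated proportion $4/11 \approx 0.364$.

Design choices that were genuinely open:

* **Mediator-specific effects are essential, not optional.** If SNPs
  affected the mediator only through the exposure, the exposure and
  mediator beta columns would be exactly proportional and the
  multivariable regression would be identified only through sampling
  noise, converging to $t\alpha/(\alpha^2+1)$ rather than $\beta_2$. The
  $\pi_j$ term is the mediator's own GWAS signal and is what makes the
  two-step design estimable; its default SD (0.05) gives the mediator a
  realistic independent heritable component while keeping cumulative
  $R^2$ well below 1.
* **The pleiotropy violation lives on the outcome equation** (`none`,
  `balanced` = $N(0,\text{mag})$, `directional` = constant mag). This is
  the classic horizontal-pleiotropy benchmark that the Egger intercept
  and PRESSO are designed to detect, and it keeps the noise-free
  construction exact: constant directional pleiotropy yields an Egger
  intercept equal to the constant, exactly, when noise is switched off
  (`noise_scale = 0`).
* **Planted outliers** displace the outcome beta by `outlier_shift`
  outcome-SEs on randomly chosen SNPs.

What the generator does *not* emulate: LD between instruments (the LD
module generates separate block matrices for clumping tests), winner's
curse, sample overlap between GWAS, allele-frequency mismatch between
studies, and real effect-size spectra (instrument effects are strong so
that selection never interacts with estimation). Passing tests therefore
validate the estimators and the pipeline arithmetic, not the package's
robustness to those real-data complications.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(explicit normal equations, brute-force clumping, exhaustive
harmonization case enumeration, dense grid searches for mode and RAPS)
and the pipeline against simulation truth. Monte-Carlo checks use 200
replicates of the 100-SNP, $N=10^5$ scenario; recovery is asserted as
standardized bias (mean error relative to the replicate SD) below 2, and
delta-method CI coverage of the mediated proportion at or above 90% for
a nominal 95% interval. Standardized bias is the right scale here: with
per-SNP errors $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$, total
instrument strength is bounded by $N R^2$, so regression-dilution bias of
order $K/\sum F$ is unavoidable and a test against the much smaller
standard error of the 200-replicate *mean* would fail for any admissible
instrument-strength distribution — a property of summary-statistic MR,
not of this implementation.

Two diagnostic calibration facts surfaced by the same simulations, and
documented as limitations rather than patched over:

* The Egger intercept test assumes no measurement error on the exposure
  associations (NOME). At $N_{exposure}=10^5$ with the narrow default
  instrument-effect distribution the test over-rejects substantially
  (empirically ~0.6 at nominal 0.05) because regression dilution of the
  slope leaks into the intercept; with an effectively noise-free
  exposure GWAS ($N_{exposure}=10^7$ in the calibration scenario) the
  empirical size is nominal. Practitioners check this condition with the
  $I^2_{GX}$ statistic; the calibration test runs in the regime where
  the assumption holds.
* A "clean" PRESSO fixture must have `med_effect_sd = 0`: mediator
  pathways contribute genuine effect heterogeneity to the
  exposure–outcome pair, and PRESSO — whose null is built from the
  stated sampling errors only — correctly refuses to call such data
  outlier-free.

## Numerical choices

Fixed-effect covariance matrices are computed from the weighted normal
equations rather than rescaled regression output, so exact-fit (zero
residual) inputs yield finite SEs. The random-effects dispersion is
floored at 1 everywhere. RAPS brackets its root around the IVW estimate,
doubling the interval until the score changes sign (error with the
bracket reported if it never does). Bootstrap and PRESSO seeds are
arguments with recorded defaults, and seeded code restores the caller's
RNG state. Proportions are reported as percentages at one decimal in
display output while full precision is kept internally. Degenerate
inputs (single instrument, all-zero mediator column, identical ratios)
take documented special paths rather than failing.

## Known limitations

No I² statistic or funnel asymmetry tests beyond Egger; no MVMR-Egger or
Q-minimization MVMR; no joint multi-mediator decomposition (mediators
are decomposed one at a time, as in the source analysis, and
mediator–mediator interaction is out of scope); no Steiger filtering;
no individual-level data, proxy-SNP lookup or liftover. The delta-method
independence assumption across $\beta_0,\beta_1,\beta_2$ is an
approximation whenever the same outcome GWAS feeds $\beta_0$ and
$\beta_2$; the simulation coverage results (≥90% at nominal 95%) bound
the practical cost at the study scale.
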