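test_that("Cochran's Q matches hand arithmetic and doubles under duplication", {
  # identical ratios: Q = 0, p = 1
  h0 <- make_pair(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15), sy = 0.01)
  q0 <- cochran_q(h0)
  expect_equal(q0$statistic, 0, tolerance = 1e-18)
  expect_equal(q0$pvalue, 1)
  expect_equal(q0$df, 2)
  # 3-SNP hand instance
  bx <- c(0.1, 0.2, 0.1); by <- c(0.05, 0.08, 0.07); sy <- c(0.01, 0.02, 0.01)
  h <- make_pair(bx, by, sy = sy)
  w <- bx^2 / sy^2
  r <- by / bx
  b <- sum(w * r) / sum(w)
  expect_equal(cochran_q(h)$statistic, sum(w * (r - b)^2), tolerance = 1e-12)
  # duplicating every SNP exactly doubles Q
  h2 <- make_pair(c(bx, bx), c(by, by), sy = c(sy, sy))
  expect_equal(cochran_q(h2)$statistic, 2 * cochran_q(h)$statistic,
               tolerance = 1e-10)
  expect_error(cochran_q(make_pair(0.1, 0.05)),
               class = "twostepmr_data_error")
})

test_that("Rucker's Q is the Egger residual and never exceeds Cochran's Q", {
  # exact line with intercept -> zero residual
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_pair(bx, 0.02 + 0.5 * bx, sy = 0.01)
  expect_equal(rucker_q(h)$statistic, 0, tolerance = 1e-16)
  expect_equal(rucker_q(h)$df, 2)
  # 4-SNP instance vs explicit residual arithmetic
  set.seed(4)
  by <- 0.02 + 0.5 * bx + rnorm(4, 0, 0.02)
  sy <- runif(4, 0.008, 0.02)
  h2 <- make_pair(bx, by, sy = sy)
  o <- oracle_wls_intercept(bx, by, 1 / sy^2)
  rq <- sum((by - o$intercept - o$slope * bx)^2 / sy^2)
  expect_equal(rucker_q(h2)$statistic, rq, tolerance = 1e-10)
  # inequality over random instances
  set.seed(12)
  for (i in 1:1000) {
    k <- sample(3:8, 1)
    bxr <- runif(k, 0.05, 0.4)
    byr <- rnorm(k, 0.3 * bxr, 0.05)
    syr <- runif(k, 0.005, 0.05)
    hr <- make_pair(bxr, byr, sy = syr)
    expect_lte(rucker_q(hr)$statistic, cochran_q(hr)$statistic + 1e-10)
  }
})

test_that("Egger intercept recovers planted directional pleiotropy exactly", {
  sim0 <- simulate_mediation_gwas(sim_config(
    n_snps = 20, med_effect_sd = 0, noise_scale = 0, seed = 60))
  h0 <- harmonize(sim0$exposure, sim0$outcome)
  expect_equal(egger_intercept_test(h0)$intercept, 0, tolerance = 1e-12)
  sim <- simulate_mediation_gwas(sim_config(
    n_snps = 20, med_effect_sd = 0, pleiotropy = "directional",
    pleiotropy_mag = 0.01, noise_scale = 0, seed = 61))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(egger_intercept_test(h)$intercept, 0.01, tolerance = 1e-10)
})

test_that("Egger intercept type-I error is calibrated under the null", {
  # 500 null replicates (no pleiotropy): rejection rate at 0.05 within
  # binomial 95% bounds. The null scenario uses an effectively noise-free
  # exposure GWAS so the regression's no-measurement-error (NOME)
  # assumption holds; with appreciable exposure-side error the intercept
  # test is known to over-reject (see the methods vignette).
  n_rep <- 500
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_mediation_gwas(sim_config(
      n_snps = 50, med_effect_sd = 0, n_exposure = 1e7, seed = 5000 + r))
    h <- harmonize(sim$exposure, sim$outcome)
    rej[r] <- egger_intercept_test(h)$pvalue < 0.05
  }
  bounds <- 0.05 + c(-1.96, 1.96) * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("MR-PRESSO is clean on null data and recovers a planted outlier", {
  # "clean" means no pleiotropy and no mediator-specific heterogeneity:
  # the PRESSO null simulates residuals from the stated SEs alone
  sim <- simulate_mediation_gwas(sim_config(
    n_snps = 20, med_effect_sd = 0, seed = 314))
  h <- harmonize(sim$exposure, sim$outcome)
  clean <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_equal(nrow(clean$outlier_snps), 0)
  expect_gt(clean$global_pvalue, 0.05)
  expect_null(clean$corrected_estimate)

  # displace one SNP's outcome beta by 10 sigma
  simo <- simulate_mediation_gwas(sim_config(
    n_snps = 20, med_effect_sd = 0, n_outliers = 1, outlier_shift = 10,
    seed = 314))
  ho <- harmonize(simo$exposure, simo$outcome)
  pres <- mr_presso(ho, n_sim = 1000, seed = 11)
  expect_equal(pres$outlier_snps$SNP, simo$truth$outlier_snps)
  expect_lt(pres$global_pvalue, 0.05)
  # corrected estimate is closer to the simulation truth
  full <- mr_ivw(ho)
  expect_lt(abs(pres$corrected_estimate$beta - simo$truth$total_true),
            abs(full$beta - simo$truth$total_true))
  expect_false(is.null(pres$distortion_pvalue))
  expect_error(mr_presso(make_pair(1:3 / 10, 1:3 / 20), n_sim = 1000),
               class = "twostepmr_data_error")
  expect_error(mr_presso(h, n_sim = 10),
               class = "twostepmr_parameter_error")
})

test_that("MR-PRESSO is reproducible and input-order invariant", {
  sim <- simulate_mediation_gwas(sim_config(n_snps = 12, seed = 9))
  h <- harmonize(sim$exposure, sim$outcome)
  a <- mr_presso(h, n_sim = 500, seed = 3)
  b <- mr_presso(h, n_sim = 500, seed = 3)
  expect_identical(a$global_pvalue, b$global_pvalue)
  expect_identical(a$pvalues, b$pvalues)
  # permute SNP order: identical diagnostics
  perm <- sample(n_snps(h))
  hp <- harmonized_set(h$snp_id[perm], h$traits,
                       h$beta[perm, ], h$se[perm, ])
  p2 <- mr_presso(hp, n_sim = 500, seed = 3)
  expect_identical(a$global_pvalue, p2$global_pvalue)
  expect_equal(a$pvalues[order(a$pvalues$SNP), ],
               p2$pvalues[order(p2$pvalues$SNP), ], ignore_attr = TRUE)
  # order invariance of the deterministic diagnostics too
  expect_equal(cochran_q(hp)$statistic, cochran_q(h)$statistic)
  expect_equal(rucker_q(hp)$statistic, rucker_q(h)$statistic)
  expect_equal(egger_intercept_test(hp)$intercept,
               egger_intercept_test(h)$intercept)
})

test_that("MR-PRESSO global p is near-uniform under the null", {
  # Kolmogorov-Smirnov check over 300 null datasets (empirical p-values
  # are discrete at resolution 1/(n_sim+1); tolerance reflects that)
  n_rep <- 300
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    k <- 10
    set.seed(80000 + r)
    gamma <- runif(k, 0.05, 0.2)
    sx <- rep(0.004, k); sy <- rep(0.004, k)
    bx <- gamma + rnorm(k, 0, sx)
    by <- 0.5 * gamma + rnorm(k, 0, sy)
    h <- make_pair(bx, by, sx, sy)
    pvals[r] <- mr_presso(h, n_sim = 200, seed = r)$global_pvalue
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("leave-one-out flags influential SNPs and keeps cardinality", {
  # identical SNPs: every LOO estimate equals the full estimate
  h <- make_pair(rep(0.1, 5), rep(0.05, 5), sy = 0.01)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 5)
  expect_true(all(abs(loo$beta - attr(loo, "full")$beta) < 1e-12))
  expect_false(any(loo$flag))
  # a planted dominant outlier: its exclusion moves the estimate toward truth
  simo <- simulate_mediation_gwas(sim_config(
    n_snps = 10, med_effect_sd = 0, n_outliers = 1, outlier_shift = 30,
    seed = 17))
  ho <- harmonize(simo$exposure, simo$outcome)
  loo2 <- leave_one_out(ho)
  expect_equal(nrow(loo2), 10)
  out_id <- simo$truth$outlier_snps
  full_beta <- attr(loo2, "full")$beta
  excl <- loo2$beta[loo2$SNP == out_id]
  truth <- simo$truth$total_true
  expect_lt(abs(excl - truth), abs(full_beta - truth))
})
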