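test_that("IVW matches the weighted-least-squares-through-origin oracle", {
  # single SNP: Wald ratio
  h1 <- make_pair(0.1, 0.05, sy = 0.01)
  expect_warning(e1 <- mr_ivw(h1), "single instrument")
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.1)
  # exact shared ratio: Q = 0, random-effects floor keeps the fixed SE
  h2 <- make_pair(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15), sy = 0.01)
  er <- mr_ivw(h2, "random")
  ef <- mr_ivw(h2, "fixed")
  expect_equal(er$beta, 0.5)
  expect_equal(er$extras$Q, 0, tolerance = 1e-20)
  expect_equal(er$se, ef$se)
  # 3-SNP instance against the closed-form oracle
  bx <- c(0.1, 0.2, 0.15); by <- c(0.06, 0.09, 0.08); sy <- c(0.01, 0.01, 0.02)
  h3 <- make_pair(bx, by, sy = sy)
  want <- oracle_wls_origin(bx, by, 1 / sy^2)
  got <- mr_ivw(h3, "fixed")
  expect_equal(got$beta, want$beta, tolerance = 1e-12)
  expect_equal(got$se, want$se, tolerance = 1e-12)
  expect_equal(got$ci_low, got$beta - 1.96 * got$se)
  expect_error(mr_ivw(make_pair(c(0, 0), c(0.1, 0.2))),
               class = "twostepmr_data_error")
})

test_that("Egger regression matches the two-parameter normal-equations oracle", {
  # exact line with intercept: slope/intercept recovered, zero residual Q
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.01 + 0.5 * bx
  h <- make_pair(bx, by, sy = 0.01)
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.01, tolerance = 1e-10)
  expect_equal(rucker_q(h)$statistic, 0, tolerance = 1e-16)
  # through-origin data: intercept exactly 0
  h0 <- make_pair(bx, 0.5 * bx, sy = 0.01)
  expect_equal(mr_egger(h0)$extras$intercept, 0, tolerance = 1e-12)
  # noisy 4-SNP instance vs explicit matrix closed form
  set.seed(8)
  by2 <- 0.02 + 0.4 * bx + rnorm(4, 0, 0.01)
  sy2 <- runif(4, 0.005, 0.02)
  h2 <- make_pair(bx, by2, sy = sy2)
  want <- oracle_wls_intercept(bx, by2, 1 / sy2^2)
  got <- mr_egger(h2)
  expect_equal(got$beta, want$slope, tolerance = 1e-10)
  expect_equal(got$extras$intercept, want$intercept, tolerance = 1e-10)
  expect_error(mr_egger(make_pair(1:2 / 10, 1:2 / 10)),
               class = "twostepmr_data_error")
})

test_that("Egger orients exposure effects to be non-negative", {
  bx <- c(0.1, -0.2, 0.3, -0.4)
  by <- 0.01 * sign(bx) + 0.5 * bx  # pleiotropy acts along orientation
  h <- make_pair(bx, by, sy = 0.01)
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.01, tolerance = 1e-10)
})

test_that("weighted median crosses cumulative weight 0.5 with interpolation", {
  h <- make_pair(c(0.1, 0.1, 0.1), c(0.05, 0.05, 0.05), sy = 0.01)
  expect_equal(mr_weighted_median(h, n_boot = 100)$beta, 0.5)
  # ratios {0.1, 0.5, 0.9} with equal weights -> 0.5 by hand
  h2 <- make_pair(rep(0.1, 3), c(0.01, 0.05, 0.09), sy = 0.01)
  expect_equal(mr_weighted_median(h2, n_boot = 100)$beta, 0.5)
  # hand-computed asymmetric-weight crossing: ratios {1,2,3}, weights
  # proportional to {1,1,2}: cumulative (.125,.375,.75) -> interpolate
  # between 2 and 3: 2 + (0.5-0.375)/(0.75-0.375) = 2.3333...
  sy3 <- c(0.01, 0.01, 0.01 / sqrt(2))
  h3 <- make_pair(rep(0.01, 3), c(0.01, 0.02, 0.03), sy = sy3)
  expect_equal(mr_weighted_median(h3, n_boot = 100)$beta, 2 + 1 / 3,
               tolerance = 1e-10)
  # determinism: same seed -> identical SE; different seed -> close
  a <- mr_weighted_median(h2, n_boot = 300, seed = 1)
  b <- mr_weighted_median(h2, n_boot = 300, seed = 1)
  c <- mr_weighted_median(h2, n_boot = 300, seed = 2)
  expect_identical(a$se, b$se)
  expect_gt(c$se, 0)
  expect_lt(abs(c$se - a$se) / a$se, 0.5)
  expect_error(mr_weighted_median(h2, n_boot = 1),
               class = "twostepmr_parameter_error")
  expect_warning(mr_weighted_median(h2, n_boot = 50), "unstable")
})

test_that("mode estimators find the dominant ratio cluster", {
  # majority cluster at 0.5
  h <- make_pair(rep(0.1, 10),
                 c(rep(0.05, 9), 0.2), sy = 0.01)
  expect_equal(mr_mode(h, "simple", n_boot = 100)$beta, 0.5,
               tolerance = 0.05)
  expect_equal(mr_mode(h, "weighted", n_boot = 100)$beta, 0.5,
               tolerance = 0.05)
  h4 <- make_pair(rep(0.1, 4), c(0.05, 0.05, 0.05, 0.2), sy = 0.01)
  expect_equal(mr_mode(h4, "simple", n_boot = 100)$beta, 0.5,
               tolerance = 0.2)
  # single-SNP edge: mode equals the Wald ratio
  h1 <- make_pair(0.1, 0.07)
  expect_warning(e1 <- mr_mode(h1, "simple", n_boot = 100))
  expect_equal(e1$beta, 0.7)
  # dense-grid argmax oracle for the same kernel density
  set.seed(21)
  bx <- runif(8, 0.05, 0.3)
  by <- 0.5 * bx + rnorm(8, 0, 0.02)
  sy <- runif(8, 0.005, 0.02)
  h8 <- make_pair(bx, by, sy = sy)
  e8 <- mr_mode(h8, "weighted", n_boot = 100)
  r <- by / bx
  w <- (bx / sy)^2
  bw <- e8$extras$bandwidth
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 20000)
  dens <- vapply(grid, function(g)
    sum(w / sum(w) * dnorm((g - r) / bw)), numeric(1))
  expect_equal(e8$beta, grid[which.max(dens)], tolerance = 3 * bw * 1e-2)
  expect_error(mr_mode(h8, "simple", bandwidth_factor = 0),
               class = "twostepmr_parameter_error")
})

test_that("RAPS solves the profile score and matches limits", {
  # noise-free shared ratio: root at the common ratio
  bx <- c(0.1, 0.2, 0.15, 0.25, 0.3)
  h <- make_pair(bx, 0.4 * bx, sx = 0.01, sy = 0.01)
  expect_equal(mr_raps(h)$beta, 0.4, tolerance = 1e-8)
  # sigma_x -> 0 limit equals fixed-effects IVW
  set.seed(13)
  by <- 0.4 * bx + rnorm(5, 0, 0.01)
  h2 <- make_pair(bx, by, sx = 1e-8, sy = 0.01)
  ivw <- mr_ivw(h2, "fixed")
  raps <- mr_raps(h2)
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(raps$se, ivw$se, tolerance = 1e-4)
  # root agrees with a dense grid search of the score's zero crossing
  h3 <- make_pair(bx, by, sx = 0.02, sy = 0.01)
  e3 <- mr_raps(h3)
  score <- function(b) {
    v <- 0.01^2 + b^2 * 0.02^2
    sum((by - b * bx) / sqrt(v) * (bx * 0.01^2 + b * by * 0.02^2) / v^1.5)
  }
  grid <- seq(e3$beta - 0.5, e3$beta + 0.5, length.out = 40001)
  sg <- vapply(grid, score, numeric(1))
  cross <- grid[which(diff(sign(sg)) != 0)[1]]
  expect_lt(abs(e3$beta - cross), 2 * diff(grid[1:2]))
  expect_error(mr_raps(make_pair(1:2 / 10, 1:2 / 10)),
               class = "twostepmr_data_error")
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(31)
  bx <- runif(8, 0.05, 0.3)
  by <- 0.5 * bx + rnorm(8, 0, 0.01)
  sx <- runif(8, 0.005, 0.02)
  sy <- runif(8, 0.005, 0.02)
  h <- make_pair(bx, by, sx, sy)
  hneg <- make_pair(bx, -by, sx, sy)
  c2 <- 4
  hscale <- make_pair(c2 * bx, by, c2 * sx, sy)
  for (f in list(function(g) mr_ivw(g), function(g) mr_egger(g),
                 function(g) mr_raps(g),
                 function(g) mr_weighted_median(g, n_boot = 200, seed = 5),
                 function(g) mr_mode(g, "weighted", n_boot = 200, seed = 5))) {
    e <- f(h); en <- f(hneg); es <- f(hscale)
    expect_equal(en$beta, -e$beta, tolerance = 1e-8)
    expect_equal(es$beta, e$beta / c2, tolerance = 1e-8)
    # exact SE invariance for the analytic estimators; bootstrap SEs agree
    # within Monte-Carlo error
    tol_se <- if (e$method %in% c("IVW", "Egger", "RAPS")) 1e-8 else 0.3
    expect_equal(en$se, e$se, tolerance = tol_se)
    expect_equal(es$se, e$se / c2, tolerance = tol_se)
  }
})

test_that("estimator output is reproducible on identical input and seed", {
  set.seed(77)
  bx <- runif(6, 0.05, 0.3)
  by <- 0.3 * bx + rnorm(6, 0, 0.01)
  h <- make_pair(bx, by, sy = rep(0.01, 6))
  r1 <- mr_all(h, n_boot = 150, seed = 9)
  r2 <- mr_all(h, n_boot = 150, seed = 9)
  expect_identical(r1, r2)
  expect_setequal(r1$method, c("IVW", "Egger", "weighted-median",
                               "simple-mode", "weighted-mode", "RAPS"))
  # seeded estimators do not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123)
  suppressWarnings(invisible(mr_weighted_median(h, n_boot = 50, seed = 4)))
  expect_identical(runif(1), a)
})

test_that("weighted median resists up to 50% invalid weight where IVW fails", {
  # 12 valid + 8 pleiotropic instruments (ratio shifted by +1), 200 reps
  set.seed(1405)
  truth <- 0.5
  k <- 20
  med_est <- ivw_est <- numeric(200)
  for (r in 1:200) {
    gamma <- runif(k, 0.1, 0.3)
    pleio <- c(rep(0, 12), rep(1, 8)) * gamma  # ratio shift +1 on 8 SNPs
    sx <- rep(0.005, k); sy <- rep(0.01, k)
    bx <- gamma + rnorm(k, 0, sx)
    by <- truth * gamma + pleio + rnorm(k, 0, sy)
    h <- make_pair(bx, by, sx, sy)
    med_est[r] <- twostepmr:::weighted_median_value(by / bx, (bx / sy)^2)
    ivw_est[r] <- mr_ivw(h, "fixed")$beta
  }
  # median recovers truth within 2 MC SDs; IVW is clearly biased
  expect_lt(abs(mean(med_est) - truth), 2 * sd(med_est))
  expect_gt(abs(mean(ivw_est) - truth), 4 * sd(ivw_est))
})
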