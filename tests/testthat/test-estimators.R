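test_that("Wald ratio and delta-method SEs match arithmetic and Monte Carlo", {
  w <- wald_ratio(0.05, 0.01, 0.01, 0.004, "first")
  expect_equal(w$ratio, 0.2)
  expect_equal(w$se, 0.08)
  expect_equal(w$weight, 1 / 0.08^2)

  w2 <- wald_ratio(0.05, 0.01, 0.01, 0.004, "second")
  expect_equal(w2$se, sqrt(0.0064 + 0.0016))

  # Monte-Carlo delta-method oracle: SD of simulated ratios, checked in a
  # regime where the denominator CV is small enough for the expansion to hold
  set.seed(123)
  n <- 1e6
  w4 <- wald_ratio(0.05, 0.002, 0.01, 0.004, "second")
  r <- rnorm(n, 0.01, 0.004) / rnorm(n, 0.05, 0.002)
  expect_equal(sd(r), w4$se, tolerance = 0.01)

  # sign equivariance of the ratio; SE unchanged
  w3 <- wald_ratio(-0.05, 0.01, 0.01, 0.004, "first")
  expect_equal(w3$ratio, -0.2)
  expect_equal(w3$se, 0.08)
  expect_error(wald_ratio(0, 0.01, 0.01, 0.004), "undefined ratio")
})

test_that("IVW is the inverse-variance weighted mean with Q-based inflation", {
  # two SNPs, ratios 0.1 and 0.3 at equal SE: brute-force weighted mean
  h <- make_harmonized(bx = c(1, 1), sx = c(1e-6, 1e-6), by = c(0.1, 0.3),
                       sy = c(0.05, 0.05))
  est <- ivw_estimate(h, "fixed")
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.05 / sqrt(2))

  # identical ratios: Q = 0, random-effects equals fixed
  h0 <- make_harmonized(bx = c(0.5, 0.25), sx = c(0.01, 0.01),
                        by = c(0.1, 0.05), sy = c(0.01, 0.005))
  fe <- ivw_estimate(h0, "fixed")
  re <- ivw_estimate(h0, "multiplicative_random")
  expect_equal(fe$beta, 0.2)
  expect_equal(re$q_statistic, 0)
  expect_equal(re$se, fe$se)

  # single instrument reduces to the Wald ratio (with a fall-back warning)
  h1 <- make_harmonized(0.05, 0.01, 0.01, 0.004)
  expect_warning(e1 <- ivw_estimate(h1), "fixed")
  expect_equal(e1$beta, 0.2)
  expect_equal(e1$se, 0.08)

  # fixed-effects IVW == WLS of outcome on exposure betas through the origin
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    h <- make_harmonized(bx = runif(k, 0.02, 0.2), sx = runif(k, 1e-3, 1e-2),
                         by = rnorm(k, 0, 0.05), sy = runif(k, 0.005, 0.05))
    est <- ivw_estimate(h, "fixed")
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
              weights = 1 / h$se_outcome^2)
    expect_equal(est$beta, unname(coef(wls)), tolerance = 1e-12)
  }
})

test_that("maximum likelihood reduces to the Wald ratio and the IVW limit", {
  h1 <- make_harmonized(0.05, 0.01, 0.01, 0.004)
  ml1 <- max_likelihood_estimate(h1)
  expect_equal(ml1$beta, 0.2, tolerance = 1e-7)

  # negligible exposure-side error: agrees with fixed-effects IVW
  set.seed(21)
  k <- 40
  bx <- runif(k, 0.02, 0.15)
  by <- 0.1 * bx + rnorm(k, 0, 0.01)
  h <- make_harmonized(bx, sx = 1e-6 * rep(0.01, k), by = by,
                       sy = rep(0.01, k))
  ml <- max_likelihood_estimate(h)
  fe <- ivw_estimate(h, "fixed")
  expect_equal(ml$beta, fe$beta, tolerance = 1e-6)
  expect_equal(ml$se, fe$se, tolerance = 1e-4)
})

test_that("maximum likelihood recovers the causal effect in simulation", {
  oc <- evaluate_operating_characteristics(
    make_scenario("balanced_pleiotropy", n_snps = 50, true_beta = 0.08,
                  pleiotropy = list(type = "none", mu = 0, tau = 0,
                                    fraction = 1)),
    n_reps = 200, methods = "max_likelihood", seed = 404)
  mcse <- oc$empirical_se / sqrt(oc$n_ok)
  expect_lt(abs(oc$mean_estimate - 0.08), 2 * mcse)
})

test_that("weighted median interpolates the cumulative-weight midpoint", {
  # brute-force oracle over a dense grid of candidate medians
  brute_median <- function(x, w) {
    w <- w / sum(w)
    o <- order(x); x <- x[o]; w <- w[o]
    s <- cumsum(w) - w / 2
    stats::approx(s, x, xout = 0.5, rule = 2)$y
  }
  h <- make_harmonized(bx = rep(1, 3), sx = rep(1e-6, 3),
                       by = c(0.1, 0.2, 0.3), sy = rep(0.05, 3))
  est <- weighted_median_estimate(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2)

  set.seed(31)
  for (i in 1:50) {
    k <- sample(3:25, 1)
    x <- rnorm(k); w <- runif(k, 0.1, 5)
    expect_equal(bimr:::weighted_median_value(x, w), brute_median(x, w),
                 tolerance = 1e-12)
  }
  # equal weights equal the ordinary interpolated median
  for (i in 1:20) {
    k <- sample(3:15, 1)
    x <- rnorm(k)
    expect_equal(bimr:::weighted_median_value(x, rep(1, k)),
                 brute_median(x, rep(1, k)))
  }

  # degenerate case: all ratios equal; bootstrap SE on the common scale
  hd <- make_harmonized(bx = rep(1, 5), sx = rep(1e-6, 5), by = rep(0.2, 5),
                        sy = rep(0.05, 5))
  estd <- weighted_median_estimate(hd, n_boot = 500, seed = 2)
  expect_equal(estd$beta, 0.2)
  expect_gt(estd$se, 0.05 / 10)
  expect_lt(estd$se, 0.05)
  expect_error(weighted_median_estimate(h[1:2, ], seed = 1), "at least 3")
  expect_warning(weighted_median_estimate(h, n_boot = 50, seed = 1), "n_boot")
  # identical seed, identical bootstrap SE
  expect_identical(weighted_median_estimate(h, n_boot = 200, seed = 9)$se,
                   weighted_median_estimate(h, n_boot = 200, seed = 9)$se)
})

test_that("weighted median resists a minority of invalid instruments", {
  # 6 clean precise instruments at beta 0.1, 4 contaminated by +0.5
  bx <- rep(0.1, 10)
  by <- 0.1 * bx
  by[7:10] <- by[7:10] + 0.5 * bx[7:10]
  h <- make_harmonized(bx, sx = rep(1e-5, 10), by = by, sy = rep(1e-4, 10))
  est <- weighted_median_estimate(h, n_boot = 200, seed = 3)
  ivw <- ivw_estimate(h)
  expect_lt(abs(est$beta - 0.1), 0.02)       # near the truth...
  expect_gt(ivw$beta, 0.25)                  # ...while the mean is dragged
})

test_that("Egger recovers an exact affine relation and tests the intercept", {
  set.seed(41)
  bx <- runif(8, 0.05, 0.2)
  by <- 0.01 + 0.3 * bx
  h <- make_harmonized(bx, sx = rep(0.01, 8), by = by, sy = rep(0.01, 8))
  est <- egger_estimate(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$intercept, 0.01, tolerance = 1e-10)
  expect_lte(sqrt(est$q_statistic / (8 - 2)), 1)   # residual scale <= 1
  expect_true(est$se > 0 && est$intercept_se > 0)
  expect_error(egger_estimate(h[1:2, ]), "insufficient for Egger")

  # orientation invariance: flipping exposure signs leaves Egger unchanged
  h2 <- h
  h2$beta_exposure[1:4] <- -h2$beta_exposure[1:4]
  h2$beta_outcome[1:4] <- -h2$beta_outcome[1:4]
  est2 <- egger_estimate(h2)
  expect_equal(est2$beta, est$beta, tolerance = 1e-12)
  expect_equal(est2$intercept, est$intercept, tolerance = 1e-12)
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(51)
  k <- 20
  h <- make_harmonized(bx = abs(rnorm(k, 0.1, 0.03)), sx = rep(0.005, k),
                       by = rnorm(k, 0.02, 0.01), sy = runif(k, 0.005, 0.02))
  base <- list(ivw = ivw_estimate(h),
               ml = max_likelihood_estimate(h),
               wm = weighted_median_estimate(h, n_boot = 300, seed = 5),
               egger = egger_estimate(h))
  # negate all exposure betas
  hneg <- h; hneg$beta_exposure <- -h$beta_exposure
  neg <- list(ivw = ivw_estimate(hneg),
              ml = max_likelihood_estimate(hneg),
              wm = weighted_median_estimate(hneg, n_boot = 300, seed = 5),
              egger = egger_estimate(hneg))
  for (m in names(base)) {
    expect_equal(neg[[m]]$beta, -base[[m]]$beta, tolerance = 1e-6,
                 label = paste(m, "beta sign"))
    # the weighted-median bootstrap draws differ under negation, so its SE
    # is only equal in distribution; analytic SEs must match exactly
    expect_equal(neg[[m]]$se, base[[m]]$se,
                 tolerance = if (m == "wm") 0.15 else 1e-6,
                 label = paste(m, "se under sign flip"))
  }
  # scale all outcome betas and SEs by c
  cc <- 3.7
  hsc <- h; hsc$beta_outcome <- cc * h$beta_outcome
  hsc$se_outcome <- cc * h$se_outcome
  sc <- list(ivw = ivw_estimate(hsc),
             ml = max_likelihood_estimate(hsc),
             wm = weighted_median_estimate(hsc, n_boot = 300, seed = 5),
             egger = egger_estimate(hsc))
  for (m in names(base)) {
    expect_equal(sc[[m]]$beta, cc * base[[m]]$beta, tolerance = 1e-5,
                 label = paste(m, "beta scale"))
    expect_equal(sc[[m]]$se, cc * base[[m]]$se, tolerance = 1e-5,
                 label = paste(m, "se scale"))
  }
})

test_that("the estimator suite degrades gracefully and labels OR scales", {
  h_bin <- make_harmonized(bx = c(0.1, 0.12, 0.09, 0.11), sx = rep(0.01, 4),
                           by = c(0.02, 0.025, 0.017, 0.022),
                           sy = rep(0.008, 4), binary = TRUE)
  suite <- run_estimator_suite(h_bin, config = list(seed = 1, n_boot = 200))
  expect_equal(nrow(suite), 5)
  ok <- suite$status == "ok"
  expect_equal(suite$or[ok], exp(suite$beta[ok]))
  expect_identical(suite$status[suite$method == "ivw_modified"], "skipped")
  expect_true(all(suite$ci_low[ok] <= suite$beta[ok] &
                    suite$beta[ok] <= suite$ci_high[ok]))
  expect_true(all(is.na(suite$intercept[suite$method != "egger"])))
  expect_false(is.na(suite$intercept[suite$method == "egger"]))

  # continuous outcome: no OR scale anywhere
  h_cont <- make_harmonized(bx = c(0.1, 0.12, 0.09), sx = rep(0.01, 3),
                            by = c(0.02, 0.025, 0.017), sy = rep(0.008, 3))
  suite2 <- run_estimator_suite(h_cont,
                                confounder_filtered = h_cont,
                                config = list(seed = 1, n_boot = 200))
  expect_true(all(is.na(suite2$or)))
  expect_identical(suite2$status[suite2$method == "ivw_modified"], "ok")

  # a failing member is reported as failed without aborting the suite
  h_tiny <- make_harmonized(bx = c(0.1, 0.12), sx = rep(0.01, 2),
                            by = c(0.02, 0.025), sy = rep(0.008, 2))
  suite3 <- suppressWarnings(run_estimator_suite(
    h_tiny, config = list(seed = 1, n_boot = 200)))
  expect_match(suite3$status[suite3$method == "weighted_median"], "failed")
  expect_match(suite3$status[suite3$method == "egger"], "failed")
  expect_identical(suite3$status[suite3$method == "ivw"], "ok")
})
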