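test_that("mid-range generation times convert to minutes", {
  expect_equal(midpoint_generation_time("~7–15 min"), 11)
  expect_equal(midpoint_generation_time("~7-15 min"), 11)   # plain hyphen too
  expect_equal(midpoint_generation_time("~20–30 h"), 1500)
  expect_equal(midpoint_generation_time("~7 days"), 10080)
  expect_equal(midpoint_generation_time("~2 h"), 120)
  expect_equal(midpoint_generation_time("~1.8–4.6 h"), 192)
  expect_error(midpoint_generation_time("fast"), "unparseable")
})

test_that("profile log-likelihood matches its closed form", {
  # y = {3, 5}, C = 4: sigma2 = 1, lnL = -(ln(2*pi) + 1)
  lnl <- profile_loglik(c(1, 2), c(3, 5), list(C = 4), "constant_null")
  expect_equal(as.numeric(lnl), -(log(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(round(as.numeric(lnl), 4), -2.8379)

  # the Gaussian MLE of a constant mean is the sample mean
  set.seed(3)
  y <- rnorm(12, 10, 2); T <- seq_along(y)
  at_mean <- profile_loglik(T, y, list(C = mean(y)), "constant_null")
  for (c_off in c(-1, -0.1, 0.1, 1)) {
    expect_lt(profile_loglik(T, y, list(C = mean(y) + c_off), "constant_null"),
              at_mean)
  }

  # perfect fit is flagged degenerate
  mu <- 1 + 9 * exp(-0.01 * T)
  lnl_d <- profile_loglik(T, mu, list(alpha = 9, beta = 0.01), "rrn_eq1")
  expect_true(is.infinite(lnl_d) && isTRUE(attr(lnl_d, "degenerate")))

  # at the generating parameters the profile lnL is close to the value
  # implied by the true noise variance (Monte-Carlo, large n)
  set.seed(41)
  n <- 4000; Tm <- runif(n, 10, 500); sig <- 2
  ym <- 1 + 9 * exp(-0.012 * Tm) + rnorm(n, 0, sig)
  lnl_mc <- profile_loglik(Tm, ym, list(alpha = 9, beta = 0.012), "rrn_eq1")
  expected <- -(n / 2) * (log(2 * pi * sig^2) + 1)
  expect_lt(abs(lnl_mc - expected) / abs(expected), 0.02)
})

test_that("zero-noise data identify the decay parameters to high precision", {
  Tb <- study_species()$T_minutes
  d1 <- simulate_growth_dataset("rrn_eq1", alpha = 9.000380, beta = 0.011936,
                                sigma = 0, T_grid = Tb[1:10])
  f1 <- fit_growth_model(d1, "rrn_eq1")
  expect_equal(f1$alpha, 9.000380, tolerance = 1e-5)
  expect_equal(f1$beta, 0.011936, tolerance = 1e-5)

  d2 <- simulate_growth_dataset("trna_eq2", alpha = 157.323365,
                                beta = 0.056354, gamma = 40.954750,
                                sigma = 0, T_grid = Tb[11:20])
  f2 <- fit_growth_model(d2, "trna_eq2")
  expect_equal(f2$alpha, 157.323365, tolerance = 1e-5)
  expect_equal(f2$beta, 0.056354, tolerance = 1e-5)
  expect_equal(f2$gamma, 40.954750, tolerance = 1e-5)
})

test_that("stochastic parameter recovery is accurate at simulation scale", {
  # estimated-floor model at published-scale parameters, sigma = 5, n = 50
  d <- simulate_growth_dataset("trna_eq2", alpha = 157, beta = 0.056,
                               gamma = 41, sigma = 5, n = 50, seed = 99)
  f <- fit_growth_model(d, "trna_eq2")
  expect_lt(abs(f$alpha / 157 - 1), 0.15)
  expect_lt(abs(f$beta / 0.056 - 1), 0.15)
  expect_lt(abs(f$gamma / 41 - 1), 0.15)
})

test_that("the decay fit never scores below the constant null", {
  Tg <- study_species()$T_minutes
  for (i in 1:25) {
    d <- simulate_growth_dataset("rrn_eq1", alpha = 9, beta = 0.012,
                                 sigma = 1.5, T_grid = Tg, seed = 500 + i,
                                 round_to_integers = TRUE)
    fm <- fit_growth_model(d, "rrn_eq1")
    fn <- fit_growth_model(d, "constant_null")
    expect_gte(fm$lnL - fn$lnL, -1e-6)
  }
  # flat (null-generated) data: decay fit cannot lose either
  for (i in 1:10) {
    d0 <- data.frame(T_minutes = Tg,
                     y = 5 + with_seed_vec(600 + i, length(Tg)))
    fm <- fit_growth_model(d0, "rrn_eq1")
    fn <- fit_growth_model(d0, "constant_null")
    expect_gte(fm$lnL - fn$lnL, -1e-6)
  }
})

test_that("fitted mean functions decay monotonically to their floors", {
  Tg <- seq(1, 20000, length.out = 200)
  d <- simulate_growth_dataset("trna_eq2", alpha = 100, beta = 0.03,
                               gamma = 40, sigma = 3, n = 30, seed = 12)
  f <- fit_growth_model(d, "trna_eq2")
  mu <- f$gamma + f$alpha * exp(-f$beta * Tg)
  # strictly decreasing while the exponential term is non-negligible,
  # never increasing anywhere (it may saturate at the floor)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(diff(mu[1:5]) < 0))
  expect_equal(mu[length(mu)], f$gamma, tolerance = 1e-6)

  d1 <- simulate_growth_dataset("rrn_eq1", alpha = 9, beta = 0.012,
                                sigma = 0.5, n = 30, seed = 13)
  f1 <- fit_growth_model(d1, "rrn_eq1")
  mu1 <- 1 + f1$alpha * exp(-f1$beta * Tg)
  expect_true(all(diff(mu1) <= 0))
  expect_true(all(diff(mu1[1:5]) < 0))
  expect_equal(mu1[length(mu1)], 1, tolerance = 1e-4)
})

test_that("LRT arithmetic reproduces the published chi-square p-values", {
  ref <- reference_growth_fits()
  rrn <- ref[ref$model == "rrn_eq1", ]
  # df = 1: difference in mean-function parameters between decay and null
  for (k in seq_len(nrow(rrn))) {
    r <- lrt_from_loglik(rrn$lnL_model[k], rrn$lnL_null[k], df = 1)
    expect_equal(signif(r$p_value, 2), signif(rrn$p[k], 2))
  }
  # the published G2 values by arithmetic
  r1 <- lrt_from_loglik(-19.5164, -25.8209, df = 1)
  expect_equal(round(r1$G2, 4), 12.609)
  expect_equal(signif(r1$p_value, 2), 0.00038)
  r2 <- lrt_from_loglik(-18.9248, -26.0992, df = 1)
  expect_equal(round(r2$G2, 4), 14.3488)
  expect_equal(signif(r2$p_value, 2), 0.00015)
  # chi-square(2) applied to the same pairs does NOT reproduce them,
  # pinning down the df convention
  expect_false(isTRUE(all.equal(
    signif(lrt_from_loglik(-19.5164, -25.8209, df = 2)$p_value, 2), 0.00038)))

  # tRNA-model rows: df = 2, printed p rounds to 0.000000
  trna <- ref[ref$model == "trna_eq2", ]
  for (k in seq_len(nrow(trna))) {
    r <- lrt_from_loglik(trna$lnL_model[k], trna$lnL_null[k], df = 2)
    expect_lt(r$p_value, 5e-7)
  }
})

test_that("likelihood_ratio_test enforces nesting and handles the null case", {
  d <- simulate_growth_dataset("rrn_eq1", alpha = 9, beta = 0.012,
                               sigma = 0.5, n = 15, seed = 44)
  fm <- fit_growth_model(d, "rrn_eq1")
  fn <- fit_growth_model(d, "constant_null")
  lrt <- likelihood_ratio_test(fm, fn)
  expect_identical(lrt$df, 1L)
  expect_gte(lrt$G2, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$G2, 1, lower.tail = FALSE))

  # equal likelihoods -> G2 = 0, p = 1
  fn2 <- fn; fn2$lnL <- fm$lnL; fn2$n_params_mean <- 1L
  expect_equal(likelihood_ratio_test(fm, fn2)$p_value, 1)

  # mismatched data sizes refused
  d2 <- simulate_growth_dataset("rrn_eq1", alpha = 9, beta = 0.012,
                                sigma = 0.5, n = 9, seed = 45)
  fn3 <- fit_growth_model(d2, "constant_null")
  expect_error(likelihood_ratio_test(fm, fn3), "different data")
})

test_that("fits refuse under-sized datasets", {
  d <- data.frame(T_minutes = c(10, 100, 1000), y = c(9, 4, 1))
  expect_error(fit_growth_model(d, "trna_eq2"), "at least 4")
  expect_silent(fit_growth_model(d, "rrn_eq1"))
})
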