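test_that("slope_loglik collapses to the iid normal likelihood without random effects", {
  withr::with_seed(20, {
    d <- tibble::tibble(individual_id = rep(1:5, each = 3),
                        t = rnorm(15), y = rnorm(15))
  })
  ll <- slope_loglik(d, u1 = 0.3, u2 = -0.2, sigma_a2 = 0, sigma_b2 = 0,
                     sigma_e2 = 1.3)
  r <- d$y - 0.3 + 0.2 * d$t
  expect_equal(ll, sum(dnorm(r, 0, sqrt(1.3), log = TRUE)))
})

test_that("slope_loglik matches a dense multivariate-normal oracle", {
  # 2-individual toy with fixed printed values
  d <- tibble::tibble(
    individual_id = c("a", "a", "a", "b", "b"),
    t = c(-1.2, 0.1, 1.3, -0.6, 0.8),
    y = c(0.42, -0.31, 1.77, -1.05, 0.23))
  pars <- list(u1 = 0.1, u2 = 0.4, sigma_a2 = 0.7, sigma_b2 = 0.3,
               sigma_e2 = 0.5, sigma_ab = 0.2)
  ll <- do.call(slope_loglik, c(list(d), pars))
  oracle <- do.call(dense_mvn_loglik, c(list(d), pars))
  expect_equal(ll, oracle, tolerance = 1e-10)

  # larger random instance
  d2 <- make_balanced(12, seed = 5)$observations
  expect_equal(slope_loglik(d2, 0.2, -0.1, 0.9, 0.4, 0.8, 0.1),
               dense_mvn_loglik(d2, 0.2, -0.1, 0.9, 0.4, 0.8, 0.1),
               tolerance = 1e-9)
})

test_that("slope_loglik is invariant to a joint location shift", {
  d <- make_balanced(8, seed = 6)$observations
  ll1 <- slope_loglik(d, 0, 0.1, 1, 0.5, 1)
  d2 <- dplyr::mutate(d, y = y + 7)
  ll2 <- slope_loglik(d2, 7, 0.1, 1, 0.5, 1)
  expect_equal(ll1, ll2)
})

test_that("ML fit agrees with an independent mixed-model fitter on random instances", {
  skip_if_not_installed("lme4")
  withr::with_seed(30, seeds <- sample.int(1e6, 20))
  for (s in seeds) {
    pars <- withr::with_seed(s, list(
      n = sample(30:60, 1), sa = runif(1, 0, 1.5), sb = runif(1, 0, 1),
      se = runif(1, 0.3, 1.5)))
    d <- make_balanced(pars$n, sigma_a2 = pars$sa, sigma_b2 = pars$sb,
                       sigma_e2 = pars$se, u1 = 1, u2 = 0.2,
                       seed = s)$observations
    fit <- fit_slope_model(d)
    lf <- suppressMessages(lme4::lmer(
      y ~ t + (1 | individual_id) + (0 + t | individual_id),
      data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    expect_gte(fit$loglik_full, as.numeric(stats::logLik(lf)) - 1e-4)
  }
})

test_that("fit recovers the slope variance within its sampling error", {
  d <- make_balanced(2000, sigma_a2 = 1, sigma_b2 = 0.5, sigma_e2 = 1,
                     seed = 41)$observations
  fit <- fit_slope_model(d)
  expect_true(fit$converged)
  # rough information-based SE for a variance component at this design
  se <- sqrt(2 / 2000) * 0.75
  expect_lt(abs(fit$sigma_b2 - 0.5), 4 * se)
  expect_lt(abs(fit$sigma_a2 - 1), 4 * sqrt(2 / 2000) * 1.3)
})

test_that("a noiseless generative model drives sigma_e2 to the boundary", {
  d <- make_balanced(60, sigma_a2 = 1, sigma_b2 = 0.5, sigma_e2 = 0,
                     seed = 42)$observations
  fit <- fit_slope_model(d)
  expect_true(fit$converged)
  expect_lt(fit$sigma_e2, 1e-6)
  expect_gt(fit$sigma_b2, 0.2)
})

test_that("mixture LRT p-values follow the halved chi-square tail", {
  expect_equal(lrt_mixture_p(0), 0.5)
  expect_equal(lrt_mixture_p(qchisq(0.90, 1)), 0.05, tolerance = 1e-12)
  expect_equal(lrt_mixture_p(qchisq(0.95, 1)), 0.025, tolerance = 1e-12)
  expect_equal(lrt_mixture_p(-1e-12), 0.5)   # numerical negatives clipped
  expect_error(lrt_mixture_p(NaN), "non-NA")
})

test_that("model nesting holds on every converged fit", {
  for (s in 1:8) {
    d <- make_balanced(40, sigma_b2 = 0.06 * (s - 1), seed = 100 + s)$observations
    f <- fit_slope_model(d)
    expect_gte(f$loglik_full, f$loglik_null_slope - 1e-6)
    expect_gte(f$loglik_full, f$loglik_null_intercept - 1e-6)
    expect_gte(f$lrt_slope, 0)
    expect_gt(f$p_slope, 0)
    expect_lte(f$p_slope, 0.5)
  }
})

test_that("BLUPs are zero under zero variances and shrink OLS slopes", {
  # degenerate: both variances fitted at zero -> BLUPs exactly zero
  d <- simulate_probe(20, rep(list(c(-1, 0, 1)), 20), 2, 0,
                      0, 0, 1, seed = 51)$observations
  f <- fit_slope_model(d)
  if (f$sigma_a2 == 0 && f$sigma_b2 == 0) {
    expect_true(all(f$blup$intercept == 0))
    expect_true(all(f$blup$slope == 0))
  }

  # shrinkage: |BLUP slope| <= |per-individual OLS slope| on balanced data
  d <- make_balanced(100, sigma_b2 = 0.5, seed = 52)$observations
  f <- fit_slope_model(d)
  bl <- predict_blups(f)
  r <- d$y - f$u[1] - f$u[2] * d$t
  ols <- tapply(seq_len(nrow(d)), d$individual_id, function(i)
    coef(lm.fit(cbind(1, d$t[i]), r[i]))[2])
  ols <- ols[as.character(bl$individual_id)]
  expect_true(all(abs(bl$slope) <= abs(ols) + 1e-10))

  # sigma_e2 -> 0 limit: BLUP slope approaches the per-individual OLS slope
  d0 <- make_balanced(50, sigma_b2 = 0.5, sigma_e2 = 1e-6, seed = 53)$observations
  f0 <- fit_slope_model(d0)
  bl0 <- predict_blups(f0)
  r0 <- d0$y - f0$u[1] - f0$u[2] * d0$t
  ols0 <- tapply(seq_len(nrow(d0)), d0$individual_id, function(i)
    coef(lm.fit(cbind(1, d0$t[i]), r0[i]))[2])
  expect_equal(as.numeric(bl0$slope),
               as.numeric(ols0[as.character(bl0$individual_id)]),
               tolerance = 1e-2)
})

test_that("null slope statistics follow the boundary mixture", {
  long <- make_null_long(n_probes = 300, n_ind = 150, seed = 61)
  sc <- scan_probes(long)
  stats <- sc$lrt_slope[sc$converged]
  # about half the statistics sit at the zero boundary
  expect_lt(abs(mean(stats < 1e-8) - 0.5), 0.1)
  # mean statistic close to the mixture null expectation 0.5
  expect_lt(abs(mean(stats) - 0.5), 0.12)
  # p-values never exceed 0.5 and are stochastically >= uniform on (0, 0.5]
  expect_true(all(sc$p_slope <= 0.5 & sc$p_slope > 0))
})

test_that("covariance-free and covariance-full fits give nearly identical slopes", {
  # data generated with sigma_ab = 0: per-individual predicted slopes from
  # the two model variants must correlate strongly
  cors <- vapply(1:6, function(s) {
    d <- make_balanced(150, sigma_a2 = 1, sigma_b2 = 0.4, sigma_e2 = 0.7,
                       seed = 200 + s)$observations
    f1 <- fit_slope_model(d)
    f2 <- fit_slope_model(d, covariance = TRUE)
    cor(f1$blup$slope, f2$blup$slope)
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
  expect_true(all(cors > 0.7))
})

test_that("an unnecessary quadratic term barely moves slope-variance estimates", {
  rel <- vapply(1:8, function(s) {
    d <- make_balanced(120, sigma_a2 = 0.8, sigma_b2 = 0.4, sigma_e2 = 0.6,
                       u2 = 0.2, seed = 300 + s)$observations
    f1 <- fit_slope_model(d)
    f2 <- fit_slope_model(d, quadratic = TRUE)
    abs(f2$sigma_b2 - f1$sigma_b2) / f1$sigma_b2
  }, numeric(1))
  expect_lt(median(rel), 0.02)
})

test_that("tidy, glance and print expose the fit in broom style", {
  d <- make_balanced(30, seed = 71)$observations
  f <- fit_slope_model(d)
  td <- tidy(f)
  expect_true(all(c("term", "type", "estimate") %in% names(td)))
  expect_setequal(td$term[td$type == "varcomp"],
                  c("sigma_a2", "sigma_b2", "sigma_ab", "sigma_e2"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_output(print(f), "Longitudinal random-slope model")
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
})

test_that("fitting rejects malformed observation sets", {
  d <- tibble::tibble(individual_id = c(1, 1, 2), t = c(0, 1, 0),
                      y = rnorm(3))
  expect_error(fit_slope_model(d), "at least 2 observations")
  expect_error(fit_slope_model(dplyr::mutate(d, y = NA_real_)), "missing")
})
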