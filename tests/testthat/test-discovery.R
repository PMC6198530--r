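test_that("scanning one probe reproduces the single fit, deterministically", {
  d <- make_balanced(50, seed = 80)$observations
  d$probe_id <- "cg1"
  sc1 <- scan_probes(d)
  sc2 <- scan_probes(d)
  expect_identical(as.data.frame(sc1), as.data.frame(sc2))
  f <- fit_slope_model(d)
  expect_equal(sc1$lrt_slope, f$lrt_slope)
  expect_equal(sc1$sigma_b2, f$sigma_b2)
  expect_equal(sc1$p_slope, f$p_slope)
})

test_that("scan discoveries at Bonferroni are truly non-null probes with power", {
  seeds <- withr::with_seed(81, sample.int(1e6, 50))
  long <- purrr::map_dfr(1:50, function(j) {
    sb <- if (j <= 25) 0.5 else 0
    sim <- simulate_probe(500, rep(list(c(-1.2, 0, 1.2)), 500), 0, 0.1,
                          1, sb, 1, seed = seeds[j])
    dplyr::mutate(sim$observations, probe_id = sprintf("p%02d", j))
  })
  sc <- scan_probes(long)
  thr <- bonferroni_threshold(0.05, 50)
  hits <- sc$probe_id[sc$converged & sc$p_slope < thr]
  truth_nonnull <- sprintf("p%02d", 1:25)
  expect_gt(length(hits), 0)
  expect_true(all(hits %in% truth_nonnull))
})

test_that("Bonferroni thresholds match their definition", {
  expect_equal(bonferroni_threshold(0.05, 344000), 0.05 / 344000)
  expect_equal(round(bonferroni_threshold(0.05, 344000), 8), 1.5e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(5e-8, 1507), 5e-8 / 1507)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("replication split groups individuals by timepoint count", {
  # individuals with wave counts 2, 3, 4, 4
  long <- purrr::map_dfr(1:2, function(j) {
    obs <- purrr::map_dfr(1:4, function(i) {
      k <- c(2, 3, 4, 4)[i]
      tibble::tibble(individual_id = sprintf("i%d", i),
                     t = seq(-1, 1, length.out = k),
                     y = rnorm(k, sd = 0.5) + rnorm(1) +
                       rnorm(1, 0, 0.8) * seq(-1, 1, length.out = k))
    })
    dplyr::mutate(obs, probe_id = sprintf("p%d", j))
  })
  withr::with_seed(83, sr <- suppressWarnings(split_replicate(long)))
  expect_setequal(sr$groups$individual_id[sr$groups$group == "2-3"],
                  c("i1", "i2"))
  expect_setequal(sr$groups$individual_id[sr$groups$group == "4"],
                  c("i3", "i4"))
  expect_equal(sr$threshold, 0.05 / 2)
})

test_that("a null cohort yields no replicated rsCpGs; strong slopes replicate", {
  # strong slope variance everywhere, decent n: every probe replicates
  seeds <- withr::with_seed(84, sample.int(1e6, 6))
  mk <- function(sb) purrr::map_dfr(1:6, function(j) {
    waves <- rep(c(2, 3, 4), length.out = 120)
    ages <- lapply(waves, function(k) seq(-1.2, 1.2, length.out = k))
    sim <- simulate_probe(120, ages, 0, 0, 0.5, sb, 0.3, seed = seeds[j])
    dplyr::mutate(sim$observations, probe_id = sprintf("p%d", j))
  })
  sr_strong <- suppressWarnings(split_replicate(mk(2)))
  expect_setequal(sr_strong$rscpg, sprintf("p%d", 1:6))
  sr_null <- suppressWarnings(split_replicate(mk(0)))
  expect_length(sr_null$rscpg, 0)
})

test_that("bootstrap correlation CI behaves at its edges and is seeded", {
  x <- c(1.2, 0.3, -0.7, 2.2, 0.9, -1.4)
  ci <- bootstrap_corr_ci(x, x, B = 200, seed = 4)
  expect_equal(ci$r, 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  withr::with_seed(85, { a <- rnorm(300); b <- 0.5 * a + rnorm(300) })
  ci1 <- bootstrap_corr_ci(a, b, B = 500, seed = 9)
  ci2 <- bootstrap_corr_ci(a, b, B = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1$ci_low, ci1$r)
  expect_gt(ci1$ci_high, ci1$r)
  expect_error(bootstrap_corr_ci(rep(1, 5), rnorm(5)), "variance")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  withr::with_seed(86, { a <- rnorm(4000); b <- 0.4 * a + rnorm(4000) })
  w <- vapply(c(250, 4000), function(n) {
    ci <- bootstrap_corr_ci(a[1:n], b[1:n], B = 400, seed = 2)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  # 16x more data: width ratio should be near 4, allow wide slack
  expect_gt(w[1] / w[2], 2.5)
})

test_that("bootstrap CI covers the true null correlation at its nominal rate", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(1000 + s, { a <- rnorm(400); b <- rnorm(400) })
    ci <- bootstrap_corr_ci(a, b, B = 300, seed = s)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  }, logical(1))
  # 95% nominal; binomial 3-sigma band around 38/40
  expect_gte(sum(hits), 33)
})

test_that("overlap odds ratio and permutation p follow the 2x2 arithmetic", {
  universe <- sprintf("u%03d", 1:100)
  a <- universe[1:10]
  b <- universe[6:15]   # overlap 5
  res <- overlap_or_perm(a, b, universe, B = 2000, seed = 7)
  expect_equal(res$odds_ratio, (5 * 85) / (5 * 5))
  expect_equal(res$overlap, 5)

  disj <- overlap_or_perm(universe[1:10], universe[21:30], universe,
                          B = 200, seed = 7)
  expect_equal(disj$odds_ratio, 0)

  # p floor is 1/(B+1)
  full <- overlap_or_perm(universe[1:10], universe[1:10], universe,
                          B = 2000, seed = 7)
  expect_equal(full$p_perm, 1 / 2001)
})

test_that("permuting ages destroys the age linkage but keeps calibration", {
  long <- make_null_long(n_probes = 30, n_ind = 80, seed = 87)
  pc <- permutation_calibration(long, n_perm = 5, seed = 3)
  expect_equal(nrow(pc), 5)
  # null data: permuted means stay near the mixture expectation 0.5
  expect_lt(abs(mean(pc$mean_stat) - 0.5), 0.25)
  pc2 <- permutation_calibration(long, n_perm = 5, seed = 3)
  expect_identical(pc, pc2)

  # strong-signal cohort: permutation wipes out the signal
  seeds <- withr::with_seed(88, sample.int(1e6, 10))
  sig <- purrr::map_dfr(1:10, function(j) {
    sim <- simulate_probe(80, rep(list(c(-1.2, 0, 1.2)), 80), 0, 0,
                          0.5, 1.5, 0.3, seed = seeds[j])
    dplyr::mutate(sim$observations, probe_id = sprintf("s%d", j))
  })
  pcs <- permutation_calibration(sig, n_perm = 3, seed = 5)
  expect_lt(max(pcs$mean_stat), attr(pcs, "observed_mean") / 5)
})

test_that("lambda summaries follow the stated conventions", {
  chi_med <- qchisq(0.5, 1)
  # all-zero mixture statistics
  ls0 <- lambda_stats(rep(0, 100), kind = "mixture")
  expect_equal(ls0$lambda_mean, 0)
  expect_equal(ls0$proportion_zero, 1)
  # chisq1 statistics all at the chi-square median
  ls1 <- lambda_stats(rep(chi_med, 10), kind = "chisq1")
  expect_equal(ls1$lambda_median, 1)
  # large null mixture sample: lambda_mean near 1
  withr::with_seed(89, {
    stats <- ifelse(runif(20000) < 0.5, 0, rchisq(20000, 1))
  })
  ls2 <- lambda_stats(stats, kind = "mixture")
  expect_lt(abs(ls2$lambda_mean - 1), 0.05)
  expect_lt(abs(ls2$proportion_zero - 0.5), 0.02)
  expect_error(lambda_stats(numeric(0)), "non-empty")
})
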