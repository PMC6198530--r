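#' Genome-wide random-slope scan
#'
#' Fits the longitudinal random-slope model to every probe of a
#' preprocessed long-format dataset and returns one row of estimates and
#' test results per converged probe. Fitting is deterministic: identical
#' input gives identical output.
#'
#' @param data Long tibble with columns `probe_id`, `individual_id`, `t`
#'   (standardized age) and `y` (residual M-value), e.g. from
#'   [preprocess_meth()].
#' @param covariance,quadratic Model variants, see [fit_slope_model()].
#' @param keep_blups If `TRUE`, adds a list-column `blup` holding each
#'   probe's per-individual predicted random effects.
#' @param control Optimizer settings.
#' @return A tibble of class `slope_scan`: `probe_id`, fixed effects,
#'   variance components, `lrt_slope`, `p_slope`, `lrt_intercept`,
#'   `p_intercept`, `converged`, `n_ind`, `n_obs`.
#' @export
scan_probes <- function(data, covariance = FALSE, quadratic = FALSE,
                        keep_blups = FALSE, control = slope_control()) {
  .assert(all(c("probe_id", "individual_id", "t", "y") %in% names(data)),
          "data needs columns probe_id, individual_id, t, y")
  .assert(nrow(data) > 0, "empty probe set")
  by_probe <- split(seq_len(nrow(data)),
                    factor(data$probe_id, levels = unique(data$probe_id)))
  rows <- purrr::imap(by_probe, function(idx, pid) {
    d <- data[idx, ]
    # drop individuals with fewer than 2 observations
    n_per <- table(d$individual_id)
    if (any(n_per < 2L))
      d <- d[d$individual_id %in% names(n_per)[n_per >= 2L], ]
    if (length(unique(d$individual_id)) < 2L)
      return(tibble::tibble(probe_id = pid, converged = FALSE))
    f <- fit_slope_model(d, covariance = covariance, quadratic = quadratic,
                         control = control)
    out <- dplyr::bind_cols(tibble::tibble(probe_id = pid),
                            glance(f)[, c("sigma_a2", "sigma_b2", "sigma_ab",
                                          "sigma_e2", "lrt_slope", "p_slope",
                                          "lrt_intercept", "p_intercept",
                                          "converged", "n_ind", "n_obs")])
    out$u1 <- f$u[1]; out$u2 <- f$u[2]
    out$logLik <- f$loglik_full
    if (keep_blups) out$blup <- list(f$blup)
    out
  })
  res <- dplyr::bind_rows(rows)
  n_bad <- sum(!res$converged)
  if (n_bad > 0)
    inform(sprintf("%d probe(s) failed to converge and are flagged", n_bad))
  class(res) <- c("slope_scan", class(res))
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 344000)   # 1.45e-07
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  .assert(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .assert(.is_count(n_tests), "n_tests must be a positive integer")
  alpha / n_tests
}

#' Two-group replication of the random-slope scan (rsCpG definition)
#'
#' Partitions individuals by their number of observed timepoints — one
#' group with 2 or 3 timepoints, the other with 4 — scans each group
#' separately, and returns the probes whose random-slope test passes the
#' Bonferroni threshold `alpha / n_probes` in *both* groups (the
#' replicated set, "rsCpGs"). Age is re-standardized within each group
#' when an `age_years` column is present.
#'
#' @inheritParams scan_probes
#' @param alpha Family-wise level used for the per-group Bonferroni
#'   threshold (same threshold in both groups).
#' @param min_group Minimum individuals per group below which a warning is
#'   raised.
#' @return A list: `rscpg` (character vector of replicated probe ids),
#'   `threshold`, `scans` (list of the two `slope_scan` tibbles) and
#'   `groups` (tibble individual_id, group).
#' @export
split_replicate <- function(data, alpha = 0.05, min_group = 20L,
                            covariance = FALSE, quadratic = FALSE,
                            control = slope_control()) {
  .assert(all(c("probe_id", "individual_id", "y") %in% names(data)),
          "data needs probe_id, individual_id, y")
  # timepoint count per individual: the most complete probe's record count
  tp <- data |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(n_tp = max(table(.data$probe_id)), .groups = "drop")
  groups <- dplyr::mutate(tp, group = ifelse(.data$n_tp >= 4, "4", "2-3"))
  .assert(any(groups$group == "2-3") && any(groups$group == "4"),
          "both replication groups must be non-empty")
  for (g in c("2-3", "4"))
    if (sum(groups$group == g) < min_group)
      warn(sprintf("replication group '%s' has fewer than %d individuals",
                   g, min_group))
  scans <- lapply(c("2-3", "4"), function(g) {
    d <- data[data$individual_id %in%
                groups$individual_id[groups$group == g], ]
    if ("age_years" %in% names(d))
      d <- d |>
        dplyr::group_by(.data$probe_id) |>
        dplyr::mutate(t = standardize_age(.data$age_years)) |>
        dplyr::ungroup()
    scan_probes(d, covariance = covariance, quadratic = quadratic,
                control = control)
  })
  names(scans) <- c("2-3", "4")
  n_probes <- length(unique(data$probe_id))
  thr <- bonferroni_threshold(alpha, n_probes)
  sig <- lapply(scans, function(s)
    s$probe_id[s$converged & s$p_slope < thr])
  list(rscpg = intersect(sig[["2-3"]], sig[["4"]]),
       threshold = thr, scans = scans,
       groups = dplyr::select(groups, "individual_id", "group"))
}

#' Bootstrap percentile confidence interval for a Pearson correlation
#'
#' Resamples the (x, y) pairs with replacement `B` times and returns the
#' 2.5/97.5 percentile bounds of the resampled correlations, alongside the
#' correlation of the original pairs.
#'
#' @param x,y Numeric vectors of equal length (>= 3), e.g. per-probe slope
#'   variances estimated in two groups.
#' @param B Number of bootstrap resamples (default 30000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble: `r`, `ci_low`, `ci_high`, `B`.
#' @export
bootstrap_corr_ci <- function(x, y, B = 30000L, seed = 1L, conf = 0.95) {
  .assert(length(x) == length(y) && length(x) >= 3L,
          "x and y must have equal length >= 3")
  .assert(sd(x) > 0 && sd(y) > 0, "x and y must have positive variance")
  n <- length(x)
  r <- cor(x, y)
  rs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[idx], y[idx]))
    }, numeric(1))
  })
  qs <- quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  tibble::tibble(r = r, ci_low = qs[1], ci_high = qs[2], B = B)
}

#' Permutation test of the overlap between two probe sets
#'
#' Forms the 2x2 table of membership in `set_a` x membership in `set_b`
#' over the `universe` and reports its odds ratio, with an empirical
#' p-value from `B` random draws of `|set_a|` probes from the universe
#' (add-one correction: the smallest attainable p is `1/(B+1)`, 3.33e-5 at
#' B = 30000).
#'
#' @param set_a,set_b Probe id vectors, subsets of `universe`.
#' @param universe All probe ids under consideration.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return A tibble: `odds_ratio`, `p_perm`, `overlap`, `B`, `infinite`
#'   (flag set when a zero cell makes the OR infinite).
#' @export
overlap_or_perm <- function(set_a, set_b, universe, B = 30000L, seed = 1L) {
  .assert(all(set_a %in% universe) && all(set_b %in% universe),
          "both sets must be subsets of the universe")
  in_b <- universe %in% set_b
  or_of <- function(in_a) {
    a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
    c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
    if (b * c_ == 0) Inf else (a * d) / (b * c_)
  }
  obs <- or_of(universe %in% set_a)
  n_a <- length(unique(set_a))
  perm <- withr::with_seed(seed, {
    vapply(seq_len(B), function(k) {
      or_of(seq_along(universe) %in% sample.int(length(universe), n_a))
    }, numeric(1))
  })
  p <- (sum(perm >= obs) + 1) / (B + 1)
  tibble::tibble(odds_ratio = obs, p_perm = p,
                 overlap = length(intersect(set_a, set_b)), B = B,
                 infinite = is.infinite(obs))
}

#' Permutation calibration of the random-slope test statistic
#'
#' Permutes the standardized-age labels across all sample records (jointly
#' for every probe, preserving each individual's observation count but
#' breaking the individual-age linkage), refits every probe, and records
#' the mean slope LRT statistic of each round. Under a well-calibrated
#' mixture null the mean statistic is 0.5.
#'
#' @inheritParams scan_probes
#' @param n_perm Number of permutation rounds (>= 2).
#' @param seed Integer seed.
#' @return A tibble with one row per round: `perm`, `mean_stat`,
#'   `prop_zero`; attribute `observed_mean` holds the unpermuted mean
#'   statistic.
#' @export
permutation_calibration <- function(data, n_perm = 500L, seed = 1L,
                                    control = slope_control()) {
  .assert(.is_count(n_perm) && n_perm >= 2, "n_perm must be >= 2")
  obs_scan <- scan_probes(data, control = control)
  observed <- mean(obs_scan$lrt_slope[obs_scan$converged])
  # permute the age of each sample record once per round, consistently
  # across probes
  samp <- dplyr::distinct(data, .data$individual_id, .data$t)
  seeds <- .child_seeds(seed, n_perm)
  rows <- purrr::map(seq_len(n_perm), function(k) {
    pt <- withr::with_seed(seeds[k], sample(samp$t))
    lut <- stats::setNames(pt, paste(samp$individual_id, samp$t))
    d <- dplyr::mutate(data,
                       t = unname(lut[paste(.data$individual_id, .data$t)]))
    s <- scan_probes(d, control = control)
    tibble::tibble(perm = k,
                   mean_stat = mean(s$lrt_slope[s$converged]),
                   prop_zero = mean(s$lrt_slope[s$converged] < 1e-5))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "observed_mean") <- observed
  out
}

#' Genomic-control lambda summaries of a statistic set
#'
#' For boundary-mixture LRT statistics (`kind = "mixture"`): `lambda_mean`
#' is the mean statistic divided by its null expectation 0.5 (the raw mean
#' is also returned, since the mean statistic itself is often quoted as
#' the inflation value), and `lambda_median` is computed on the non-zero
#' statistics against the chi-squared(1) median 0.4549. For plain
#' chi-squared(1) statistics (`kind = "chisq1"`, the GWAS convention):
#' `lambda_median = median / 0.4549` and `lambda_mean = mean / 1`.
#'
#' @param statistics Non-empty numeric vector of test statistics.
#' @param kind `"mixture"` for the boundary-mixture LRT, `"chisq1"` for
#'   one-df chi-squared statistics.
#' @return A tibble: `lambda_mean`, `lambda_median`, `mean_stat`,
#'   `proportion_zero` (fraction below 1e-5), `n`.
#' @export
lambda_stats <- function(statistics, kind = c("mixture", "chisq1")) {
  kind <- match.arg(kind)
  .assert(length(statistics) > 0 && !anyNA(statistics),
          "statistics must be non-empty without NAs")
  chi_med <- qchisq(0.5, df = 1)
  prop0 <- mean(statistics < 1e-5)
  if (kind == "mixture") {
    nz <- statistics[statistics >= 1e-5]
    lam_med <- if (length(nz)) median(nz) / chi_med else 0
    tibble::tibble(lambda_mean = mean(statistics) / 0.5,
                   lambda_median = lam_med,
                   mean_stat = mean(statistics),
                   proportion_zero = prop0,
                   n = length(statistics))
  } else {
    tibble::tibble(lambda_mean = mean(statistics),
                   lambda_median = median(statistics) / chi_med,
                   mean_stat = mean(statistics),
                   proportion_zero = prop0,
                   n = length(statistics))
  }
}
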