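#' Configuration for the SNP-by-age simulation study
#'
#' Describes the generative model
#' \deqn{y_{ij} = (\beta_k d_{ik} + e_i) t_{ij} + e_{ij}}
#' of a single SNP's effect on the methylation slope: dosages are HWE
#' draws at a MAF uniform on `maf_range`, the residual slope `e_i` and
#' noise `e_ij` are standard normal, and each individual is observed at
#' three ages around 60, 70 and 80 years (normal jitter, SD
#' `age_jitter_sd`; set it to 0 for exact ages). Ages are standardized to
#' mean 0, variance 1 across all observations before simulation, the same
#' scale the main longitudinal model uses.
#'
#' @param n_individuals Individuals per replicate (default 3000).
#' @param ages Mean ages of the three timepoints.
#' @param age_jitter_sd SD of the per-sample age jitter, years.
#' @param maf_range MAF range, within (0, 0.5].
#' @param beta_mode `"zero"` (null: no SNP effect) or `"uniform"` (beta
#'   drawn uniformly on `beta_range`).
#' @param beta_range Range of the SNP slope effect under
#'   `beta_mode = "uniform"`.
#' @param standardize_t Standardize ages before simulating (default TRUE);
#'   exposed because the inflation magnitude of the naive interaction test
#'   depends on the age scale.
#' @return A list of class `sim_study_config`.
#' @export
sim_study_config <- function(n_individuals = 3000L,
                             ages = c(60, 70, 80),
                             age_jitter_sd = 0.5,
                             maf_range = c(0.05, 0.5),
                             beta_mode = c("zero", "uniform"),
                             beta_range = c(-0.1, 0.1),
                             standardize_t = TRUE) {
  beta_mode <- match.arg(beta_mode)
  .assert(.is_count(n_individuals) && n_individuals >= 10,
          "n_individuals must be an integer >= 10")
  .assert(all(diff(ages) > 0), "ages must be strictly increasing")
  .assert(all(maf_range > 0 & maf_range <= 0.5),
          "maf_range must lie in (0, 0.5]")
  .assert(age_jitter_sd >= 0, "age_jitter_sd must be >= 0")
  structure(as.list(environment()), class = "sim_study_config")
}

#' Simulate one replicate of the SNP-by-age study
#'
#' @param config A [sim_study_config()].
#' @param seed Integer seed for this replicate.
#' @return A tibble `individual_id`, `t`, `y`, `dosage`; attributes
#'   `beta` (the true SNP effect) and `e_i` (the residual slopes).
#' @export
simulate_interaction_rep <- function(config, seed = 1L) {
  .assert(inherits(config, "sim_study_config"),
          "config must be a sim_study_config")
  n <- config$n_individuals
  k <- length(config$ages)
  withr::with_seed(seed, {
    maf <- runif(1, config$maf_range[1], config$maf_range[2])
    d <- rbinom(n, 2L, maf)
    beta <- if (config$beta_mode == "uniform")
      runif(1, config$beta_range[1], config$beta_range[2]) else 0
    age <- rep(config$ages, n) + rnorm(n * k, 0, config$age_jitter_sd)
    e_i <- rnorm(n)
    e_ij <- rnorm(n * k)
  })
  t <- if (config$standardize_t) standardize_age(age) else age
  id <- rep(seq_len(n), each = k)
  y <- (beta * d[id] + e_i[id]) * t + e_ij
  structure(tibble::tibble(individual_id = id, t = t, y = y,
                           dosage = d[id]),
            beta = beta, e_i = e_i, maf = maf)
}

#' Method 1: SNP association with the mixed-model predicted slope
#'
#' Fits the longitudinal random intercept + random slope model to the
#' replicate, predicts the per-individual BLUP slopes, and regresses them
#' on the SNP dosage (simple linear regression, two-sided t-test).
#'
#' @param rep_data A replicate from [simulate_interaction_rep()].
#' @param control Optimizer settings.
#' @return A one-row tibble: `method`, `p`, `beta_hat`, `converged`.
#' @export
method1_slope_assoc <- function(rep_data, control = slope_control()) {
  d_ind <- rep_data |>
    dplyr::distinct(.data$individual_id, .data$dosage)
  .assert(stats::var(d_ind$dosage) > 0, "monomorphic SNP: dosage has no variance")
  X <- cbind(1, rep_data$t)
  fit <- .fit_core(rep_data$y, X, rep_data$t, rep_data$individual_id,
                   re = c("intercept", "slope"), control = control)
  if (!fit$converged)
    return(tibble::tibble(method = 1L, p = NA_real_, beta_hat = NA_real_,
                          converged = FALSE))
  b <- fit$blup[match(d_ind$individual_id, fit$ids), 2]
  dv <- d_ind$dosage - mean(d_ind$dosage)
  bv <- b - mean(b)
  n <- length(b)
  beta <- sum(dv * bv) / sum(dv^2)
  rss <- sum((bv - beta * dv)^2)
  se <- sqrt(rss / (n - 2) / sum(dv^2))
  tibble::tibble(method = 1L, p = 2 * stats::pt(-abs(beta / se), n - 2),
                 beta_hat = beta, converged = TRUE)
}

#' Method 2: naive pooled-OLS SNP-by-age interaction test
#'
#' Ordinary least squares of methylation on dosage, age and their
#' interaction across all observations, ignoring the repeated-measures
#' structure. Under a non-zero residual slope variance this test is
#' miscalibrated (inflated) even with no SNP effect.
#'
#' @inheritParams method1_slope_assoc
#' @return A one-row tibble: `method`, `p`, `beta_hat`, `converged`.
#' @export
method2_interaction_ols <- function(rep_data) {
  X <- cbind(1, rep_data$dosage, rep_data$t, rep_data$dosage * rep_data$t)
  qrX <- qr(X)
  .assert(qrX$rank == 4L, "singular interaction design")
  n <- nrow(X)
  cf <- qr.coef(qrX, rep_data$y)
  res <- rep_data$y - X %*% cf
  s2 <- sum(res^2) / (n - 4)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * XtXinv[4, 4])
  stat <- cf[4] / se
  tibble::tibble(method = 2L, p = 2 * stats::pt(-abs(stat), n - 4),
                 beta_hat = unname(cf[4]), converged = TRUE)
}

#' Method 3: interaction test with the random slope in the model
#'
#' The default fits the longitudinal mixed model `y ~ dosage + t +
#' dosage:t` with a per-individual random slope on `t` (optionally also a
#' random intercept) and Wald-tests the fixed interaction coefficient.
#' The alternative `variant = "blup_covariate"` reading first predicts
#' BLUP slopes from a dosage-free random-slope model and adds them,
#' multiplied by `t`, as an OLS covariate.
#'
#' @inheritParams method1_slope_assoc
#' @param variant `"mixed"` (default) or `"blup_covariate"`.
#' @param random_intercept Include a random intercept alongside the
#'   random slope (default `FALSE`, matching the generative model).
#' @return A one-row tibble: `method`, `p`, `beta_hat`, `converged`.
#' @export
method3_interaction_adjusted <- function(rep_data,
                                         variant = c("mixed", "blup_covariate"),
                                         random_intercept = FALSE,
                                         control = slope_control()) {
  variant <- match.arg(variant)
  X <- cbind(1, rep_data$dosage, rep_data$t, rep_data$dosage * rep_data$t)
  if (variant == "mixed") {
    re <- if (random_intercept) c("intercept", "slope") else "slope"
    fit <- .fit_core(rep_data$y, X, rep_data$t, rep_data$individual_id,
                     re = re, control = control)
    if (!fit$converged)
      return(tibble::tibble(method = 3L, p = NA_real_, beta_hat = NA_real_,
                            converged = FALSE))
    z <- fit$u[4] / sqrt(fit$vcov_u[4, 4])
    tibble::tibble(method = 3L, p = 2 * pnorm(-abs(z)),
                   beta_hat = fit$u[4], converged = TRUE)
  } else {
    base <- .fit_core(rep_data$y, cbind(1, rep_data$t), rep_data$t,
                      rep_data$individual_id, re = "slope", control = control)
    if (!base$converged)
      return(tibble::tibble(method = 3L, p = NA_real_, beta_hat = NA_real_,
                            converged = FALSE))
    s_i <- base$blup[match(rep_data$individual_id, base$ids), 2]
    X2 <- cbind(X, s_i * rep_data$t)
    qrX <- qr(X2)
    .assert(qrX$rank == ncol(X2), "singular adjusted design")
    cf <- qr.coef(qrX, rep_data$y)
    res <- rep_data$y - X2 %*% cf
    n <- nrow(X2)
    s2 <- sum(res^2) / (n - ncol(X2))
    se <- sqrt(s2 * chol2inv(qr.R(qrX))[4, 4])
    stat <- cf[4] / se
    tibble::tibble(method = 3L, p = 2 * stats::pt(-abs(stat), n - ncol(X2)),
                   beta_hat = unname(cf[4]), converged = TRUE)
  }
}

#' Run the SNP-by-age simulation study
#'
#' Simulates `n_reps` independent replicates (per-replicate seeds derived
#' from `seed`), applies the requested methods, converts each method's
#' p-values to chi-squared(1) quantiles and summarises their
#' median-based genomic-control lambda, `median(chisq) / 0.4549`, plus
#' power at the genome-wide 5e-8 threshold.
#'
#' @param config A [sim_study_config()].
#' @param n_reps Number of replicates (>= 100).
#' @param methods Integer subset of 1:3.
#' @param seed Master seed.
#' @param control Optimizer settings passed to the mixed-model methods.
#' @param variant3 Variant for method 3, see
#'   [method3_interaction_adjusted()].
#' @return A list of class `sim_study`: `results` (tibble `rep`, `method`,
#'   `p`, `beta_hat`, `converged`), `summary` (tibble `method`,
#'   `lambda_median`, `power_5e8`, `n_converged`), `config`.
#' @export
run_sim_study <- function(config, n_reps = 10000L, methods = 1:3,
                          seed = 1L, control = slope_control(),
                          variant3 = "mixed") {
  .assert(inherits(config, "sim_study_config"),
          "config must be a sim_study_config")
  .assert(.is_count(n_reps) && n_reps >= 100, "n_reps must be >= 100")
  .assert(all(methods %in% 1:3), "methods must be a subset of 1:3")
  seeds <- .child_seeds(seed, n_reps)
  rows <- purrr::map(seq_len(n_reps), function(r) {
    rep_data <- simulate_interaction_rep(config, seed = seeds[r])
    res <- dplyr::bind_rows(
      if (1L %in% methods) method1_slope_assoc(rep_data, control),
      if (2L %in% methods) method2_interaction_ols(rep_data),
      if (3L %in% methods) method3_interaction_adjusted(
        rep_data, variant = variant3, control = control))
    res$rep <- r
    res$beta_true <- attr(rep_data, "beta")
    res
  })
  results <- dplyr::bind_rows(rows)
  .assert(any(results$converged), "all replicates failed")
  summary <- results |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      lambda_median = median(qchisq(.data$p, df = 1, lower.tail = FALSE)) /
        qchisq(0.5, df = 1),
      power_5e8 = mean(.data$p < 5e-8),
      n_converged = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary, config = config,
                 n_reps = n_reps, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d replicates, beta_mode = %s\n", x$n_reps,
              x$config$beta_mode))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sim_study <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.sim_study <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "method",
                     values_from = c("lambda_median", "power_5e8",
                                     "n_converged"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sim_study <- function(object, ...) {
  d <- object$results |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(expected = -log10(stats::ppoints(dplyr::n())),
                  observed = -log10(.data$p)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed,
                                  colour = factor(.data$method))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)",
                  colour = "method",
                  title = "QQ plot of SNP-by-age association p-values")
}
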