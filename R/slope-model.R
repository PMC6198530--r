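#' Fit the per-probe longitudinal random-slope model
#'
#' Fits, by maximum likelihood, the linear mixed model
#' \deqn{y_{ij} = u_1 + u_2 t_{ij} + a_i + b_i t_{ij} + e_{ij}}
#' where \eqn{t_{ij}} is standardized age, \eqn{(a_i, b_i)} are a
#' per-individual random intercept and random slope with covariance
#' \eqn{\Omega}, and \eqn{e_{ij}} is iid Gaussian noise. The slope variance
#' \eqn{\sigma_b^2} (and, analogously, the intercept variance
#' \eqn{\sigma_a^2}) is tested with a likelihood-ratio statistic whose null
#' distribution is the boundary mixture \eqn{0.5\,\chi^2_0 + 0.5\,\chi^2_1},
#' i.e. the \eqn{\chi^2_1} p-value halved (see [lrt_mixture_p()]).
#'
#' ML (not REML) is used throughout: the tested models share their fixed
#' effects and the mixture rule applies to a genuine likelihood ratio.
#' The statistic is `2 * (loglik_full - loglik_null)`, clipped at zero.
#' Optimization runs from three deterministic starts (method-of-moments,
#' equal variance split, near-null); no randomness enters the fit.
#'
#' @param data A data frame with one row per sample observation.
#' @param y,t,id Columns of `data` (tidy-eval) holding the residual M-value,
#'   standardized age, and individual identifier. Defaults `y`, `t`,
#'   `individual_id`.
#' @param covariance If `TRUE`, the intercept-slope covariance
#'   \eqn{\sigma_{ab}} is a free parameter; the default fixes it at zero
#'   (independence of \eqn{a_i} and \eqn{b_i}).
#' @param quadratic If `TRUE`, a fixed quadratic age term \eqn{u_3 t^2} is
#'   added to the mean model.
#' @param control Optimizer settings, see [slope_control()].
#' @return An object of class `slope_fit` with [tidy()], [glance()],
#'   [predict_blups()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' d <- simulate_probe(n_individuals = 80, ages = rep(list(c(-1, 0, 1)), 80),
#'                     u1 = 0, u2 = 0.2, sigma_a2 = 1, sigma_b2 = 0.4,
#'                     sigma_e2 = 0.5, seed = 7)
#' fit <- fit_slope_model(d$observations)
#' glance(fit)
#' @export
fit_slope_model <- function(data, y = y, t = t, id = individual_id,
                            covariance = FALSE, quadratic = FALSE,
                            control = slope_control()) {
  yv <- dplyr::pull(data, {{ y }})
  tv <- dplyr::pull(data, {{ t }})
  iv <- dplyr::pull(data, {{ id }})
  .assert(is.numeric(yv) && is.numeric(tv), "y and t must be numeric")
  .assert(!anyNA(yv) && !anyNA(tv) && !anyNA(iv),
          "missing values in y, t or id")
  n_per <- table(iv)
  .assert(length(n_per) >= 2L, "need at least 2 individuals")
  .assert(all(n_per >= 2L), "every individual needs at least 2 observations")

  X <- cbind(`(Intercept)` = 1, t = tv)
  if (quadratic) X <- cbind(X, `t^2` = tv^2)

  full <- .fit_core(yv, X, tv, iv, re = c("intercept", "slope"),
                    covariance = covariance, control = control)
  null_slope <- .fit_core(yv, X, tv, iv, re = "intercept", control = control)
  null_int <- .fit_core(yv, X, tv, iv, re = "slope", control = control)

  lrt_s <- max(0, 2 * (full$loglik - null_slope$loglik))
  lrt_a <- max(0, 2 * (full$loglik - null_int$loglik))
  structure(list(
    u = setNames(full$u, colnames(X)),
    sigma_a2 = full$sigma_a2, sigma_b2 = full$sigma_b2,
    sigma_ab = full$sigma_ab, sigma_e2 = full$s2e,
    vcov_u = full$vcov_u,
    loglik_full = full$loglik,
    loglik_null_slope = null_slope$loglik,
    loglik_null_intercept = null_int$loglik,
    lrt_slope = lrt_s, p_slope = lrt_mixture_p(lrt_s),
    lrt_intercept = lrt_a, p_intercept = lrt_mixture_p(lrt_a),
    converged = full$converged && null_slope$converged && null_int$converged,
    n_ind = full$n_ind, n_obs = full$n_obs,
    covariance = covariance, quadratic = quadratic,
    blup = tibble::tibble(individual_id = full$ids,
                          intercept = full$blup[, 1],
                          slope = full$blup[, 2]),
    data = tibble::tibble(individual_id = iv, t = tv, y = yv)
  ), class = "slope_fit")
}

#' Boundary-mixture p-value for a variance-component LRT
#'
#' A variance tested on the boundary of its parameter space has a null LRT
#' distribution that is a 50:50 mixture of a point mass at zero and
#' \eqn{\chi^2_1}: the p-value is half the \eqn{\chi^2_1} tail probability,
#' so a statistic of exactly zero maps to p = 0.5.
#'
#' @param stat Non-negative LRT statistic(s); small negative values from
#'   numerical round-off are clipped to zero.
#' @return p-value(s) in (0, 0.5].
#' @examples
#' lrt_mixture_p(c(0, 2.706, 3.841))
#' @export
lrt_mixture_p <- function(stat) {
  .assert(is.numeric(stat) && !anyNA(stat), "stat must be numeric, non-NA")
  stat <- pmax(stat, 0)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Exact log-likelihood of the random-slope model at given parameters
#'
#' Evaluates, blockwise over individuals, the multivariate-normal
#' log-likelihood of the longitudinal model at user-supplied parameter
#' values (no fitting). Useful for audits and as the target the optimizer
#' maximizes.
#'
#' @inheritParams fit_slope_model
#' @param u1,u2 Fixed intercept and age effect; `u3` the optional fixed
#'   quadratic coefficient (`NULL` to omit the term).
#' @param sigma_a2,sigma_b2,sigma_e2,sigma_ab Variance components of the
#'   random intercept, random slope, residual, and their covariance.
#' @param u3 Optional fixed quadratic age coefficient.
#' @return The log-likelihood (scalar).
#' @export
slope_loglik <- function(data, u1, u2, sigma_a2, sigma_b2, sigma_e2,
                         sigma_ab = 0, u3 = NULL,
                         y = y, t = t, id = individual_id) {
  .assert(all(c(sigma_a2, sigma_b2, sigma_e2) >= 0), "variances must be >= 0")
  .assert(sigma_ab^2 <= sigma_a2 * sigma_b2 + 1e-12,
          "sigma_ab violates the Cauchy-Schwarz bound")
  yv <- dplyr::pull(data, {{ y }})
  tv <- dplyr::pull(data, {{ t }})
  iv <- dplyr::pull(data, {{ id }})
  mu <- u1 + u2 * tv + if (is.null(u3)) 0 else u3 * tv^2
  r <- yv - mu
  Om <- matrix(c(sigma_a2, sigma_ab, sigma_ab, sigma_b2), 2, 2)
  ll <- 0
  for (idx in split(seq_along(yv), factor(iv, levels = unique(iv)))) {
    Zi <- cbind(1, tv[idx])
    Vi <- tcrossprod(Zi %*% Om, Zi) + diag(sigma_e2, length(idx))
    ch <- tryCatch(chol(Vi), error = function(e)
      abort("singular within-individual covariance (degenerate parameters)"))
    z <- backsolve(ch, r[idx], transpose = TRUE)
    ll <- ll - 0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(z^2))
  }
  ll
}

#' Predicted per-individual random effects (BLUPs)
#'
#' Returns the conditional means \eqn{(\hat a_i, \hat b_i) =
#' \Omega Z_i' V_i^{-1} (y_i - X_i \hat u)} of each individual's random
#' intercept and slope given the fitted variance components. When both
#' fitted variances are zero all BLUPs are exactly zero; the predicted
#' slopes are shrunken towards zero relative to per-individual OLS slopes.
#'
#' @param fit A converged [fit_slope_model()] object.
#' @return A tibble with columns `individual_id`, `intercept`, `slope`.
#' @export
predict_blups <- function(fit) {
  .assert(inherits(fit, "slope_fit"), "fit must be a slope_fit")
  if (!fit$converged) abort("cannot predict random effects from a non-converged fit")
  fit$blup
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("Longitudinal random-slope model (ML)\n")
  cat(sprintf("  %d individuals, %d observations%s%s\n", x$n_ind, x$n_obs,
              if (x$covariance) ", free sigma_ab" else "",
              if (x$quadratic) ", quadratic age term" else ""))
  cat(sprintf("  fixed: u1 = %.4g, u2 = %.4g\n", x$u[1], x$u[2]))
  cat(sprintf("  varcomp: sigma_a2 = %.4g, sigma_b2 = %.4g, sigma_ab = %.4g, sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_b2, x$sigma_ab, x$sigma_e2))
  cat(sprintf("  slope LRT = %.4g (mixture p = %.3g); intercept LRT = %.4g (p = %.3g)\n",
              x$lrt_slope, x$p_slope, x$lrt_intercept, x$p_intercept))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slope_fit <- function(x, ...) {
  fixed <- tibble::tibble(
    term = names(x$u), type = "fixed", estimate = unname(x$u),
    std.error = sqrt(diag(x$vcov_u)))
  vc <- tibble::tibble(
    term = c("sigma_a2", "sigma_b2", "sigma_ab", "sigma_e2"),
    type = "varcomp",
    estimate = c(x$sigma_a2, x$sigma_b2, x$sigma_ab, x$sigma_e2),
    std.error = NA_real_)
  dplyr::bind_rows(fixed, vc)
}

#' @exportS3Method generics::glance
glance.slope_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik_full,
    logLik_null_slope = x$loglik_null_slope,
    lrt_slope = x$lrt_slope, p_slope = x$p_slope,
    lrt_intercept = x$lrt_intercept, p_intercept = x$p_intercept,
    sigma_a2 = x$sigma_a2, sigma_b2 = x$sigma_b2,
    sigma_ab = x$sigma_ab, sigma_e2 = x$sigma_e2,
    converged = x$converged, n_ind = x$n_ind, n_obs = x$n_obs)
}

#' @describeIn fit_slope_model Spaghetti plot of observed trajectories with
#'   the population mean line and per-individual BLUP lines.
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.slope_fit <- function(object, ...) {
  d <- object$data
  bl <- object$blup
  pred <- dplyr::left_join(d, bl, by = "individual_id") |>
    dplyr::mutate(fitted = object$u[1] + object$u[2] * .data$t +
                    .data$intercept + .data$slope * .data$t)
  ggplot2::ggplot(pred, ggplot2::aes(.data$t, .data$y,
                                     group = .data$individual_id)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = object$u[1], slope = object$u[2],
                         colour = "red", linewidth = 1) +
    ggplot2::labs(x = "standardized age", y = "residual M-value",
                  title = "Fitted individual methylation trajectories")
}
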