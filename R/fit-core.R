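# Internal fitting machinery shared by fit_slope_model(), scan_probes() and
# the simulation study. The residual variance and fixed effects are profiled
# out analytically, so the optimizer works on the 1-3 free entries of
# Gamma = Omega / sigma_e^2 under box constraints (variance ratios >= 0,
# correlation in (-1, 1)).

#' Control parameters for the mixed-model optimizer
#'
#' @param rel_tol Relative convergence tolerance on the profile
#'   log-likelihood.
#' @param max_iter Maximum optimizer iterations per start.
#' @param starts Which deterministic initializations to use: method-of-moments
#'   from per-individual OLS lines, an equal split of the total variance, and
#'   a near-null start with the slope variance just off the boundary.
#' @return A list of class `slope_control`.
#' @export
slope_control <- function(rel_tol = 1e-10, max_iter = 500L,
                          starts = c("mom", "equal", "null")) {
  structure(list(rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 starts = match.arg(starts, several.ok = TRUE)),
            class = "slope_control")
}

# Order observations by individual and describe the block structure.
# match() instead of factor(): no character coercion on the hot path.
#' @noRd
.block_index <- function(id) {
  uid <- unique(id)
  code <- match(id, uid)
  ord <- order(code)
  sizes <- tabulate(code, nbins = length(uid))
  list(order = ord,
       ids = uid,
       code = code,
       start = as.integer(cumsum(c(0L, sizes[-length(sizes)]))),
       size = as.integer(sizes))
}

# Deterministic method-of-moments start from per-individual OLS lines,
# computed from per-individual sufficient statistics (no per-block fits).
# Expects y, X, t already ordered by individual; returns c(gamma_a, gamma_b).
#' @noRd
.mom_start <- function(y, X, t, code_ordered) {
  r <- tryCatch(resid(lm.fit(X, y)), error = function(e) y - mean(y))
  S <- rowsum(cbind(1, t, t^2, r, t * r, r^2), code_ordered, reorder = FALSE)
  m <- S[, 1]; St <- S[, 2]; Stt <- S[, 3]
  Sr <- S[, 4]; Str <- S[, 5]; Srr <- S[, 6]
  Sxx <- Stt - St^2 / m
  Sxy <- Str - St * Sr / m
  ok <- Sxx > 1e-10
  b <- ifelse(ok, Sxy / pmax(Sxx, 1e-10), NA_real_)
  a <- ifelse(ok, (Sr - b * St) / m, Sr / m)
  ryy <- Srr - Sr^2 / m
  rss <- sum((ryy - b^2 * Sxx)[ok & m > 2])
  df <- sum((m - 2)[ok & m > 2])
  s2 <- if (df > 0) rss / df else var(r) / 2
  s2 <- max(s2, 1e-8)
  ga <- max(var(a, na.rm = TRUE), 0) / s2
  gb <- if (all(is.na(b))) 1 else max(var(b, na.rm = TRUE), 0) / s2
  pmin(pmax(c(ga, gb), 1e-4), 1e4)
}

# Fit the block mixed model by profiled maximum likelihood.
#   y, X, t: observation-level response, fixed design, age covariate
#   id: individual labels; re: which random effects ("intercept", "slope")
#   covariance: free sigma_ab (only meaningful with both random effects)
# Returns loglik, fixed effects, variance components (on the data scale),
# vcov of fixed effects, BLUPs, and a convergence flag.
#' @noRd
.fit_core <- function(y, X, t, id, re = c("intercept", "slope"),
                      covariance = FALSE, control = slope_control()) {
  blocks <- .block_index(id)
  ord <- blocks$order
  yo <- y[ord]; Xo <- X[ord, , drop = FALSE]; to <- t[ord]
  N <- length(yo)
  q_int <- "intercept" %in% re
  q_slope <- "slope" %in% re
  Z <- cbind(if (q_int) rep(1, N), if (q_slope) to)
  if (is.null(Z)) {                      # iid model: closed-form ML
    fit <- lm.fit(Xo, yo)
    s2e <- sum(fit$residuals^2) / N
    ll <- -0.5 * N * (log(2 * pi * s2e) + 1)
    XtXinv <- chol2inv(chol(crossprod(Xo)))
    return(list(loglik = ll, u = unname(coef(fit)), s2e = s2e,
                sigma_a2 = 0, sigma_b2 = 0, sigma_ab = 0,
                vcov_u = XtXinv * s2e,
                blup = matrix(0, length(blocks$size), 2),
                ids = blocks$ids, converged = TRUE,
                n_ind = length(blocks$size), n_obs = N))
  }
  free_cov <- covariance && q_int && q_slope
  q <- ncol(Z)

  make_gamma <- function(par) {
    if (q == 1L) return(matrix(par[1], 1, 1))
    g <- diag(par[1:2])
    if (free_cov) g[1, 2] <- g[2, 1] <- par[3] * sqrt(par[1] * par[2])
    g
  }
  # objective and analytic gradient share one kernel call per parameter
  # value (nlminb evaluates both at the same point); the covariance
  # variant falls back to numerical differences through its correlation
  # parametrization
  cache <- new.env(parent = emptyenv())
  eval_point <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return()
    res <- tryCatch(
      .profile_nll_grad_cpp(yo, Xo, Z, blocks$start, blocks$size,
                            make_gamma(par)),
      error = function(e) NULL)
    cache$par <- par
    if (is.null(res) || !is.finite(res$nll)) {
      cache$nll <- 1e300
      cache$grad <- rep(0, q)
    } else {
      cache$nll <- res$nll
      g <- res$grad
      cache$grad <- if (q == 1L) g[1, 1] else c(g[1, 1], g[2, 2])
    }
  }
  if (!free_cov) {
    objective <- function(par) { eval_point(par); cache$nll }
    gradient <- function(par) { eval_point(par); cache$grad }
  } else {
    objective <- function(par) {
      val <- tryCatch(
        .profile_nll_cpp(yo, Xo, Z, blocks$start, blocks$size,
                         make_gamma(par), FALSE)$nll,
        error = function(e) Inf)
      if (!is.finite(val)) 1e300 else val
    }
    gradient <- NULL
  }

  mom <- .mom_start(yo, Xo, to, blocks$code[ord])
  pick <- function(ab) {
    p <- c(if (q_int) ab[1], if (q_slope) ab[2])
    if (free_cov) p <- c(p, 0)
    p
  }
  start_list <- list(mom = pick(mom),
                     equal = pick(c(1, 1)),
                     null = pick(c(max(mom[1], 1e-2), 1e-4)))
  start_list <- start_list[control$starts]
  # variance ratios live in [0, 1e8]: the upper cap pins degenerate fits
  # (sigma_e2 -> 0 with exact within-individual lines) at a finite corner
  # instead of letting the profile likelihood run away
  lower <- c(rep(0, q), if (free_cov) -0.99)
  upper <- c(rep(1e8, q), if (free_cov) 0.99)

  best <- NULL
  objs <- numeric(0)
  for (st in start_list) {
    opt <- tryCatch(
      stats::nlminb(st, objective, gradient = gradient,
                    lower = lower, upper = upper,
                    control = list(iter.max = control$max_iter,
                                   eval.max = 4L * control$max_iter,
                                   rel.tol = control$rel_tol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    objs <- c(objs, opt$objective)
    if (is.null(best) || opt$objective < best$objective - 1e-12 ||
        (opt$objective < best$objective + 1e-12 && opt$convergence == 0 &&
         best$convergence != 0)) best <- opt
  }
  if (is.null(best))
    return(list(loglik = NA_real_, converged = FALSE,
                n_ind = length(blocks$size), n_obs = N))

  det_fit <- .profile_nll_cpp(yo, Xo, Z, blocks$start, blocks$size,
                              make_gamma(best$par), TRUE)
  s2e <- det_fit$s2e
  gam <- best$par
  sa2 <- if (q_int) s2e * gam[1] else 0
  sb2 <- if (q_slope) s2e * gam[if (q_int) 2 else 1] else 0
  sab <- if (free_cov) s2e * gam[3] * sqrt(gam[1] * gam[2]) else 0
  blup <- det_fit$blup
  # expand BLUP matrix to (intercept, slope) columns regardless of re set
  full_blup <- matrix(0, nrow(blup), 2)
  j <- 1L
  if (q_int) { full_blup[, 1] <- blup[, j]; j <- j + 1L }
  if (q_slope) full_blup[, 2] <- blup[, j]
  list(loglik = -best$objective, u = drop(det_fit$u), s2e = s2e,
       sigma_a2 = sa2, sigma_b2 = sb2, sigma_ab = sab,
       vcov_u = det_fit$vcov_u, blup = full_blup, ids = blocks$ids,
       # optimizer success, or agreement of independent starts on the same
       # optimum (covers boundary fits where nlminb reports false
       # convergence despite a well-identified maximum)
       converged = best$convergence == 0 ||
         sum(abs(objs - best$objective) < 1e-6 * (1 + abs(best$objective))) >= 2L,
       n_ind = length(blocks$size), n_obs = N)
}
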