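#' Convert methylation beta-values to M-values
#'
#' The M-value is the logit2 of the methylation fraction,
#' \eqn{M = \log_2(\beta / (1 - \beta))}; beta 0.5 maps to M = 0, beta 0.999
#' to 9.96 and beta 0.99 to 6.6.
#'
#' @param beta Methylation fractions, strictly inside (0, 1).
#' @return M-values.
#' @examples
#' beta_to_m(c(0.5, 0.99, 0.999))
#' @export
beta_to_m <- function(beta) {
  .assert(is.numeric(beta) && all(is.finite(beta)), "beta must be finite numeric")
  .assert(all(beta > 0 & beta < 1), "beta must be strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' Inverse of [beta_to_m()]
#' @param m M-values.
#' @return Beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  .assert(is.numeric(m) && all(is.finite(m)), "m must be finite numeric")
  2^m / (1 + 2^m)
}

#' Clamp M-values to the working range
#'
#' Constrains M-values to \[-9.96, 9.96\], the M-values of beta 0.001 and
#' 0.999. Idempotent.
#'
#' @param m M-values (finite).
#' @param limit Absolute bound, default 9.96.
#' @return Clamped M-values.
#' @export
clamp_m <- function(m, limit = 9.96) {
  .assert(is.numeric(m) && all(is.finite(m)), "m must be finite numeric")
  pmin(limit, pmax(-limit, m))
}

#' Remove per-probe outlier samples beyond 3 SD of the mean
#'
#' Mean and SD are computed once over all input values (no iterative
#' re-computation); samples outside mean +/- `n_sd` * SD are removed. With
#' zero SD nothing is removed.
#'
#' @param values Numeric M-values for one probe (>= 3 values).
#' @param n_sd Number of SDs defining the outlier bound (default 3).
#' @return A list: `retained` (values), `retained_idx`, `removed_idx`
#'   (indices into the input), and `removed_fraction`.
#' @export
remove_outliers <- function(values, n_sd = 3) {
  .assert(is.numeric(values) && length(values) >= 3L,
          "need at least 3 numeric values")
  .assert(!anyNA(values), "missing values not allowed")
  mu <- mean(values); s <- sd(values)
  out <- if (s == 0) rep(FALSE, length(values))
         else abs(values - mu) > n_sd * s
  list(retained = values[!out],
       retained_idx = which(!out),
       removed_idx = which(out),
       removed_fraction = mean(out))
}

#' Standardize ages over an analysis set
#'
#' Subtracts the mean and divides by the sample SD (denominator n - 1),
#' computed over all sample-level ages supplied. Invariant to affine
#' transformations of the input with positive scale.
#'
#' @param ages Ages in years (>= 2 distinct values).
#' @return Standardized ages with mean 0 and variance 1.
#' @examples
#' standardize_age(c(70, 72, 74))
#' @export
standardize_age <- function(ages) {
  .assert(is.numeric(ages) && !anyNA(ages), "ages must be numeric, non-NA")
  .assert(length(unique(ages)) >= 2L, "ages are all identical")
  (ages - mean(ages)) / sd(ages)
}

#' Residualize one probe on covariates and batch factors
#'
#' Fits, by maximum likelihood, a linear mixed model of the probe's
#' M-values on the given fixed covariates with independent random
#' intercepts for each random batch factor (plate and array in the default
#' pipeline), and returns the residuals after subtracting both the fitted
#' fixed effects and the predicted random effects. With no random factors
#' an ordinary least-squares fit is used.
#'
#' @param data Data frame with the probe values and all covariate columns.
#' @param y Column (tidy-eval) holding the M-values.
#' @param fixed Character vector of fixed-effect column names (factors and
#'   numeric covariates; may be empty).
#' @param random Character vector of random-intercept factor column names.
#'   A factor with a single level is dropped with a warning.
#' @return `data` with two added columns: `resid` (the residual) and the
#'   input values mean-centered implicitly through the intercept.
#' @export
residualize <- function(data, y = y, fixed = character(), random = character()) {
  yv <- dplyr::pull(data, {{ y }})
  .assert(is.numeric(yv) && !anyNA(yv), "y must be numeric without NAs")
  .assert(all(c(fixed, random) %in% names(data)),
          "fixed/random name columns absent from data")
  for (v in c(fixed, random))
    .assert(!anyNA(data[[v]]), paste0("covariate '", v, "' has missing values"))
  drop_r <- random[vapply(random, function(v)
    length(unique(data[[v]])) < 2L, logical(1))]
  if (length(drop_r)) {
    warn(paste0("random factor(s) with a single level dropped: ",
                paste(drop_r, collapse = ", ")))
    random <- setdiff(random, drop_r)
  }
  # detect rank deficiency in the fixed design before fitting
  Xf <- if (length(fixed))
    model.matrix(as.formula(paste("~", paste(fixed, collapse = "+"))), data)
  else matrix(1, nrow(data), 1)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    abort(paste0("fixed design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  df <- as.data.frame(data)
  df$.y <- yv
  if (length(random) == 0L) {
    fml <- if (length(fixed))
      as.formula(paste(".y ~", paste(fixed, collapse = "+")))
    else .y ~ 1
    r <- resid(lm(fml, data = df))
  } else {
    fml <- as.formula(paste(
      ".y ~", paste(c(if (length(fixed)) fixed else "1",
                      paste0("(1|", random, ")")), collapse = "+")))
    fit <- lme4::lmer(fml, data = df, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    r <- resid(fit)   # conditional residuals: y - X beta - Z u
  }
  dplyr::mutate(data, resid = as.numeric(r))
}

#' Preprocess a methylation matrix for the random-slope scan
#'
#' Runs the fixed pipeline per probe: clamp M-values to \[-9.96, 9.96\],
#' remove samples more than 3 SD from the probe mean, then residualize on
#' covariates (sex, age, cell counts, and fixed batch factors) with plate
#' and array as random intercepts. Returns a long tibble ready for
#' [scan_probes()], with age standardized over all retained samples of
#' each probe's analysis set.
#'
#' @param meth Matrix of M-values, probes x samples (dimnames required).
#' @param samples Sample sheet tibble with columns `sample_id`,
#'   `individual_id`, `wave`, `age_years`, plus the covariate columns
#'   named in `fixed` / `random`.
#' @param fixed,random Covariate column names, as in [residualize()].
#' @param extra Optional further fixed covariate column names (e.g. BMI).
#' @param n_sd Outlier bound in SDs.
#' @return A tibble: `probe_id`, `sample_id`, `individual_id`, `age_years`,
#'   `t` (standardized age), `y` (residual M-value); attribute
#'   `removed` records per-probe outlier counts.
#' @export
preprocess_meth <- function(meth, samples,
                            fixed = c("sex", "age_years", "cc_gran",
                                      "cc_lymph", "cc_mono", "batch_pia",
                                      "batch_hd", "batch_si"),
                            random = c("batch_pi", "batch_ai"),
                            extra = NULL, n_sd = 3) {
  .assert(is.matrix(meth) && !is.null(rownames(meth)) && !is.null(colnames(meth)),
          "meth must be a matrix with probe and sample dimnames")
  .assert(all(colnames(meth) %in% samples$sample_id),
          "every meth column needs a sample sheet row")
  samples <- samples[match(colnames(meth), samples$sample_id), ]
  fixed <- c(fixed, extra)
  fixed <- fixed[vapply(fixed, function(v)
    length(unique(samples[[v]])) > 1L, logical(1))]
  out <- vector("list", nrow(meth))
  removed <- integer(nrow(meth))
  for (j in seq_len(nrow(meth))) {
    v <- clamp_m(meth[j, ])
    keep <- remove_outliers(v, n_sd = n_sd)
    removed[j] <- length(keep$removed_idx)
    d <- samples[keep$retained_idx, ]
    d$.m <- keep$retained
    d <- residualize(d, y = .m, fixed = fixed, random = random)
    # drop individuals left with a single observation after outlier removal
    d <- dplyr::add_count(d, .data$individual_id, name = ".n_obs")
    d <- dplyr::filter(d, .data$.n_obs >= 2L)
    out[[j]] <- tibble::tibble(
      probe_id = rownames(meth)[j],
      sample_id = d$sample_id,
      individual_id = d$individual_id,
      age_years = d$age_years,
      t = standardize_age(d$age_years),
      y = d$resid)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "removed") <- tibble::tibble(probe_id = rownames(meth),
                                         n_removed = removed)
  res
}

#' Filter SNPs on MAF, Hardy-Weinberg and missingness
#'
#' Drops SNPs with minor allele frequency below `maf_min`, Hardy-Weinberg
#' chi-squared test p-value below `hwe_alpha` (computed on hard-called
#' genotypes, i.e. dosages rounded to 0/1/2), or a missing rate above
#' `max_missing`. A matrix already passing all thresholds is returned
#' unchanged.
#'
#' @param geno A `genotype_matrix` (see [simulate_genotypes()]).
#' @param maf_min MAF threshold (SNPs strictly below are removed).
#' @param hwe_alpha HWE p-value threshold (strictly below removed).
#' @param max_missing Maximum tolerated missing fraction (strictly above
#'   removed).
#' @return The filtered `genotype_matrix`; attribute `filter_counts` gives
#'   the number of SNPs failing each criterion.
#' @export
filter_genotypes <- function(geno, maf_min = 0.01, hwe_alpha = 1e-6,
                             max_missing = 0.10) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  d <- geno$dosage
  .assert(nrow(d) > 0 && ncol(d) > 0, "empty genotype matrix")
  .assert(all(d >= 0 & d <= 2, na.rm = TRUE), "dosages must lie in [0, 2]")
  miss <- rowMeans(is.na(d))
  p_alt <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- apply(d, 1, .hwe_p)
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_alpha
  fail_miss <- miss > max_missing
  keep <- !(fail_maf | fail_hwe | fail_miss)
  out <- structure(list(info = geno$info[keep, , drop = FALSE],
                        dosage = d[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "filter_counts") <- c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                                  missing = sum(fail_miss),
                                  kept = sum(keep))
  out
}

# One-df chi-squared HWE test on hard calls; returns the p-value.
#' @noRd
.hwe_p <- function(dos) {
  g <- round(dos[!is.na(dos)])
  n <- length(g)
  if (n == 0) return(1)
  obs <- tabulate(g + 1L, nbins = 3L)
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(e == 0)) return(1)           # monomorphic: trivially in HWE
  stat <- sum((obs - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}
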