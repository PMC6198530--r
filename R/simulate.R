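#' Configuration for a synthetic longitudinal methylation cohort
#'
#' Describes the cohort shape and generative parameters used by
#' [simulate_cohort()]. Defaults mimic a longitudinal ageing cohort profiled
#' at 2-4 waves: 954 individuals of whom 283/356/315 have 2/3/4 waves, wave
#' mean ages around 70-79 years with a within-wave SD of 0.6 years.
#'
#' Per-probe fixed effects and variance components are drawn uniformly from
#' the given ranges; a fraction `fraction_null_slope` of probes has its
#' slope variance forced to exactly zero (the null of the random-slope
#' test). Batch effects are additive Gaussian on the M-value scale — the
#' structure the downstream mixed-model residualization assumes.
#'
#' @param n_individuals Number of individuals.
#' @param wave_counts Named proportions (names "2","3","4") giving the
#'   distribution of waves per individual.
#' @param wave_ages Mean age (years) at each wave, strictly increasing.
#' @param wave_age_sd Within-wave SD of age in years.
#' @param n_probes Number of CpG probes.
#' @param u1_range,u2_range Ranges for the per-probe fixed intercept and
#'   fixed age effect (M-value units / M per SD of age).
#' @param sigma_a2_range,sigma_b2_range,sigma_e2_range Ranges for the
#'   per-probe random-intercept, random-slope and residual variances.
#' @param sigma_ab Intercept-slope covariance (single value applied to
#'   non-null probes; must satisfy the Cauchy-Schwarz bound against the
#'   smallest variances in the ranges). Default 0.
#' @param fraction_null_slope Proportion of probes with `sigma_b2 = 0`.
#' @param batch_sd Named SDs of the additive batch effects: `pia`
#'   (position in array), `hd` (hybridization date), `si` (set), `pi`
#'   (plate), `ai` (array).
#' @param n_plates,n_arrays,n_dates Number of plate / array / hybridization
#'   date levels.
#' @param sex_effect_sd,cc_effect_sd SDs of the per-probe sex and cell-count
#'   coefficients.
#' @param n_snps Number of independent SNPs to simulate (0 for none).
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param n_causal Number of SNP-probe pairs with a true SNP effect on the
#'   random slope.
#' @param causal_beta_sd SD of the causal SNP slope effects.
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 954,
                          wave_counts = c(`2` = 283, `3` = 356, `4` = 315),
                          wave_ages = c(70, 73, 76, 79),
                          wave_age_sd = 0.6,
                          n_probes = 100,
                          u1_range = c(-3, 3),
                          u2_range = c(-0.3, 0.3),
                          sigma_a2_range = c(0.2, 1),
                          sigma_b2_range = c(0.05, 0.5),
                          sigma_e2_range = c(0.2, 1),
                          sigma_ab = 0,
                          fraction_null_slope = 0.5,
                          batch_sd = c(pia = 0.05, hd = 0.05, si = 0.05,
                                       pi = 0.2, ai = 0.2),
                          n_plates = 12, n_arrays = 96, n_dates = 30,
                          sex_effect_sd = 0.2, cc_effect_sd = 0.3,
                          n_snps = 0, maf_range = c(0.05, 0.5),
                          n_causal = 0, causal_beta_sd = 0.2,
                          seed = 1L) {
  .assert(.is_count(n_individuals), "n_individuals must be a positive integer")
  .assert(.is_count(n_probes), "n_probes must be a positive integer")
  .assert(all(diff(wave_ages) > 0), "wave ages must be strictly increasing")
  .assert(fraction_null_slope >= 0 && fraction_null_slope <= 1,
          "fraction_null_slope must be in [0, 1]")
  for (rg in list(sigma_a2_range, sigma_b2_range, sigma_e2_range))
    .assert(all(rg >= 0) && rg[2] >= rg[1], "variance ranges must be >= 0")
  .assert(all(batch_sd >= 0), "batch effect SDs must be >= 0")
  .assert(sigma_ab^2 <= sigma_a2_range[1] * sigma_b2_range[1] + 1e-12,
          "sigma_ab violates the Cauchy-Schwarz bound for the variance ranges")
  .assert(all(maf_range > 0) && all(maf_range <= 0.5),
          "maf_range must lie in (0, 0.5]")
  wave_counts <- wave_counts / sum(wave_counts)
  .assert(identical(sort(names(wave_counts)), c("2", "3", "4")),
          "wave_counts must be named '2', '3', '4'")
  .assert(length(wave_ages) >= 4, "need mean ages for 4 waves")
  .assert(n_causal <= n_snps || n_snps == 0,
          "n_causal cannot exceed n_snps")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate longitudinal observations for one CpG probe
#'
#' Draws per-individual random effects \eqn{(a_i, b_i)} jointly normal with
#' covariance \eqn{\Omega = [\sigma_a^2, \sigma_{ab}; \sigma_{ab},
#' \sigma_b^2]} and assembles \eqn{y_{ij} = u_1 + u_2 t_{ij} + a_i + b_i
#' t_{ij} + e_{ij}} with iid \eqn{e_{ij} \sim N(0, \sigma_e^2)}. The `ages`
#' supplied are used directly as the time covariate \eqn{t}; standardize
#' them first (see [standardize_age()]) if they are raw ages.
#'
#' @param n_individuals Number of individuals.
#' @param ages List of length `n_individuals`; each element the time values
#'   of one individual (at least 2 each).
#' @param u1,u2 Fixed intercept and age effect.
#' @param sigma_a2,sigma_b2,sigma_e2,sigma_ab Variance components (all
#'   variances >= 0; `|sigma_ab|` bounded by Cauchy-Schwarz).
#' @param seed Integer seed.
#' @return A list with `observations` (tibble `individual_id`, `t`, `y`) and
#'   `truth` (tibble of the drawn `a`, `b` per individual plus the
#'   generative parameters as attributes).
#' @export
simulate_probe <- function(n_individuals, ages, u1, u2,
                           sigma_a2, sigma_b2, sigma_e2, sigma_ab = 0,
                           seed = 1L) {
  .assert(.is_count(n_individuals), "n_individuals must be a positive integer")
  .assert(all(c(sigma_a2, sigma_b2, sigma_e2) >= 0),
          "variances must be >= 0")
  .assert(sigma_ab^2 <= sigma_a2 * sigma_b2 + 1e-12,
          "|sigma_ab| exceeds the Cauchy-Schwarz bound")
  .assert(length(ages) == n_individuals, "need one age vector per individual")
  .assert(all(lengths(ages) >= 2L),
          "every individual needs at least 2 ages")
  withr::with_seed(seed, {
    # joint draw of (a, b): b | a is normal with regression on a
    a <- rnorm(n_individuals, 0, sqrt(sigma_a2))
    if (sigma_a2 > 0) {
      cond_var <- sigma_b2 - sigma_ab^2 / sigma_a2
      b <- sigma_ab / sigma_a2 * a + rnorm(n_individuals, 0, sqrt(max(cond_var, 0)))
    } else {
      b <- rnorm(n_individuals, 0, sqrt(sigma_b2))
    }
    m <- lengths(ages)
    id <- rep(seq_len(n_individuals), m)
    t <- unlist(ages, use.names = FALSE)
    y <- u1 + u2 * t + a[id] + b[id] * t +
      rnorm(length(t), 0, sqrt(sigma_e2))
  })
  list(
    observations = tibble::tibble(individual_id = id, t = t, y = y),
    truth = structure(
      tibble::tibble(individual_id = seq_len(n_individuals), a = a, b = b),
      params = list(u1 = u1, u2 = u2, sigma_a2 = sigma_a2,
                    sigma_b2 = sigma_b2, sigma_ab = sigma_ab,
                    sigma_e2 = sigma_e2)))
}

#' Simulate independent SNP dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP's dosage is drawn from \{0, 1, 2\} with probabilities
#' \eqn{(1-p)^2, 2p(1-p), p^2}. SNPs are placed uniformly at random on 22
#' synthetic chromosomes (50 Mb each) so that cis/trans classification and
#' positional windows can be exercised.
#'
#' @param n_individuals Number of individuals.
#' @param mafs Vector of minor allele frequencies, each in (0, 0.5].
#' @param seed Integer seed.
#' @param chrom_length Length of each synthetic chromosome in bp.
#' @return A `genotype_matrix`: list with `info` (tibble `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `maf`) and `dosage` (SNP x individual matrix).
#' @export
simulate_genotypes <- function(n_individuals, mafs, seed = 1L,
                               chrom_length = 5e7) {
  .assert(.is_count(n_individuals), "n_individuals must be a positive integer")
  .assert(all(mafs > 0 & mafs <= 0.5), "each MAF must be in (0, 0.5]")
  k <- length(mafs)
  withr::with_seed(seed, {
    dosage <- matrix(rbinom(k * n_individuals, 2L, rep(mafs, n_individuals)),
                     nrow = k, ncol = n_individuals)
    chrom <- sample.int(22L, k, replace = TRUE)
    pos <- sample.int(chrom_length, k, replace = TRUE)
  })
  ids <- sprintf("snp%05d", seq_len(k))
  rownames(dosage) <- ids
  colnames(dosage) <- sprintf("I%04d", seq_len(n_individuals))
  structure(list(
    info = tibble::tibble(snp_id = ids, chrom = chrom, pos = pos,
                          a1 = "A", a2 = "B", maf = mafs),
    dosage = dosage), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(head(x$info))
  invisible(x)
}

# CpG-island annotation scheme on synthetic chromosomes: islands with
# flanking shores (0-2 kb) and shelves (2-4 kb); everything else is Sea.
#' @noRd
.simulate_annotations <- function(n_islands, chrom_length, seed) {
  withr::with_seed(seed, {
    chrom <- sample.int(22L, n_islands, replace = TRUE)
    start <- sample.int(chrom_length - 20000L, n_islands, replace = TRUE) + 8000L
    len <- sample(500:2000, n_islands, replace = TRUE)
  })
  isl <- tibble::tibble(chrom = chrom, start = start, end = start + len)
  flank <- function(s, e, cls)
    tibble::tibble(chrom = isl$chrom, start = s, end = e, class = cls)
  dplyr::bind_rows(
    dplyr::mutate(isl, class = "Island"),
    flank(isl$start - 2000L, isl$start, "N_Shore"),
    flank(isl$end, isl$end + 2000L, "S_Shore"),
    flank(isl$start - 4000L, isl$start - 2000L, "N_Shelf"),
    flank(isl$end + 2000L, isl$end + 4000L, "S_Shelf")) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Simulate a complete longitudinal methylation cohort
#'
#' Composes [simulate_probe()] and [simulate_genotypes()] into a full
#' synthetic dataset: an M-value matrix (probes x samples) with additive
#' batch and covariate effects, a sample sheet, HWE genotypes with optional
#' causal SNP effects on per-individual slopes, a CpG-island annotation
#' track, and a truth table recording every generative quantity.
#'
#' Ages are drawn per wave as the wave mean plus normal jitter; the time
#' covariate entering the generative mixed model is age standardized over
#' all samples in the cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `meth_cohort` with elements `meth` (matrix),
#'   `samples` (tibble), `genotypes` (`genotype_matrix` or `NULL`),
#'   `annotations` (tibble `chrom`, `start`, `end`, `class`), `probes`
#'   (manifest tibble `probe_id`, `chrom`, `pos`), `truth` (list:
#'   `probe_params`, `random_effects`, `snp_effects`) and `config`.
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "cohort_config"), "config must be a cohort_config")
  cfg <- config
  seeds <- .child_seeds(cfg$seed, 6L + cfg$n_probes)

  n <- cfg$n_individuals
  ind_ids <- sprintf("I%04d", seq_len(n))
  withr::with_seed(seeds[1], {
    n_waves <- sample(2:4, n, replace = TRUE, prob = cfg$wave_counts[c("2", "3", "4")])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    # 3-part cell-count composition with estimation noise, so the parts do
    # not sum exactly to one (as with reference-based cell-count estimates)
    cc_raw <- matrix(stats::rgamma(3 * n, shape = c(12, 6, 2)), ncol = 3,
                     byrow = TRUE)
    cc <- cc_raw / rowSums(cc_raw)
    cc <- pmax(cc + matrix(rnorm(3 * n, 0, 0.02), ncol = 3), 0.001)
  })
  # individuals keep consecutive waves starting at wave 1 (dropout pattern)
  waves_of <- lapply(n_waves, seq_len)
  sheet <- tibble::tibble(
    individual_id = rep(ind_ids, n_waves),
    wave = unlist(waves_of, use.names = FALSE))
  withr::with_seed(seeds[2], {
    sheet$age_years <- cfg$wave_ages[sheet$wave] +
      rnorm(nrow(sheet), 0, cfg$wave_age_sd)
    n_samp <- nrow(sheet)
    sheet$batch_pia <- sprintf("pos%02d", sample.int(12L, n_samp, TRUE))
    sheet$batch_hd <- sprintf("d%03d", sample.int(cfg$n_dates, n_samp, TRUE))
    sheet$batch_si <- sprintf("set%d", sample.int(2L, n_samp, TRUE))
    sheet$batch_pi <- sprintf("plate%02d", sample.int(cfg$n_plates, n_samp, TRUE))
    sheet$batch_ai <- sprintf("arr%03d", sample.int(cfg$n_arrays, n_samp, TRUE))
  })
  sheet$sample_id <- sprintf("%s_w%d", sheet$individual_id, sheet$wave)
  idx <- match(sheet$individual_id, ind_ids)
  sheet$sex <- sex[idx]
  sheet$cc_gran <- cc[idx, 1]; sheet$cc_lymph <- cc[idx, 2]
  sheet$cc_mono <- cc[idx, 3]
  sheet <- dplyr::select(sheet, "sample_id", "individual_id", "wave",
                         "age_years", "sex", dplyr::starts_with("cc_"),
                         dplyr::starts_with("batch_"))
  t_std <- standardize_age(sheet$age_years)

  # per-probe generative parameters
  pr_ids <- sprintf("cg%07d", seq_len(cfg$n_probes))
  withr::with_seed(seeds[3], {
    pp <- tibble::tibble(
      probe_id = pr_ids,
      u1 = runif(cfg$n_probes, cfg$u1_range[1], cfg$u1_range[2]),
      u2 = runif(cfg$n_probes, cfg$u2_range[1], cfg$u2_range[2]),
      sigma_a2 = runif(cfg$n_probes, cfg$sigma_a2_range[1], cfg$sigma_a2_range[2]),
      sigma_b2 = runif(cfg$n_probes, cfg$sigma_b2_range[1], cfg$sigma_b2_range[2]),
      sigma_e2 = runif(cfg$n_probes, cfg$sigma_e2_range[1], cfg$sigma_e2_range[2]),
      sigma_ab = cfg$sigma_ab)
    null_idx <- sample.int(cfg$n_probes,
                           round(cfg$fraction_null_slope * cfg$n_probes))
    pp$sigma_b2[null_idx] <- 0
    pp$sigma_ab[null_idx] <- 0
    probe_chrom <- sample.int(22L, cfg$n_probes, replace = TRUE)
    probe_pos <- sample.int(5e7, cfg$n_probes, replace = TRUE)
    # batch effect sizes per probe x factor level
    lvl <- lapply(sheet[paste0("batch_", names(cfg$batch_sd))], unique)
    batch_eff <- lapply(seq_along(lvl), function(f)
      matrix(rnorm(cfg$n_probes * length(lvl[[f]]), 0, cfg$batch_sd[f]),
             nrow = cfg$n_probes, dimnames = list(pr_ids, lvl[[f]])))
    names(batch_eff) <- names(cfg$batch_sd)
    sex_beta <- rnorm(cfg$n_probes, 0, cfg$sex_effect_sd)
    cc_beta <- matrix(rnorm(cfg$n_probes * 3, 0, cfg$cc_effect_sd),
                      ncol = 3)
  })

  # genotypes and causal SNP -> slope effects
  genotypes <- NULL
  snp_eff <- tibble::tibble(snp_id = character(), probe_id = character(),
                            beta = numeric())
  slope_shift <- matrix(0, cfg$n_probes, n)   # added to b_i per probe
  if (cfg$n_snps > 0) {
    withr::with_seed(seeds[4], {
      mafs <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    })
    genotypes <- simulate_genotypes(n, mafs, seed = seeds[5])
    if (cfg$n_causal > 0) {
      non_null <- which(pp$sigma_b2 > 0)
      .assert(length(non_null) > 0,
              "causal SNP effects need probes with non-zero slope variance")
      withr::with_seed(seeds[6], {
        cs <- sample.int(cfg$n_snps, cfg$n_causal)
        cp <- sample(non_null, cfg$n_causal, replace = cfg$n_causal > length(non_null))
        betas <- rnorm(cfg$n_causal, 0, cfg$causal_beta_sd)
      })
      snp_eff <- tibble::tibble(snp_id = genotypes$info$snp_id[cs],
                                probe_id = pp$probe_id[cp], beta = betas)
      for (k in seq_len(cfg$n_causal))
        slope_shift[cp[k], ] <- slope_shift[cp[k], ] +
          betas[k] * genotypes$dosage[cs[k], ]
    }
  }

  # assemble methylation matrix probe by probe
  ages_by_ind <- split(t_std, factor(sheet$individual_id, levels = ind_ids))
  meth <- matrix(NA_real_, cfg$n_probes, nrow(sheet),
                 dimnames = list(pr_ids, sheet$sample_id))
  re_a <- re_b <- matrix(NA_real_, cfg$n_probes, n,
                         dimnames = list(pr_ids, ind_ids))
  sex_num <- as.numeric(sheet$sex == "M")
  cc_mat <- as.matrix(sheet[, c("cc_gran", "cc_lymph", "cc_mono")])
  for (j in seq_len(cfg$n_probes)) {
    sim <- simulate_probe(n, ages_by_ind, pp$u1[j], pp$u2[j],
                          pp$sigma_a2[j], pp$sigma_b2[j], pp$sigma_e2[j],
                          pp$sigma_ab[j], seed = seeds[6L + j])
    b_j <- sim$truth$b + slope_shift[j, ]
    y <- sim$observations$y +
      slope_shift[j, match(sheet$individual_id, ind_ids)] * t_std
    y <- y + sex_beta[j] * sex_num + drop(cc_mat %*% cc_beta[j, ])
    for (f in names(batch_eff))
      y <- y + batch_eff[[f]][j, sheet[[paste0("batch_", f)]]]
    meth[j, ] <- y
    re_a[j, ] <- sim$truth$a
    re_b[j, ] <- b_j
  }

  annotations <- .simulate_annotations(n_islands = max(20L, cfg$n_probes %/% 4L),
                                       chrom_length = 5e7, seed = seeds[2])
  structure(list(
    meth = meth,
    samples = sheet,
    genotypes = genotypes,
    annotations = annotations,
    probes = tibble::tibble(probe_id = pr_ids, chrom = probe_chrom,
                            pos = probe_pos),
    truth = list(probe_params = pp,
                 random_effects = list(intercept = re_a, slope = re_b),
                 snp_effects = snp_eff),
    config = cfg), class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("meth_cohort: %d probes x %d samples (%d individuals)\n",
              nrow(x$meth), ncol(x$meth), x$config$n_individuals))
  if (!is.null(x$genotypes))
    cat(sprintf("  genotypes: %d SNPs, %d causal SNP-probe pairs\n",
                nrow(x$genotypes$dosage), nrow(x$truth$snp_effects)))
  invisible(x)
}
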