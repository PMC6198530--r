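# Shared fixtures and independent oracles for the test suite.

# Balanced longitudinal toy data with known structure.
make_balanced <- function(n_ind, t_vals = c(-1, 0, 1), u1 = 0, u2 = 0,
                          sigma_a2 = 1, sigma_b2 = 0.5, sigma_e2 = 1,
                          sigma_ab = 0, seed = 1) {
  simulate_probe(n_ind, rep(list(t_vals), n_ind), u1, u2,
                 sigma_a2, sigma_b2, sigma_e2, sigma_ab, seed = seed)
}

# Brute-force log-likelihood oracle: stack all observations of all
# individuals into one multivariate normal with dense covariance
# Sigma = Z Omega_big Z' + sigma_e2 I and evaluate the density directly.
# Independent of the package's blockwise code path.
dense_mvn_loglik <- function(obs, u1, u2, sigma_a2, sigma_b2, sigma_e2,
                             sigma_ab = 0) {
  ids <- unique(obs$individual_id)
  Zbig <- matrix(0, nrow(obs), 2 * length(ids))
  for (k in seq_along(ids)) {
    rows <- which(obs$individual_id == ids[k])
    Zbig[rows, 2 * k - 1] <- 1
    Zbig[rows, 2 * k] <- obs$t[rows]
  }
  Om <- matrix(c(sigma_a2, sigma_ab, sigma_ab, sigma_b2), 2)
  Obig <- kronecker(diag(length(ids)), Om)
  Sig <- Zbig %*% Obig %*% t(Zbig) + diag(sigma_e2, nrow(obs))
  r <- obs$y - u1 - u2 * obs$t
  ev <- eigen(Sig, symmetric = TRUE)
  -0.5 * (nrow(obs) * log(2 * pi) + sum(log(ev$values)) +
            sum((t(ev$vectors) %*% r)^2 / ev$values))
}

# Long-format null cohort (sigma_b2 = 0) without batch structure, for
# calibration tests.
make_null_long <- function(n_probes, n_ind, seed = 1,
                           sigma_a2 = 1, sigma_e2 = 1) {
  seeds <- withr::with_seed(seed, sample.int(1e6, n_probes + 1))
  waves <- withr::with_seed(seeds[n_probes + 1],
                            sample(2:4, n_ind, TRUE, prob = c(0.3, 0.37, 0.33)))
  ages <- lapply(waves, function(k) seq(0, by = 3, length.out = k))
  age_all <- unlist(ages)
  t_all <- standardize_age(age_all + rep(seq_len(n_ind) * 1e-9, waves))
  t_by_ind <- split(t_all, rep(seq_len(n_ind), waves))
  purrr::map_dfr(seq_len(n_probes), function(j) {
    sim <- simulate_probe(n_ind, t_by_ind, u1 = 0, u2 = 0.1,
                          sigma_a2 = sigma_a2, sigma_b2 = 0,
                          sigma_e2 = sigma_e2, seed = seeds[j])
    dplyr::mutate(sim$observations, probe_id = sprintf("p%04d", j))
  })
}
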