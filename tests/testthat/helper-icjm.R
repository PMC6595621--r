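# Shared fixtures and independent oracles for the test suite.

# small deterministic dataset: 3 subjects, mixed censoring
tiny_data <- function() {
  icjm_data(list(
    subject_data("A", times = c(0.25, 1, 2), values = c(7.1, 6.8, 7.4),
                 t_L = 6, t_R = 12, right_censored = FALSE,
                 covariates = c(hla = 4)),
    subject_data("B", times = c(0.25, 3), values = c(8.2, 8.0),
                 t_L = NA, t_R = 84, right_censored = TRUE,
                 covariates = c(hla = 2)),
    subject_data("C", times = 0.25, values = 5.9,
                 t_L = 0, t_R = 1, right_censored = FALSE,
                 covariates = c(hla = 6))))
}

# quadrature oracle for the Weibull CDF with proportional-hazard offset:
# integrate the hazard numerically, never through weibull_cdf()
cdf_quadrature <- function(t, alpha, lp) {
  if (t == 0) return(0)
  H <- stats::integrate(function(u) alpha * u^(alpha - 1) * exp(lp),
                        lower = 0, upper = t,
                        rel.tol = 1e-12, abs.tol = 0)$value
  1 - exp(-H)
}

# quadrature oracle for the cumulative hazard under a step covariate
tvc_H_quadrature <- function(t, path, z, params, time_scale = 1) {
  if (t == 0) return(0)
  zb <- if (length(params$gamma)) sum(params$gamma * z[names(params$gamma)])
        else 0
  a <- params$alpha_tvc
  h <- function(u) {
    w <- locf(path, u * time_scale)
    a * u^(a - 1) * exp(params$gamma0 + zb + params$eta * w)
  }
  # integrate piecewise so the quadrature sees smooth integrands
  brk <- sort(unique(c(0, path$update_times / time_scale, t / time_scale)))
  brk <- brk[brk <= t / time_scale]
  if (max(brk) < t / time_scale) brk <- c(brk, t / time_scale)
  H <- 0
  for (j in seq_len(length(brk) - 1)) {
    H <- H + stats::integrate(h, brk[j], brk[j + 1],
                              rel.tol = 1e-12, abs.tol = 0)$value
  }
  H
}

# cached expensive fits, shared across test files
.icjm_test_cache <- new.env(parent = emptyenv())

cached_sim_data <- function() {
  if (is.null(.icjm_test_cache$data)) {
    .icjm_test_cache$data <-
      simulate_dataset(scenario(me = "low", ic_scheme = "lighter"), seed = 7)
  }
  .icjm_test_cache$data
}

cached_jm_fit <- function() {
  if (is.null(.icjm_test_cache$jm)) {
    .icjm_test_cache$jm <- fit_icjm(cached_sim_data(), model_spec("M2"),
                                    config = mcmc_config(seed = 7))
  }
  .icjm_test_cache$jm
}

cached_tvc_fit <- function() {
  if (is.null(.icjm_test_cache$tvc)) {
    .icjm_test_cache$tvc <- fit_icjm(cached_sim_data(), model_spec("M4"),
                                     config = mcmc_config(preset = "simulation_tvc",
                                                          seed = 7))
  }
  .icjm_test_cache$tvc
}

# short-chain config for replicated fits in property tests
quick_config <- function(seed = 1) {
  mcmc_config(n_chains = 2, burn_in = 600, n_samples = 600, seed = seed)
}
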