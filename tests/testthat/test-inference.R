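test_that("log prior reproduces the stated densities", {
  prior <- prior_spec()
  spec <- model_spec("M2")
  p <- param_set(b0 = 0, b1 = 0, sigma_e2 = 1, sigma0_2 = 1, sigma1_2 = 1,
                 rho = 0, beta0 = 0, beta2 = c(hla = 0), lambda0 = 0,
                 lambda1 = 0, alpha = 1)
  lp <- log_prior(p, NULL, prior, spec)
  # five free coefficients (b0, b1, beta0, beta2, lambda0) at the mode
  coef_part <- 5 * dnorm(0, 0, 100, log = TRUE)
  expect_equal(coef_part, 5 * (-0.5 * log(2 * pi * 10000)), tolerance = 1e-12)
  # gamma prior at alpha = 1, shape-rate form: r log(l) - l - lgamma(r)
  gam_part <- 100 * log(100) - 100 - lgamma(100)
  # uniform on sigma_e
  sig_part <- -log(100)
  wish_part <- icjm:::dwishart_log(diag(2), diag(c(1e-5, 1e-6)), 2)
  expect_equal(lp, coef_part + gam_part + sig_part + wish_part,
               tolerance = 1e-10)

  # out of support
  p_bad <- p; p_bad$sigma_e2 <- 150^2
  expect_identical(log_prior(p_bad, NULL, prior, spec), -Inf)

  # random effects add their bivariate normal density
  re <- cbind(c(0.2, -0.4), c(0.01, 0))
  expect_equal(log_prior(p, re, prior, spec) - lp,
               sum(random_effects_logdensity(
                 list(a0 = re[, 1], a1 = re[, 2]), p)),
               tolerance = 1e-10)
})

test_that("Wishart log-density reduces to the gamma density in one dimension", {
  # p = 1: Wishart(R, k) on a scalar is Gamma(k/2, rate = R/2)
  for (w in c(0.3, 1, 4)) {
    expect_equal(icjm:::dwishart_log(matrix(w), matrix(0.7), 5),
                 dgamma(w, shape = 5 / 2, rate = 0.7 / 2, log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("credible intervals are equal-tailed percentiles", {
  expect_equal(credible_interval(rep(3.3, 10)), c(3.3, 3.3))
  x <- 1:100
  ci <- credible_interval(x, 0.95)
  # sort-based percentile oracle (type-7 interpolation)
  pct <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(ci, c(pct(x, 0.025), pct(x, 0.975)))
  set.seed(2)
  y <- rnorm(501)
  expect_equal(credible_interval(y, 0.9), c(pct(y, 0.05), pct(y, 0.95)))
  expect_error(credible_interval(numeric(0)), "empty")
})

test_that("fits are reproducible and survive degenerate inputs", {
  d <- icjm_data(cached_sim_data()[1:30])
  cfg <- mcmc_config(n_chains = 2, burn_in = 150, n_samples = 150, seed = 5)
  f1 <- fit_icjm(d, model_spec("M2"), config = cfg)
  f2 <- fit_icjm(d, model_spec("M2"), config = cfg)
  expect_identical(f1$chains, f2$chains)
  # single-subject smoke contract, both families
  d1 <- icjm_data(cached_sim_data()[5])
  fs <- fit_icjm(d1, model_spec("M2"),
                 config = mcmc_config(n_chains = 1, burn_in = 100,
                                      n_samples = 100, seed = 2))
  expect_true(all(is.finite(posterior_draws(fs))))
  ft <- fit_icjm(d1, model_spec("M4"),
                 config = mcmc_config(n_chains = 1, burn_in = 100,
                                      n_samples = 100, seed = 2))
  expect_true(all(is.finite(posterior_draws(ft))))
  # family constraints hold in the draws
  expect_true(all(f1$chains[[1]][, "lambda1"] == 0))
  f3 <- fit_icjm(d, model_spec("M3"), config = cfg)
  expect_true(all(f3$chains[[1]][, "lambda0"] == 0))
  expect_false(all(f3$chains[[1]][, "lambda1"] == 0))
})

test_that("prior-only sampling reproduces the prior moments", {
  d <- icjm_data(cached_sim_data()[1:3])
  cfg <- mcmc_config(n_chains = 1, burn_in = 1, n_samples = 4000, seed = 11)
  f <- fit_icjm(d, model_spec("M2"), config = cfg, use_likelihood = FALSE)
  dm <- posterior_draws(f)
  for (pn in c("b0", "b1", "beta0", "lambda0")) {
    se <- 100 / sqrt(nrow(dm))
    expect_lt(abs(mean(dm[, pn])), 3 * se)
    expect_lt(abs(sd(dm[, pn]) / 100 - 1), 0.1)
  }
  # sigma_e ~ Uniform(0, 100) so sigma_e2 has mean 100^2/3
  expect_lt(abs(mean(dm[, "sigma_e2"]) / (1e4 / 3) - 1), 0.1)
  expect_lt(abs(mean(dm[, "alpha"]) - 1), 3 * 0.1 / sqrt(nrow(dm)) + 0.01)
})

test_that("posterior matches survreg on the constant-covariate exponential special case", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 250
  w <- rnorm(n, 0, 1.2)
  lp <- -1 + 0.4 * w
  Tev <- 12 * draw_event_time(lp, 1, runif(n))
  sched <- make_schedule("lighter", 84)
  subs <- lapply(seq_len(n), function(i) {
    cz <- interval_censor(Tev[i], sched)
    subject_data(i, times = 0.25, values = w[i], t_L = cz$t_L, t_R = cz$t_R,
                 right_censored = cz$right_censored)
  })
  d <- icjm_data(subs)
  f <- fit_icjm(d, model_spec("M4", hazard = "exponential"),
                config = mcmc_config(seed = 3, preset = "simulation_tvc"))
  s <- summary(f)
  expect_true(all(s$mean[s$parameter == "alpha_tvc"] == 1))
  tL <- vapply(d, function(s) if (s$right_censored) s$t_R
               else max(s$t_L, 1e-6), numeric(1)) / 12
  tR <- vapply(d, function(s) if (s$right_censored) NA_real_ else s$t_R,
               numeric(1)) / 12
  sv <- survival::survreg(survival::Surv(tL, tR, type = "interval2") ~ w,
                          dist = "exponential")
  eta_mle <- -coef(sv)[["w"]]
  g0_mle <- -coef(sv)[["(Intercept)"]]
  expect_lt(abs(s$mean[s$parameter == "eta"] - eta_mle),
            3 * s$sd[s$parameter == "eta"])
  expect_lt(abs(s$mean[s$parameter == "gamma0"] - g0_mle),
            3 * s$sd[s$parameter == "gamma0"])
})

test_that("posterior SD of the association shrinks with more subjects", {
  sds <- vapply(c(60, 240), function(n) {
    scn <- scenario(me = "low", n_subjects = n)
    mean(vapply(1:2, function(m) {
      d <- simulate_dataset(scn, seed = 500 + m)
      f <- fit_icjm(d, model_spec("M2"), config = quick_config(seed = m))
      s <- summary(f)
      s$sd[s$parameter == "lambda0"]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})
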