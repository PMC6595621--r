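test_that("locf carries the last update forward", {
  p <- covariate_path(c(0, 10), c(5, 3))
  expect_equal(locf(p, 7), 5)
  expect_equal(locf(p, 10), 3)       # boundary: the update itself
  expect_equal(locf(p, 100), 3)
  expect_error(locf(p, -1), "precedes")

  # brute-force linear-scan oracle on random step functions
  set.seed(8)
  for (k in 1:10) {
    ut <- sort(runif(6, 0, 50))
    vv <- rnorm(6)
    pp <- covariate_path(ut, vv)
    tq <- runif(20, min(ut), 60)
    oracle <- vapply(tq, function(t) vv[max(which(ut <= t))], numeric(1))
    expect_equal(locf(pp, tq), oracle)
  }
})

test_that("cumulative hazard integrates the step-covariate Weibull hazard", {
  z <- c(hla = 2)
  # eta = 0: plain Weibull
  p0 <- param_set(gamma0 = -1, gamma = c(hla = 0.2), eta = 0,
                  alpha_tvc = 0.7)
  path <- covariate_path(c(0, 4, 9), c(7, 6, 8))
  expect_equal(cumulative_hazard(5, path, z, p0),
               5^0.7 * exp(-1 + 0.4), tolerance = 1e-12)
  # single segment closed form
  p1 <- param_set(gamma0 = -1.5, eta = -0.3, alpha_tvc = 0.5)
  single <- covariate_path(0, 6.5)
  expect_equal(cumulative_hazard(8, single, numeric(0), p1),
               8^0.5 * exp(-1.5 - 0.3 * 6.5), tolerance = 1e-12)
  expect_equal(cumulative_hazard(0, single, numeric(0), p1), 0)

  # multi-segment path vs adaptive quadrature
  set.seed(12)
  for (k in 1:20) {
    ut <- c(0, sort(runif(4, 0.5, 30)))
    pp <- covariate_path(ut, rnorm(5, 7, 1.5))
    pr <- param_set(gamma0 = runif(1, -3, 0), gamma = c(hla = 0.25),
                    eta = runif(1, -0.6, 0), alpha_tvc = runif(1, 0.4, 1.5))
    t <- runif(1, 1, 40)
    ts <- sample(c(1, 12), 1)
    expect_equal(cumulative_hazard(t, pp, z, pr, time_scale = ts),
                 tvc_H_quadrature(t, pp, z, pr, time_scale = ts),
                 tolerance = 1e-8)
  }
})

test_that("cumulative hazard is nondecreasing with CDF in [0,1)", {
  path <- covariate_path(c(0, 3, 12, 30), c(8, 5, 9, 4))
  p <- param_set(gamma0 = -1, eta = -0.2, alpha_tvc = 0.6)
  tt <- seq(0, 60, by = 0.25)
  H <- cumulative_hazard(tt, path, numeric(0), p, time_scale = 12)
  expect_true(all(diff(H) >= 0))
  F <- 1 - exp(-H)
  expect_true(all(F >= 0 & F < 1))
  # continuity across an update time
  expect_lt(abs(cumulative_hazard(3 + 1e-9, path, numeric(0), p) -
                  cumulative_hazard(3 - 1e-9, path, numeric(0), p)), 1e-6)
})

test_that("TVC subject log-likelihood matches oracles and special cases", {
  p <- param_set(gamma0 = -2, gamma = c(hla = 0.25), eta = -0.4,
                 alpha_tvc = 0.5)

  # right-censored with vanishing follow-up carries no information
  s0 <- subject_data("a", times = 1e-7, values = 7, t_L = NA, t_R = 1e-6,
                     right_censored = TRUE, covariates = c(hla = 1))
  path0 <- covariate_path(0, 7)
  expect_equal(subject_loglik_tvc(s0, path0, p), 0, tolerance = 1e-4)

  # constant covariate path reduces to the Weibull-CDF likelihood
  s1 <- subject_data("b", times = 1, values = 6, t_L = 6, t_R = 24,
                     right_censored = FALSE, covariates = c(hla = 3))
  cpath <- covariate_path(0, 6)
  lp <- -2 + 0.25 * 3 - 0.4 * 6
  expect_equal(subject_loglik_tvc(s1, cpath, p, time_scale = 12),
               log(weibull_cdf(2, 0.5, lp) - weibull_cdf(0.5, 0.5, lp)),
               tolerance = 1e-12)

  # four-segment path against the quadrature oracle
  s2 <- subject_data("c", times = c(1, 5, 11, 20), values = c(8, 7, 5, 6),
                     t_L = 12, t_R = 24, right_censored = FALSE,
                     covariates = c(hla = 2))
  path2 <- covariate_path(c(0, 5, 11, 20), c(8, 7, 5, 6))
  HL <- tvc_H_quadrature(12, path2, s2$covariates, p, 12)
  HR <- tvc_H_quadrature(24, path2, s2$covariates, p, 12)
  expect_equal(subject_loglik_tvc(s2, path2, p, time_scale = 12),
               log(exp(-HL) - exp(-HR)), tolerance = 1e-8)
})

test_that("TVC and joint-model survival terms agree for a constant trajectory", {
  # a noise-free subject with a flat trajectory: the TVC likelihood with
  # lp = gamma0 + gamma z + eta w must equal the joint model's survival
  # contribution with the matching linear predictor, over a parameter grid
  w <- 6.2
  s <- subject_data("k", times = c(1, 6), values = c(w, w), t_L = 12,
                    t_R = 36, right_censored = FALSE, covariates = c(hla = 3))
  path <- covariate_path(0, w)
  spec <- model_spec("M2", time_scale = 12)
  for (eta in c(-0.5, -0.2, 0.1)) {
    for (a in c(0.5, 1, 1.4)) {
      ptvc <- param_set(gamma0 = -2, gamma = c(hla = 0.25), eta = eta,
                        alpha_tvc = a)
      pjm <- param_set(b0 = w, b1 = 0, sigma_e2 = 1,
                       beta0 = -2 + eta * w, beta2 = c(hla = 0.25),
                       lambda0 = 0, alpha = a)
      lljm <- attr(subject_loglik(s, pjm, list(a0 = 0, a1 = 0), spec),
                   "parts")[["surv"]]
      expect_equal(subject_loglik_tvc(s, path, ptvc, time_scale = 12),
                   lljm, tolerance = 1e-10)
    }
  }
})

test_that("paths built from records anchor at time zero and reproduce the data", {
  d <- tiny_data()
  paths <- build_paths(d)
  expect_equal(paths[[1]]$update_times[1], 0)
  expect_equal(paths[[1]]$values[1], d[[1]]$values[1])  # duplicated anchor
  # single-measurement subject: constant path
  expect_equal(paths[[3]]$values, c(5.9, 5.9))
  # locf at the measurement times returns the measured values
  for (i in seq_along(d))
    expect_equal(locf(paths[[i]], d[[i]]$times), d[[i]]$values)
})

test_that("dataset-level TVC log-likelihood is permutation invariant", {
  d <- cached_sim_data()[1:15]
  d <- icjm_data(d)
  paths <- build_paths(d)
  p <- param_set(gamma0 = -2, gamma = c(hla = 0.25), eta = -0.3,
                 alpha_tvc = 0.6)
  ll <- icjm:::dataset_loglik_tvc(d, paths, p)
  perm <- c(3, 1, 2, 15:4)
  llp <- icjm:::dataset_loglik_tvc(icjm_data(d[perm]), paths[perm], p)
  expect_equal(as.numeric(ll), as.numeric(llp), tolerance = 1e-10)
})
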