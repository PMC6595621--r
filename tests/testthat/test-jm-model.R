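test_that("longitudinal mean assembles fixed effects, covariates and random terms", {
  p <- param_set(b0 = 7.24, b1 = 0)
  expect_equal(longitudinal_mean(0, p), 7.24)
  p2 <- param_set(b0 = 7, b1 = -0.03)
  expect_equal(longitudinal_mean(10, p2, re = list(a0 = 0.5, a1 = 0.01)),
               7 - 0.3 + 0.5 + 0.1)
  # covariate contribution through named coefficients
  p3 <- param_set(b0 = 1, b1 = 0, beta1 = c(hla = 0.2))
  expect_equal(longitudinal_mean(0, p3, covariates = c(hla = 3)), 1.6)
})

test_that("B-spline basis keeps partition of unity", {
  tt <- seq(0, 84, by = 0.5)
  K <- 3 + 3 + 1
  basis <- trajectory_basis("bspline", degree = 3, n_knots = 3, times = tt,
                            coefficients = rep(4.2, K))
  expect_identical(basis$K, 7L)
  p <- param_set()
  f <- longitudinal_mean(tt, p, basis = basis)
  expect_equal(f, rep(4.2, length(tt)), tolerance = 1e-12)
})

test_that("weibull_cdf matches closed forms and the quadrature oracle", {
  expect_equal(weibull_cdf(0, 0.5, -2), 0)
  expect_equal(weibull_cdf(log(2), 1, 0), 0.5, tolerance = 1e-12)
  # exponential special case, alpha = 1
  tt <- c(0.1, 1, 5, 40)
  expect_equal(weibull_cdf(tt, 1, -1.3), 1 - exp(-tt * exp(-1.3)),
               tolerance = 1e-12)
  # randomized toys against numerical integration of the hazard
  set.seed(11)
  for (k in 1:20) {
    a <- runif(1, 0.3, 2.5)
    lp <- runif(1, -4, 1)
    t <- runif(1, 0.05, 20)
    expect_equal(weibull_cdf(t, a, lp), cdf_quadrature(t, a, lp),
                 tolerance = 1e-8)
  }
})

test_that("weibull_cdf is monotone and bounded", {
  tt <- seq(0, 60, by = 0.5)
  F1 <- weibull_cdf(tt, 0.5, -2)
  expect_true(all(diff(F1) >= 0))
  expect_true(all(F1 >= 0 & F1 < 1))
  expect_true(all(weibull_cdf(5, 0.5, c(-3, -1, 0, 1)) ==
                    cummax(weibull_cdf(5, 0.5, c(-3, -1, 0, 1)))))
  expect_gt(weibull_cdf(1e8, 0.5, -2), 1 - 1e-10)
})

test_that("random-effects log-density is the bivariate normal", {
  p <- param_set(sigma0_2 = 1, sigma1_2 = 1, rho = 0)
  expect_equal(random_effects_logdensity(list(a0 = 0, a1 = 0), p),
               -log(2 * pi), tolerance = 1e-12)
  # independence factorization at rho = 0
  p2 <- param_set(sigma0_2 = 2.5, sigma1_2 = 0.3, rho = 0)
  expect_equal(random_effects_logdensity(list(a0 = 0.7, a1 = -0.2), p2),
               dnorm(0.7, 0, sqrt(2.5), log = TRUE) +
                 dnorm(-0.2, 0, sqrt(0.3), log = TRUE),
               tolerance = 1e-12)
  # generic linear-algebra oracle
  p3 <- param_set(sigma0_2 = 1.75, sigma1_2 = 0.004, rho = -0.4)
  S <- matrix(c(1.75, -0.4 * sqrt(1.75 * 0.004),
                -0.4 * sqrt(1.75 * 0.004), 0.004), 2)
  x <- c(0.9, -0.05)
  oracle <- -log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * drop(x %*% solve(S) %*% x)
  expect_equal(random_effects_logdensity(list(a0 = x[1], a1 = x[2]), p3),
               oracle, tolerance = 1e-10)
  expect_error(random_effects_logdensity(list(a0 = 0, a1 = 0),
                                         param_set(rho = 0.999999999)),
               NA)
  p_bad <- param_set(); p_bad$rho <- 1
  expect_error(random_effects_logdensity(list(a0 = 0, a1 = 0), p_bad),
               "positive definite")
})

test_that("subject log-likelihood combines Gaussian and censoring terms", {
  spec <- model_spec("M2", time_scale = 12)
  p <- param_set(b0 = 7, b1 = 0, sigma_e2 = 2, beta0 = -2, alpha = 0.5,
                 lambda0 = -0.5)
  re <- list(a0 = 0, a1 = 0)
  # one on-mean observation, vanishing follow-up: survival term ~ 0
  s <- subject_data("x", times = 1e-9, values = 7, t_L = NA, t_R = 1e-8,
                    right_censored = TRUE)
  expect_equal(as.numeric(subject_loglik(s, p, re, spec)),
               -0.5 * log(2 * pi * 2), tolerance = 1e-5)

  # doubling sigma_e on-mean lowers each Gaussian term by log 2
  s2 <- subject_data("y", times = c(6, 12), values = 7 + c(0, 0),
                     t_L = NA, t_R = 84, right_censored = TRUE)
  p4 <- p; p4$sigma_e2 <- 4 * p$sigma_e2   # sigma_e doubled
  d <- as.numeric(subject_loglik(s2, p, re, spec)) -
    as.numeric(subject_loglik(s2, p4, re, spec))
  expect_equal(d, 2 * log(2), tolerance = 1e-12)

  # interval term equals the quadrature-oracle CDF difference
  s3 <- subject_data("z", times = 1, values = 6.5, t_L = 6, t_R = 24,
                     right_censored = FALSE, covariates = c(hla = 3))
  p5 <- param_set(b0 = 7, b1 = -0.03, sigma_e2 = 1, beta0 = -2,
                  beta2 = c(hla = 0.25), lambda0 = -0.5, alpha = 0.5)
  re5 <- list(a0 = 0.4, a1 = -0.02)
  lp <- -2 + 0.25 * 3 - 0.5 * 0.4
  ll <- subject_loglik(s3, p5, re5, spec)
  oracle_surv <- log(cdf_quadrature(24 / 12, 0.5, lp) -
                       cdf_quadrature(6 / 12, 0.5, lp))
  expect_equal(unname(attr(ll, "parts")["surv"]), oracle_surv,
               tolerance = 1e-8)

  # collapsed interval: guarded floor, finite, very negative
  s4 <- subject_data("w", times = 1, values = 7, t_L = 12 - 1e-13, t_R = 12,
                     right_censored = FALSE)
  llc <- as.numeric(subject_loglik(s4, p, re, spec))
  expect_true(is.finite(llc))
  expect_lt(llc, -25)   # log of a vanishing interval probability
  # fully degenerate interval probability hits the guard, stays finite
  expect_true(is.finite(icjm:::log_interval_prob(0.5, 0.5)))
  expect_true(is.finite(icjm:::log_interval_prob(0.5, 0.4)))

  # degenerate residual variance
  p0 <- p; p0$sigma_e2 <- 0
  s5 <- subject_data("v", times = 1, values = 6.0, t_L = 6, t_R = 12,
                     right_censored = FALSE)
  expect_identical(as.numeric(subject_loglik(s5, p0, re, spec)), -Inf)
})

test_that("dataset log-likelihood is additive, permutation-invariant, and respects family constraints", {
  d <- cached_sim_data()[1:20]
  d <- icjm_data(d)
  spec2 <- model_spec("M2")
  p <- default_truth()
  set.seed(4)
  re <- cbind(rnorm(20, 0, 1.3), rnorm(20, 0, 0.06))
  ll <- dataset_loglik(d, p, re, spec2)
  expect_equal(as.numeric(ll), sum(attr(ll, "per_subject")), tolerance = 1e-10)
  per <- vapply(seq_along(d), function(i)
    as.numeric(subject_loglik(d[[i]], p, list(a0 = re[i, 1], a1 = re[i, 2]),
                              spec2)), numeric(1))
  expect_equal(attr(ll, "per_subject"), per, tolerance = 1e-12)

  # permutation invariance
  perm <- sample(20)
  llp <- dataset_loglik(icjm_data(d[perm]), p, re[perm, ], spec2)
  expect_equal(as.numeric(llp), as.numeric(ll), tolerance = 1e-10)

  # M1 with lambda1 = 0 equals M2 exactly
  ll1 <- dataset_loglik(d, p, re, model_spec("M1"))
  expect_identical(as.numeric(ll1), as.numeric(ll))

  # empty dataset
  expect_identical(as.numeric(dataset_loglik(icjm_data(list()), p,
                                             list(), spec2)), 0)
  expect_error(dataset_loglik(d, p, re[1:3, ], spec2), "one random-effects")
})
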