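test_that("DIC formula on hand-computable toys", {
  # degenerate posterior: all draws identical -> p_D = 0, DIC = D(theta-hat)
  ll <- matrix(rep(c(-1.2, -0.7), 3), nrow = 2)
  d0 <- dic_from_loglik(ll, c(-1.2, -0.7))
  expect_equal(as.numeric(d0), -2 * (-1.9), tolerance = 1e-12)
  expect_equal(attr(d0, "p_D"), 0, tolerance = 1e-12)

  # 3-draw toy, hand-expanded formula
  ll3 <- matrix(c(-1.0, -2.0,
                  -1.5, -1.8,
                  -0.8, -2.4), nrow = 2)
  hat <- c(-1.1, -2.05)
  dbar <- mean(-2 * colSums(ll3))
  expect_equal(as.numeric(dic_from_loglik(ll3, hat)),
               2 * dbar - (-2 * sum(hat)), tolerance = 1e-12)

  # affine property: adding c to every log-likelihood shifts DIC by -2c
  cshift <- 0.37
  d1 <- dic_from_loglik(ll3, hat)
  d2 <- dic_from_loglik(ll3 + cshift / 2, hat + cshift / 2)
  expect_equal(as.numeric(d2), as.numeric(d1) - 2 * cshift,
               tolerance = 1e-12)
})

test_that("WAIC formula on hand-computable toys", {
  # identical draws: p_waic = 0, WAIC = -2 sum(ll)
  ll <- matrix(rep(c(-1.2, -0.7), 4), nrow = 2)
  w0 <- waic_from_loglik(ll)
  expect_equal(as.numeric(w0), -2 * (-1.9), tolerance = 1e-12)
  expect_equal(attr(w0, "p_waic"), 0, tolerance = 1e-12)

  # 2-subject 3-draw toy against the direct formula
  ll3 <- matrix(c(-1.0, -2.0,
                  -1.5, -1.8,
                  -0.8, -2.4), nrow = 2)
  lppd <- sum(log(rowMeans(exp(ll3))))
  p <- sum(apply(ll3, 1, var))
  expect_equal(as.numeric(waic_from_loglik(ll3)), -2 * (lppd - p),
               tolerance = 1e-12)
  # subject-permutation invariance
  expect_equal(as.numeric(waic_from_loglik(ll3[2:1, ])),
               as.numeric(waic_from_loglik(ll3)), tolerance = 1e-12)
  # numerically stable under large magnitudes
  expect_true(is.finite(waic_from_loglik(ll3 - 800)))
})

test_that("fit-level criteria decompose into sub-model parts", {
  f <- cached_jm_fit()
  d <- dic(f)
  w <- waic(f)
  expect_equal(sum(attr(d, "parts")), as.numeric(d), tolerance = 1e-8)
  expect_equal(sum(attr(w, "parts")), as.numeric(w), tolerance = 1e-8)
  expect_gt(attr(d, "p_D"), 0)
  ft <- cached_tvc_fit()
  expect_true(is.finite(as.numeric(dic(ft))))
  expect_true(is.finite(as.numeric(waic(ft))))
  cmp <- compare_models(jm = f, tvc = ft)
  expect_identical(nrow(cmp), 2L)
  expect_true(is.finite(sum(cmp$DIC, cmp$WAIC)))
})

test_that("information criteria prefer the generating sharing structure", {
  # Data generated from the shared random-intercept model: M2 should beat
  # M3 (shared slope only).  The slope variance is raised so that the
  # individual slopes are identified by the longitudinal records; under
  # the default truth the slopes of early-event subjects are so weakly
  # identified that lambda1 * a1 degenerates into a free per-subject
  # frailty, which conditional-likelihood criteria reward (see the
  # methods vignette's limitations section).
  wins_dic <- 0; wins_waic <- 0
  R <- 8
  tr <- default_truth()
  tr$sigma1_2 <- 0.25
  for (m in seq_len(R)) {
    scn <- scenario(me = "low", n_subjects = 120, truth = tr)
    d <- simulate_dataset(scn, seed = 720 + m)
    f2 <- fit_icjm(d, model_spec("M2"), config = quick_config(seed = m))
    f3 <- fit_icjm(d, model_spec("M3"), config = quick_config(seed = m))
    wins_dic <- wins_dic + (as.numeric(dic(f2)) < as.numeric(dic(f3)))
    wins_waic <- wins_waic + (as.numeric(waic(f2)) < as.numeric(waic(f3)))
  }
  expect_gte(wins_dic / R, 0.8)
  expect_gte(wins_waic / R, 0.8)
})

test_that("posterior predictive trajectories centre on the fitted mean", {
  f <- cached_jm_fit()
  id <- f$data[[4]]$id
  rep <- ppc_longitudinal(f, id, n_rep = 400)
  mu <- attr(rep, "mu_hat")
  # pointwise replicate mean within 3 MC SEs of the posterior-mean curve
  se <- apply(rep, 2, sd) / sqrt(nrow(rep))
  expect_true(all(abs(colMeans(rep) - mu) < 3 * se + 0.05))
  expect_identical(nrow(ppc_longitudinal(f, id, n_rep = 0)), 0L)
  expect_error(ppc_longitudinal(f, "no-such-subject"), "not present")

  # with a point-mass posterior and vanishing sigma_e the replicates
  # collapse onto the fitted mean line
  g <- f
  pm <- colMeans(posterior_draws(f))
  g$chains <- lapply(g$chains, function(m) {
    m[] <- rep(pm, each = nrow(m))
    m[, "sigma_e2"] <- 1e-18
    m
  })
  rep0 <- ppc_longitudinal(g, id, n_rep = 20)
  expect_lt(max(apply(rep0, 2, sd)), 1e-8)
  expect_equal(unname(rep0[1, ]), unname(attr(rep0, "mu_hat")),
               tolerance = 1e-6)
})

test_that("posterior predictive survival curves behave like CDFs", {
  f <- cached_jm_fit()
  set.seed(3)
  out <- ppc_survival(f, c(hla = 4), n_rep = 200,
                      schedule = make_schedule("lighter", 84))
  expect_true(all(apply(out$curves, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(out$curves >= 0 & out$curves <= 1))
  expect_identical(nrow(out$intervals), 200L)

  # a point-mass posterior yields identical curves
  g <- f
  g$chains <- lapply(g$chains, function(m) {
    m[] <- rep(colMeans(posterior_draws(f)), each = nrow(m)); m
  })
  out1 <- ppc_survival(g, c(hla = 4), n_rep = 20)
  expect_equal(max(apply(out1$curves, 2, sd)), 0, tolerance = 1e-12)

  # the generating CDF lies inside the pointwise 95% replicate band
  truth <- attr(f$data, "truth")
  gen <- weibull_cdf(out$times / 12, truth$alpha,
                     truth$beta0 + 0.25 * 4)
  lo <- apply(out$curves, 2, quantile, 0.025)
  hi <- apply(out$curves, 2, quantile, 0.975)
  inside <- mean(gen >= lo & gen <= hi)
  expect_gte(inside, 0.9)
})
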