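# Bayesian fitting of models M1-M4: prior specification, the sampler
# front-end, and posterior summaries.

#' Prior specification
#'
#' Weakly informative defaults: independent Normal(0, 100^2) priors on all
#' regression, association and TVC coefficients; Uniform(0, 100) on the
#' residual SD `sigma_e`; Gamma(shape 100, rate 100) on the Weibull shapes
#' (mean 1, SD 0.1); and a Wishart prior with rate matrix
#' `diag(1e-5, 1e-6)` and 2 degrees of freedom on the precision matrix of
#' the random intercept and slope.  Alternatives used for sensitivity
#' analysis are available: a Uniform(-100, 100) prior on coefficients and a
#' half-Cauchy(0, 25) prior on `sigma_e`.
#'
#' @param coefficient_sd normal prior SD for coefficients.
#' @param coefficient_prior `"normal"` or `"uniform"`.
#' @param coefficient_range support of the uniform alternative.
#' @param sigma_e_upper upper bound of the uniform prior on `sigma_e`.
#' @param sigma_prior `"uniform"` or `"half_cauchy"`.
#' @param half_cauchy_scale scale of the half-Cauchy alternative.
#' @param alpha_shape,alpha_rate Gamma prior (shape-rate) on the Weibull
#'   shapes.
#' @param wishart_scale 2x2 rate matrix of the Wishart prior on the
#'   random-effects precision.
#' @param wishart_df Wishart degrees of freedom.
#' @return An object of class `icjm_prior`.
#' @export
prior_spec <- function(coefficient_sd = sqrt(10000),
                       coefficient_prior = c("normal", "uniform"),
                       coefficient_range = c(-100, 100),
                       sigma_e_upper = 100,
                       sigma_prior = c("uniform", "half_cauchy"),
                       half_cauchy_scale = 25,
                       alpha_shape = 100, alpha_rate = 100,
                       wishart_scale = diag(c(1e-5, 1e-6)),
                       wishart_df = 2) {
  coefficient_prior <- match.arg(coefficient_prior)
  sigma_prior <- match.arg(sigma_prior)
  stopifnot(coefficient_sd > 0, sigma_e_upper > 0, alpha_shape > 0,
            alpha_rate > 0, wishart_df >= 2, half_cauchy_scale > 0)
  structure(list(coefficient_sd = coefficient_sd,
                 coefficient_prior = coefficient_prior,
                 coefficient_range = coefficient_range,
                 sigma_e_upper = sigma_e_upper,
                 sigma_prior = sigma_prior,
                 half_cauchy_scale = half_cauchy_scale,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 wishart_scale = wishart_scale, wishart_df = wishart_df),
            class = "icjm_prior")
}

#' MCMC configuration
#'
#' Defaults mirror the simulation-study settings: the TVC model uses a
#' burn-in of 1000 and 1000 kept samples, the joint model 2000 and 2000,
#' both with two chains.  `preset = "full_data"` gives the long-run setting
#' used for a real cohort analysis (burn-in 20000, thinning 40, 2000 kept
#' samples per chain).
#'
#' @param n_chains number of chains.
#' @param burn_in burn-in iterations per chain.
#' @param n_samples kept samples per chain.
#' @param thin thinning interval.
#' @param seed integer seed controlling all chains.
#' @param preset optional name: `"simulation_jm"`, `"simulation_tvc"` or
#'   `"full_data"`.
#' @return An object of class `icjm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, burn_in = 2000, n_samples = 2000,
                        thin = 1, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("simulation_jm", "simulation_tvc",
                                  "full_data"))
    set <- switch(preset,
      simulation_jm = list(burn_in = 2000, n_samples = 2000, thin = 1),
      simulation_tvc = list(burn_in = 1000, n_samples = 1000, thin = 1),
      full_data = list(burn_in = 20000, n_samples = 2000, thin = 40))
    burn_in <- set$burn_in; n_samples <- set$n_samples; thin <- set$thin
  }
  stopifnot(n_chains >= 1, burn_in >= 1, n_samples >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "icjm_mcmc_config")
}

default_config <- function(spec, seed = 1) {
  if (spec$family == "M4") mcmc_config(preset = "simulation_tvc", seed = seed)
  else mcmc_config(preset = "simulation_jm", seed = seed)
}

# log of the multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Wishart log-density of precision Omega under rate-matrix parameterization
# p(Omega) \propto |Omega|^{(k-p-1)/2} |R|^{k/2} exp(-Tr(R Omega)/2)
dwishart_log <- function(Omega, R, k) {
  p <- nrow(Omega)
  ld <- as.numeric(determinant(Omega, logarithm = TRUE)$modulus)
  ldR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  (k - p - 1) / 2 * ld + k / 2 * ldR -
    sum(diag(R %*% Omega)) / 2 - p * k / 2 * log(2) - lmvgamma(k / 2, p)
}

#' Joint log prior density
#'
#' Sum of the stated log prior densities over the free parameters of the
#' model family, plus the random-effects log-density (for joint models).
#' Parameters outside the support (e.g. `sigma_e` above its uniform bound)
#' give `-Inf`.
#'
#' @param params an `icjm_params` object.
#' @param re_all list (or 2-column matrix) of per-subject random effects;
#'   ignored for `M4`.
#' @param prior an [prior_spec()].
#' @param spec an [model_spec()].
#' @return scalar log prior density.
#' @export
log_prior <- function(params, re_all = NULL, prior = prior_spec(),
                      spec = model_spec("M2")) {
  coef_ld <- function(x) {
    if (prior$coefficient_prior == "uniform") {
      lo <- prior$coefficient_range[1]; hi <- prior$coefficient_range[2]
      if (any(x < lo | x > hi)) return(-Inf)
      return(-length(x) * log(hi - lo))
    }
    sum(dnorm(x, 0, prior$coefficient_sd, log = TRUE))
  }
  gamma_ld <- function(x) {
    if (x <= 0) return(-Inf)
    stats::dgamma(x, shape = prior$alpha_shape, rate = prior$alpha_rate,
                  log = TRUE)
  }
  if (spec$family == "M4") {
    return(coef_ld(c(params$gamma0, params$gamma, params$eta)) +
             gamma_ld(params$alpha_tvc))
  }
  params <- constrain_params(params, spec)
  coefs <- c(params$b0, params$b1, params$beta1, params$beta0, params$beta2)
  if (spec$family %in% c("M1", "M2")) coefs <- c(coefs, params$lambda0)
  if (spec$family %in% c("M1", "M3")) coefs <- c(coefs, params$lambda1)
  lp <- coef_ld(coefs)
  sigma_e <- sqrt(params$sigma_e2)
  lp <- lp + if (prior$sigma_prior == "uniform") {
    if (sigma_e <= 0 || sigma_e >= prior$sigma_e_upper) -Inf
    else -log(prior$sigma_e_upper)
  } else {
    stats::dcauchy(sigma_e, 0, prior$half_cauchy_scale, log = TRUE) + log(2)
  }
  if (spec$hazard == "weibull") lp <- lp + gamma_ld(params$alpha)
  Sigma <- matrix(c(params$sigma0_2,
                    params$rho * sqrt(params$sigma0_2 * params$sigma1_2),
                    params$rho * sqrt(params$sigma0_2 * params$sigma1_2),
                    params$sigma1_2), 2, 2)
  Omega <- solve(Sigma)
  lp <- lp + dwishart_log(Omega, prior$wishart_scale, prior$wishart_df)
  if (!is.null(re_all)) {
    if (is.matrix(re_all))
      re_all <- lapply(seq_len(nrow(re_all)),
                       function(i) list(a0 = re_all[i, 1], a1 = re_all[i, 2]))
    lp <- lp + sum(vapply(re_all, random_effects_logdensity, numeric(1),
                          params = params))
  }
  lp
}

# --- fitting -----------------------------------------------------------------

jm_prepare <- function(data, spec) {
  cn <- covariate_names(data)
  lc <- spec$long_covariates
  stopifnot(all(lc %in% cn))
  N <- length(data)
  mom <- function(f) vapply(data, f, numeric(1))
  Xs <- if (length(cn))
    do.call(rbind, lapply(data, function(s) s$covariates[cn]))
  else matrix(0, N, 0)
  Xl <- if (length(lc)) Xs[, lc, drop = FALSE] else matrix(0, N, 0)
  ts <- spec$time_scale
  list(
    n = mom(function(s) length(s$times)),
    Sy = mom(function(s) sum(s$values)),
    St = mom(function(s) sum(s$times / ts)),
    Stt = mom(function(s) sum((s$times / ts)^2)),
    Sty = mom(function(s) sum(s$times / ts * s$values)),
    Syy = mom(function(s) sum(s$values^2)),
    Xl = Xl, Xs = Xs,
    tL = mom(function(s) if (s$right_censored) 0 else s$t_L / ts),
    tR = mom(function(s) s$t_R / ts),
    rc = vapply(data, function(s) as.integer(s$right_censored), integer(1)))
}

tvc_prepare <- function(data, paths, spec) {
  cn <- covariate_names(data)
  N <- length(data)
  ts <- spec$time_scale
  Xs <- if (length(cn))
    do.call(rbind, lapply(data, function(s) s$covariates[cn]))
  else matrix(0, N, 0)
  segR <- vector("list", N); segL <- vector("list", N)
  for (i in seq_len(N)) {
    s <- data[[i]]
    sr <- path_segments(paths[[i]], s$t_R, ts)
    segR[[i]] <- cbind(i - 1L, sr$start, sr$end, sr$w)
    if (!s$right_censored && s$t_L > 0) {
      sl <- path_segments(paths[[i]], s$t_L, ts)
      segL[[i]] <- cbind(i - 1L, sl$start, sl$end, sl$w)
    }
  }
  R <- do.call(rbind, segR)
  L <- do.call(rbind, segL[!vapply(segL, is.null, logical(1))])
  if (is.null(L)) L <- matrix(0, 0, 4)
  list(N = as.integer(N),
       rc = vapply(data, function(s) as.integer(s$right_censored),
                   integer(1)),
       Xs = Xs,
       segR_subj = as.integer(R[, 1]), segR_a = R[, 2], segR_b = R[, 3],
       segR_w = R[, 4],
       segL_subj = as.integer(L[, 1]), segL_a = L[, 2], segL_b = L[, 3],
       segL_w = L[, 4])
}

prior_for_cpp <- function(prior) {
  list(coefficient_sd = prior$coefficient_sd,
       coef_uniform = as.integer(prior$coefficient_prior == "uniform"),
       coef_lo = prior$coefficient_range[1],
       coef_hi = prior$coefficient_range[2],
       sigma_e_upper = prior$sigma_e_upper,
       sigma_half_cauchy = as.integer(prior$sigma_prior == "half_cauchy"),
       half_cauchy_scale = prior$half_cauchy_scale,
       alpha_shape = prior$alpha_shape, alpha_rate = prior$alpha_rate,
       wishart_scale = prior$wishart_scale, wishart_df = prior$wishart_df)
}

jm_init <- function(data, prep, spec, jitter = 0) {
  yall <- unlist(lapply(data, `[[`, "values"))
  subj_means <- prep$Sy / prep$n
  nev <- sum(prep$rc == 0)
  exposure <- sum(prep$tR)
  init <- list(
    b0 = mean(yall), b1 = 0,
    beta1 = rep(0, ncol(prep$Xl)),
    sigma_e2 = max(0.5 * var(yall), 1e-4),
    sigma0_2 = max(var(subj_means), 0.1), sigma1_2 = 0.01, rho = 0,
    beta0 = log(max(nev, 1) / exposure),
    beta2 = rep(0, ncol(prep$Xs)),
    lambda0 = 0, lambda1 = 0, alpha = 1,
    a = matrix(0, length(data), 2))
  if (jitter > 0) {
    for (nm in c("b0", "b1", "beta0", "lambda0", "lambda1"))
      init[[nm]] <- init[[nm]] + rnorm(1, 0, jitter)
    for (nm in c("sigma_e2", "sigma0_2", "sigma1_2", "alpha"))
      init[[nm]] <- init[[nm]] * exp(rnorm(1, 0, jitter))
  }
  init
}

tvc_init <- function(prep, jitter = 0) {
  nev <- sum(prep$rc == 0)
  exposure <- sum(tapply(pmax(prep$segR_b, 0), prep$segR_subj, max))
  init <- list(gamma0 = log(max(nev, 1) / max(exposure, 1)),
               gamma = rep(0, ncol(prep$Xs)), eta = 0, alpha_tvc = 1)
  if (jitter > 0) {
    init$gamma0 <- init$gamma0 + rnorm(1, 0, jitter)
    init$eta <- init$eta + rnorm(1, 0, jitter)
    init$alpha_tvc <- init$alpha_tvc * exp(rnorm(1, 0, jitter))
  }
  init
}

jm_param_names <- function(prep) {
  c("b0", "b1",
    if (ncol(prep$Xl)) paste0("beta1_", colnames(prep$Xl)),
    "sigma_e2", "sigma0_2", "sigma1_2", "rho", "beta0",
    if (ncol(prep$Xs)) paste0("beta2_", colnames(prep$Xs)),
    "lambda0", "lambda1", "alpha")
}

tvc_param_names <- function(prep) {
  c("gamma0", if (ncol(prep$Xs)) paste0("gamma_", colnames(prep$Xs)),
    "eta", "alpha_tvc")
}

#' Fit a model by MCMC
#'
#' Posterior sampling for the joint models (M1, M2, M3) or the
#' time-varying-covariate survival model (M4) under the priors of
#' [prior_spec()].  The sampler is an adaptive Metropolis-within-Gibbs
#' scheme with conjugate updates for the longitudinal fixed effects,
#' residual variance and random-effects covariance; proposal scales adapt
#' during burn-in only.  Runs are reproducible given `config$seed`.
#'
#' With `use_likelihood = FALSE` the data are ignored and independent draws
#' from the prior are returned (useful for prior predictive checks and for
#' validating the sampler's target).
#'
#' @param data an `icjm_data` object.
#' @param spec an [model_spec()].
#' @param prior an [prior_spec()].
#' @param config an [mcmc_config()]; when `NULL`, the family-specific
#'   simulation default is used.
#' @param paths for `M4`: list of [covariate_path()]s; built with
#'   [build_paths()] when omitted.
#' @param save_re keep per-draw random effects (joint models).
#' @param use_likelihood set `FALSE` for prior-only sampling.
#' @return An object of class `icjm_fit`.
#' @export
fit_icjm <- function(data, spec = model_spec("M2"), prior = prior_spec(),
                     config = NULL, paths = NULL, save_re = FALSE,
                     use_likelihood = TRUE) {
  stopifnot(inherits(data, "icjm_data"), length(data) >= 1)
  if (is.null(config)) config <- default_config(spec)
  if (spec$family != "M4" && spec$trajectory != "linear")
    stop("the sampler supports the linear trajectory; ",
         "spline bases are available in the likelihood functions")
  if (!use_likelihood)
    return(prior_only_fit(data, spec, prior, config))
  if (spec$family == "M4") {
    if (is.null(paths)) paths <- build_paths(data)
    prep <- tvc_prepare(data, paths, spec)
    pn <- tvc_param_names(prep)
  } else {
    prep <- jm_prepare(data, spec)
    pn <- jm_param_names(prep)
  }
  pc <- prior_for_cpp(prior)
  chains <- vector("list", config$n_chains)
  ll_tot <- NULL; ll_long <- NULL; ll_surv <- NULL
  re_mean_acc <- NULL; re_draws <- list()
  for (ch in seq_len(config$n_chains)) {
    set.seed((config$seed + 104729L * (ch - 1L)) %% .Machine$integer.max)
    cfg <- list(burn_in = config$burn_in, n_samples = config$n_samples,
                thin = config$thin,
                est_alpha = as.integer(spec$hazard == "weibull"))
    if (spec$family == "M4") {
      init <- tvc_init(prep, jitter = if (ch > 1) 0.1 else 0)
      if (spec$hazard == "exponential") init$alpha_tvc <- 1
      res <- tvc_mcmc_cpp(prep, pc, cfg, init)
      ll_tot <- cbind(ll_tot, res$ll)
    } else {
      init <- jm_init(data, prep, spec, jitter = if (ch > 1) 0.1 else 0)
      # constrained parameters stay at their fixed values
      if (spec$family == "M2") init$lambda1 <- 0
      if (spec$family == "M3") init$lambda0 <- 0
      if (spec$hazard == "exponential") init$alpha <- 1
      res <- jm_mcmc_cpp(prep, pc, cfg, init,
                         est_lambda0 = as.integer(spec$family %in% c("M1", "M2")),
                         est_lambda1 = as.integer(spec$family %in% c("M1", "M3")),
                         est_alpha = cfg$est_alpha,
                         save_re = as.integer(save_re))
      ll_long <- cbind(ll_long, res$ll_long)
      ll_surv <- cbind(ll_surv, res$ll_surv)
      ll_tot <- cbind(ll_tot, res$ll_long + res$ll_surv)
      re_mean_acc <- if (is.null(re_mean_acc)) res$re_mean
                     else re_mean_acc + res$re_mean
      if (save_re)
        re_draws[[ch]] <- list(a0 = res$a0_draws, a1 = res$a1_draws)
    }
    dm <- res$draws
    colnames(dm) <- pn
    chains[[ch]] <- dm
    if (!is.finite(sum(dm[nrow(dm), ])))
      stop("non-finite state at the end of chain ", ch)
  }
  structure(list(spec = spec, prior = prior, config = config,
                 param_names = pn, chains = chains,
                 loglik = list(total = ll_tot, long = ll_long,
                               surv = ll_surv),
                 re_mean = if (!is.null(re_mean_acc))
                   re_mean_acc / config$n_chains,
                 re_draws = if (save_re && length(re_draws)) re_draws,
                 data = data,
                 paths = if (spec$family == "M4") paths,
                 prior_only = FALSE),
            class = "icjm_fit")
}

prior_only_fit <- function(data, spec, prior, config) {
  S <- config$n_samples
  draw_coefs <- function(n) {
    if (prior$coefficient_prior == "uniform")
      matrix(runif(n * S, prior$coefficient_range[1],
                   prior$coefficient_range[2]), S, n)
    else matrix(rnorm(n * S, 0, prior$coefficient_sd), S, n)
  }
  cn <- covariate_names(data)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed((config$seed + 104729L * (ch - 1L)) %% .Machine$integer.max)
    if (spec$family == "M4") {
      dm <- cbind(draw_coefs(1 + length(cn) + 1),
                  rgamma(S, prior$alpha_shape, prior$alpha_rate))
      colnames(dm) <- c("gamma0", if (length(cn)) paste0("gamma_", cn),
                        "eta", "alpha_tvc")
    } else {
      sig <- if (prior$sigma_prior == "uniform")
        runif(S, 0, prior$sigma_e_upper)^2
      else abs(stats::rcauchy(S, 0, prior$half_cauchy_scale))^2
      Vprior <- solve(prior$wishart_scale)
      Om <- stats::rWishart(S, prior$wishart_df, Vprior)
      s02 <- s12 <- rho <- numeric(S)
      for (s in seq_len(S)) {
        Sg <- solve(Om[, , s])
        s02[s] <- Sg[1, 1]; s12[s] <- Sg[2, 2]
        rho[s] <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
      }
      co <- draw_coefs(2 + length(cn) + 3)
      dm <- cbind(co[, 1:2, drop = FALSE], sig, s02, s12, rho,
                  co[, 3, drop = FALSE],
                  if (length(cn)) co[, 3 + seq_along(cn), drop = FALSE],
                  co[, (4 + length(cn)):(5 + length(cn)), drop = FALSE],
                  rgamma(S, prior$alpha_shape, prior$alpha_rate))
      colnames(dm) <- c("b0", "b1", "sigma_e2", "sigma0_2", "sigma1_2",
                        "rho", "beta0", if (length(cn)) paste0("beta2_", cn),
                        "lambda0", "lambda1", "alpha")
    }
    chains[[ch]] <- dm
  }
  structure(list(spec = spec, prior = prior, config = config,
                 param_names = colnames(chains[[1]]), chains = chains,
                 loglik = NULL, re_mean = NULL, re_draws = NULL,
                 data = data, paths = NULL, prior_only = TRUE),
            class = "icjm_fit")
}

#' Pooled posterior draws
#'
#' @param fit an `icjm_fit`.
#' @return matrix of draws, chains stacked.
#' @export
posterior_draws <- function(fit) {
  do.call(rbind, fit$chains)
}

#' Equal-tailed credible interval
#'
#' @param draws numeric vector of posterior draws.
#' @param level interval probability (default 0.95).
#' @return numeric `c(lower, upper)` at the `(1-level)/2` and
#'   `1-(1-level)/2` percentiles.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!length(draws)) stop("empty draw vector")
  stopifnot(level > 0, level < 1)
  unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' @export
summary.icjm_fit <- function(object, level = 0.95, ...) {
  dm <- posterior_draws(object)
  out <- data.frame(
    parameter = colnames(dm),
    mean = colMeans(dm),
    sd = apply(dm, 2, sd),
    lower = apply(dm, 2, function(x) credible_interval(x, level)[1]),
    upper = apply(dm, 2, function(x) credible_interval(x, level)[2]),
    row.names = NULL)
  if (length(object$chains) >= 2)
    out$rhat <- vapply(colnames(dm), function(p)
      gelman_rhat(lapply(object$chains, function(m) m[, p])), numeric(1))
  out
}

#' @export
print.icjm_fit <- function(x, ...) {
  cat(sprintf("<icjm_fit> family=%s, %d chains x %d draws%s\n",
              x$spec$family, length(x$chains), nrow(x$chains[[1]]),
              if (isTRUE(x$prior_only)) " (prior only)" else ""))
  print(summary(x), digits = 3)
  invisible(x)
}

# posterior-mean parameter set from a fit
posterior_mean_params <- function(fit) {
  m <- colMeans(posterior_draws(fit))
  pick <- function(prefix) {
    idx <- grep(paste0("^", prefix, "_"), names(m))
    v <- m[idx]
    names(v) <- sub(paste0("^", prefix, "_"), "", names(m)[idx])
    v
  }
  if (fit$spec$family == "M4") {
    param_set(gamma0 = m[["gamma0"]], gamma = pick("gamma"),
              eta = m[["eta"]], alpha_tvc = m[["alpha_tvc"]])
  } else {
    param_set(b0 = m[["b0"]], b1 = m[["b1"]], beta1 = pick("beta1"),
              sigma_e2 = m[["sigma_e2"]], sigma0_2 = m[["sigma0_2"]],
              sigma1_2 = m[["sigma1_2"]], rho = m[["rho"]],
              beta0 = m[["beta0"]], beta2 = pick("beta2"),
              lambda0 = m[["lambda0"]], lambda1 = m[["lambda1"]],
              alpha = m[["alpha"]])
  }
}
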