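# Model comparison on the conditional likelihood (DIC, WAIC) and posterior
# predictive checks.

#' DIC from a log-likelihood matrix
#'
#' `DIC = 2 * Dbar - D(theta_hat)` with `D = -2 log L`; `Dbar` is the
#' posterior mean deviance and `D(theta_hat)` the deviance at the posterior
#' mean of the parameters (and, for hierarchical models, of the latent
#' random effects — the conditional-likelihood convention).
#'
#' @param ll matrix of conditional log-likelihoods, subjects x draws.
#' @param ll_at_mean per-subject log-likelihood vector (or its sum)
#'   evaluated at the posterior mean.
#' @return DIC with attribute `p_D`.
#' @export
dic_from_loglik <- function(ll, ll_at_mean) {
  dev <- -2 * colSums(ll)
  dbar <- mean(dev)
  dhat <- -2 * sum(ll_at_mean)
  out <- 2 * dbar - dhat
  attr(out, "p_D") <- dbar - dhat
  out
}

#' WAIC from a log-likelihood matrix
#'
#' `WAIC = -2 (lppd - p_waic)` where `lppd` sums, over subjects, the log of
#' the posterior-mean likelihood (computed with log-sum-exp for stability)
#' and `p_waic` sums the posterior variances of the log-likelihood.
#'
#' @param ll matrix of conditional log-likelihoods, subjects x draws.
#' @return WAIC with attributes `lppd` and `p_waic`.
#' @export
waic_from_loglik <- function(ll) {
  if (is.vector(ll)) ll <- matrix(ll, nrow = 1)
  S <- ncol(ll)
  lppd <- sum(apply(ll, 1, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  p_waic <- sum(apply(ll, 1, var))
  if (S == 1) p_waic <- 0
  out <- -2 * (lppd - p_waic)
  attr(out, "lppd") <- lppd
  attr(out, "p_waic") <- p_waic
  out
}

# per-subject conditional log-likelihood at the posterior mean of the
# parameters and random effects
loglik_at_posterior_mean <- function(fit) {
  params <- posterior_mean_params(fit)
  if (fit$spec$family == "M4") {
    ll <- dataset_loglik_tvc(fit$data, fit$paths, params,
                             fit$spec$time_scale)
    list(total = attr(ll, "per_subject"))
  } else {
    parts_long <- numeric(length(fit$data))
    parts_surv <- numeric(length(fit$data))
    for (i in seq_along(fit$data)) {
      re <- list(a0 = fit$re_mean[i, 1], a1 = fit$re_mean[i, 2])
      li <- subject_loglik(fit$data[[i]], params, re, fit$spec)
      p <- attr(li, "parts")
      parts_long[i] <- p[["long"]]
      parts_surv[i] <- p[["surv"]]
    }
    list(total = parts_long + parts_surv, long = parts_long,
         surv = parts_surv)
  }
}

#' Deviance information criterion of a fit
#'
#' Computed on the likelihood conditional on the sampled random effects;
#' the plug-in deviance uses posterior means of both the parameters and the
#' latent random effects.  For joint models the value decomposes into
#' longitudinal and survival parts (attribute `parts`), which sum to the
#' total, so the survival part is directly comparable with the TVC model's
#' criterion.
#'
#' @param fit an `icjm_fit` (fitted with the likelihood enabled).
#' @return DIC value with attributes `p_D` and (for joint models) `parts`.
#' @export
dic <- function(fit) {
  if (is.null(fit$loglik)) stop("fit carries no likelihood draws")
  hat <- loglik_at_posterior_mean(fit)
  if (!all(is.finite(hat$total))) {
    bad <- which(!is.finite(hat$total))
    stop("non-finite deviance at the posterior mean for subjects: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- dic_from_loglik(fit$loglik$total, hat$total)
  if (fit$spec$family != "M4") {
    attr(out, "parts") <- c(
      long = as.numeric(dic_from_loglik(fit$loglik$long, hat$long)),
      surv = as.numeric(dic_from_loglik(fit$loglik$surv, hat$surv)))
  }
  out
}

#' Watanabe-Akaike information criterion of a fit
#'
#' Conditional-likelihood WAIC; joint-model values decompose into
#' longitudinal and survival parts (attribute `parts`).  The survival part
#' is the WAIC of the survival sub-likelihood alone (directly comparable to
#' the TVC model's criterion) and the longitudinal part is the remainder,
#' so the two parts sum to the total by construction.
#'
#' @param fit an `icjm_fit`.
#' @return WAIC with attributes `lppd`, `p_waic`, and `parts` for joint
#'   models.
#' @export
waic <- function(fit) {
  if (is.null(fit$loglik)) stop("fit carries no likelihood draws")
  out <- waic_from_loglik(fit$loglik$total)
  if (fit$spec$family != "M4") {
    surv <- as.numeric(waic_from_loglik(fit$loglik$surv))
    attr(out, "parts") <- c(long = as.numeric(out) - surv, surv = surv)
  }
  out
}

#' Compare fitted models by DIC and WAIC
#'
#' @param ... named `icjm_fit` objects.
#' @param materiality difference considered meaningful (default 5 points).
#' @return data frame with DIC, WAIC, their decompositions where available,
#'   and a `preferred` flag (lowest WAIC, and lower than the runner-up by at
#'   least `materiality`; ties by DIC).
#' @export
compare_models <- function(..., materiality = 5) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- dic(f); w <- waic(f)
    dp <- attr(d, "parts"); wp <- attr(w, "parts")
    data.frame(model = nm, family = f$spec$family,
               DIC = as.numeric(d), WAIC = as.numeric(w),
               DIC_long = if (is.null(dp)) NA_real_ else dp[["long"]],
               DIC_surv = if (is.null(dp)) NA_real_ else dp[["surv"]],
               WAIC_long = if (is.null(wp)) NA_real_ else wp[["long"]],
               WAIC_surv = if (is.null(wp)) NA_real_ else wp[["surv"]])
  })
  out <- do.call(rbind, rows)
  ord <- order(out$WAIC)
  out$preferred <- FALSE
  if (nrow(out) > 1) {
    gap <- out$WAIC[ord[2]] - out$WAIC[ord[1]]
    out$preferred[ord[1]] <- gap >= materiality
  } else {
    out$preferred[1] <- TRUE
  }
  attr(out, "materiality") <- materiality
  out
}

#' Posterior predictive biomarker trajectories
#'
#' Replicated trajectories at a subject's observed measurement times, with
#' the random effects fixed at their posterior means and the fixed effects
#' and residual SD redrawn across posterior draws.
#'
#' @param fit a fitted joint model.
#' @param subject_id id of a subject present in the fit.
#' @param n_rep number of replicated trajectories.
#' @return matrix `n_rep` x number of times, with attributes `times` and
#'   `mu_hat` (the posterior-mean trajectory).
#' @export
ppc_longitudinal <- function(fit, subject_id, n_rep = 100) {
  if (fit$spec$family == "M4") stop("posterior predictive trajectories need a joint-model fit")
  ids <- vapply(fit$data, function(s) as.character(s$id), character(1))
  i <- match(as.character(subject_id), ids)
  if (is.na(i)) stop("subject not present in the fitted data: ", subject_id)
  subj <- fit$data[[i]]
  re <- list(a0 = fit$re_mean[i, 1], a1 = fit$re_mean[i, 2])
  dm <- posterior_draws(fit)
  out <- matrix(NA_real_, n_rep, length(subj$times))
  if (n_rep > 0) {
    idx <- rep_len(seq_len(nrow(dm)), n_rep)
    th <- subj$times / fit$spec$time_scale
    for (r in seq_len(n_rep)) {
      p <- dm[idx[r], ]
      mu <- p[["b0"]] + p[["b1"]] * th + re$a0 + re$a1 * th
      out[r, ] <- mu + rnorm(length(mu), 0, sqrt(p[["sigma_e2"]]))
    }
  }
  pm <- posterior_mean_params(fit)
  attr(out, "times") <- subj$times
  attr(out, "mu_hat") <- longitudinal_mean(
    subj$times / fit$spec$time_scale, pm, subj$covariates, re)
  out
}

#' Posterior predictive survival CDF curves
#'
#' For each posterior draw: draws random effects from that draw's
#' covariance, simulates an event time for the given covariate profile,
#' interval-censors it on `schedule` (the artificial screening intervals),
#' and records the draw's population-level Weibull CDF curve.
#'
#' @param fit a fitted joint model.
#' @param covariate_profile named covariate vector (e.g. `c(hla = 4)`).
#' @param n_rep number of replicate draws.
#' @param schedule an [make_schedule()] used to build artificial intervals.
#' @param grid evaluation times in months (default: monthly to the
#'   schedule horizon).
#' @return list with `times`, `curves` (`n_rep` x times matrix of CDF
#'   values) and `intervals` (data frame of censored replicates).
#' @export
ppc_survival <- function(fit, covariate_profile, n_rep = 100,
                         schedule = make_schedule("lighter"),
                         grid = NULL) {
  if (fit$spec$family == "M4") stop("survival predictive checks need a joint-model fit")
  if (is.null(grid)) grid <- seq(0, schedule$horizon, by = 1)
  ts <- fit$spec$time_scale
  dm <- posterior_draws(fit)
  idx <- rep_len(seq_len(nrow(dm)), max(n_rep, 0))
  curves <- matrix(NA_real_, n_rep, length(grid))
  ints <- vector("list", n_rep)
  cn <- grep("^beta2_", colnames(dm), value = TRUE)
  for (r in seq_len(n_rep)) {
    p <- dm[idx[r], ]
    xb <- 0
    if (length(cn))
      xb <- sum(p[cn] * covariate_profile[sub("^beta2_", "", cn)])
    s0 <- sqrt(p[["sigma0_2"]]); s1 <- sqrt(p[["sigma1_2"]])
    z1 <- rnorm(1); z2 <- rnorm(1)
    a0 <- s0 * z1
    a1 <- s1 * (p[["rho"]] * z1 + sqrt(1 - p[["rho"]]^2) * z2)
    lp_re <- p[["beta0"]] + xb + p[["lambda0"]] * a0 + p[["lambda1"]] * a1
    tev <- ts * draw_event_time(lp_re, p[["alpha"]], runif(1))
    cens <- interval_censor(max(tev, 1e-8), schedule)
    ints[[r]] <- data.frame(t_L = cens$t_L, t_R = cens$t_R,
                            right_censored = cens$right_censored)
    curves[r, ] <- weibull_cdf(grid / ts, p[["alpha"]],
                               p[["beta0"]] + xb)
  }
  list(times = grid, curves = curves,
       intervals = if (n_rep > 0) do.call(rbind, ints)
                   else data.frame(t_L = numeric(0), t_R = numeric(0),
                                   right_censored = logical(0)))
}

#' Midpoint estimate of the observed event-time CDF
#'
#' Simple observed-data CDF estimate for overlaying posterior predictive
#' curves: each interval-censored event is imputed at its interval
#' midpoint, right-censored subjects censor at `t_R`.
#'
#' @param data an `icjm_data`.
#' @param grid evaluation times in months.
#' @return data frame with `time` and `cdf`.
#' @export
observed_cdf_midpoint <- function(data, grid = seq(0, 84, by = 1)) {
  mid <- vapply(data, function(s)
    if (s$right_censored) Inf else (s$t_L + s$t_R) / 2, numeric(1))
  cdf <- vapply(grid, function(g) mean(mid <= g), numeric(1))
  data.frame(time = grid, cdf = cdf)
}
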