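# Orchestration of the measurement-error x interval-censoring simulation
# study: replicate fits of the joint (M2) and TVC (M4) models, Monte Carlo
# summaries, power and type-I error, and coverage.

#' Fit both models to one simulated replicate
#'
#' Simulates one dataset from the scenario and fits the shared
#' random-intercept joint model (M2) and/or the TVC model (M4).  A
#' replicate is flagged non-convergent when the Gelman-Rubin statistic of
#' the association parameter (`lambda0`, resp. `eta`) or the Weibull shape
#' exceeds 1.2.
#'
#' @param scn an [scenario()].
#' @param rep_seed integer seed for this replicate (drives the simulation
#'   and both fits).
#' @param config_jm,config_tvc optional [mcmc_config()]s; defaults are the
#'   simulation presets.
#' @param models character subset of `c("jm", "tvc")`.
#' @return list with per-model summary data frames (posterior mean, sd,
#'   CrI), convergence flags and the generating truth.
#' @export
run_replicate <- function(scn, rep_seed, config_jm = NULL,
                          config_tvc = NULL, models = c("jm", "tvc")) {
  models <- match.arg(models, several.ok = TRUE)
  dat <- simulate_dataset(scn, seed = rep_seed)
  out <- list(truth = attr(dat, "truth"), seed = rep_seed)
  key <- function(fam) if (fam == "M4") c("eta", "alpha_tvc")
                       else c("lambda0", "alpha")
  fit_one <- function(spec, config) {
    if (is.null(config)) config <- default_config(spec)
    config$seed <- as.integer((rep_seed + 49999L) %% .Machine$integer.max)
    f <- fit_icjm(dat, spec, config = config)
    sm <- summary(f)
    conv <- if (length(f$chains) >= 2) {
      all(sm$rhat[sm$parameter %in% key(spec$family)] < 1.2, na.rm = TRUE)
    } else TRUE
    list(summary = sm, converged = conv)
  }
  if ("jm" %in% models)
    out$jm <- fit_one(model_spec("M2", time_scale = scn$time_scale),
                      config_jm)
  if ("tvc" %in% models)
    out$tvc <- fit_one(model_spec("M4", time_scale = scn$time_scale),
                       config_tvc)
  out
}

#' Power from a list of credible intervals
#'
#' `1 - (1/M) * sum I(lower < 0 < upper)`: the fraction of intervals that
#' exclude zero.
#'
#' @param cri_list list of length-2 numeric vectors, or a 2-column matrix.
#' @return rejection proportion in `[0, 1]`.
#' @export
cri_power <- function(cri_list) {
  if (is.matrix(cri_list))
    cri_list <- split(cri_list, row(cri_list))
  M <- length(cri_list)
  if (M < 1) stop("need at least one interval")
  contains <- vapply(cri_list, function(ci) ci[1] < 0 && 0 < ci[2],
                     logical(1))
  1 - mean(contains)
}

# truth value of a reported parameter, for coverage bookkeeping
truth_value <- function(truth, parameter) {
  switch(parameter,
    b0 = truth$b0, b1 = truth$b1, sigma_e2 = truth$sigma_e2,
    sigma0_2 = truth$sigma0_2, sigma1_2 = truth$sigma1_2, rho = truth$rho,
    beta0 = truth$beta0, lambda0 = truth$lambda0, lambda1 = truth$lambda1,
    alpha = truth$alpha,
    gamma0 = truth$beta0, eta = truth$lambda0, alpha_tvc = truth$alpha,
    beta2_hla = unname(truth$beta2["hla"]),
    gamma_hla = unname(truth$beta2["hla"]),
    NA_real_)
}

#' Run a full scenario of the simulation study
#'
#' Aggregates [run_replicate()] over `M` seeds: Monte Carlo mean and SD of
#' the posterior means of every parameter of each fitted model, the power
#' of the association parameter (fraction of 95% CrIs excluding zero), and
#' coverage of the generating values.  Non-convergent replicates are
#' excluded and replaced by fresh seeds up to a 10% top-up; a scenario with
#' more than 20% exclusions is marked unreliable.
#'
#' @param scn an [scenario()].
#' @param M number of Monte Carlo replicates.
#' @param base_seed integer; replicate `m` uses seed `base_seed + m`.
#' @param config_jm,config_tvc optional [mcmc_config()]s.
#' @param models character subset of `c("jm", "tvc")`.
#' @return An object of class `icjm_scenario_result`.
#' @export
run_scenario <- function(scn, M = 50, base_seed = 1, config_jm = NULL,
                         config_tvc = NULL, models = c("jm", "tvc")) {
  stopifnot(M >= 1)
  models <- match.arg(models, several.ok = TRUE)
  keep <- list(); used <- 0L; excluded <- 0L
  topup <- ceiling(0.1 * M)
  m <- 0L
  while (length(keep) < M && m < M + topup) {
    m <- m + 1L
    rep <- run_replicate(scn, base_seed + m, config_jm, config_tvc, models)
    ok <- all(vapply(models, function(md) rep[[md]]$converged, logical(1)))
    if (ok) keep[[length(keep) + 1L]] <- rep else excluded <- excluded + 1L
  }
  Mu <- length(keep)
  agg <- function(md) {
    sms <- lapply(keep, function(r) r[[md]]$summary)
    pn <- sms[[1]]$parameter
    means <- sapply(sms, function(s) s$mean)   # params x reps
    rownames(means) <- pn
    cri <- lapply(sms, function(s) cbind(s$lower, s$upper))
    cover <- vapply(seq_along(pn), function(j) {
      tv <- truth_value(scn$truth, pn[j])
      if (is.na(tv)) return(NA_real_)
      mean(vapply(cri, function(ci) ci[j, 1] <= tv && tv <= ci[j, 2],
                  logical(1)))
    }, numeric(1))
    assoc <- if (md == "tvc") "eta" else "lambda0"
    j <- match(assoc, pn)
    pw <- cri_power(lapply(cri, function(ci) ci[j, ]))
    list(mean = rowMeans(means),
         sd = if (Mu > 1) apply(means, 1, sd)
              else stats::setNames(rep(NA_real_, length(pn)), pn),
         coverage = stats::setNames(cover, pn),
         power = pw,
         post_means = means)
  }
  res <- lapply(stats::setNames(models, models), agg)
  structure(list(scenario = scn, M = Mu, excluded = excluded,
                 unreliable = excluded > 0.2 * (Mu + excluded),
                 models = res),
            class = "icjm_scenario_result")
}

#' @export
print.icjm_scenario_result <- function(x, ...) {
  cat(sprintf(
    "<icjm_scenario_result> sigma_e2=%g ic=%s lambda0=%g M=%d%s\n",
    x$scenario$sigma_e2, x$scenario$ic_scheme, x$scenario$lambda0_true,
    x$M, if (x$unreliable) " (UNRELIABLE)" else ""))
  for (md in names(x$models)) {
    cat(sprintf("-- %s (power %.2f):\n", md, x$models[[md]]$power))
    print(round(rbind(mean = x$models[[md]]$mean,
                      sd = x$models[[md]]$sd), 3))
  }
  invisible(x)
}

#' Power curve over a grid of true associations
#'
#' Runs [run_scenario()] at each value of the true association and reports
#' the rejection rate of each model's 95% CrI; the row at 0 is the type-I
#' error.
#'
#' @param scn an [scenario()] (its `lambda0` is overridden by the grid).
#' @param lambda0_grid association values, within `[-0.5, 0]`.
#' @param M replicates per grid point.
#' @param base_seed integer; grid point `g` uses `base_seed + 1000 * g`.
#' @param config_jm,config_tvc optional [mcmc_config()]s.
#' @param models character subset of `c("jm", "tvc")`.
#' @return data frame `(lambda0_true, power_jm, power_tvc)` ordered by
#'   `lambda0_true`.
#' @export
power_curve <- function(scn, lambda0_grid = seq(0, -0.5, by = -0.1),
                        M = 50, base_seed = 1, config_jm = NULL,
                        config_tvc = NULL, models = c("jm", "tvc")) {
  stopifnot(all(lambda0_grid >= -0.5 & lambda0_grid <= 0))
  models <- match.arg(models, several.ok = TRUE)
  grid <- sort(lambda0_grid)
  rows <- lapply(seq_along(grid), function(g) {
    scg <- scenario(me = scn$sigma_e2, ic_scheme = scn$ic_scheme,
                    lambda0 = grid[g], n_subjects = scn$n_subjects,
                    horizon = scn$horizon, miss_prob = scn$miss_prob,
                    time_scale = scn$time_scale)
    res <- run_scenario(scg, M = M,
                        base_seed = (base_seed + 1000L * g) %% .Machine$integer.max,
                        config_jm = config_jm, config_tvc = config_tvc,
                        models = models)
    data.frame(lambda0_true = grid[g],
               power_jm = if ("jm" %in% models) res$models$jm$power
                          else NA_real_,
               power_tvc = if ("tvc" %in% models) res$models$tvc$power
                           else NA_real_)
  })
  do.call(rbind, rows)
}
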