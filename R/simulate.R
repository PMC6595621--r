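# Generative model: shared-random-intercept joint model (M2).  Longitudinal
# times are months; event times are drawn on the hazard scale (years by
# default) and converted to months before interval censoring.

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation scenario
#'
#' One cell of the measurement-error by interval-censoring grid of the
#' simulation study.  Measurement error is `"none"`, `"low"` or `"high"`
#' (residual variance 0, 1 or 8 ng^2/ml^2); interval censoring is
#' `"lighter"` (the transplant-clinic screening schedule), `"random50"`
#' (the lighter schedule with visits missed at random) or `"heavier"`
#' (3-year screening).
#'
#' @param me measurement-error level (`"none"`, `"low"`, `"high"`) or a
#'   nonnegative residual variance.
#' @param ic_scheme screening scheme (see [make_schedule()]).
#' @param lambda0 true association parameter; the study grid spans
#'   `[-0.5, 0]`.
#' @param n_subjects number of subjects per dataset (default 300).
#' @param truth generating `icjm_params` (default [default_truth()]).
#' @param horizon administrative end of follow-up, months.
#' @param miss_prob probability a non-final screen is missed under
#'   `"random50"`.
#' @param time_scale months per hazard time unit (see [model_spec()]).
#' @return An object of class `icjm_scenario`.
#' @export
scenario <- function(me = "low", ic_scheme = "lighter", lambda0 = -0.5,
                     n_subjects = 300, truth = NULL, horizon = 84,
                     miss_prob = 0.5,
                     time_scale = .icjm_default_time_scale) {
  sigma_e2 <- if (is.character(me)) {
    switch(match.arg(me, c("none", "low", "high")),
           none = 0, low = 1, high = 8)
  } else {
    stopifnot(is.numeric(me), me >= 0)
    me
  }
  if (is.null(truth)) truth <- default_truth(sigma_e2 = sigma_e2,
                                             lambda0 = lambda0)
  truth$sigma_e2 <- sigma_e2
  truth$lambda0 <- lambda0
  stopifnot(n_subjects >= 1, horizon > 0,
            ic_scheme %in% c("lighter", "random50", "heavier"))
  structure(list(sigma_e2 = sigma_e2, ic_scheme = ic_scheme,
                 lambda0_true = lambda0, n_subjects = n_subjects,
                 truth = truth, horizon = horizon, miss_prob = miss_prob,
                 time_scale = time_scale),
            class = "icjm_scenario")
}

#' Screening and measurement schedule
#'
#' The `"lighter"` scheme screens for the event at 1, 6, 12 and 24 months
#' and yearly afterwards up to the horizon; `"heavier"` screens every 36
#' months (plus the horizon); `"random50"` starts from the lighter scheme
#' and drops each non-final screen independently with probability
#' `miss_prob` (the final screen is always kept so every subject has a
#' defined censoring time).  Biomarker measurement times follow a monthly
#' grid starting at 0.25 months.
#'
#' @param scheme `"lighter"`, `"random50"` or `"heavier"`.
#' @param horizon months of administrative follow-up.
#' @param seed optional integer; when given, the random50 draw uses a
#'   private RNG stream.  When `NULL`, the current RNG is used.
#' @param miss_prob per-screen missingness probability for `"random50"`.
#' @return A list of class `icjm_schedule` with elements `screen_times`,
#'   `biomarker_times`, `horizon`.
#' @export
make_schedule <- function(scheme = c("lighter", "random50", "heavier"),
                          horizon = 84, seed = NULL, miss_prob = 0.5) {
  scheme <- match.arg(scheme)
  stopifnot(horizon > 0)
  lighter <- c(1, 6, 12, 24, seq(36, horizon, by = 12))
  lighter <- sort(unique(c(lighter[lighter <= horizon], horizon)))
  screens <- switch(scheme,
    lighter = lighter,
    heavier = sort(unique(c(seq(36, horizon, by = 36), horizon))),
    random50 = with_seed(seed, {
      keep <- runif(length(lighter) - 1L) >= miss_prob
      c(lighter[-length(lighter)][keep], horizon)
    }))
  structure(list(screen_times = screens,
                 biomarker_times = c(0.25, seq(1, horizon, by = 1)),
                 horizon = horizon),
            class = "icjm_schedule")
}

#' Inverse-CDF draw of a Weibull event time
#'
#' Inverts `F(t) = 1 - exp(-t^alpha * exp(lp))`: given a uniform draw `u`,
#' returns `T = (-log(1 - u) * exp(-lp))^(1/alpha)`.  The returned time is
#' on the hazard time scale (multiply by the model's `time_scale` to obtain
#' months).
#'
#' @param linear_predictor log proportional-hazard offset.
#' @param alpha Weibull shape, `> 0`.
#' @param u uniform(0,1) draw (strictly inside the interval).
#' @return event time on the hazard scale.
#' @export
draw_event_time <- function(linear_predictor, alpha, u) {
  stopifnot(alpha > 0)
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  (-log1p(-u) * exp(-linear_predictor))^(1 / alpha)
}

#' Interval-censor an event time on a screening schedule
#'
#' The event is detected at the first screen at or after the true event
#' time; the preceding screen (or 0) is the left bound.  An event after the
#' last screen is right-censored at the last screen.
#'
#' @param event_time true event time in months, `> 0`.
#' @param schedule an [make_schedule()] object.
#' @return list with `t_L`, `t_R`, `right_censored`.
#' @export
interval_censor <- function(event_time, schedule) {
  screens <- schedule$screen_times
  if (!length(screens)) stop("empty screening schedule")
  stopifnot(event_time > 0)
  if (event_time > max(screens)) {
    return(list(t_L = NA_real_, t_R = max(screens), right_censored = TRUE))
  }
  t_R <- screens[which(screens >= event_time)[1L]]
  before <- screens[screens < t_R]
  t_L <- if (length(before)) max(before) else 0
  list(t_L = t_L, t_R = t_R, right_censored = FALSE)
}

#' Simulate a dataset from the shared-random-intercept joint model
#'
#' Per subject: an HLA-mismatch count is drawn uniformly from 0..6; random
#' intercept and slope are drawn from their bivariate normal law; the event
#' time follows the Weibull hazard with linear predictor
#' `beta0 + beta2 * hla + lambda0 * a0 + lambda1 * a1`; the event is
#' interval-censored on the subject's screening schedule; and biomarker
#' values `y = b0 + b1 t + a0 + a1 t + e` are generated on the monthly
#' measurement grid truncated at the subject's censoring bound.
#'
#' @param scn an [scenario()] object.
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed.
#' @return An `icjm_data` object with attributes `truth` (the generating
#'   `icjm_params`) and `scenario`.
#' @export
simulate_dataset <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "icjm_scenario"))
  tr <- scn$truth
  with_seed(seed, {
    n <- scn$n_subjects
    hla <- sample(0:6, n, replace = TRUE)
    # bivariate normal random effects
    s0 <- sqrt(tr$sigma0_2); s1 <- sqrt(tr$sigma1_2)
    z1 <- rnorm(n); z2 <- rnorm(n)
    a0 <- s0 * z1
    a1 <- s1 * (tr$rho * z1 + sqrt(1 - tr$rho^2) * z2)
    lp <- tr$beta0 + tr$beta2[["hla"]] * hla +
      tr$lambda0 * a0 + tr$lambda1 * a1
    u <- runif(n)
    t_event <- scn$time_scale * draw_event_time(lp, tr$alpha, u)
    fixed_sched <- if (scn$ic_scheme == "random50") NULL
                   else make_schedule(scn$ic_scheme, scn$horizon)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      sched <- if (is.null(fixed_sched))
        make_schedule("random50", scn$horizon, miss_prob = scn$miss_prob)
      else fixed_sched
      cens <- interval_censor(t_event[i], sched)
      bt <- sched$biomarker_times
      bt <- bt[bt <= cens$t_R]
      if (!length(bt)) bt <- sched$biomarker_times[1L]
      th <- bt / scn$time_scale   # model time unit (years by default)
      mu <- tr$b0 + tr$b1 * th + a0[i] + a1[i] * th
      y <- mu + if (tr$sigma_e2 > 0) rnorm(length(bt), 0, sqrt(tr$sigma_e2))
                else 0
      subjects[[i]] <- subject_data(
        id = sprintf("S%04d", i), times = bt, values = y,
        t_L = cens$t_L, t_R = cens$t_R,
        right_censored = cens$right_censored,
        covariates = c(hla = hla[i]))
    }
    out <- icjm_data(subjects)
    attr(out, "truth") <- tr
    attr(out, "scenario") <- scn
    attr(out, "random_effects") <- cbind(a0 = a0, a1 = a1)
    out
  })
}
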