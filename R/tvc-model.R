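# Interval-censored Weibull survival model with a piecewise-constant
# (last-observation-carried-forward) time-varying covariate.

#' Piecewise-constant covariate path
#'
#' @param update_times strictly increasing update times in months.
#' @param values covariate value at each update (carried forward until the
#'   next update).
#' @return An object of class `icjm_path`.
#' @export
covariate_path <- function(update_times, values) {
  stopifnot(length(update_times) == length(values),
            length(update_times) >= 1,
            all(is.finite(update_times)), all(is.finite(values)))
  if (any(diff(update_times) <= 0))
    stop("update times must be strictly increasing")
  structure(list(update_times = as.numeric(update_times),
                 values = as.numeric(values)),
            class = "icjm_path")
}

#' Last observation carried forward
#'
#' Value of the step function at time `t`: the value at the latest update
#' time at or before `t`.
#'
#' @param path an [covariate_path()] object.
#' @param t times in months (vectorized); each must be at or after the
#'   first update.
#' @return covariate values at `t`.
#' @export
locf <- function(path, t) {
  idx <- findInterval(t, path$update_times)
  if (any(idx == 0L))
    stop("time precedes the first covariate update")
  path$values[idx]
}

# Segment decomposition of the LOCF path on [first update, t):
# returns start, end (hazard scale) and covariate value per segment.
path_segments <- function(path, t, time_scale = 1) {
  u <- path$update_times
  keep <- u < t
  if (!any(keep)) {
    return(list(start = numeric(0), end = numeric(0), w = numeric(0)))
  }
  s <- u[keep]
  e <- c(s[-1], t)
  list(start = pmax(s, 0) / time_scale, end = e / time_scale,
       w = path$values[keep])
}

#' Cumulative hazard under a piecewise-constant covariate
#'
#' `H(t)` integrates the Weibull hazard
#' `alpha_tvc t^(alpha_tvc - 1) exp(gamma0 + gamma' z + eta w(t))` across the
#' step segments of the LOCF covariate path:
#' `H(t) = sum_j exp(gamma0 + gamma' z + eta w_j) (s_{j+1}^a - s_j^a)` with
#' segment boundaries clipped at `t`.  The implied CDF is
#' `F(t) = 1 - exp(-H(t))`.
#'
#' @param t evaluation times in months (vectorized, `>= 0`).
#' @param path an [covariate_path()].
#' @param z named numeric vector of baseline covariates (those named in
#'   `params$gamma`).
#' @param params an `icjm_params` with `gamma0`, `gamma`, `eta`,
#'   `alpha_tvc` set.
#' @param time_scale months per hazard time unit (1 leaves `t` unscaled).
#' @return cumulative hazards at `t`.
#' @export
cumulative_hazard <- function(t, path, z = numeric(0), params,
                              time_scale = 1) {
  stopifnot(params$alpha_tvc > 0, all(t >= 0))
  zb <- 0
  if (length(params$gamma)) {
    nm <- names(params$gamma)
    zb <- sum(params$gamma * z[nm])
  }
  a <- params$alpha_tvc
  vapply(t, function(ti) {
    if (ti <= min(path$update_times) && ti <= 0) return(0)
    if (ti > 0 && ti < min(path$update_times))
      stop("time precedes the first covariate update")
    seg <- path_segments(path, ti, time_scale)
    if (!length(seg$w)) return(0)
    sum(exp(params$gamma0 + zb + params$eta * seg$w) *
          (seg$end^a - seg$start^a))
  }, numeric(1))
}

#' Interval-censored log-likelihood of one subject under the TVC model
#'
#' `I_R log[1 - F(t_R)] + (1 - I_R) log[F(t_R) - F(t_L)]` with `F` computed
#' from [cumulative_hazard()]; both CDF values use the same LOCF path
#' truncated at their respective time arguments.
#'
#' @param subject an [subject_data()] object.
#' @param path the subject's [covariate_path()]; must cover `[0, t_R]`.
#' @param params an `icjm_params` with the TVC block set.
#' @param time_scale months per hazard time unit (default: the package's
#'   yearly hazard scale).
#' @return scalar log-likelihood.
#' @export
subject_loglik_tvc <- function(subject, path, params,
                               time_scale = .icjm_default_time_scale) {
  H_R <- cumulative_hazard(subject$t_R, path, subject$covariates, params,
                           time_scale)
  if (subject$right_censored) return(-H_R)
  H_L <- cumulative_hazard(subject$t_L, path, subject$covariates, params,
                           time_scale)
  log_interval_prob(H_L, H_R)
}

#' Build LOCF covariate paths from observed longitudinal records
#'
#' Update times are the measurement times and values are the observed
#' biomarker values; a time-0 anchor duplicating the first observed value is
#' prepended so the hazard is defined from baseline.
#'
#' @param data an `icjm_data` object.
#' @return list of [covariate_path()] objects, one per subject.
#' @export
build_paths <- function(data) {
  lapply(data, function(s) {
    tt <- s$times; vv <- s$values
    if (tt[1] > 0) {
      tt <- c(0, tt)
      vv <- c(vv[1], vv)
    }
    covariate_path(tt, vv)
  })
}

# dataset-level TVC log-likelihood (used by DIC at the posterior mean)
dataset_loglik_tvc <- function(data, paths, params,
                               time_scale = .icjm_default_time_scale) {
  per <- vapply(seq_along(data), function(i)
    subject_loglik_tvc(data[[i]], paths[[i]], params, time_scale),
    numeric(1))
  out <- sum(per)
  attr(out, "per_subject") <- per
  out
}
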