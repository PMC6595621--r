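#' Parameter set for the joint and time-varying-covariate models
#'
#' Bundles every fixed-effect, variance, association and hazard parameter at
#' one point of the parameter space.  The joint-model (JM) side consists of
#' the longitudinal fixed effects (`b0`, `b1`, optional covariate
#' coefficients `beta1`), the residual variance `sigma_e2`, the
#' random-effects variance components (`sigma0_2`, `sigma1_2`, `rho`), the
#' survival intercept `beta0`, survival covariate coefficients `beta2`, the
#' association parameters (`lambda0` for the shared random intercept,
#' `lambda1` for the shared random slope) and the Weibull shape `alpha`.
#' The time-varying-covariate (TVC) model side has analogues `gamma0`,
#' `gamma`, `eta` and `alpha_tvc`.
#'
#' @param b0 fixed longitudinal intercept (ng/ml).
#' @param b1 fixed longitudinal slope, ng/ml per model time unit (the
#'   model's `time_scale` converts stored months to this unit; years by
#'   default).
#' @param beta1 named numeric vector of longitudinal covariate coefficients
#'   (empty by default; baseline covariates usually enter the survival
#'   sub-model only).
#' @param sigma_e2 residual (measurement-error) variance, `>= 0`.
#' @param sigma0_2,sigma1_2 variances of the random intercept and slope,
#'   both `> 0`.
#' @param rho correlation of the random intercept and slope, in `(-1, 1)`.
#' @param beta0 survival-model intercept / log-scale offset.
#' @param beta2 named numeric vector of survival covariate coefficients.
#' @param lambda0,lambda1 association parameters tying the shared random
#'   intercept / slope to the log hazard.
#' @param alpha Weibull shape of the joint model's baseline hazard, `> 0`.
#' @param gamma0,gamma,eta,alpha_tvc TVC-model analogues of
#'   (`beta0`, `beta2`, association, shape); `NA` when not in use.
#' @return An object of class `icjm_params` (a named list).
#' @seealso [default_truth()] for the generative values used by the
#'   simulator.
#' @export
param_set <- function(b0 = 0, b1 = 0, beta1 = numeric(0),
                      sigma_e2 = 1, sigma0_2 = 1, sigma1_2 = 1, rho = 0,
                      beta0 = 0, beta2 = numeric(0),
                      lambda0 = 0, lambda1 = 0, alpha = 1,
                      gamma0 = NA_real_, gamma = numeric(0),
                      eta = NA_real_, alpha_tvc = NA_real_) {
  p <- list(b0 = b0, b1 = b1, beta1 = beta1,
            sigma_e2 = sigma_e2, sigma0_2 = sigma0_2, sigma1_2 = sigma1_2,
            rho = rho, beta0 = beta0, beta2 = beta2,
            lambda0 = lambda0, lambda1 = lambda1, alpha = alpha,
            gamma0 = gamma0, gamma = gamma, eta = eta, alpha_tvc = alpha_tvc)
  validate_param_set(p)
  structure(p, class = "icjm_params")
}

validate_param_set <- function(p) {
  stopifnot(is.numeric(p$sigma_e2), p$sigma_e2 >= 0,
            p$sigma0_2 > 0, p$sigma1_2 > 0,
            p$rho > -1, p$rho < 1,
            p$alpha > 0,
            is.na(p$alpha_tvc) || p$alpha_tvc > 0)
  invisible(p)
}

#' Generative truth of the simulation study
#'
#' Default parameter values used by [simulate_dataset()]: the data-generating
#' model is the shared-random-intercept joint model (M2, `lambda1 = 0`) with
#' a linear biomarker trajectory starting at 7 ng/ml and declining by 0.03
#' ng/ml per model time unit (years by default), random-effect variances
#' 1.75 (intercept) and 0.004 (slope per time unit) with correlation
#' -0.005, Weibull shape 0.5, survival intercept -2 on the same time scale,
#' an HLA-mismatch coefficient of 0.25 in the survival sub-model and
#' association `lambda0 = -0.5`.  Under this truth about half of the
#' subjects experience the event within the 84-month follow-up.
#'
#' @param sigma_e2 measurement-error variance (0, 1 and 8 are the "none",
#'   "low" and "high" study conditions).
#' @param lambda0 association between the shared random intercept and the
#'   log hazard.
#' @return An `icjm_params` object.
#' @export
default_truth <- function(sigma_e2 = 1, lambda0 = -0.5) {
  param_set(b0 = 7, b1 = -0.03,
            sigma_e2 = sigma_e2, sigma0_2 = 1.75, sigma1_2 = 0.004,
            rho = -0.005,
            beta0 = -2, beta2 = c(hla = 0.25),
            lambda0 = lambda0, lambda1 = 0, alpha = 0.5)
}

#' Model specification
#'
#' Chooses between the joint-model variants and the time-varying-covariate
#' survival model, the trajectory form and the baseline hazard.  `M1` shares
#' both the random intercept and slope with the hazard, `M2` only the
#' intercept (`lambda1` fixed at 0), `M3` only the slope (`lambda0` fixed at
#' 0), and `M4` is the interval-censored Weibull model with the observed
#' biomarker carried forward as a piecewise-constant covariate.
#'
#' @param family one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param trajectory `"linear"` or `"bspline"` (see [trajectory_basis()]).
#' @param hazard baseline hazard family; `"weibull"` (shape estimated) or
#'   `"exponential"` (shape fixed at 1).  Other families are not provided.
#' @param time_scale months per hazard time unit.  The default 12 evaluates
#'   the Weibull hazard on time in years while all stored times remain in
#'   months.
#' @param long_covariates character vector naming baseline covariates to
#'   include in the longitudinal mean (default: none).
#' @param basis optional [trajectory_basis()] object for `"bspline"`.
#' @return An object of class `icjm_spec`.
#' @export
model_spec <- function(family = c("M2", "M1", "M3", "M4"),
                       trajectory = c("linear", "bspline"),
                       hazard = c("weibull", "exponential"),
                       time_scale = .icjm_default_time_scale,
                       long_covariates = character(0),
                       basis = NULL) {
  family <- match.arg(family)
  trajectory <- match.arg(trajectory)
  hazard <- match.arg(hazard)
  stopifnot(is.numeric(time_scale), time_scale > 0)
  structure(list(family = family, trajectory = trajectory, hazard = hazard,
                 time_scale = time_scale, long_covariates = long_covariates,
                 basis = basis),
            class = "icjm_spec")
}

# Apply the sharing constraints of the model family to a parameter set.
constrain_params <- function(params, spec) {
  if (spec$family == "M2") params$lambda1 <- 0
  if (spec$family == "M3") params$lambda0 <- 0
  if (spec$hazard == "exponential") params$alpha <- 1
  params
}

#' @export
print.icjm_params <- function(x, ...) {
  cat("<icjm_params>\n")
  flat <- unlist(x)
  print(round(flat[is.finite(flat)], 5))
  invisible(x)
}

#' @export
print.icjm_spec <- function(x, ...) {
  cat(sprintf("<icjm_spec> family=%s trajectory=%s hazard=%s time_scale=%g\n",
              x$family, x$trajectory, x$hazard, x$time_scale))
  invisible(x)
}
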