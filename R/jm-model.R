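# Conditional likelihood of the shared random-effects joint model:
# Gaussian longitudinal terms plus the interval-censored Weibull survival
# contribution, conditional on the subject's random intercept and slope.

#' Trajectory basis for the longitudinal mean
#'
#' Either a linear trend `f(t) = b0 + b1 t` (coefficients live in the
#' parameter set) or a cubic B-spline with inner knots at time quantiles
#' (`K = degree + n_knots + 1` basis functions, evaluated with an intercept
#' so the basis sums to one).
#'
#' @param kind `"linear"` or `"bspline"`.
#' @param degree spline degree (default 3).
#' @param knots inner knot locations in months; for `"bspline"` either given
#'   directly or computed as quantiles of `times`.
#' @param n_knots number of inner knots when computed from `times`.
#' @param times optional measurement times used to place knots/boundaries.
#' @param coefficients spline coefficients (length `K`).
#' @return An object of class `icjm_basis`.
#' @export
trajectory_basis <- function(kind = c("linear", "bspline"), degree = 3,
                             knots = NULL, n_knots = 3, times = NULL,
                             coefficients = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear")
    return(structure(list(kind = "linear"), class = "icjm_basis"))
  if (is.null(knots)) {
    if (is.null(times)) stop("bspline basis needs knots or times")
    knots <- unname(quantile(times, probs = seq_len(n_knots) / (n_knots + 1)))
  }
  boundary <- if (is.null(times)) range(knots) + c(-1, 1) * max(1, diff(range(knots)))
              else range(times)
  K <- as.integer(degree + length(knots) + 1L)
  if (!is.null(coefficients) && length(coefficients) != K)
    stop("expected ", K, " spline coefficients")
  structure(list(kind = "bspline", degree = degree, knots = knots,
                 boundary = boundary, K = K, coefficients = coefficients),
            class = "icjm_basis")
}

# Evaluate the basis matrix at times t (bspline only).
basis_matrix <- function(basis, t) {
  splines::bs(pmin(pmax(t, basis$boundary[1]), basis$boundary[2]),
              degree = basis$degree, knots = basis$knots,
              Boundary.knots = basis$boundary, intercept = TRUE)
}

#' Population mean of the biomarker trajectory
#'
#' Returns `f(t) + beta1' x + a0 + a1 t`, with `f` linear
#' (`b0 + b1 t`) or a B-spline with coefficients stored in `basis`.
#'
#' @param t times in months (vectorized).
#' @param params an `icjm_params` object.
#' @param covariates named numeric vector of baseline covariates (only those
#'   named in `params$beta1` contribute).
#' @param re list with random effects `a0`, `a1`.
#' @param basis a [trajectory_basis()]; default linear.
#' @return numeric vector of means (ng/ml).
#' @export
longitudinal_mean <- function(t, params, covariates = numeric(0),
                              re = list(a0 = 0, a1 = 0), basis = NULL) {
  stopifnot(all(t >= 0))
  if (is.null(basis)) basis <- trajectory_basis("linear")
  xb <- 0
  if (length(params$beta1)) {
    nm <- names(params$beta1)
    xb <- sum(params$beta1 * covariates[nm])
  }
  f <- if (basis$kind == "linear") params$b0 + params$b1 * t
       else as.vector(basis_matrix(basis, t) %*% basis$coefficients)
  f + xb + re$a0 + re$a1 * t
}

#' Weibull cumulative distribution under a proportional-hazard offset
#'
#' `F(t) = 1 - exp(-t^alpha * exp(lp))`, the CDF implied by the baseline
#' hazard `h0(t) = alpha t^(alpha-1)` scaled by `exp(lp)`.  `t` is on the
#' hazard time scale.
#'
#' @param t nonnegative times (vectorized).
#' @param alpha Weibull shape, `> 0`.
#' @param lp log proportional-hazard offset.
#' @return probabilities in `[0, 1)`.
#' @export
weibull_cdf <- function(t, alpha, lp) {
  stopifnot(alpha > 0, all(t >= 0))
  -expm1(-t^alpha * exp(lp))
}

# log survival: -H(t)
weibull_log_surv <- function(t, alpha, lp) -(t^alpha * exp(lp))

#' Log-density of the random effects
#'
#' Bivariate normal density of `(a0, a1)` with zero mean, variances
#' `sigma0_2`, `sigma1_2` and correlation `rho`.
#'
#' @param re list with `a0`, `a1` (vectorized).
#' @param params an `icjm_params` object.
#' @return log-density (vectorized over the random effects).
#' @export
random_effects_logdensity <- function(re, params) {
  s02 <- params$sigma0_2; s12 <- params$sigma1_2; rho <- params$rho
  if (!(s02 > 0 && s12 > 0 && abs(rho) < 1))
    stop("random-effects covariance is not positive definite")
  det <- s02 * s12 * (1 - rho^2)
  q <- (re$a0^2 / s02 - 2 * rho * re$a0 * re$a1 / sqrt(s02 * s12) +
          re$a1^2 / s12) / (1 - rho^2)
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# survival linear predictor of the joint model for one subject
jm_linear_predictor <- function(params, covariates, re) {
  xb <- 0
  if (length(params$beta2)) {
    nm <- names(params$beta2)
    xb <- sum(params$beta2 * covariates[nm])
  }
  params$beta0 + xb + params$lambda0 * re$a0 + params$lambda1 * re$a1
}

# guarded log of F(t_R) - F(t_L) = exp(-H_L) - exp(-H_R)
log_interval_prob <- function(H_L, H_R) {
  d <- H_R - H_L
  if (d <= 0) return(log(.icjm_log_floor))
  -H_L + log(max(-expm1(-d), .icjm_log_floor))
}

#' Conditional log-likelihood of one subject under the joint model
#'
#' Sum of the Gaussian longitudinal terms and the interval-censored
#' survival contribution `I_R log S(t_R) + (1 - I_R) log[F(t_R) - F(t_L)]`,
#' conditional on the subject's random effects.  Family constraints are
#' enforced (`M2`: `lambda1 = 0`; `M3`: `lambda0 = 0`).
#'
#' @param subject an [subject_data()] object.
#' @param params an `icjm_params` object.
#' @param re list with random effects `a0`, `a1`.
#' @param spec an [model_spec()] with family `M1`, `M2` or `M3`.
#' @return scalar log-likelihood with attribute `parts` (named components
#'   `long` and `surv`).  A zero residual variance with any observed value
#'   away from its mean yields `-Inf` with attribute `degenerate = TRUE`.
#' @export
subject_loglik <- function(subject, params, re, spec = model_spec("M2")) {
  if (!spec$family %in% c("M1", "M2", "M3"))
    stop("subject_loglik applies to joint-model families M1-M3")
  params <- constrain_params(params, spec)
  covs <- if (length(spec$long_covariates)) subject$covariates else numeric(0)
  pl <- params
  if (!length(spec$long_covariates)) pl$beta1 <- numeric(0)
  # both sub-models share one model time unit (months / time_scale)
  mu <- longitudinal_mean(subject$times / spec$time_scale, pl,
                          subject$covariates, re, spec$basis)
  if (params$sigma_e2 == 0) {
    degenerate <- any(subject$values != mu)
    ll_long <- if (degenerate) -Inf else Inf
    out <- ll_long
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ll_long <- sum(dnorm(subject$values, mu, sqrt(params$sigma_e2), log = TRUE))
  lp <- jm_linear_predictor(params, subject$covariates, re)
  ts <- spec$time_scale
  H_R <- (subject$t_R / ts)^params$alpha * exp(lp)
  ll_surv <- if (subject$right_censored) {
    -H_R
  } else {
    H_L <- (subject$t_L / ts)^params$alpha * exp(lp)
    log_interval_prob(H_L, H_R)
  }
  out <- ll_long + ll_surv
  attr(out, "parts") <- c(long = ll_long, surv = ll_surv)
  out
}

#' Conditional log-likelihood of a dataset under the joint model
#'
#' Sum of [subject_loglik()] over subjects, one set of random effects per
#' subject.
#'
#' @param data an `icjm_data` object.
#' @param params an `icjm_params` object.
#' @param re_all list of per-subject random-effect lists, or a two-column
#'   matrix `(a0, a1)` with one row per subject.
#' @param spec an [model_spec()].
#' @return scalar log-likelihood with attributes `per_subject` (vector) and
#'   `parts` (`long`/`surv` sums).
#' @export
dataset_loglik <- function(data, params, re_all, spec = model_spec("M2")) {
  if (is.matrix(re_all))
    re_all <- lapply(seq_len(nrow(re_all)),
                     function(i) list(a0 = re_all[i, 1], a1 = re_all[i, 2]))
  if (length(re_all) != length(data))
    stop("need one random-effects pair per subject")
  if (!length(data)) {
    out <- 0
    attr(out, "per_subject") <- numeric(0)
    attr(out, "parts") <- c(long = 0, surv = 0)
    return(out)
  }
  per <- numeric(length(data))
  parts <- c(long = 0, surv = 0)
  for (i in seq_along(data)) {
    li <- subject_loglik(data[[i]], params, re_all[[i]], spec)
    per[i] <- as.numeric(li)
    p <- attr(li, "parts")
    if (!is.null(p)) parts <- parts + p
  }
  out <- sum(per)
  attr(out, "per_subject") <- per
  attr(out, "parts") <- parts
  out
}
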