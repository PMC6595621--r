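# Convergence diagnostics: Gelman-Rubin potential scale reduction across
# chains and the Geweke equality-of-means test within a chain.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio
#' `sqrt(((n-1)/n W + B/n) / W)` for two or more chains of equal length.
#' Chains that are numerically constant return 1.
#'
#' @param chains list of numeric vectors (one per chain).
#' @return scalar R-hat.
#' @export
gelman_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  if (!is.finite(W) || W < .Machine$double.eps * max(abs(means), 1))
    return(1)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# spectral density of x at frequency zero, via an AR fit (used by the
# Geweke statistic to account for autocorrelation)
spectrum0 <- function(x) {
  x <- as.numeric(x)
  v <- var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- try(ar(x, aic = TRUE,
                order.max = min(30, floor(length(x) / 5))), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (fit$order == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke equality-of-means z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by spectral-density variance estimates.
#'
#' @param x numeric chain.
#' @param frac1 leading window fraction (default 0.1).
#' @param frac2 trailing window fraction (default 0.5).
#' @return z-score; `|z| > 2` indicates a drifting chain.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  stopifnot(n >= 20, frac1 + frac2 <= 1)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  se2 <- spectrum0(x1) / length(x1) + spectrum0(x2) / length(x2)
  if (se2 == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(se2)
}

#' Convergence report for a fit
#'
#' Per-parameter Gelman-Rubin statistic (across chains) and the largest
#' absolute Geweke z-score over chains, with pass/fail flags.
#'
#' @param fit an `icjm_fit`.
#' @param rhat_threshold pass when R-hat is below this (default 1.1).
#' @param z_threshold pass when `|z|` is below this (default 2).
#' @param frac1,frac2 Geweke window fractions.
#' @return data frame with one row per parameter.
#' @export
mcmc_diagnostics <- function(fit, rhat_threshold = 1.1, z_threshold = 2,
                             frac1 = 0.1, frac2 = 0.5) {
  pn <- fit$param_names
  multi <- length(fit$chains) >= 2
  if (!multi)
    warning("single chain: Gelman-Rubin statistic omitted")
  rhat <- vapply(pn, function(p) {
    if (!multi) return(NA_real_)
    gelman_rhat(lapply(fit$chains, function(m) m[, p]))
  }, numeric(1))
  gz <- vapply(pn, function(p) {
    zs <- vapply(fit$chains, function(m) {
      if (var(m[, p]) == 0) 0 else geweke_z(m[, p], frac1, frac2)
    }, numeric(1))
    zs[which.max(abs(zs))]
  }, numeric(1))
  data.frame(parameter = pn, rhat = rhat, geweke_z = gz,
             rhat_pass = is.na(rhat) | rhat < rhat_threshold,
             geweke_pass = abs(gz) < z_threshold,
             row.names = NULL)
}
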