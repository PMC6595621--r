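# icjm

Bayesian joint modelling of a noisy longitudinal biomarker and an
interval-censored time-to-event outcome, with the classical
time-varying-covariate (TVC) survival model as the comparator.

## The problem

After kidney transplantation, tacrolimus (TAC) trough levels are monitored
frequently, and patients are screened periodically for de novo
donor-specific antibodies (dnDSA).  Estimating how TAC exposure relates to
dnDSA formation is complicated by two facts: trough levels measure the
underlying exposure with substantial error, and dnDSA onset is
interval-censored — known only to lie between the last negative and first
positive screen.  Plugging the observed biomarker into a survival model as
a time-varying covariate attenuates the association toward zero; a shared
random-effects joint model propagates the measurement-error and censoring
uncertainty instead.

This package is for biostatisticians who want to fit either model to data
of this shape, or to study — by simulation — how measurement error and
screening-interval width bias the association estimate, its power, and its
type-I error.

## Models

Longitudinal sub-model (`ng/ml`, times in months, model time unit years):

    y_ij | a_i ~ N(b0 + b1 t_ij + a0i + a1i t_ij, sigma_e^2),
    (a0i, a1i)' ~ N2(0, [sigma0^2, rho s0 s1; rho s0 s1, sigma1^2])

Weibull survival sub-model with interval censoring:

    h_i(t) = alpha t^(alpha-1) exp(beta0 + beta2' x_i
                                   + lambda0 a0i + lambda1 a1i)

Families: **M1** shares intercept and slope, **M2** intercept only
(`lambda1 = 0`), **M3** slope only (`lambda0 = 0`), and **M4** is the
interval-censored Weibull model with the observed biomarker carried
forward as a piecewise-constant covariate (coefficient `eta`).  Estimation
is MCMC (adaptive Metropolis-within-Gibbs in C++) under weakly
informative priors; model comparison uses DIC and WAIC on the conditional
likelihood; posterior predictive checks cover both sub-models.  A
generative simulator reproduces the measurement-error (residual variance
0, 1, 8) by interval-censoring (lighter / random-missed / 3-yearly
screens) study grid.

## Worked example

```r
library(icjm)

scn <- scenario(me = "low", ic_scheme = "lighter")   # sigma_e^2 = 1
d   <- simulate_dataset(scn, seed = 7)
d
#> <icjm_data> 300 subjects, 171 events, 15386 measurements

jm  <- fit_icjm(d, model_spec("M2"))   # joint model, ~1.5 s
tvc <- fit_icjm(d, model_spec("M4"))   # TVC model,  ~3 s

summary(jm)[c(1, 2, 9, 11), ]
#>    parameter   mean    sd  lower  upper  rhat
#> 1         b0  6.995 0.073  6.854  7.144 1.000
#> 2         b1 -0.032 0.007 -0.045 -0.018 1.001
#> 9    lambda0 -0.481 0.068 -0.613 -0.355 1.000
#> 11     alpha  0.583 0.035  0.515  0.652 1.000

summary(tvc)
#>   parameter   mean    sd  lower  upper  rhat
#> 1    gamma0  0.877 0.394  0.099  1.626 1.023
#> 2 gamma_hla  0.223 0.040  0.148  0.300 1.069
#> 3       eta -0.418 0.060 -0.524 -0.304 1.000
#> 4 alpha_tvc  0.572 0.035  0.507  0.646 1.002
```

The data were generated with a true association of `lambda0 = -0.5`
between the subject-level biomarker intercept and the log hazard.  The
joint model recovers it (`-0.48`, 95% CrI `-0.61` to `-0.36`); the TVC
coefficient `eta` is attenuated toward zero (`-0.42`) because the observed
covariate carries measurement noise and within-subject drift — the
headline phenomenon the simulation study quantifies.  Attenuation worsens
sharply with more measurement error (`me = "high"`) and wider screening
intervals (`ic_scheme = "heavier"`), where the TVC model also produces
spurious detections when the true association is zero.

Convergence diagnostics and model comparison:

```r
mcmc_diagnostics(jm)              # per-parameter R-hat and Geweke z
compare_models(jm = jm, tvc = tvc)  # DIC / WAIC with sub-model parts
```

The full study grid is driven by `run_scenario()` and `power_curve()`;
a command-line front-end lives in `inst/scripts/icjm.R`
(`simulate` / `fit` / `simstudy` subcommands).

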