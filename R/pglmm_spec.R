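## Model specification objects for the PGLMM engine: MCMC settings, priors,
## and the model spec tying response, family, fixed-effect set and random
## terms together.

#' MCMC settings
#'
#' `iterations` counts post-burn-in iterations; `thin` must divide it, so
#' the chain retains `iterations / thin` samples. The reference analysis
#' profile (`mcmc_settings(profile = "reference")`) runs 500,000 iterations
#' after burn-in sampling every 5,000 (100 retained samples); the default
#' desk profile (20,000 / 20, 1,000 retained) is sized for routine use and
#' testing. Burn-in defaults to 10\% of the post-burn-in iterations.
#'
#' @param iterations post-burn-in iterations.
#' @param thin thinning interval; must divide `iterations`.
#' @param burnin burn-in iterations (adaptation of Metropolis step sizes
#'   happens only here).
#' @param seed integer RNG seed.
#' @param profile `"desk"` or `"reference"`; sets the three counts above.
#' @return a list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = NULL, thin = NULL, burnin = NULL,
                          seed = 1L, profile = c("desk", "reference")) {
  profile <- match.arg(profile)
  def <- switch(profile,
                desk = list(iterations = 20000L, thin = 20L),
                reference = list(iterations = 500000L, thin = 5000L))
  iterations <- as.integer(if (is.null(iterations)) def$iterations else iterations)
  thin <- as.integer(if (is.null(thin)) def$thin else thin)
  burnin <- as.integer(if (is.null(burnin)) ceiling(iterations / 10) else burnin)
  if (iterations < 1L || thin < 1L || burnin < 0L)
    stop("invalid MCMC settings")
  if (iterations %% thin != 0L)
    stop("thin (", thin, ") must divide iterations (", iterations, ")")
  structure(list(iterations = iterations, thin = thin, burnin = burnin,
                 seed = as.integer(seed), profile = profile),
            class = "mcmc_settings")
}

#' Priors for the PGLMM engine
#'
#' Fixed effects get independent zero-mean normal priors with a large
#' variance (1e10 by default: effectively flat). The residual variance gets
#' an inverse-gamma prior parameterised as (V, nu), i.e. shape `nu/2` and
#' rate `nu*V/2`; the default (V = 1, nu = 0.002) is only weakly
#' informative. Random-effect variances use parameter expansion: the
#' effect vector is the product of a working vector (inverse-gamma base
#' variance, `px_V`, `px_nu`) and a scalar expansion factor with a normal
#' prior of variance `px_alpha_var`. With `px_V = 1`, `px_nu = 1`,
#' `px_alpha_var = 25` the implied prior on each random-effect standard
#' deviation is approximately a half-Cauchy with scale 5 - flat over the
#' whole plausible range of probit-liability and log-rate scales ("roughly
#' uniform standard deviations") while not favouring the degenerate
#' large-variance regime that binary responses with cluster-level random
#' effects are prone to.
#'
#' @param beta_var fixed-effect prior variance.
#' @param resid_V,resid_nu residual inverse-gamma parameters.
#' @param px_V,px_nu,px_alpha_var parameter-expansion settings.
#' @param fix_resid logical; fix the residual variance at 1 instead of
#'   estimating it. For the probit family the location scale is only
#'   identified relative to the residual standard deviation, so fixing it
#'   pins the scale; estimating it (the default) mirrors specifying an
#'   inverse-gamma residual prior in the probit model and leaves p_x and
#'   h^2 unaffected because both are scale-free.
#' @return a list of class `pglmm_priors`.
#' @export
pglmm_priors <- function(beta_var = 1e10, resid_V = 1, resid_nu = 0.002,
                         px_V = 1, px_nu = 1, px_alpha_var = 25,
                         fix_resid = FALSE) {
  structure(list(beta_var = beta_var, resid_V = resid_V, resid_nu = resid_nu,
                 px_V = px_V, px_nu = px_nu, px_alpha_var = px_alpha_var,
                 fix_resid = isTRUE(fix_resid)),
            class = "pglmm_priors")
}

#' Model specification
#'
#' @param response `"versatility"` or `"use:<use_id>"`.
#' @param family `"zt_poisson"`, `"probit"` or `"gaussian"`.
#' @param fixed `"qualities"` (all 22 ordinal quality scores as numeric
#'   covariates) or `"intensity_complexity"`; the days-since-collection
#'   covariate (mean-centred) is always appended.
#' @param priors a [pglmm_priors()].
#' @param mcmc an [mcmc_settings()].
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(response, family = c("zt_poisson", "probit", "gaussian"),
                       fixed = c("qualities", "intensity_complexity"),
                       priors = pglmm_priors(), mcmc = mcmc_settings()) {
  family <- match.arg(family)
  fixed <- match.arg(fixed)
  if (!(identical(response, "versatility") || grepl("^use:", response)))
    stop("response must be \"versatility\" or \"use:<use_id>\"")
  structure(list(response = response, family = family, fixed = fixed,
                 priors = priors, mcmc = mcmc),
            class = "model_spec")
}
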