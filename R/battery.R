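## Orchestration of the full model battery: 2 zero-truncated Poisson
## versatility models (22 qualities; intensity + complexity) and, per
## therapeutic use, 2 probit models (same two fixed-effect sets) - 94
## models for 46 uses. Per-model seeds derive deterministically from one
## master seed so any subset reruns identically.

derive_seed <- function(master, index) {
  as.integer((as.double(master) + 7919 * index) %% 2147483629)
}

fit_one <- function(dataset, A, response, family, fixed, mcmc, priors,
                    versatility = NULL) {
  spec <- model_spec(response, family = family, fixed = fixed,
                     priors = priors, mcmc = mcmc)
  design <- build_design(dataset$trials, dataset$drugs, dataset$uses, A,
                         spec, versatility = versatility)
  summarize_chain(sample_posterior(design, spec))
}

#' Fit the two therapeutic-versatility models
#'
#' Versatility (the number of broader categories of use a drug is
#' recommended for) is modelled as a zero-truncated Poisson response, once
#' with the 22 quality scores as covariates and once with intensity and
#' complexity, always with the days covariate and the phylogeny, plant
#' part, and panellist random effects.
#'
#' @param dataset list with `drugs`, `trials`, `uses`.
#' @param A phylogenetic correlation matrix.
#' @param mcmc an [mcmc_settings()]; its `seed` is the master seed.
#' @param priors a [pglmm_priors()].
#' @param versatility optional externally supplied response (see
#'   [build_design()]).
#' @return list with `qualities` and `intensity_complexity`, both
#'   `posterior_summary` objects.
#' @export
run_versatility_models <- function(dataset, A, mcmc = mcmc_settings(),
                                   priors = pglmm_priors(),
                                   versatility = NULL) {
  out <- list()
  for (i in seq_along(fx <- c("qualities", "intensity_complexity"))) {
    mc_i <- mcmc
    mc_i$seed <- derive_seed(mcmc$seed, i)
    out[[fx[i]]] <- fit_one(dataset, A, "versatility", "zt_poisson", fx[i],
                            mc_i, priors, versatility)
  }
  out
}

#' Fit the per-use probit models
#'
#' For every therapeutic use, two binary probit models: qualities and
#' intensity + complexity. Uses whose indicator is constant (all 0 or all
#' 1 across drugs) carry no information for a binary response and are
#' skipped with a recorded reason rather than failing the battery; engine
#' errors in individual models are likewise recorded and do not abort the
#' remaining models.
#'
#' @inheritParams run_versatility_models
#' @return named list (one entry per use) of lists with elements
#'   `qualities` and `intensity_complexity`, each either a
#'   `posterior_summary` or a skip record `list(skipped = TRUE, reason)`.
#' @export
run_use_models <- function(dataset, A, mcmc = mcmc_settings(),
                           priors = pglmm_priors()) {
  uses <- colnames(dataset$uses$matrix)
  out <- stats::setNames(vector("list", length(uses)), uses)
  for (ui in seq_along(uses)) {
    u <- uses[ui]
    col <- dataset$uses$matrix[, u]
    if (length(unique(col)) == 1L) {
      rec <- list(skipped = TRUE,
                  reason = paste0("use indicator constant (all ", col[1L], ")"))
      out[[u]] <- list(qualities = rec, intensity_complexity = rec)
      next
    }
    fits <- list()
    for (i in seq_along(fx <- c("qualities", "intensity_complexity"))) {
      mc_i <- mcmc
      mc_i$seed <- derive_seed(mcmc$seed, 2L + 2L * ui + i)
      fits[[fx[i]]] <- tryCatch(
        fit_one(dataset, A, paste0("use:", u), "probit", fx[i], mc_i, priors),
        error = function(e) list(skipped = TRUE,
                                 reason = paste0("engine error [use:", u, " ",
                                                 fx[i], "]: ",
                                                 conditionMessage(e))))
    }
    out[[u]] <- fits
  }
  out
}

#' Run the full model battery
#'
#' @inheritParams run_versatility_models
#' @return object of class `battery_result`: `versatility` (two
#'   summaries), `use_models` (per use), and `meta` (master seed, settings,
#'   skip records).
#' @export
run_battery <- function(dataset, A, mcmc = mcmc_settings(),
                        priors = pglmm_priors(), versatility = NULL) {
  vers <- run_versatility_models(dataset, A, mcmc, priors, versatility)
  use <- run_use_models(dataset, A, mcmc, priors)
  skipped <- list()
  for (u in names(use))
    for (fx in names(use[[u]]))
      if (isTRUE(use[[u]][[fx]]$skipped))
        skipped[[paste(u, fx)]] <- use[[u]][[fx]]$reason
  structure(list(versatility = vers, use_models = use,
                 meta = list(master_seed = mcmc$seed, settings = mcmc,
                             n_uses = length(use), skipped = skipped)),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  n_fit <- 2L + sum(vapply(x$use_models, function(u)
    sum(!vapply(u, function(f) isTRUE(f$skipped), TRUE)), 0L))
  cat("Model battery:", n_fit, "fitted model summaries over",
      x$meta$n_uses, "uses (master seed", x$meta$master_seed, ")\n")
  if (length(x$meta$skipped)) {
    cat("skipped:\n")
    for (nm in names(x$meta$skipped))
      cat("  ", nm, ": ", x$meta$skipped[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Quality x use effect map and magnitude of effect
#'
#' Collects, from the quality-set probit use models, the posterior mode
#' (default; configurable to the mean) of each quality coefficient into a
#' 22 x n_uses beta matrix, masks it at `p_x < alpha`, and aggregates per
#' quality: `magnitude` is the sum of significant betas across uses,
#' `total` the sum of all betas regardless of significance. Skipped models
#' contribute no cells. Alongside the literature-standard per-model threshold an
#' optional Benjamini-Hochberg report over the whole grid is returned
#' (clearly an extension; the headline rule applies no multiple-testing
#' correction).
#'
#' @param battery a `battery_result`.
#' @param alpha significance level on p_x.
#' @param stat `"mode"` or `"mean"`.
#' @param bh also compute a BH-adjusted mask over the doubled p_x grid.
#' @return object of class `effect_map`: matrices `beta`, `px`, `mask`
#'   (logical), vectors `magnitude` and `total` (per quality), counts
#'   `n_positive`/`n_negative` of significant associations, and optionally
#'   `bh_mask`.
#' @export
effect_map <- function(battery, alpha = 0.05, stat = c("mode", "mean"),
                       bh = FALSE) {
  stat <- match.arg(stat)
  stopifnot(inherits(battery, "battery_result"))
  uses <- names(battery$use_models)
  qual <- NULL
  for (u in uses) {
    f <- battery$use_models[[u]]$qualities
    if (!isTRUE(f$skipped)) {
      qual <- setdiff(f$coefficients$term, c("(Intercept)", "days"))
      break
    }
  }
  if (is.null(qual)) stop("no fitted quality-set use models in battery")
  beta <- matrix(NA_real_, length(qual), length(uses),
                 dimnames = list(qual, uses))
  px <- beta
  for (u in uses) {
    f <- battery$use_models[[u]]$qualities
    if (isTRUE(f$skipped)) next
    cf <- f$coefficients
    ri <- match(qual, cf$term)
    beta[, u] <- cf[[stat]][ri]
    px[, u] <- cf$px[ri]
  }
  mask <- !is.na(px) & px < alpha
  masked_beta <- ifelse(mask, beta, 0)
  out <- list(beta = beta, px = px, mask = mask,
              magnitude = rowSums(masked_beta),
              total = rowSums(beta, na.rm = TRUE),
              n_positive = sum(mask & beta > 0, na.rm = TRUE),
              n_negative = sum(mask & beta < 0, na.rm = TRUE),
              alpha = alpha, stat = stat)
  if (bh) {
    px2 <- 2 * px
    adj <- stats::p.adjust(as.vector(px2), method = "BH")
    out$bh_mask <- matrix(!is.na(adj) & adj < alpha, nrow(px),
                          dimnames = dimnames(px))
  }
  structure(out, class = "effect_map")
}

#' @export
print.effect_map <- function(x, ...) {
  cat("Effect map: ", nrow(x$beta), " qualities x ", ncol(x$beta),
      " uses; ", sum(x$mask, na.rm = TRUE), " significant associations (",
      x$n_positive, " positive, ", x$n_negative, " negative) at p_x < ",
      x$alpha, "\n", sep = "")
  mag <- sort(x$magnitude, decreasing = TRUE)
  cat("largest magnitudes of effect:",
      paste(sprintf("%s=%.2f", names(utils::head(mag, 5L)),
                    utils::head(mag, 5L)), collapse = ", "), "\n")
  invisible(x)
}

#' Write effect-map tables
#'
#' @param x an `effect_map`.
#' @param dir output directory.
#' @param sep field separator.
#' @export
write_effect_map <- function(x, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bt <- data.frame(quality = rownames(x$beta), x$beta, check.names = FALSE)
  utils::write.table(bt, file.path(dir, "effect_map_beta.csv"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  mg <- data.frame(quality = rownames(x$beta), magnitude = x$magnitude,
                   total = x$total)
  utils::write.table(mg, file.path(dir, "effect_map_magnitude.csv"),
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(dir)
}
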