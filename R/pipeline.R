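## End-to-end pipeline commands. A thin command-line front-end over these
## functions lives in inst/cli/phylotaste.R; the functions themselves are
## the scripting interface.

#' Run configuration
#'
#' @param drugs,trials,uses,categories,tree input file paths.
#' @param out output directory.
#' @param profile MCMC profile, `"desk"` or `"reference"`.
#' @param alpha significance level on p_x.
#' @param seed master seed.
#' @param sep field separator of the delimited inputs.
#' @param fix_resid,doubled_px,bh option flags (see [pglmm_priors()],
#'   [compute_px()], [effect_map()]).
#' @param mcmc optional [mcmc_settings()] overriding the profile (its seed
#'   is replaced by `seed`).
#' @return list of class `run_config`.
#' @export
run_config <- function(drugs = NULL, trials = NULL, uses = NULL,
                       categories = NULL, tree = NULL, out = ".",
                       profile = "desk", alpha = 0.05, seed = 1L,
                       sep = ",", fix_resid = FALSE, doubled_px = FALSE,
                       bh = FALSE, mcmc = NULL) {
  structure(list(drugs = drugs, trials = trials, uses = uses,
                 categories = categories, tree = tree, out = out,
                 profile = profile, alpha = alpha, seed = as.integer(seed),
                 sep = sep, fix_resid = fix_resid, doubled_px = doubled_px,
                 bh = bh, mcmc = mcmc), class = "run_config")
}

check_inputs <- function(config, need) {
  for (f in need) {
    path <- config[[f]]
    if (is.null(path)) stop("config error: missing input path '", f, "'")
    if (!file.exists(path)) stop("config error: ", f, " file not found: ", path)
  }
}

load_dataset <- function(config) {
  check_inputs(config, c("drugs", "trials", "uses", "categories"))
  drugs <- load_drug_table(config$drugs, sep = config$sep)
  trials <- load_trials(config$trials, sep = config$sep)
  uses <- load_use_matrix(config$uses, config$categories, sep = config$sep)
  report <- validate_dataset(drugs, trials, uses)
  if (!is_loadable(report)) {
    print(report)
    stop("dataset validation failed; see report above")
  }
  list(drugs = drugs, trials = trials, uses = uses, report = report)
}

write_manifest <- function(config, dir, extra = list()) {
  lines <- c(
    paste0("package_version: ", as.character(utils::packageVersion("phylotaste"))),
    paste0("seed: ", config$seed),
    paste0("profile: ", config$profile),
    paste0("alpha: ", config$alpha))
  for (f in c("drugs", "trials", "uses", "categories", "tree"))
    if (!is.null(config[[f]]) && file.exists(config[[f]]))
      lines <- c(lines, paste0(f, ": ", config[[f]], " md5=",
                               tools::md5sum(config[[f]])))
  for (nm in names(extra)) lines <- c(lines, paste0(nm, ": ", extra[[nm]]))
  writeLines(lines, file.path(dir, "manifest.txt"))
}

#' Generate and write a synthetic fixture set
#'
#' Writes the three panel tables, the Newick tree, and a manifest under
#' `config$out`. Identical seeds produce byte-identical files.
#'
#' @param config a [run_config()] (only `out` and `seed` are used).
#' @param scenario a [simulation_scenario()]; its seed is overridden by
#'   `config$seed`.
#' @return invisibly, the `synthetic_dataset`.
#' @export
cmd_simulate <- function(config = run_config(), scenario = simulation_scenario()) {
  scenario$seed <- config$seed
  sim <- simulate_panel(scenario)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- write_dataset(sim$drugs, sim$trials, sim$uses, config$out,
                         sep = config$sep)
  ape::write.tree(sim$tree, file.path(config$out, "tree.nwk"))
  tv <- sim$truth$versatility
  utils::write.table(tv, file.path(config$out, "true_versatility.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  write_manifest(config, config$out,
                 extra = list(n_trials = nrow(sim$trials),
                              n_drugs = nrow(sim$drugs)))
  invisible(sim)
}

#' Descriptive-statistics report
#'
#' Loads and validates the dataset, then writes the per-quality,
#' per-strength-level and per-use tables plus a plain-text report.
#'
#' @param config a [run_config()] with input paths set.
#' @return invisibly, the `descriptive_stats`.
#' @export
cmd_metrics <- function(config) {
  ds <- load_dataset(config)
  stats <- descriptive_summary(ds$trials, ds$uses)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(stats$per_quality,
                     file.path(config$out, "per_quality.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  utils::write.table(stats$by_level, file.path(config$out, "by_level.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  utils::write.table(stats$per_use, file.path(config$out, "per_use.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  con <- file(file.path(config$out, "report.txt"), "w")
  sink(con); print(ds$report); print(stats); sink(); close(con)
  write_manifest(config, config$out)
  invisible(stats)
}

#' Run the full model battery from files
#'
#' Loads the dataset and tree, grafts any missing taxa, builds the
#' phylogenetic correlation matrix, runs the 2 + 2-per-use model battery,
#' and writes per-model summary tables, the effect map, the magnitude
#' table, and a run log.
#'
#' @param config a [run_config()] with all five input paths set.
#' @return invisibly, a list with `battery` and `map`.
#' @export
cmd_battery <- function(config) {
  check_inputs(config, c("drugs", "trials", "uses", "categories", "tree"))
  ds <- load_dataset(config)
  tree <- parse_newick(file = config$tree)
  if (!attr(tree, "ultrametric")) tree <- repair_ultrametric(tree)
  taxa <- unique(taxon_label(ds$drugs$taxon_name))
  ranks <- rank_map(ds$drugs$taxon_name, genus = ds$drugs$genus,
                    family = ds$drugs$family)
  tree <- graft_missing_taxa(tree, taxa, ranks)
  A <- phylo_correlation(tree, taxa)
  mcmc <- if (is.null(config$mcmc))
    mcmc_settings(profile = config$profile, seed = config$seed)
  else {
    m <- config$mcmc; m$seed <- config$seed; m
  }
  priors <- pglmm_priors(fix_resid = config$fix_resid)
  battery <- run_battery(ds, A, mcmc = mcmc, priors = priors)
  map <- effect_map(battery, alpha = config$alpha, bh = config$bh)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("master seed: %d", config$seed),
                 sprintf("profile: %s", config$profile))
  for (nm in c("qualities", "intensity_complexity")) {
    s <- battery$versatility[[nm]]
    write_chain(s, file.path(config$out, paste0("versatility_", nm, ".csv")),
                sep = config$sep)
    log_lines <- c(log_lines,
                   sprintf("versatility %s: h2_mode=%.3f accept=%.2f dropped=%d",
                           nm, s$h2_mode, s$accept_rate, s$n_dropped))
  }
  for (u in names(battery$use_models)) {
    for (nm in names(battery$use_models[[u]])) {
      f <- battery$use_models[[u]][[nm]]
      if (isTRUE(f$skipped)) {
        log_lines <- c(log_lines, sprintf("use %s %s: SKIPPED (%s)",
                                          u, nm, f$reason))
      } else {
        write_chain(f, file.path(config$out,
                                 paste0("use_", u, "_", nm, ".csv")),
                    sep = config$sep)
        log_lines <- c(log_lines,
                       sprintf("use %s %s: h2_mode=%.3f%s", u, nm, f$h2_mode,
                               if (length(f$separation))
                                 paste0(" separation=",
                                        paste(f$separation, collapse = "+"))
                               else ""))
      }
    }
  }
  write_effect_map(map, config$out, sep = config$sep)
  writeLines(log_lines, file.path(config$out, "run_log.txt"))
  write_manifest(config, config$out)
  invisible(list(battery = battery, map = map))
}
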