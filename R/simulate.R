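## Synthetic-data generator. Produces complete datasets (ultrametric tree,
## drugs, sensory trials, binary use matrix) whose statistical structure
## matches the analysis model, plus a truth bundle of every parameter used,
## so that parameter recovery and calibration are testable end to end.
##
## Ordinal scores arise by thresholding a latent Gaussian quality trait
## with phylogenetic, plant-part, panellist and trial-residual components;
## use indicators arise from probit liabilities driven by drug-mean quality
## scores; the versatility response arises from a zero-truncated Poisson
## whose log rate is linear in drug-mean quality scores.

#' Simulation scenario
#'
#' Defaults describe the desk-scale study: 80 taxa, 100 drugs (some
#' species contributing several plant parts), 5 panellists, on average 5.7
#' trials per drug (the tasting-panel workload reported for the real
#' study, which used 11 panellists and 700 drugs), 6 therapeutic uses with
#' 8 non-zero true quality effects, and versatility effects mirroring the
#' qualities found predictive in the field (bitter, starchy, musky, sweet
#' and soapy positive; sour negative).
#'
#' Quality-trait variance components are chosen for a trained consensus
#' panel after calibration sessions: between-drug components (phylogeny
#' 0.6, plant part 0.12) dominate within-drug components (panellist
#' 0.005, trial residual 0.01), so a drug's trial scores are a highly
#' repeatable proxy of its chemosensory profile. This matters for
#' known-truth validation: drug-level responses are driven by drug-mean
#' scores while models fit per-trial scores, and within-drug score noise
#' would otherwise bias correlated coefficients (multivariate
#' measurement-error contamination). Response-level components make the phylogenetic share
#' dominant, as observed in real drug-use data: the versatility log rate
#' has share 1.5 / (1.5 + 0.15) ~ 0.91 and the use liabilities (unit
#' probit residual) ~ 0.57.
#'
#' @param n_taxa,n_drugs,n_panellists,n_uses scenario sizes.
#' @param trials_per_drug_mean,trials_per_drug_sd normal approximation of
#'   the per-drug trial count (rounded, floored at 1).
#' @param vc_quality,vc_versatility,vc_use named variance components
#'   `(phylo, part, panellist, resid)` for the latent quality traits, the
#'   versatility log rate, and the use liabilities.
#' @param quality_mu baseline of the latent quality traits.
#' @param cutpoints three increasing thresholds mapping the latent trait to
#'   scores 0/1/2/3.
#' @param versatility_intercept,beta_versatility zero-truncated Poisson
#'   log-rate intercept and named sparse quality effects (per unit of
#'   drug-mean score).
#' @param use_intercept,use_effects probit liability intercept and a named
#'   list `use -> named quality effects` (per unit of drug-mean score).
#' @param days_shape,days_scale gamma parameters for the days-since-
#'   collection covariate (rounded to days).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of (scenario, seed).
#' @return a list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(
    n_taxa = 80L, n_drugs = 100L, n_panellists = 5L, n_uses = 6L,
    trials_per_drug_mean = 5.7, trials_per_drug_sd = 1.3,
    vc_quality = c(phylo = 0.6, part = 0.12, panellist = 0.005, resid = 0.01),
    vc_versatility = c(phylo = 1.5, part = 0.15, panellist = 0, resid = 0),
    vc_use = c(phylo = 1.5, part = 0.15, panellist = 0, resid = 1.0),
    quality_mu = -0.15,
    cutpoints = c(0.8, 1.8, 2.8),
    versatility_intercept = log(4),
    beta_versatility = c(bitter = 0.15, starchy = 0.12, musky = 0.12,
                         sweet = 0.10, soapy = 0.10, sour = -0.15),
    use_intercept = -0.5,
    use_effects = default_use_effects(),
    days_shape = 4, days_scale = 30,
    seed = 1L) {
  for (vc in list(vc_quality, vc_versatility, vc_use))
    if (any(vc < 0) || !all(c("phylo", "part", "panellist", "resid") %in% names(vc)))
      stop("scenario error: variance components must be named (phylo, part, panellist, resid) and non-negative")
  if (any(diff(cutpoints) <= 0) || length(cutpoints) != 3L)
    stop("scenario error: cutpoints must be three strictly increasing values")
  if (n_taxa < 2L) stop("scenario error: n_taxa must be at least 2")
  if (n_drugs < n_taxa) stop("scenario error: n_drugs must be >= n_taxa")
  structure(list(
    n_taxa = as.integer(n_taxa), n_drugs = as.integer(n_drugs),
    n_panellists = as.integer(n_panellists), n_uses = as.integer(n_uses),
    trials_per_drug_mean = trials_per_drug_mean,
    trials_per_drug_sd = trials_per_drug_sd,
    vc_quality = vc_quality, vc_versatility = vc_versatility,
    vc_use = vc_use, quality_mu = quality_mu, cutpoints = cutpoints,
    versatility_intercept = versatility_intercept,
    beta_versatility = beta_versatility,
    use_intercept = use_intercept, use_effects = use_effects,
    days_shape = days_shape, days_scale = days_scale,
    seed = as.integer(seed)), class = "simulation_scenario")
}

#' @rdname simulation_scenario
#' @export
default_use_effects <- function() {
  list(use1 = c(bitter = 0.8),
       use2 = c(astringent = 0.7, woody = 0.6),
       use3 = c(sour = -0.7),
       use4 = c(sweet = 0.7, starchy = 0.7),
       use5 = c(fresh_cooling = 0.8),
       use6 = c(salty = -0.7))
}

#' Simulate a pure-birth ultrametric tree with rank structure
#'
#' Tips are labelled `Genus<g>_species<i>`; genera are the clades whose
#' crown age is at most 30\% of the tree height, families those with crown
#' age at most 80\%, so grafting by genus/family MRCA is exercised
#' naturally. The tree is scaled to height 1.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return an ultrametric `phylo` with attributes `ranks` (a [rank_map()])
#'   and `ultrametric = TRUE`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop("domain error: n_taxa must be at least 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  h <- tree_height(tree)
  tree$edge.length <- tree$edge.length / h
  D <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(D, method = "average")
  genus <- stats::cutree(hc, h = 0.6)    # MRCA depth >= 0.7
  family <- stats::cutree(hc, h = 1.6)   # MRCA depth >= 0.2
  labels <- sprintf("Genus%02d_species%03d", genus[tree$tip.label],
                    seq_len(n_taxa))
  fam_labels <- sprintf("Family%02d", family[tree$tip.label])
  tree$tip.label <- labels
  attr(tree, "ranks") <- rank_map(labels,
                                  genus = sprintf("Genus%02d",
                                                  genus[names(genus)]),
                                  family = fam_labels)
  attr(tree, "ultrametric") <- TRUE
  tree
}

## columns of z (q x m) transformed to have covariance v * A, given R = chol(A)
phylo_draws <- function(R, m, v) {
  q <- ncol(R)
  sqrt(v) * crossprod(R, matrix(stats::rnorm(q * m), q, m))
}

#' Simulate a complete panel dataset with known truth
#'
#' See [simulation_scenario()] for the generating model. The returned
#' tables are exactly what [load_drug_table()], [load_trials()] and
#' [load_use_matrix()] produce from disk, so every downstream stage can be
#' exercised without file round trips (and [write_dataset()] round-trips
#' them).
#'
#' @param scenario a [simulation_scenario()].
#' @param tree optional tree with at least `n_taxa` tips; simulated from
#'   the scenario seed when omitted.
#' @return list of class `synthetic_dataset` with `drugs`, `trials`,
#'   `uses`, `tree`, `A` (phylogenetic correlation over the drug taxa) and
#'   `truth` (scenario echo, all realised effects, and the generated
#'   versatility response as `versatility = data.frame(drug_id, value)`).
#' @export
simulate_panel <- function(scenario, tree = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  if (is.null(tree)) tree <- simulate_tree(sc$n_taxa, seed = sc$seed)
  if (length(tree$tip.label) < sc$n_taxa)
    stop("scenario error: tree has fewer tips than n_taxa")
  set.seed(sc$seed + 1L)
  vocab <- quality_vocabulary()
  nq <- length(vocab)
  taxa <- sort(tree$tip.label)[seq_len(sc$n_taxa)]
  A <- phylo_correlation(tree, taxa)
  R <- chol(A)

  ## drugs: every taxon gets one drug; extras are additional plant parts
  ## (at most one drug per (taxon, part) pair, so a taxon yields at most
  ## length(parts_pool) drugs)
  parts_pool <- c("root", "bark", "herb", "seed", "leaf")
  if (sc$n_drugs > sc$n_taxa * length(parts_pool))
    stop("scenario error: n_drugs exceeds n_taxa x ", length(parts_pool),
         " distinct plant parts")
  capacity <- rep(taxa, each = length(parts_pool) - 1L)
  extra <- sample(capacity)[seq_len(sc$n_drugs - sc$n_taxa)]
  taxon_of_drug <- c(taxa, extra)
  part_of_drug <- character(sc$n_drugs)
  for (d in seq_len(sc$n_drugs)) {
    used <- part_of_drug[taxon_of_drug == taxon_of_drug[d] & seq_len(sc$n_drugs) < d]
    part_of_drug[d] <- sample(setdiff(parts_pool, used), 1L)
  }
  drug_ids <- sprintf("d%03d", seq_len(sc$n_drugs))
  drugs <- data.frame(
    drug_id = drug_ids,
    taxon_name = gsub("_", " ", taxon_of_drug),
    genus = vapply(strsplit(taxon_of_drug, "_"), `[`, "", 1L),
    family = NA_character_, plant_part = part_of_drug,
    collection_date = NA_character_, stringsAsFactors = FALSE)
  class(drugs) <- c("drug_table", "data.frame")

  ## latent quality traits. The per-quality phylogenetic effects are
  ## centred across taxa: the panel protocol retains only descriptors that
  ## discriminate among drugs, so no quality is shifted wholesale out of
  ## (or into) every drug's profile; the common component would in any
  ## case be absorbed by the intercept.
  vq <- sc$vc_quality
  a_taxon <- phylo_draws(R, nq, vq["phylo"])          # taxa x qualities
  a_taxon <- sweep(a_taxon, 2L, colMeans(a_taxon))
  b_part <- matrix(stats::rnorm(length(parts_pool) * nq, 0, sqrt(vq["part"])),
                   length(parts_pool), nq, dimnames = list(parts_pool, NULL))
  pan_ids <- sprintf("p%02d", seq_len(sc$n_panellists))
  c_pan <- matrix(stats::rnorm(sc$n_panellists * nq, 0, sqrt(vq["panellist"])),
                  sc$n_panellists, nq, dimnames = list(pan_ids, NULL))

  ## trials
  n_t <- pmax(1L, round(stats::rnorm(sc$n_drugs, sc$trials_per_drug_mean,
                                     sc$trials_per_drug_sd)))
  trial_drug <- rep(seq_len(sc$n_drugs), n_t)
  n_trials <- length(trial_drug)
  trial_pan <- unlist(lapply(n_t, function(k)
    if (k <= sc$n_panellists) sample(sc$n_panellists, k)
    else sample(sc$n_panellists, k, replace = TRUE)))
  days <- pmin(round(stats::rgamma(n_trials, sc$days_shape,
                                   scale = sc$days_scale)), 730)
  ti <- match(taxon_of_drug[trial_drug], taxa)
  latent <- matrix(sc$quality_mu, n_trials, nq) +
    a_taxon[ti, , drop = FALSE] +
    b_part[part_of_drug[trial_drug], , drop = FALSE] +
    c_pan[trial_pan, , drop = FALSE] +
    matrix(stats::rnorm(n_trials * nq, 0, sqrt(vq["resid"])), n_trials, nq)
  scores <- matrix(findInterval(latent, sc$cutpoints), n_trials, nq,
                   dimnames = list(NULL, unclass(vocab)))
  storage.mode(scores) <- "integer"
  trials <- cbind(
    data.frame(trial_id = sprintf("t%05d", seq_len(n_trials)),
               drug_id = drug_ids[trial_drug],
               panellist_id = pan_ids[trial_pan],
               days = as.integer(days), stringsAsFactors = FALSE),
    as.data.frame(scores, check.names = FALSE))
  attr(trials, "vocabulary") <- vocab
  class(trials) <- c("trial_table", "data.frame")

  ## drug-mean scores drive the drug-level responses
  qbar <- rowsum(scores, trial_drug) / as.vector(n_t)
  rownames(qbar) <- drug_ids

  expand_beta <- function(named) {
    out <- stats::setNames(numeric(nq), unclass(vocab))
    if (length(named)) {
      unknown <- setdiff(names(named), unclass(vocab))
      if (length(unknown))
        stop("scenario error: unknown quality in effects: ",
             paste(unknown, collapse = ", "))
      out[names(named)] <- named
    }
    out
  }

  ## Random effects on the drug-level responses, centred across levels:
  ## the realised common component of a phylogenetic (or plant-part)
  ## effect is confounded with the intercept in any fitted model, so
  ## leaving it in would make the recorded intercept truth untestable.
  drug_response_effects <- function(vc) {
    u_tax <- as.vector(phylo_draws(R, 1L, vc["phylo"]))
    u_tax <- u_tax - mean(u_tax)
    u_part <- stats::rnorm(length(parts_pool), 0, sqrt(vc["part"]))
    u_part <- u_part - mean(u_part)
    u_tax[match(taxon_of_drug, taxa)] + u_part[match(part_of_drug, parts_pool)] +
      stats::rnorm(sc$n_drugs, 0, sqrt(vc["resid"]))
  }

  ## versatility: zero-truncated Poisson with log rate linear in qbar.
  ## The rate is used exactly as generated (no truncation), so the
  ## recorded truth is the data-generating process the engine fits;
  ## occasional large counts are expected under a high phylogenetic
  ## variance and are harmless.
  beta_v <- expand_beta(sc$beta_versatility)
  eta_v <- sc$versatility_intercept + drop(qbar %*% beta_v) +
    drug_response_effects(sc$vc_versatility)
  versatility <- rztpois(sc$n_drugs, exp(eta_v))

  ## uses: probit liabilities
  use_ids <- sprintf("use%d", seq_len(sc$n_uses))
  B <- matrix(0, nq, sc$n_uses, dimnames = list(unclass(vocab), use_ids))
  for (u in names(sc$use_effects))
    if (u %in% use_ids) B[, u] <- expand_beta(sc$use_effects[[u]])
  um <- matrix(0L, sc$n_drugs, sc$n_uses,
               dimnames = list(drug_ids, use_ids))
  for (u in use_ids) {
    liab <- sc$use_intercept + drop(qbar %*% B[, u]) +
      drug_response_effects(sc$vc_use)
    um[, u] <- as.integer(liab > 0)
  }
  category_map <- stats::setNames(sprintf("cat%d", ceiling(seq_len(sc$n_uses) / 2)),
                                  use_ids)
  uses <- new_use_matrix(um, category_map)

  truth <- list(
    scenario = sc,
    beta_versatility = beta_v,
    versatility_intercept = sc$versatility_intercept,
    use_effects = B, use_intercept = sc$use_intercept,
    versatility = data.frame(drug_id = drug_ids, value = versatility,
                             stringsAsFactors = FALSE),
    qbar = qbar, a_taxon = a_taxon,
    h2_versatility = unname(sc$vc_versatility["phylo"] / sum(sc$vc_versatility)),
    h2_use = unname(sc$vc_use["phylo"] / sum(sc$vc_use)))

  structure(list(drugs = drugs, trials = trials, uses = uses, tree = tree,
                 A = A, truth = truth),
            class = "synthetic_dataset")
}

#' @rdname simulate_panel
#' @export
simulate_dataset <- function(scenario = simulation_scenario()) {
  simulate_panel(scenario)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic panel dataset:", nrow(x$drugs), "drugs on",
      nrow(x$A), "taxa;", nrow(x$trials), "trials;",
      ncol(x$uses$matrix), "uses (seed",
      x$truth$scenario$seed, ")\n")
  invisible(x)
}
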