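## Assembles the response vector, fixed-effect matrix and random-effect
## incidence structures for one model. The analysis row unit is the sensory
## trial; drug-level responses (versatility, use indicators) are repeated
## across a drug's trials so that the panellist random effect is estimable.

#' Build the design data for one PGLMM
#'
#' Rows are sensory trials. The response is drug-level and repeated across
#' each drug's trials: the versatility category count (zero-truncated
#' Poisson), or one binary use indicator (probit). Fixed effects are either
#' the 22 ordinal quality scores treated as numeric covariates, or
#' intensity and complexity; the mean-centred days-since-collection
#' covariate is always included. Random terms are, in order: the
#' phylogenetic effect (taxon-level, covariance `A`), plant part, and
#' panellist. Under the zero-truncated family, trials belonging to drugs
#' with response 0 lie outside the support and are dropped; the drop count
#' is recorded.
#'
#' @param trials a `trial_table`.
#' @param drugs a `drug_table` (provides drug -> taxon and plant part).
#' @param uses a `use_matrix`.
#' @param A phylogenetic correlation matrix whose dimnames cover every
#'   taxon in `drugs`.
#' @param spec a [model_spec()].
#' @param versatility optional data.frame `drug_id`, `value` overriding the
#'   category count computed from `uses` (used when an externally generated
#'   versatility response is analysed).
#' @return a list of class `design_data`: `y`, `X`, `terms` (per random
#'   term: `label`, `index` of level per row, `levels`, `K` covariance or
#'   `NULL` for identity), `family`, `n_dropped`, `separation`.
#' @export
build_design <- function(trials, drugs, uses, A, spec, versatility = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  di <- match(trials$drug_id, drugs$drug_id)
  if (anyNA(di))
    stop("trial references unknown drug: ",
         paste(unique(trials$drug_id[is.na(di)]), collapse = ", "))

  ## drug-level response, repeated over trials
  if (identical(spec$response, "versatility")) {
    if (is.null(versatility)) {
      v <- drug_versatility(uses)
      resp_of_drug <- stats::setNames(v$n_categories, v$drug_id)
    } else {
      resp_of_drug <- stats::setNames(versatility$value, versatility$drug_id)
    }
  } else {
    use_id <- sub("^use:", "", spec$response)
    if (!use_id %in% colnames(uses$matrix))
      stop("unknown use: ", use_id)
    resp_of_drug <- uses$matrix[, use_id]
  }
  y <- as.numeric(resp_of_drug[trials$drug_id])
  if (anyNA(y))
    stop("response undefined for drug(s): ",
         paste(unique(trials$drug_id[is.na(y)]), collapse = ", "))

  ## fixed effects
  days_c <- trials$days - mean(trials$days)
  if (spec$fixed == "qualities") {
    X <- cbind("(Intercept)" = 1, score_matrix(trials), days = days_c)
  } else {
    X <- cbind("(Intercept)" = 1, intensity = trial_intensity(trials),
               complexity = trial_complexity(trials), days = days_c)
  }

  ## random terms: phylo (taxon level, covariance A), plant part, panellist
  taxon <- taxon_label(drugs$taxon_name)[di]
  taxa <- sort(unique(taxon))
  missing_tax <- setdiff(taxa, rownames(A))
  if (length(missing_tax))
    stop("correlation matrix does not cover taxa: ",
         paste(missing_tax, collapse = ", "))
  K_phylo <- A[taxa, taxa, drop = FALSE]
  part <- drugs$plant_part[di]
  parts <- sort(unique(part))
  pan <- trials$panellist_id
  pans <- sort(unique(pan))
  terms <- list(
    phylo = list(label = "phylo", index = match(taxon, taxa),
                 levels = taxa, K = K_phylo),
    plant_part = list(label = "plant_part", index = match(part, parts),
                      levels = parts, K = NULL),
    panellist = list(label = "panellist", index = match(pan, pans),
                     levels = pans, K = NULL))

  ## zero-truncated support
  n_dropped <- 0L
  if (spec$family == "zt_poisson") {
    keep <- y > 0
    n_dropped <- sum(!keep)
    if (!any(keep))
      stop("degenerate-model error: no rows remain after zero truncation")
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
    for (k in seq_along(terms))
      terms[[k]]$index <- terms[[k]]$index[keep]
  }

  const <- apply(X[, -1L, drop = FALSE], 2L, function(col) all(col == col[1L]))
  if (any(const))
    stop("degenerate-design error: constant fixed-effect column(s): ",
         paste(names(const)[const], collapse = ", "))

  ## quasi-complete separation screen for binary responses: per quality,
  ## the (drug ever scored non-zero) x (use recommended) cross-table
  separation <- character()
  if (grepl("^use:", spec$response) && spec$fixed == "qualities") {
    sm <- score_matrix(trials)
    drug_y <- resp_of_drug[match(unique(trials$drug_id), names(resp_of_drug))]
    drug_any <- rowsum(1L * (sm > 0L), trials$drug_id)
    drug_any <- drug_any[names(drug_y), , drop = FALSE] > 0L
    for (q in colnames(drug_any)) {
      tab <- table(factor(drug_any[, q], levels = c(FALSE, TRUE)),
                   factor(drug_y, levels = c(0, 1)))
      if (any(tab == 0L)) separation <- c(separation, q)
    }
  }

  structure(list(y = y, X = X, terms = terms, family = spec$family,
                 response = spec$response, fixed = spec$fixed,
                 n_dropped = n_dropped, separation = separation),
            class = "design_data")
}
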