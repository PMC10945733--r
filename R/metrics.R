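## Per-trial and per-drug chemosensory statistics.
##
## Intensity of a trial is the sum of the panellist's 22 ordinal scores
## (0-66); complexity is the number of qualities scored non-zero (0-22).
## Therapeutic versatility of a drug is the number of distinct broader
## categories of use it is recommended for.

#' Per-trial chemosensory intensity and complexity
#'
#' `trial_intensity()` sums all 22 ordinal scores of each trial;
#' `trial_complexity()` counts the qualities scored non-zero.
#' `trial_metrics()` returns both per trial. By construction
#' `complexity <= intensity <= 3 * complexity`.
#'
#' @param trials a `trial_table`.
#' @return integer vector (one value per trial), or for `trial_metrics()` a
#'   data.frame with `trial_id`, `drug_id`, `panellist_id`, `days`,
#'   `intensity`, `complexity`.
#' @export
trial_intensity <- function(trials) {
  as.integer(rowSums(score_matrix(trials)))
}

#' @rdname trial_intensity
#' @export
trial_complexity <- function(trials) {
  as.integer(rowSums(score_matrix(trials) > 0L))
}

#' @rdname trial_intensity
#' @export
trial_metrics <- function(trials) {
  data.frame(trial_id = trials$trial_id, drug_id = trials$drug_id,
             panellist_id = trials$panellist_id, days = trials$days,
             intensity = trial_intensity(trials),
             complexity = trial_complexity(trials),
             stringsAsFactors = FALSE)
}

#' Therapeutic versatility per drug
#'
#' For each drug, counts the recommended uses (`n_uses`, out of the 46) and
#' the distinct broader categories of use they fall into (`n_categories`,
#' out of 25). The category count is the versatility measure used as the
#' zero-truncated Poisson response.
#'
#' @param uses a `use_matrix`.
#' @param drug_id optional character vector restricting/ordering the result;
#'   unknown ids raise a lookup error.
#' @return data.frame `drug_id`, `n_uses`, `n_categories`.
#' @export
drug_versatility <- function(uses, drug_id = NULL) {
  m <- uses$matrix
  if (!is.null(drug_id)) {
    missing <- setdiff(drug_id, rownames(m))
    if (length(missing))
      stop("lookup error: drug(s) absent from use matrix: ",
           paste(missing, collapse = ", "))
    m <- m[drug_id, , drop = FALSE]
  }
  cat_of <- uses$category_map[colnames(m)]
  n_categories <- apply(m, 1L, function(row)
    length(unique(cat_of[row == 1L])))
  data.frame(drug_id = rownames(m),
             n_uses = as.integer(rowSums(m)),
             n_categories = as.integer(n_categories),
             stringsAsFactors = FALSE)
}

#' Pooled qualities per drug
#'
#' Union, across all of a drug's trials, of the qualities scored non-zero by
#' any panellist. This is the drug-level "qualities per drug" descriptive
#' count; per-panellist complexity (see [trial_complexity()]) is the
#' modelling covariate.
#'
#' @param trials a `trial_table`.
#' @return data.frame `drug_id`, `n_qualities_pooled`.
#' @export
pooled_drug_qualities <- function(trials) {
  sm <- score_matrix(trials)
  by_drug <- rowsum(1L * (sm > 0L), trials$drug_id)
  data.frame(drug_id = rownames(by_drug),
             n_qualities_pooled = as.integer(rowSums(by_drug > 0L)),
             stringsAsFactors = FALSE)
}

#' Percentage rounding used in descriptive reports
#'
#' Percentages of at least 10 are reported as integers, smaller ones to one
#' decimal place (so 39.16 prints as 39, 3.22 as 3.2).
#'
#' @param count numerator count.
#' @param total denominator count.
#' @return numeric percentage, rounded per the reporting rule.
#' @export
report_percent <- function(count, total) {
  p <- 100 * count / total
  ifelse(p >= 10, round(p), round(p, 1L))
}

#' Descriptive summary of a panel dataset
#'
#' Reproduces the descriptive tallies of a panel study: per-quality report
#' counts (trials scoring the quality non-zero) with percentages of all
#' trials; counts of weak/medium/strong perceptions with percentages of all
#' perception reports; per-quality strength profile; pooled qualities per
#' drug; uses per drug; and per-use record counts.
#'
#' @param trials a `trial_table`.
#' @param uses a `use_matrix`.
#' @return an object of class `descriptive_stats`.
#' @export
descriptive_summary <- function(trials, uses) {
  sm <- score_matrix(trials)
  n_trials <- nrow(trials)
  total_reports <- sum(sm > 0L)
  q_counts <- colSums(sm > 0L)
  per_quality <- data.frame(
    quality = colnames(sm),
    reports = as.integer(q_counts),
    pct_of_trials = report_percent(q_counts, n_trials),
    n_weak = as.integer(colSums(sm == 1L)),
    n_medium = as.integer(colSums(sm == 2L)),
    n_strong = as.integer(colSums(sm == 3L)),
    stringsAsFactors = FALSE)
  per_quality$pct_weak <- report_percent(per_quality$n_weak, per_quality$reports)
  per_quality$pct_strong <- report_percent(per_quality$n_strong, per_quality$reports)
  lv_counts <- c(weak = sum(sm == 1L), medium = sum(sm == 2L),
                 strong = sum(sm == 3L))
  by_level <- data.frame(
    level = names(lv_counts),
    reports = as.integer(lv_counts),
    pct_of_reports = report_percent(lv_counts, total_reports),
    stringsAsFactors = FALSE)
  vers <- drug_versatility(uses)
  use_records <- colSums(uses$matrix)
  per_use <- data.frame(use_id = colnames(uses$matrix),
                        category_id = unname(uses$category_map),
                        records = as.integer(use_records),
                        stringsAsFactors = FALSE)
  pooled <- pooled_drug_qualities(trials)
  structure(list(
    n_trials = n_trials,
    n_drugs = nrow(uses$matrix),
    n_panellists = length(unique(trials$panellist_id)),
    total_perception_reports = total_reports,
    per_quality = per_quality,
    by_level = by_level,
    per_use = per_use,
    mean_uses_per_drug = mean(vers$n_uses),
    mean_categories_per_drug = mean(vers$n_categories),
    pooled_quality_range = range(pooled$n_qualities_pooled)),
    class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("%d panellists conducted %d sensory trials and reported %d individual perceptions of qualities.\n",
              x$n_panellists, x$n_trials, x$total_perception_reports))
  pq <- x$per_quality[order(-x$per_quality$reports), ]
  top <- utils::head(pq, 4L)
  cat("Most frequently reported qualities: ",
      paste(sprintf("%s (%d reports; %s%% of all assessed samples)",
                    top$quality, top$reports,
                    format(top$pct_of_trials, trim = TRUE)),
            collapse = ", "), ".\n", sep = "")
  least <- utils::tail(pq, 1L)
  cat(sprintf("Least reported: %s (%d reports; %s%%).\n", least$quality,
              least$reports, format(least$pct_of_trials, trim = TRUE)))
  for (i in seq_len(nrow(x$by_level)))
    cat(sprintf("%s perceptions: %d reports (%s%% of all perception reports).\n",
                x$by_level$level[i], x$by_level$reports[i],
                format(x$by_level$pct_of_reports[i], trim = TRUE)))
  cat(sprintf("Panellists perceived between %d and %d individual qualities per drug (pooled).\n",
              x$pooled_quality_range[1], x$pooled_quality_range[2]))
  cat(sprintf("Mean number of therapeutic uses per botanical drug: %.1f.\n",
              x$mean_uses_per_drug))
  pu <- x$per_use[order(-x$per_use$records), ]
  cat(sprintf("Most frequently mentioned use: '%s' (%d use records); least: '%s' (%d).\n",
              pu$use_id[1], pu$records[1],
              pu$use_id[nrow(pu)], pu$records[nrow(pu)]))
  invisible(x)
}
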