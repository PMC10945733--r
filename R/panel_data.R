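## Readers, writers and validation for the three panel-dataset tables:
## drugs (one row per botanical drug), sensory trials (one row per
## panellist x drug sample tasting) and the binary therapeutic-use matrix
## with its use -> category map. All files are delimited text with a header
## row; comma is the default, semicolon and tab are accepted.

read_delim_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", strip.white = TRUE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Read a botanical-drug table
#'
#' One row per botanical drug (a specific plant part of a specific taxon).
#' Required columns: `drug_id`, `taxon_name`, `plant_part`. Optional columns
#' `genus`, `family`, `collection_date` are honoured verbatim; if `genus` is
#' absent it is parsed as the first whitespace-separated token of the
#' binomial `taxon_name`. Drugs identified only to genus must already carry
#' a representative species in `taxon_name`; the package never re-chooses
#' representatives.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator: `","` (default), `";"` or `"\t"`.
#' @return a `data.frame` of class `drug_table` with columns `drug_id`,
#'   `taxon_name`, `genus`, `family`, `plant_part`, `collection_date`.
#' @export
load_drug_table <- function(path, sep = ",") {
  df <- read_delim_table(path, sep)
  require_columns(df, c("drug_id", "taxon_name", "plant_part"), "drug table")
  df$drug_id <- as.character(df$drug_id)
  df$taxon_name <- as.character(df$taxon_name)
  df$plant_part <- as.character(df$plant_part)
  dup <- df$drug_id[duplicated(df$drug_id)]
  if (length(dup))
    stop("integrity error: duplicate drug_id ",
         paste(unique(dup), collapse = ", "))
  if (is.null(df$genus))
    df$genus <- vapply(strsplit(df$taxon_name, "[ _]+"), `[`, "", 1L)
  df$genus <- as.character(df$genus)
  df$family <- if (is.null(df$family)) NA_character_ else as.character(df$family)
  df$collection_date <- if (is.null(df$collection_date)) NA_character_ else
    as.character(df$collection_date)
  dup_tp <- duplicated(paste(df$taxon_name, df$plant_part, sep = "\r"))
  if (any(dup_tp))
    stop("integrity error: duplicate (taxon_name, plant_part) pair for ",
         paste(df$drug_id[dup_tp], collapse = ", "))
  out <- df[, c("drug_id", "taxon_name", "genus", "family", "plant_part",
                "collection_date")]
  class(out) <- c("drug_table", "data.frame")
  out
}

#' Read a sensory-trial table
#'
#' Each sensory trial is one panellist's assessment of one drug sample,
#' scoring every quality in the vocabulary on the 4-point ordinal scale
#' absent (0) / weak (1) / medium (2) / strong (3). Two layouts are
#' supported:
#' \describe{
#'   \item{wide}{one row per trial; columns `trial_id`, `drug_id`,
#'     `panellist_id`, `days` plus one column per quality label. Absent
#'     quality columns and blank cells are filled with 0 (the scale itself
#'     encodes "absent").}
#'   \item{long}{columns `trial_id`, `drug_id`, `panellist_id`, `days`,
#'     `quality`, `score`; qualities not listed for a trial are 0.}
#' }
#'
#' @param path path to the delimited file.
#' @param vocab a [quality_vocabulary()].
#' @param layout `"wide"` (default) or `"long"`.
#' @param sep field separator.
#' @return a `data.frame` of class `trial_table`: columns `trial_id`,
#'   `drug_id`, `panellist_id`, `days`, then the 22 quality score columns in
#'   vocabulary order.
#' @export
load_trials <- function(path, vocab = quality_vocabulary(),
                        layout = c("wide", "long"), sep = ",") {
  vocab <- as_vocabulary(vocab)
  layout <- match.arg(layout)
  df <- read_delim_table(path, sep)
  id_cols <- c("trial_id", "drug_id", "panellist_id", "days")
  if (layout == "wide") {
    require_columns(df, id_cols, "trial table")
    extra <- setdiff(names(df), c(id_cols, unclass(vocab)))
    if (length(extra))
      stop("vocabulary error: unknown quality column(s) ",
           paste(extra, collapse = ", "))
    scores <- matrix(0L, nrow(df), length(vocab),
                     dimnames = list(NULL, unclass(vocab)))
    for (q in intersect(unclass(vocab), names(df))) {
      v <- df[[q]]
      v[is.na(v)] <- 0L
      scores[, q] <- as.integer(v)
    }
    trials <- df[, id_cols]
  } else {
    require_columns(df, c(id_cols, "quality", "score"), "trial table (long)")
    bad_q <- setdiff(unique(df$quality), unclass(vocab))
    if (length(bad_q))
      stop("vocabulary error: unknown quality label(s) ",
           paste(bad_q, collapse = ", "))
    ids <- unique(df[, id_cols])
    if (anyDuplicated(ids$trial_id))
      stop("integrity error: trial_id maps to conflicting drug/panellist/days")
    scores <- matrix(0L, nrow(ids), length(vocab),
                     dimnames = list(NULL, unclass(vocab)))
    row_of <- match(df$trial_id, ids$trial_id)
    col_of <- match(df$quality, unclass(vocab))
    sc <- df$score
    sc[is.na(sc)] <- 0L
    scores[cbind(row_of, col_of)] <- as.integer(sc)
    trials <- ids
  }
  if (any(is.na(scores)) || any(scores < 0L) || any(scores > 3L))
    stop("range error: scores must lie in {0,1,2,3}")
  trials$trial_id <- as.character(trials$trial_id)
  trials$drug_id <- as.character(trials$drug_id)
  trials$panellist_id <- as.character(trials$panellist_id)
  trials$days <- as.integer(trials$days)
  if (any(is.na(trials$days)) || any(trials$days < 0L))
    stop("range error: days must be non-negative integers")
  if (anyDuplicated(trials$trial_id))
    stop("integrity error: duplicate trial_id")
  out <- cbind(trials, as.data.frame(scores, check.names = FALSE))
  attr(out, "vocabulary") <- vocab
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Read the binary therapeutic-use matrix and its category map
#'
#' The use matrix records, for every drug, whether it is recommended (1) or
#' not (0) for each of the 46 therapeutic uses. The category map assigns
#' every use to one of at most 25 broader categories of use; therapeutic
#' versatility is counted over categories, not raw uses.
#'
#' @param path path to the binary matrix file: first column `drug_id`, one
#'   column per use.
#' @param category_path path to a two-column file `use_id`, `category_id`.
#' @param sep field separator.
#' @return an object of class `use_matrix`: a list with `matrix` (integer
#'   drugs x uses matrix, dimnames set) and `category_map` (named character
#'   vector use -> category).
#' @export
load_use_matrix <- function(path, category_path, sep = ",") {
  df <- read_delim_table(path, sep)
  require_columns(df, "drug_id", "use matrix")
  cm <- read_delim_table(category_path, sep)
  require_columns(cm, c("use_id", "category_id"), "category map")
  use_ids <- setdiff(names(df), "drug_id")
  m <- as.matrix(df[, use_ids, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(!m %in% c(0L, 1L)))
    stop("range error: use matrix entries must be 0 or 1")
  rownames(m) <- as.character(df$drug_id)
  if (anyDuplicated(rownames(m)))
    stop("integrity error: duplicate drug_id in use matrix")
  category_map <- stats::setNames(as.character(cm$category_id),
                                  as.character(cm$use_id))
  unmapped <- setdiff(use_ids, names(category_map))
  if (length(unmapped))
    stop("mapping error: use(s) without category: ",
         paste(unmapped, collapse = ", "))
  category_map <- category_map[use_ids]
  new_use_matrix(m, category_map)
}

new_use_matrix <- function(m, category_map) {
  stopifnot(identical(colnames(m), names(category_map)))
  structure(list(matrix = m, category_map = category_map),
            class = "use_matrix")
}

#' @export
print.use_matrix <- function(x, ...) {
  cat("Therapeutic-use matrix: ", nrow(x$matrix), " drugs x ",
      ncol(x$matrix), " uses, ",
      length(unique(x$category_map)), " categories\n", sep = "")
  invisible(x)
}

score_matrix <- function(trials) {
  vocab <- attr(trials, "vocabulary")
  as.matrix(trials[, unclass(vocab), drop = FALSE])
}

#' Cross-validate a loaded panel dataset
#'
#' Checks referential integrity between the drug, trial and use tables and
#' tallies the dataset: trials, drugs, panellists, and perception reports
#' (the number of non-zero trial x quality scores, i.e. the sum of per-trial
#' complexity).
#'
#' @param drugs a `drug_table`.
#' @param trials a `trial_table`.
#' @param uses a `use_matrix`.
#' @return an object of class `validation_report`: list with `errors`
#'   (data.frame `severity`, `message`, `locator`) and `counts`. A dataset
#'   is analysable iff no entry has severity `"error"`.
#' @export
validate_dataset <- function(drugs, trials, uses) {
  errs <- list()
  note <- function(severity, message, locator = NA_character_) {
    errs[[length(errs) + 1L]] <<- data.frame(
      severity = severity, message = message, locator = locator,
      stringsAsFactors = FALSE)
  }
  unknown <- setdiff(trials$drug_id, drugs$drug_id)
  for (d in unknown)
    note("error", paste0("trial references unknown drug '", d, "'"),
         paste(trials$trial_id[trials$drug_id == d], collapse = ","))
  no_use_row <- setdiff(drugs$drug_id, rownames(uses$matrix))
  for (d in no_use_row)
    note("error", paste0("drug '", d, "' has no therapeutic-use row"), d)
  untasted <- setdiff(drugs$drug_id, trials$drug_id)
  if (length(untasted))
    note("warning", paste0(length(untasted), " drug(s) without any trial"),
         paste(untasted, collapse = ","))
  if (nrow(trials) == 0L) note("warning", "trial table is empty")
  sm <- score_matrix(trials)
  counts <- list(
    trials = nrow(trials),
    drugs = nrow(drugs),
    panellists = length(unique(trials$panellist_id)),
    perception_reports = sum(sm > 0L))
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(severity = character(), message = character(),
               locator = character(), stringsAsFactors = FALSE)
  structure(list(errors = errors, counts = counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Panel dataset validation\n")
  cat(sprintf("  trials: %d  drugs: %d  panellists: %d  perception reports: %d\n",
              x$counts$trials, x$counts$drugs, x$counts$panellists,
              x$counts$perception_reports))
  n_err <- sum(x$errors$severity == "error")
  n_warn <- sum(x$errors$severity == "warning")
  cat(sprintf("  %d error(s), %d warning(s)\n", n_err, n_warn))
  if (nrow(x$errors))
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [%s] %s\n", x$errors$severity[i], x$errors$message[i]))
  invisible(x)
}

#' @rdname validate_dataset
#' @param report a `validation_report`.
#' @export
is_loadable <- function(report) {
  !any(report$errors$severity == "error")
}

#' Write a panel dataset to delimited text files
#'
#' Inverse of the loaders: writes the drug table, the wide-layout trial
#' table, the use matrix and the category map so that reloading reproduces
#' the tables field by field.
#'
#' @param drugs,trials,uses the three tables.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return invisibly, the named character vector of file paths written.
#' @export
write_dataset <- function(drugs, trials, uses, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(drugs = file.path(dir, "drugs.csv"),
             trials = file.path(dir, "trials.csv"),
             uses = file.path(dir, "uses.csv"),
             categories = file.path(dir, "use_categories.csv"))
  utils::write.table(drugs, paths["drugs"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(trials, paths["trials"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  um <- data.frame(drug_id = rownames(uses$matrix),
                   as.data.frame(uses$matrix, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(um, paths["uses"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  cm <- data.frame(use_id = names(uses$category_map),
                   category_id = unname(uses$category_map))
  utils::write.table(cm, paths["categories"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
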