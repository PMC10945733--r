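#' Default chemosensory quality vocabulary
#'
#' The tasting-panel protocol scores every botanical drug sample on a fixed
#' set of exactly 22 chemosensory descriptors (tastes, flavours and
#' chemesthetic sensations), each on a 4-point ordinal scale: absent (0),
#' weak (1), medium (2), strong (3). The vocabulary is an ordered character
#' vector; its order fixes the column order of every score matrix, design
#' matrix and effect map in the package.
#'
#' @param qualities character vector of descriptor labels. Must contain
#'   exactly 22 unique, non-empty labels.
#' @return an object of class `quality_vocabulary` (a character vector of
#'   length 22 with attribute `n = 22`).
#' @examples
#' v <- quality_vocabulary()
#' length(v) # 22
#' @export
quality_vocabulary <- function(qualities = default_qualities()) {
  qualities <- as.character(qualities)
  if (length(qualities) != 22L)
    stop("a quality vocabulary must contain exactly 22 descriptors, got ",
         length(qualities))
  if (anyDuplicated(qualities))
    stop("duplicate quality labels: ",
         paste(unique(qualities[duplicated(qualities)]), collapse = ", "))
  if (any(!nzchar(qualities)))
    stop("empty quality labels are not allowed")
  structure(qualities, class = "quality_vocabulary")
}

#' @rdname quality_vocabulary
#' @export
default_qualities <- function() {
  c("bitter", "sweet", "sour", "salty", "astringent", "aromatic",
    "herby_leafy", "stinging", "starchy", "musky", "soapy", "nutty",
    "woody", "mucilaginous", "balsamic", "burning_hot", "fresh_cooling",
    "smoky", "earthy", "fruity", "resinous", "spicy")
}

#' @export
print.quality_vocabulary <- function(x, ...) {
  cat("Chemosensory quality vocabulary (22 descriptors):\n")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

as_vocabulary <- function(vocab) {
  if (inherits(vocab, "quality_vocabulary")) vocab else quality_vocabulary(vocab)
}
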