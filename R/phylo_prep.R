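## Phylogeny preparation: Newick parsing, grafting of analysis taxa missing
## from the supertree onto the most recent common ancestor of their genus
## (family as fallback), ultrametricity maintenance, and construction of the
## phylogenetic correlation matrix used as a random-effect covariance.

taxon_label <- function(x) gsub("[ ]+", "_", trimws(x))

#' Root-to-tip height and ultrametricity of a tree
#'
#' A tree is treated as ultrametric when every root-to-tip path length
#' equals the tree height within a relative tolerance (default 1e-8).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative tolerance on root-to-tip path differences.
#' @return `tree_height()`: the maximum root-to-tip path length.
#'   `is_ultrametric_tree()`: logical.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' @rdname tree_height
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (h - min(depths)) <= tol * h
}

#' Parse a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the
#' downstream analysis needs: branch lengths present and non-negative,
#' unique tip labels, and an ultrametricity flag. Non-ultrametric input is
#' flagged (attribute `ultrametric`), never silently corrected; see
#' [repair_ultrametric()].
#'
#' @param text a Newick string, or `NULL` to read from `file`.
#' @param file path to a Newick file.
#' @param tol relative ultrametricity tolerance.
#' @return a `phylo` with logical attribute `ultrametric`.
#' @export
parse_newick <- function(text = NULL, file = NULL, tol = 1e-8) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: input does not encode a single rooted tree")
  if (is.null(tree$edge.length))
    stop("Newick parse error: branch lengths are required")
  if (any(tree$edge.length < 0))
    stop("Newick parse error: negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("Newick parse error: duplicate tip labels")
  attr(tree, "ultrametric") <- is_ultrametric_tree(tree, tol)
  tree
}

#' Repair small ultrametricity violations
#'
#' Extends every tip's pendant edge so that all root-to-tip paths equal the
#' current maximum. Intended for numerical drift in published supertrees;
#' it is only applied when called explicitly.
#'
#' @param tree a `phylo`.
#' @return an ultrametric `phylo`.
#' @export
repair_ultrametric <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  h <- max(depths[seq_len(ntip)])
  tip_edge <- match(seq_len(ntip), tree$edge[, 2L])
  tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] +
    (h - depths[seq_len(ntip)])
  attr(tree, "ultrametric") <- TRUE
  tree
}

#' Build a genus/family rank map
#'
#' @param taxon character vector of taxon names (binomials).
#' @param genus genus per taxon; parsed from the binomial when omitted.
#' @param family family per taxon (may be `NA` where unknown).
#' @return data.frame of class `rank_map` with columns `taxon`, `genus`,
#'   `family`.
#' @export
rank_map <- function(taxon, genus = NULL, family = NA_character_) {
  taxon <- taxon_label(taxon)
  if (is.null(genus))
    genus <- vapply(strsplit(taxon, "_"), `[`, "", 1L)
  out <- data.frame(taxon = taxon, genus = as.character(genus),
                    family = rep_len(as.character(family), length(taxon)),
                    stringsAsFactors = FALSE)
  class(out) <- c("rank_map", "data.frame")
  out
}

tip_depths <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
}

## Attach one new tip so that the tree stays ultrametric. With >= 2
## candidate tips the attachment point is their MRCA; with exactly one, a
## new node is inserted at the midpoint of that tip's pendant edge (the
## MRCA of a single tip is undefined).
attach_tip <- function(tree, label, tip_idx) {
  h <- tree_height(tree)
  if (length(tip_idx) >= 2L) {
    node <- ape::getMRCA(tree, tip_idx)
    node_depth <- ape::node.depth.edgelength(tree)[node]
    ape::bind.tree(tree,
                   structure(list(edge = matrix(c(2L, 1L), 1L),
                                  tip.label = label,
                                  edge.length = h - node_depth,
                                  Nnode = 1L), class = "phylo"),
                   where = node)
  } else {
    edge_row <- match(tip_idx, tree$edge[, 2L])
    pend <- tree$edge.length[edge_row]
    new_tip <- structure(list(edge = matrix(c(2L, 1L), 1L),
                              tip.label = label,
                              edge.length = pend / 2,
                              Nnode = 1L), class = "phylo")
    ape::bind.tree(tree, new_tip, where = tip_idx, position = pend / 2)
  }
}

#' Graft analysis taxa missing from a supertree
#'
#' Taxa absent from the tree are attached to the most recent common
#' ancestor of their genus or, if the genus is absent, of their family;
#' pendant branch lengths are set so the result stays ultrametric. When the
#' genus (or family) is represented by a single tip, the new taxon is
#' attached at the midpoint of that tip's pendant edge. Taxa already in the
#' tree are left untouched (the operation is idempotent).
#'
#' @param tree an ultrametric `phylo`.
#' @param wanted character vector of taxon names required as tips.
#' @param ranks a [rank_map()] covering at least the wanted taxa; tree-tip
#'   genera are parsed from tip labels, and tip families are looked up via
#'   the genus -> family relation implied by `ranks`.
#' @param tol ultrametricity tolerance.
#' @return an ultrametric `phylo` containing every wanted taxon as a tip.
#' @export
graft_missing_taxa <- function(tree, wanted, ranks, tol = 1e-8) {
  if (!is_ultrametric_tree(tree, tol))
    stop("graft_missing_taxa requires an ultrametric tree; see repair_ultrametric()")
  wanted <- taxon_label(wanted)
  missing_rank <- setdiff(wanted, ranks$taxon)
  if (length(missing_rank))
    stop("rank map does not cover taxa: ", paste(missing_rank, collapse = ", "))
  genus_family <- unique(ranks[!is.na(ranks$family), c("genus", "family")])
  fam_of_genus <- stats::setNames(genus_family$family, genus_family$genus)
  unresolved <- character()
  for (tax in setdiff(wanted, taxon_label(tree$tip.label))) {
    row <- ranks[match(tax, ranks$taxon), ]
    tip_genus <- vapply(strsplit(taxon_label(tree$tip.label), "_"), `[`, "", 1L)
    in_genus <- which(tip_genus == row$genus)
    if (length(in_genus) == 0L && !is.na(row$family)) {
      tip_family <- unname(fam_of_genus[tip_genus])
      in_genus <- which(!is.na(tip_family) & tip_family == row$family)
    }
    if (length(in_genus) == 0L) {
      unresolved <- c(unresolved, tax)
      next
    }
    tree <- attach_tip(tree, tax, in_genus)
  }
  if (length(unresolved))
    stop("unresolvable taxa (genus and family absent from tree): ",
         paste(unresolved, collapse = ", "))
  if (!is_ultrametric_tree(tree, max(tol, 1e-10)))
    stop("internal error: grafting broke ultrametricity")
  attr(tree, "ultrametric") <- TRUE
  tree
}

#' Phylogenetic correlation matrix
#'
#' For an ultrametric tree, the correlation between two tips is the shared
#' root-to-MRCA path length divided by the tree height (so the matrix has a
#' unit diagonal and the phylogenetic variance component is on the same
#' scale as the other variance components, making h^2 a proportion). The
#' construction is invariant to rescaling all branch lengths.
#'
#' @param tree an ultrametric `phylo`.
#' @param taxa ordered taxon names selecting and ordering rows/columns;
#'   defaults to all tips.
#' @param tol ultrametricity tolerance.
#' @return a symmetric positive semi-definite matrix with unit diagonal and
#'   dimnames `taxa`.
#' @export
phylo_correlation <- function(tree, taxa = tree$tip.label, tol = 1e-8) {
  if (!is_ultrametric_tree(tree, tol))
    stop("phylo_correlation requires an ultrametric tree")
  taxa <- taxon_label(taxa)
  labels <- taxon_label(tree$tip.label)
  missing <- setdiff(taxa, labels)
  if (length(missing))
    stop("lookup error: taxa not in tree: ", paste(missing, collapse = ", "))
  V <- ape::vcv.phylo(tree, corr = FALSE)
  dimnames(V) <- list(labels, labels)
  A <- V / tree_height(tree)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A[taxa, taxa, drop = FALSE]
}

#' Write / read a correlation matrix as delimited text
#'
#' @param A matrix with taxon dimnames.
#' @param path file path.
#' @param sep field separator.
#' @export
write_correlation <- function(A, path, sep = ",") {
  df <- data.frame(taxon = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path, sep = ",") {
  df <- read_delim_table(path, sep)
  A <- as.matrix(df[, -1L, drop = FALSE])
  rownames(A) <- df$taxon
  storage.mode(A) <- "double"
  A
}
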