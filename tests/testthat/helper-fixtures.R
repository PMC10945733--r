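# In-code fixtures shared across test files. Everything is generated
# programmatically; nothing is read from disk except what the tests
# themselves write to tempdirs.

vocab22 <- quality_vocabulary()

# minimal three-table dataset: 3 drugs, 4 trials, 4 uses in 3 categories
tiny_dataset <- function() {
  drugs <- data.frame(
    drug_id = c("d1", "d2", "d3"),
    taxon_name = c("Cinnamomum verum", "Anemone coronaria", "Cinnamomum cassia"),
    genus = c("Cinnamomum", "Anemone", "Cinnamomum"),
    family = c("Lauraceae", "Ranunculaceae", "Lauraceae"),
    plant_part = c("bark", "root", "bark"),
    collection_date = NA_character_,
    stringsAsFactors = FALSE)
  class(drugs) <- c("drug_table", "data.frame")

  scores <- matrix(0L, 4, 22, dimnames = list(NULL, unclass(vocab22)))
  scores[1, c("bitter", "sweet")] <- c(2L, 1L)
  scores[2, "bitter"] <- 3L
  scores[3, c("aromatic", "sweet", "woody")] <- c(1L, 2L, 1L)
  trials <- cbind(
    data.frame(trial_id = paste0("t", 1:4),
               drug_id = c("d1", "d1", "d3", "d2"),
               panellist_id = c("p1", "p2", "p1", "p2"),
               days = c(10L, 12L, 5L, 30L), stringsAsFactors = FALSE),
    as.data.frame(scores, check.names = FALSE))
  attr(trials, "vocabulary") <- vocab22
  class(trials) <- c("trial_table", "data.frame")

  m <- matrix(c(1L, 1L, 0L, 0L,
                0L, 0L, 0L, 0L,
                1L, 0L, 1L, 1L), 3, 4, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"),
                              c("u_cough", "u_fever", "u_wound", "u_pain")))
  cmap <- c(u_cough = "respiratory", u_fever = "fever",
            u_wound = "topical", u_pain = "topical")
  uses <- phylotaste:::new_use_matrix(m, cmap)
  list(drugs = drugs, trials = trials, uses = uses)
}

# small synthetic dataset for engine-level tests (fast to generate);
# the higher quality baseline keeps all 22 qualities expressed even in a
# dataset of ~140 trials, so all-quality designs stay estimable
small_scenario <- function(seed = 7, quality_mu = 0.25, ...) {
  simulation_scenario(n_taxa = 20L, n_drugs = 25L, n_panellists = 3L,
                      n_uses = 3L, quality_mu = quality_mu, seed = seed, ...)
}

tiny_tree <- function() {
  parse_newick("((Cinnamomum_verum:1,Cinnamomum_cassia:1):1,Anemone_coronaria:2);")
}

# hand-rolled design for engine oracle tests (no random terms)
flat_design <- function(y, X, family) {
  structure(list(y = y, X = X, terms = list(), family = family,
                 response = "versatility", fixed = "qualities",
                 n_dropped = 0L, separation = character()),
            class = "design_data")
}
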