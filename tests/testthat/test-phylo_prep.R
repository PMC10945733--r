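test_that("Newick parsing flags ultrametricity and rejects malformed input", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_true(attr(tr, "ultrametric"))
  expect_equal(tree_height(tr), 2)

  tr2 <- parse_newick("((A:1,B:2):1,C:2);")
  expect_false(attr(tr2, "ultrametric"))
  expect_true(attr(repair_ultrametric(tr2), "ultrametric"))

  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "parse error")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(parse_newick("((A,B),C);"), "branch lengths")
})

test_that("phylogenetic correlation is shared path length over height", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  A <- phylo_correlation(tr)
  expected <- matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 1), 3,
                     dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(A[c("A", "B", "C"), c("A", "B", "C")], expected)

  # scale invariance
  tr10 <- tr
  tr10$edge.length <- tr10$edge.length * 10
  expect_equal(phylo_correlation(tr10), A)

  # star tree -> identity
  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(unname(phylo_correlation(star)), diag(3))

  expect_error(phylo_correlation(tr, c("A", "Z")), "lookup error")
})

test_that("grafting attaches at genus MRCA with ultrametric pendant length", {
  tr <- parse_newick("((Quercus_robur:1,Quercus_ilex:1):1,Pinus_nigra:2);")
  ranks <- rank_map(c("Quercus_suber", "Quercus_robur", "Quercus_ilex",
                      "Pinus_nigra"),
                    family = c("Fagaceae", "Fagaceae", "Fagaceae", "Pinaceae"))
  out <- graft_missing_taxa(tr, "Quercus_suber", ranks)
  expect_true("Quercus_suber" %in% out$tip.label)
  expect_true(is_ultrametric_tree(out))
  # attached at the Quercus MRCA (depth 1): pendant length 1
  edge <- out$edge.length[match(match("Quercus_suber", out$tip.label),
                                out$edge[, 2])]
  expect_equal(edge, 1)

  # idempotence: taxon already present leaves the tree unchanged
  again <- graft_missing_taxa(out, "Quercus_suber", ranks)
  expect_equal(ape::cophenetic.phylo(again), ape::cophenetic.phylo(out))
})

test_that("grafting onto a single congener bisects its pendant edge", {
  tr <- parse_newick("((Quercus_robur:1,Fagus_sylvatica:1):1,Pinus_nigra:2);")
  ranks <- rank_map(c("Quercus_ilex", "Quercus_robur", "Fagus_sylvatica",
                      "Pinus_nigra"),
                    family = c("Fagaceae", "Fagaceae", "Fagaceae", "Pinaceae"))
  out <- graft_missing_taxa(tr, "Quercus_ilex", ranks)
  expect_true(is_ultrametric_tree(out))
  A <- phylo_correlation(out)
  # sister to Quercus_robur, diverging at depth 1.5 of height 2
  expect_equal(A["Quercus_ilex", "Quercus_robur"], 0.75)
})

test_that("family fallback is used when the genus is absent, else an error", {
  tr <- parse_newick("((Quercus_robur:1,Fagus_sylvatica:1):1,Pinus_nigra:2);")
  ranks <- rank_map(c("Castanea_sativa", "Quercus_robur", "Fagus_sylvatica",
                      "Pinus_nigra"),
                    family = c("Fagaceae", "Fagaceae", "Fagaceae", "Pinaceae"))
  out <- graft_missing_taxa(tr, "Castanea_sativa", ranks)
  expect_true(is_ultrametric_tree(out))
  # family MRCA of Fagaceae is at depth 1
  A <- phylo_correlation(out)
  expect_equal(A["Castanea_sativa", "Quercus_robur"], 0.5)

  orphan <- rank_map("Ginkgo_biloba", family = "Ginkgoaceae")
  expect_error(graft_missing_taxa(tr, "Ginkgo_biloba",
                                  rbind(ranks, orphan)),
               "unresolvable")
})

test_that("grafting preserves ultrametricity over random trees and graft sets", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    tr <- simulate_tree(n, seed = i)
    ranks <- attr(tr, "ranks")
    k <- sample(1:4, 1)
    genera <- unique(ranks$genus)
    new_taxa <- paste0(sample(genera, k, replace = TRUE),
                       "_novel", seq_len(k), i)
    fam_of <- ranks$family[match(sub("_.*", "", new_taxa), ranks$genus)]
    all_ranks <- rbind(ranks, rank_map(new_taxa, family = fam_of))
    out <- graft_missing_taxa(tr, new_taxa, all_ranks)
    expect_true(is_ultrametric_tree(out, tol = 1e-8))
    expect_true(all(new_taxa %in% out$tip.label))
    A <- phylo_correlation(out)
    expect_true(isSymmetric(A))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_true(all(A >= -1e-12 & A <= 1 + 1e-12))
  }
})

test_that("correlation of sister tips approaches 1 as divergence nears the present", {
  for (eps in c(0.1, 0.01, 0.001)) {
    txt <- sprintf("((A:%f,B:%f):%f,C:1);", eps, eps, 1 - eps)
    A <- phylo_correlation(parse_newick(txt))
    expect_equal(A["A", "B"], 1 - eps)
  }
})

test_that("correlation matrix round-trips through delimited text", {
  tr <- simulate_tree(8, seed = 3)
  A <- phylo_correlation(tr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation(A, path)
  A2 <- read_correlation(path)
  expect_equal(A2, A, tolerance = 1e-12)
})
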