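test_that("simulated trees are ultrametric, unit height, deterministic", {
  tr <- simulate_tree(12, seed = 5)
  expect_true(is_ultrametric_tree(tr))
  expect_equal(tree_height(tr), 1, tolerance = 1e-9)
  expect_length(tr$tip.label, 12L)
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(12, seed = 5)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_tree(12, seed = 6))))
  ranks <- attr(tr, "ranks")
  expect_s3_class(ranks, "rank_map")
  expect_setequal(ranks$taxon, tr$tip.label)
  expect_error(simulate_tree(1), "domain error")

  # two tips: single split, off-diagonal correlation in [0, 1)
  A2 <- phylo_correlation(simulate_tree(2, seed = 1))
  expect_gte(A2[1, 2], 0)
  expect_lt(A2[1, 2], 1)
})

test_that("scenario validation rejects inconsistent settings", {
  expect_error(simulation_scenario(vc_quality = c(phylo = -1, part = 0,
                                                  panellist = 0, resid = 1)),
               "variance components")
  expect_error(simulation_scenario(cutpoints = c(1, 0.5, 2)), "cutpoints")
  expect_error(simulation_scenario(n_taxa = 1), "n_taxa")
  expect_error(simulation_scenario(n_taxa = 50, n_drugs = 10), "n_drugs")
  expect_error(simulate_panel(small_scenario(
    use_effects = list(use1 = c(umami = 1)))), "unknown quality")
})

test_that("generated datasets are deterministic and pass validation", {
  sc <- small_scenario(seed = 3)
  sim1 <- simulate_panel(sc)
  sim2 <- simulate_panel(sc)
  expect_equal(sim1$trials, sim2$trials)
  expect_equal(sim1$uses$matrix, sim2$uses$matrix)
  expect_equal(sim1$truth$versatility, sim2$truth$versatility)

  rep <- validate_dataset(sim1$drugs, sim1$trials, sim1$uses)
  expect_true(is_loadable(rep))
  expect_equal(sum(rep$errors$severity == "error"), 0L)

  # file round trip through the panel_data readers
  dir <- withr::local_tempdir()
  write_dataset(sim1$drugs, sim1$trials, sim1$uses, dir)
  expect_equal(as.data.frame(load_trials(file.path(dir, "trials.csv"))),
               as.data.frame(sim1$trials))
})

test_that("zero variances and zero means give deterministic all-zero scores", {
  sc <- small_scenario(
    vc_quality = c(phylo = 0, part = 0, panellist = 0, resid = 0),
    quality_mu = 0)
  sim <- simulate_panel(sc)
  sm <- as.matrix(sim$trials[, unclass(vocab22)])
  expect_true(all(sm == 0L))
})

test_that("trial counts per drug match the scenario distribution", {
  sc <- simulation_scenario(n_taxa = 300L, n_drugs = 330L, seed = 10)
  sim <- simulate_panel(sc)
  n_t <- table(factor(sim$trials$drug_id, levels = sim$drugs$drug_id))
  expect_equal(mean(n_t), 5.7, tolerance = 0.03)  # ~1900 trials
  expect_equal(sd(n_t), 1.3, tolerance = 0.15)
  expect_true(all(n_t >= 1))
})

test_that("truth bundle reproduces the generated responses", {
  sim <- simulate_panel(small_scenario(seed = 9))
  # versatility must lie in the zero-truncated support
  expect_true(all(sim$truth$versatility$value >= 1))
  # drug-mean scores in the truth bundle agree with the trials table
  sm <- as.matrix(sim$trials[, unclass(vocab22)])
  qbar <- rowsum(sm, sim$trials$drug_id) /
    as.vector(table(factor(sim$trials$drug_id,
                           levels = sort(unique(sim$trials$drug_id)))))
  expect_equal(unname(sim$truth$qbar[rownames(qbar), ]), unname(qbar))
  expect_equal(dim(sim$truth$use_effects),
               c(22L, sim$truth$scenario$n_uses))
})
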