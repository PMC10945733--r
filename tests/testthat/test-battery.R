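# Battery orchestration with a deliberately short MCMC profile: these
# tests exercise seeding, skip rules and aggregation, not posterior
# accuracy (which the engine tests cover).

fast_mcmc <- function(seed = 1) {
  mcmc_settings(iterations = 600, thin = 6, burnin = 120, seed = seed)
}

test_that("battery runs 2 + 2-per-use models deterministically", {
  sim <- simulate_panel(small_scenario(seed = 7))
  ds <- list(drugs = sim$drugs, trials = sim$trials, uses = sim$uses)
  b1 <- run_battery(ds, sim$A, mcmc = fast_mcmc(11),
                    versatility = sim$truth$versatility)
  expect_s3_class(b1, "battery_result")
  expect_named(b1$versatility, c("qualities", "intensity_complexity"))
  expect_equal(length(b1$use_models), 3L)
  n_summaries <- 2L + sum(vapply(b1$use_models, function(u)
    sum(!vapply(u, function(f) isTRUE(f$skipped), TRUE)), 0L))
  expect_equal(n_summaries, 2L + 2L * 3L - length(b1$meta$skipped))

  # rerun with the same master seed reproduces every summary
  b2 <- run_battery(ds, sim$A, mcmc = fast_mcmc(11),
                    versatility = sim$truth$versatility)
  expect_equal(b1$versatility$qualities$coefficients,
               b2$versatility$qualities$coefficients)
  for (u in names(b1$use_models))
    expect_equal(b1$use_models[[u]], b2$use_models[[u]])
})

test_that("constant use indicators are skipped with a reason, not a crash", {
  sim <- simulate_panel(small_scenario(seed = 7))
  sim$uses$matrix[, "use2"] <- 1L
  ds <- list(drugs = sim$drugs, trials = sim$trials, uses = sim$uses)
  res <- run_use_models(ds, sim$A, mcmc = fast_mcmc(2))
  expect_true(res$use2$qualities$skipped)
  expect_match(res$use2$qualities$reason, "constant")
  expect_false(isTRUE(res$use1$qualities$skipped))
})

test_that("effect map masks betas at alpha and sums magnitudes", {
  # hand-built battery: one quality across three uses with known p_x
  mk_summary <- function(beta, px) {
    cf <- data.frame(term = c("(Intercept)", "bitter", "days"),
                     mean = c(0, beta, 0), mode = c(0, beta, 0),
                     lower = NA, upper = NA, px = c(0.5, px, 0.5),
                     px_doubled = pmin(1, 2 * c(0.5, px, 0.5)),
                     px_floor = 0.01, stringsAsFactors = FALSE)
    structure(list(coefficients = cf), class = "posterior_summary")
  }
  battery <- structure(list(
    versatility = list(),
    use_models = list(
      uA = list(qualities = mk_summary(0.5, 0.01)),
      uB = list(qualities = mk_summary(0.3, 0.20)),
      uC = list(qualities = mk_summary(-0.2, 0.03))),
    meta = list()), class = "battery_result")
  em <- effect_map(battery)
  expect_equal(unname(em$magnitude["bitter"]), 0.3)   # 0.5 - 0.2
  expect_equal(unname(em$total["bitter"]), 0.6)       # 0.5 + 0.3 - 0.2
  expect_equal(em$n_positive, 1L)
  expect_equal(em$n_negative, 1L)
  # nothing significant -> all magnitudes zero, totals unchanged
  em0 <- effect_map(battery, alpha = 1e-9)
  expect_equal(unname(em0$magnitude["bitter"]), 0)
  expect_equal(unname(em0$total["bitter"]), 0.6)
})

test_that("effect map magnitudes match an independent brute-force pass", {
  sim <- simulate_panel(small_scenario(seed = 7))
  ds <- list(drugs = sim$drugs, trials = sim$trials, uses = sim$uses)
  b <- run_battery(ds, sim$A, mcmc = fast_mcmc(5),
                   versatility = sim$truth$versatility)
  em <- effect_map(b, alpha = 0.05)
  for (q in rownames(em$beta)) {
    acc_sig <- 0; acc_all <- 0
    for (u in names(b$use_models)) {
      f <- b$use_models[[u]]$qualities
      if (isTRUE(f$skipped)) next
      row <- f$coefficients[f$coefficients$term == q, ]
      acc_all <- acc_all + row$mode
      if (row$px < 0.05) acc_sig <- acc_sig + row$mode
    }
    expect_equal(unname(em$magnitude[q]), acc_sig)
    expect_equal(unname(em$total[q]), acc_all)
  }
  expect_true(all(abs(em$magnitude) <= rowSums(abs(em$beta), na.rm = TRUE) + 1e-12))
})

test_that("skipped models contribute no cells to the effect map", {
  sim <- simulate_panel(small_scenario(seed = 7))
  sim$uses$matrix[, "use3"] <- 0L
  ds <- list(drugs = sim$drugs, trials = sim$trials, uses = sim$uses)
  b <- run_battery(ds, sim$A, mcmc = fast_mcmc(3),
                   versatility = sim$truth$versatility)
  em <- effect_map(b)
  expect_true(all(is.na(em$beta[, "use3"])))
  expect_false(any(em$mask[, "use3"]))
})
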