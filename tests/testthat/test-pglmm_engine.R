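# Engine correctness against independent oracles. The gaussian family has
# a closed-form conjugate posterior (OLS under the effectively flat
# default prior); the probit and zero-truncated Poisson families are
# checked on designs with known truth where the posterior is identified.

test_that("gaussian posterior matches the conjugate closed form", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    d <- flat_design(y, X, "gaussian")
    sp <- model_spec("versatility", family = "gaussian",
                     mcmc = mcmc_settings(iterations = 4000, thin = 4,
                                          burnin = 500, seed = i))
    ch <- sample_posterior(d, sp)
    ols <- qr.solve(X, y)
    post_sd <- apply(ch$beta, 2, sd)
    # posterior mean within Monte-Carlo error of the closed-form solution
    expect_lt(max(abs(colMeans(ch$beta) - ols) / post_sd), 0.25)
    # posterior spread close to the classical sampling covariance
    s2 <- sum((y - X %*% ols)^2) / (n - p)
    se <- sqrt(diag(s2 * solve(crossprod(X))))
    expect_lt(max(abs(post_sd / se - 1)), 0.35)
  }
})

test_that("probit intercept posterior is centred for a balanced response", {
  y <- rep(c(0, 1), each = 250)
  d <- flat_design(y, matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)")),
                   "probit")
  sp <- model_spec("use:u1", family = "probit",
                   priors = pglmm_priors(fix_resid = TRUE),
                   mcmc = mcmc_settings(iterations = 4000, thin = 4,
                                        burnin = 500, seed = 3))
  ch <- sample_posterior(d, sp)
  expect_lt(abs(mean(ch$beta)), 3 * sd(ch$beta) / sqrt(100))
  # matches the asymptotic standard error sqrt(p(1-p))/(phi(0) sqrt(n))
  expect_equal(sd(ch$beta), 0.5 / (dnorm(0) * sqrt(500)), tolerance = 0.2)
})

test_that("zero-truncated Poisson recovers a known rate", {
  set.seed(11)
  y <- as.numeric(rztpois(2000, 3))
  d <- flat_design(y, matrix(1, 2000, 1, dimnames = list(NULL, "(Intercept)")),
                   "zt_poisson")
  sp <- model_spec("versatility", family = "zt_poisson",
                   mcmc = mcmc_settings(iterations = 4000, thin = 4,
                                        burnin = 1000, seed = 4))
  ch <- sample_posterior(d, sp)
  expect_equal(exp(posterior_mode(ch$beta[, 1])), 3, tolerance = 0.1)
  # the adaptive Metropolis step lands in a workable acceptance range
  expect_gt(ch$accept_rate, 0.1)
  expect_lt(ch$accept_rate, 0.6)
})

test_that("chains are bit-reproducible given the seed", {
  sim <- simulate_panel(small_scenario(seed = 7))
  sp <- model_spec("versatility", family = "zt_poisson",
                   fixed = "intensity_complexity",
                   mcmc = mcmc_settings(iterations = 400, thin = 4,
                                        burnin = 100, seed = 42))
  d <- build_design(sim$trials, sim$drugs, sim$uses, sim$A, sp,
                    versatility = sim$truth$versatility)
  ch1 <- sample_posterior(d, sp)
  ch2 <- sample_posterior(d, sp)
  expect_identical(ch1$beta, ch2$beta)
  expect_identical(ch1$vc, ch2$vc)
  sp$mcmc$seed <- 43L
  ch3 <- sample_posterior(d, sp)
  expect_false(identical(ch1$beta, ch3$beta))
  # retained sample count honours iterations / thin
  expect_equal(nrow(ch1$beta), 100L)
  expect_true(all(ch1$vc > 0))
})

test_that("probit with a phylogenetic random effect recovers truth in an identified design", {
  set.seed(33)
  A <- phylo_correlation(simulate_tree(25, seed = 3))
  n <- 400
  idx <- sample(25, n, replace = TRUE)
  u <- drop(crossprod(chol(A), rnorm(25))) * sqrt(0.8)
  x <- rnorm(n)
  y <- as.numeric(-0.3 + 0.7 * x + u[idx] + rnorm(n) > 0)
  d <- structure(list(
    y = y, X = cbind("(Intercept)" = 1, x = x),
    terms = list(phylo = list(label = "phylo", index = idx,
                              levels = rownames(A), K = A)),
    family = "probit", response = "use:u1", fixed = "qualities",
    n_dropped = 0L, separation = character()), class = "design_data")
  sp <- model_spec("use:u1", family = "probit",
                   priors = pglmm_priors(fix_resid = TRUE),
                   mcmc = mcmc_settings(iterations = 20000, thin = 20,
                                        burnin = 2000, seed = 9))
  s <- summarize_chain(sample_posterior(d, sp))
  slope <- s$coefficients[s$coefficients$term == "x", ]
  expect_lt(slope$lower, 0.7)
  expect_gt(slope$upper, 0.7)
  expect_lt(slope$px, 0.05)
  expect_equal(unname(s$vc_modes["sig2_phylo"]), 0.8, tolerance = 0.5)
  expect_equal(s$h2_mode, 0.8 / 1.8, tolerance = 0.25)
})

test_that("truncated liability draws always respect the response sign", {
  set.seed(21)
  for (i in 1:20) {
    n <- 200
    y <- rbinom(n, 1, 0.5)
    mu <- rnorm(n, 0, 3)
    w <- phylotaste:::draw_liability(y, mu, sd = runif(1, 0.5, 2))
    expect_true(all(w[y == 1] >= 0))
    expect_true(all(w[y == 0] <= 0))
  }
})

test_that("level sums match a tapply oracle including empty levels", {
  set.seed(2)
  x <- rnorm(50)
  idx <- sample(c(1L, 2L, 4L), 50, replace = TRUE)   # level 3 empty
  got <- phylotaste:::level_sums(x, idx, 4L)
  want <- vapply(1:4, function(l) sum(x[idx == l]), 0)
  expect_equal(got, want)
})

test_that("non-positive-definite covariance raises a decomposition error", {
  ds <- tiny_dataset()
  A <- phylo_correlation(tiny_tree())
  sp <- model_spec("versatility", family = "gaussian",
                   fixed = "intensity_complexity",
                   mcmc = mcmc_settings(iterations = 100, thin = 1,
                                        burnin = 10, seed = 1))
  d <- build_design(ds$trials, ds$drugs, ds$uses, A, sp)
  d$terms$phylo$K <- matrix(1, 3, 3, dimnames = dimnames(A))  # rank 1
  expect_error(sample_posterior(d, sp), "decomposition error")
})

test_that("mcmc settings validate thinning and profiles", {
  expect_error(mcmc_settings(iterations = 100, thin = 3), "divide")
  s <- mcmc_settings(profile = "reference")
  expect_equal(s$iterations, 500000L)
  expect_equal(s$thin, 5000L)
  expect_equal(s$iterations / s$thin, 100L)
  expect_equal(mcmc_settings()$iterations, 20000L)
})
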