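test_that("retained-draw bookkeeping is exact", {
  cfg <- chain_config(n_chains = 2, n_iterations = 1000, burn_in = 400,
                      thinning = 10)
  d <- simulate_motif_dataset("SIM", seed = 3)
  fit <- run_metropolis(d, "SIM", config = cfg, seed = 3)
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 2 * (1000 - 400) / 10)
  expect_equal(sort(unique(tab$chain)), 1:2)
  expect_equal(unique(tab$iteration[tab$chain == 1]), seq(410, 1000, by = 10))
  expect_error(chain_config(n_iterations = 100, burn_in = 100))
  expect_error(chain_config(thinning = 0))
})

test_that("stored log-likelihoods reproduce recomputation from stored draws", {
  sf <- small_sim_fit()
  tab <- as.data.frame(sf$fit)
  set.seed(1)
  for (i in sample(nrow(tab), 15)) {
    ll <- log_likelihood(
      sf$data, "SIM",
      unlist(tab[i, c("beta_y", "alpha_y", "beta_z", "alpha_z")]),
      tab$sigma2[i]
    )
    expect_equal(ll, tab$log_lik[i], tolerance = 1e-8)
  }
})

test_that("reruns with the same seed are draw-for-draw identical", {
  cfg <- chain_config(n_chains = 2, n_iterations = 600, burn_in = 200,
                      thinning = 5)
  d <- simulate_motif_dataset("RC", seed = 4)
  f1 <- run_metropolis(d, "RC", config = cfg, seed = 11)
  f2 <- run_metropolis(d, "RC", config = cfg, seed = 11)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("a flat target accepts every proposal", {
  ch <- motifcompare:::metropolis_chain(
    function(u) 0, function(u) 0, c(0, 0),
    n_iterations = 500, burn_in = 100, thinning = 2, adapt = FALSE
  )
  expect_equal(ch$acceptance, 1)
})

test_that("a chain that cannot move raises a diagnostic error", {
  init <- c(0.3, -0.2)
  stuck_ll <- function(u) if (isTRUE(all.equal(u, init))) 0 else -Inf
  expect_error(
    motifcompare:::metropolis_chain(
      stuck_ll, function(u) 0, init,
      n_iterations = 300, burn_in = 100, thinning = 2, adapt = FALSE
    ),
    class = "motifcompare_stuck_chain"
  )
})

test_that("the sampler reproduces a conjugate Gaussian posterior", {
  toy <- conjugate_toy()
  set.seed(10)
  ch <- motifcompare:::metropolis_chain(
    function(u) toy$log_lik(u[1]), function(u) toy$log_prior(u[1]),
    0, n_iterations = 30000, burn_in = 5000, thinning = 5,
    proposal_scale = 0.5
  )
  draws <- ch$draws[, 1]
  n_eff <- length(draws) / 8 # conservative for autocorrelated draws
  mc_se_mean <- toy$post_sd / sqrt(n_eff)
  expect_lt(abs(mean(draws) - toy$post_mean), 3 * mc_se_mean)
  expect_lt(abs(sd(draws) - toy$post_sd), 3 * toy$post_sd / sqrt(2 * n_eff))
})

test_that("the sampler reproduces a 2-D Gaussian target", {
  mu <- c(1, -2)
  sds <- c(0.5, 2)
  rho <- 0.6
  Sig <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
  P <- solve(Sig)
  set.seed(11)
  ch <- motifcompare:::metropolis_chain(
    function(u) -0.5 * drop(t(u - mu) %*% P %*% (u - mu)),
    function(u) 0, c(0, 0),
    n_iterations = 40000, burn_in = 8000, thinning = 4
  )
  n_eff <- nrow(ch$draws) / 10
  for (j in 1:2) {
    expect_lt(abs(mean(ch$draws[, j]) - mu[j]), 3 * sds[j] / sqrt(n_eff))
  }
  expect_equal(cor(ch$draws)[1, 2], rho, tolerance = 0.1)
})

test_that("Gelman-Rubin flags agreement and disagreement correctly", {
  set.seed(14)
  base <- tibble::tibble(
    chain = rep(1:4, each = 2000),
    x = rep(exp(rnorm(2000, 0, 0.1)), 4)
  )
  # exact copies: B = 0, so rhat = sqrt((n - 1) / n) ~ 1
  expect_equal(gelman_rubin(base, params = "x")$rhat, 1, tolerance = 1e-3)
  apart <- base
  apart$x <- exp(log(apart$x) + apart$chain * 5) # chains far apart
  expect_gt(gelman_rubin(apart, params = "x")$rhat, 5)
  one <- base[base$chain == 1, ]
  expect_error(gelman_rubin(one, params = "x"),
    class = "motifcompare_contract_violation"
  )
})

test_that("the chain maximum equals an exhaustive scan of stored draws", {
  sf <- small_sim_fit()
  tab <- as.data.frame(sf$fit)
  ml <- max_likelihood_from_chains(sf$fit)
  i <- which.max(tab$log_lik)
  expect_equal(ml$log_lik, max(tab$log_lik))
  expect_equal(unname(ml$theta["beta_y"]), tab$beta_y[i])
  one <- sf$fit[7, ]
  attr(one, "param_names") <- attr(sf$fit, "param_names")
  ml1 <- max_likelihood_from_chains(one)
  expect_equal(ml1$log_lik, tab$log_lik[7])
})
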