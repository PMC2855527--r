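# archive-shaped tibble for the conjugate toy, with exact posterior draws
toy_archive <- function(toy, n = 10000, seed = 20) {
  set.seed(seed)
  mu_s <- rnorm(n, toy$post_mean, toy$post_sd)
  tibble::tibble(
    chain = 1L, iteration = seq_len(n), mu = mu_s,
    log_lik = vapply(mu_s, toy$log_lik, numeric(1)),
    log_prior = vapply(mu_s, toy$log_prior, numeric(1))
  )
}

test_that("the reciprocal importance sampler recovers an analytic evidence", {
  toy <- conjugate_toy()
  arch <- toy_archive(toy)
  ev <- log_evidence_gd(arch, transform = "identity", params = "mu")
  expect_lt(abs(ev$log_evidence - toy$log_evidence), 0.1)
  expect_lt(abs(ev$log_evidence - toy$log_evidence), 3 * max(ev$se, 0.01))
})

test_that("the estimate is invariant under draw permutation", {
  toy <- conjugate_toy()
  arch <- toy_archive(toy, n = 2000)
  set.seed(21)
  shuffled <- arch[sample(nrow(arch)), ]
  e1 <- log_evidence_gd(arch, transform = "identity", params = "mu")
  e2 <- log_evidence_gd(shuffled, transform = "identity", params = "mu")
  expect_equal(e1$log_evidence, e2$log_evidence, tolerance = 1e-12)
})

test_that("halving the archive moves the estimate within combined MC error", {
  sf <- small_sim_fit()
  full <- log_evidence_gd(sf$fit)
  half <- log_evidence_gd(sf$fit[seq(1, nrow(sf$fit), by = 2), ],
    params = attr(sf$fit, "param_names")
  )
  expect_lt(
    abs(full$log_evidence - half$log_evidence),
    3 * sqrt(full$se^2 + half$se^2) + 0.05
  )
})

test_that("an archive with no finite posterior density is flagged -Inf", {
  arch <- tibble::tibble(
    chain = 1L, iteration = 1:50, mu = rnorm(50),
    log_lik = rep(-Inf, 50), log_prior = 0
  )
  ev <- log_evidence_gd(arch, transform = "identity", params = "mu")
  expect_identical(ev$log_evidence, -Inf)
})

test_that("a singular draw covariance is ridge-regularized with a warning", {
  toy <- conjugate_toy()
  arch <- toy_archive(toy, n = 1000)
  arch$mu2 <- arch$mu # perfectly collinear second column
  expect_warning(
    ev <- log_evidence_gd(arch, transform = "identity",
                          params = c("mu", "mu2")),
    "ridge"
  )
  expect_true(is.finite(ev$log_evidence))
})
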