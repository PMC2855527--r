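test_that("noiseless data recover the generating parameters", {
  d <- simulate_motif_dataset("SIM", seed = 1, noise_sd = 0)
  fit <- least_squares_fit(d, "SIM", n_starts = 4)
  expect_equal(unname(fit$estimate), rep(1, 4), tolerance = 5e-3)
  expect_lt(fit$sigma2_hat, 1e-8)
  expect_lt(fit$rss, 1e-6)
})

test_that("the unbiased variance estimator divides by N - p", {
  d <- simulate_motif_dataset("SIM", seed = 9)
  fit <- least_squares_fit(d, "SIM", n_starts = 4)
  pred <- motifcompare:::predict_records(d, motif_model("SIM"), fit$estimate,
                                         rtol = 1e-8, atol = 1e-10)
  rss <- sum((d$value - pred)^2)
  expect_equal(fit$sigma2_hat, rss / (nrow(d) - 4), tolerance = 1e-6)
  # and the estimate should be near the truth with sensible intervals
  expect_equal(unname(fit$estimate), rep(1, 4), tolerance = 0.3)
  td <- tidy(fit)
  expect_true(all(is.finite(td$std.error)))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
})

test_that("an exponential-decay step matches the closed-form least squares", {
  # CONTROL.FLA in an OFF step is z' = -alpha z, z(0) = 1: z = exp(-alpha t);
  # the zero signal makes beta unidentifiable, so intervals must be flagged
  d <- simulate_ff_dataset("flagella", seed = 3, noise_sd = 0.02)
  off <- d[d$step == "OFF", ]
  doff <- motifcompare:::new_motif_dataset(
    off, list(steps = attr(d, "design")$steps["OFF"]),
    motif_model("CONTROL.FLA"), c(beta_z = 1, alpha_z = 1), 0.02, 3
  )
  fit <- suppressWarnings(least_squares_fit(doff, "CONTROL.FLA", n_starts = 4))
  # closed-form: alpha-hat minimises sum (z_i - exp(-alpha t_i))^2; golden
  # section over a fine grid is an adequate independent oracle
  grid <- seq(0.05, 3, by = 1e-4)
  rss_grid <- vapply(grid, function(a) {
    sum((off$value - exp(-a * off$time))^2)
  }, numeric(1))
  a_star <- grid[which.min(rss_grid)]
  expect_equal(unname(fit$estimate["alpha_z"]), a_star, tolerance = 2e-3)
})

test_that("a singular Hessian leaves the point estimate with NA intervals", {
  d <- simulate_ff_dataset("flagella", seed = 3, noise_sd = 0.02)
  off <- d[d$step == "OFF", ]
  doff <- motifcompare:::new_motif_dataset(
    off, list(steps = attr(d, "design")$steps["OFF"]),
    motif_model("CONTROL.FLA"), c(beta_z = 1, alpha_z = 1), 0.02, 3
  )
  expect_warning(fit <- least_squares_fit(doff, "CONTROL.FLA", n_starts = 4),
                 "intervals")
  expect_true(is.finite(fit$estimate["alpha_z"]))
  expect_true(anyNA(fit$se))
})
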