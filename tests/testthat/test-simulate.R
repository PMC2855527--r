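test_that("dataset sizes match the five study designs exactly", {
  d <- simulate_motif_dataset("SIM", seed = 1)
  expect_equal(nrow(d), 60)
  expect_equal(as.vector(table(d$variable)), c(30L, 30L))
  ara <- simulate_ff_dataset("ara", seed = 1)
  expect_equal(nrow(ara), 60)
  expect_equal(as.vector(table(ara$step)[c("ON", "OFF")]), c(30L, 30L))
  fla <- simulate_ff_dataset("flagella", seed = 1)
  expect_equal(nrow(fla), 37)
  expect_equal(as.vector(table(fla$step)[c("ON", "OFF")]), c(20L, 17L))
  gal <- simulate_ff_dataset("gal", seed = 1)
  expect_equal(nrow(gal), 15)
  expect_equal(unique(gal$step), "ON")
  # only the target z is monitored in the feed-forward designs
  expect_equal(unique(ara$variable), "z")
  expect_equal(unique(fla$variable), "z")
  expect_setequal(unique(d$variable), c("y", "z"))
  expect_error(simulate_ff_dataset("lac"), "arg")
  expect_error(simulate_motif_dataset("FF.C1.AND"),
               class = "motifcompare_unknown_model")
})

test_that("generation is reproducible under a seed", {
  a <- simulate_motif_dataset("RC", seed = 7)
  b <- simulate_motif_dataset("RC", seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c3 <- simulate_motif_dataset("RC", seed = 8)
  expect_false(identical(a$value, c3$value))
})

test_that("zero noise reproduces the integrated trajectory", {
  d <- simulate_motif_dataset("FF", seed = 1, noise_sd = 0)
  tr <- trajectory_wide(integrate_model(
    "FF", motif_model("FF")$default_params,
    motif_grid_signal(), sort(unique(d$time))
  ))
  for (v in c("y", "z")) {
    obs <- d$value[d$variable == v][order(d$time[d$variable == v])]
    expect_equal(obs, tr[[v]], tolerance = 1e-8)
  }
})

test_that("observation noise has the designed standard deviation", {
  resid <- unlist(lapply(1:40, function(s) {
    noisy <- simulate_motif_dataset("SIM", seed = s)
    clean <- simulate_motif_dataset("SIM", seed = s, noise_sd = 0)
    noisy$value - clean$value
  }))
  # 2400 draws: MC standard error of the sd is ~0.05/sqrt(2*2400)
  expect_equal(sd(resid), 0.05, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.01)
})

test_that("custom generating parameters flow through", {
  d <- simulate_motif_dataset("SIM", seed = 1, noise_sd = 0,
                              params = c(2, 1, 1, 1))
  tr <- trajectory_wide(integrate_model("SIM", c(2, 1, 1, 1),
    motif_grid_signal(), sort(unique(d$time))))
  expect_equal(max(d$value[d$variable == "y"]), max(tr$y), tolerance = 1e-8)
})
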