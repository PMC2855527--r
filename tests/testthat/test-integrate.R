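paper_grid <- seq(0, 10, length.out = 30)

test_that("linear motifs match the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  sig <- motif_grid_signal()
  set.seed(4)
  for (m in c("SIM", "RC", "FF")) {
    model <- motif_model(m)
    for (rep in 1:3) {
      p <- setNames(exp(rnorm(length(model$params), 0, 0.5)), model$params)
      tr <- trajectory_wide(
        integrate_model(m, p, sig, paper_grid, rtol = 1e-10, atol = 1e-12)
      )
      ref <- linear_motif_closed_form(m, p, sig, paper_grid)
      scale <- pmax(abs(ref), 1e-6)
      expect_lt(max(abs(as.matrix(tr[, c("y", "z")]) - ref) / scale), 1e-6)
    }
  }
  # SIM under constant signal: y(t) = 1 - exp(-t)
  tr <- trajectory_wide(integrate_model("SIM", c(1, 1, 1, 1),
    signal_profile(0, 1), c(0, 1, 2)))
  expect_equal(tr$y, 1 - exp(-c(0, 1, 2)), tolerance = 1e-7)
  expect_equal(tr$y[2], 0.632, tolerance = 1e-3)
})

test_that("zero signal and zero initial state stay at rest", {
  tr <- integrate_model("FF", c(1, 1, 1, 1, 1), signal_profile(0, 0),
                        paper_grid)
  expect_true(all(abs(tr$value) < 1e-12))
})

test_that("nesting holds on whole trajectories", {
  sig <- motif_grid_signal()
  base <- c(1.3, 0.8, 1.1, 0.9)
  sim <- integrate_model("SIM", base, sig, paper_grid)
  ff <- integrate_model("FF", c(1.3, 0.8, 1.1, 1e-300, 0.9), sig, paper_grid)
  expect_lt(max(abs(sim$value - ff$value)), 1e-7)
  rc <- integrate_model("RC", base, sig, paper_grid)
  ff2 <- integrate_model("FF", c(1.3, 0.8, 1e-300, 1.1, 0.9), sig, paper_grid)
  expect_lt(max(abs(rc$value - ff2$value)), 1e-7)
})

test_that("delay models reduce to the plain OR loop as the lag vanishes", {
  sig <- signal_profile(0, 1, pre_level = 0)
  p7 <- motif_model("FF.C1.OR.1")$default_params
  base <- integrate_model("FF.C1.OR.1", p7, sig, paper_grid)
  for (m in c("FF.C1.OR.2", "FF.C1.OR.3")) {
    tr <- integrate_model(m, c(p7, tau = 1e-9), sig, paper_grid)
    expect_lt(max(abs(tr$value - base$value)), 2e-3)
  }
})

test_that("nonlinear models agree with an independent general-purpose solver", {
  skip_if_not_installed("deSolve")
  sig <- motif_grid_signal()
  for (m in c("FB", "FF.I1.AND", "FF.C1.AND")) {
    model <- motif_model(m)
    p <- model$default_params
    ours <- trajectory_wide(
      integrate_model(m, p, sig, paper_grid, rtol = 1e-10, atol = 1e-12)
    )
    ref <- deSolve::ode(
      y = c(0, 0), times = paper_grid,
      func = function(t, state, parms) {
        list(unname(eval_rhs(m, state, t, p, sig)))
      },
      parms = NULL, rtol = 1e-10, atol = 1e-12
    )
    expect_lt(max(abs(as.matrix(ours[, c("y", "z")]) - ref[, 2:3])), 1e-6)
  }
})

test_that("the delay solver agrees with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  sig <- signal_profile(0, 1, pre_level = 0)
  p <- c(motif_model("FF.C1.OR.1")$default_params, tau = 0.8)
  ours <- trajectory_wide(integrate_model("FF.C1.OR.2", p, sig, paper_grid))
  ref <- deSolve::dede(
    y = c(0, 0), times = paper_grid,
    func = function(t, state, parms) {
      hist <- function(tt) {
        if (tt <= 0) c(0, 0) else deSolve::lagvalue(tt)
      }
      list(unname(eval_rhs("FF.C1.OR.2", state, t, p, sig, history = hist)))
    },
    parms = NULL
  )
  expect_lt(max(abs(as.matrix(ours[, c("y", "z")]) - ref[, 2:3])), 1e-3)
})

test_that("states remain non-negative for positive parameters", {
  set.seed(6)
  sig <- motif_grid_signal()
  for (m in c("SIM", "RC", "FF", "FB", "FF.C1.AND", "FF.I1.AND")) {
    model <- motif_model(m)
    p <- exp(rnorm(length(model$params), 0, 0.7))
    tr <- integrate_model(m, p, sig, paper_grid)
    expect_true(all(tr$value > -1e-8))
  }
})

test_that("a diverging solve is flagged, not silently returned", {
  expect_warning(
    tr <- integrate_model("SIM", c(1, 1e12, 1, 1), signal_profile(0, 1),
                          paper_grid),
    "solver failure"
  )
  expect_false(attr(tr, "ok"))
  expect_true(all(is.na(tr$value)))
})
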