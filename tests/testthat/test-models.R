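test_that("the registry holds the sixteen models with the right bookkeeping", {
  reg <- motif_models()
  expect_equal(nrow(reg), 16)
  counts <- setNames(reg$aic_param_count, reg$name)
  expect_equal(counts[["SIM"]], 4L)
  expect_equal(counts[["RC"]], 4L)
  expect_equal(counts[["FF"]], 5L)
  expect_equal(counts[["FB"]], 5L)
  expect_equal(counts[["FF.C1.AND"]], 7L)
  expect_equal(counts[["FF.C1.OR.1"]], 7L)
  expect_equal(counts[["FF.I1.AND"]], 7L)
  expect_equal(counts[["FF.C1.OR.2"]], 8L)
  expect_equal(counts[["FF.C1.OR.3"]], 8L)
  expect_equal(counts[["CONTROL.ARA"]], 4L)
  expect_equal(counts[["CONTROL.FLA"]], 2L)
  expect_equal(counts[["CONTROL.GAL"]], 4L)
  # only z is observed in the feed-forward subtype studies
  expect_equal(unname(reg$observed[reg$name == "FF.C1.AND"]), "z")
  expect_equal(unname(reg$observed[reg$name == "SIM"]), "y,z")
  expect_true(all(reg$delayed == (reg$name %in% c("FF.C1.OR.2", "FF.C1.OR.3"))))
  expect_error(motif_model("NOPE"), class = "motifcompare_unknown_model")
})

test_that("SIM rates of change match hand calculations", {
  sig <- signal_profile(0, 1)
  expect_equal(
    unname(eval_rhs("SIM", c(0, 0), 1, c(1, 1, 1, 1), sig)), c(1, 1)
  )
  expect_equal(
    unname(eval_rhs("SIM", c(1, 1), 1, c(1, 1, 1, 1), sig)), c(0, 0)
  )
})

test_that("FF nests SIM and RC at vanishing branch rates", {
  sig <- motif_grid_signal()
  set.seed(3)
  for (i in 1:20) {
    st <- runif(2, 0, 2)
    tt <- runif(1, 0, 10)
    p4 <- exp(rnorm(4, 0, 0.5))
    d_sim <- eval_rhs("SIM", st, tt, p4, sig)
    d_ff <- eval_rhs("FF", st, tt,
      c(beta_y = p4[1], alpha_y = p4[2], beta_zs = p4[3],
        beta_zy = 1e-300, alpha_z = p4[4]), sig)
    expect_equal(unname(d_ff), unname(d_sim), tolerance = 1e-12)
    d_rc <- eval_rhs("RC", st, tt, p4, sig)
    d_ff2 <- eval_rhs("FF", st, tt,
      c(beta_y = p4[1], alpha_y = p4[2], beta_zs = 1e-300,
        beta_zy = p4[3], alpha_z = p4[4]), sig)
    expect_equal(unname(d_ff2), unname(d_rc), tolerance = 1e-12)
  }
})

test_that("delay models demand a history accessor", {
  sig <- signal_profile(0, 1)
  p <- motif_model("FF.C1.OR.2")$default_params
  expect_error(eval_rhs("FF.C1.OR.2", c(0, 0), 1, p, sig),
    class = "motifcompare_contract_violation"
  )
  d <- eval_rhs("FF.C1.OR.2", c(0.5, 0.5), 1, p, sig,
    history = function(t) c(0.2, 0.2)
  )
  expect_true(all(is.finite(d)))
})

test_that("non-positive kinetic parameters are rejected", {
  sig <- signal_profile(0, 1)
  expect_error(eval_rhs("SIM", c(0, 0), 1, c(1, -1, 1, 1), sig),
    class = "motifcompare_invalid_parameter"
  )
})
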