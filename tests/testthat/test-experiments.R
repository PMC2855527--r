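tiny_chains <- chain_config(n_chains = 2, n_iterations = 3000, burn_in = 1500,
                            thinning = 5)

test_that("the motif grid driver emits one report per generating model", {
  cfg <- experiment_config("motif_grid",
    generating = c("SIM", "RC"), candidates = c("SIM", "RC"),
    config = tiny_chains, seed = 2
  )
  res <- run_motif_grid(cfg)
  expect_named(res$reports, c("SIM", "RC"))
  expect_equal(nrow(res$summary), 4) # 2 generating x 2 candidates
  expect_setequal(unique(res$summary$data_source), c("SIM", "RC"))
  expect_equal(sum(res$summary$top_evidence), 2)
  # end-to-end rerun with the same master seed is identical
  res2 <- run_motif_grid(cfg)
  expect_equal(res$summary, res2$summary, tolerance = 1e-12)
})

test_that("the feed-forward grid uses each system's own control model", {
  cfg <- experiment_config("ff_grid",
    generating = "gal", config = tiny_chains, seed = 3
  )
  res <- run_ff_grid(cfg)
  expect_named(res$reports, "gal")
  expect_setequal(
    res$summary$model,
    c("CONTROL.GAL", "FF.C1.AND", "FF.C1.OR.1", "FF.I1.AND")
  )
})

test_that("the flagella extension fits the delay models", {
  cfg <- experiment_config("flagella_extension",
    candidates = c("CONTROL.FLA", "FF.C1.OR.2"),
    config = tiny_chains, seed = 4
  )
  res <- run_ff_grid(cfg)
  expect_setequal(res$summary$model, c("CONTROL.FLA", "FF.C1.OR.2"))
  expect_true(all(is.finite(res$summary$log_evidence)))
})

test_that("experiment summaries export to CSV and JSON", {
  cfg <- experiment_config("motif_grid",
    generating = "SIM", candidates = "SIM", config = tiny_chains, seed = 5
  )
  res <- run_motif_grid(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_experiment(res, csv, js)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 1)
  expect_equal(jsonlite::read_json(js)$study, "motif_grid")
})

test_that("configs validate their model sets", {
  expect_error(experiment_config("motif_grid", generating = "NOPE"))
  expect_error(
    experiment_config("motif_grid", candidates = character(0)),
    "non-empty"
  )
})

test_that("cooperative variants run end to end and rank an identified row", {
  cfg <- chain_config(preset = "reduced")
  d <- simulate_motif_dataset("FB.H", seed = 23)
  ev <- vapply(c("SIM.H", "RC.H", "FF.H", "FB.H"), function(m) {
    fit <- run_metropolis(d, m, config = cfg, seed = 24)
    log_evidence_gd(fit)$log_evidence
  }, numeric(1))
  expect_equal(names(which.max(ev)), "FB.H")
})
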