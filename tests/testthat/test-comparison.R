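test_that("AIC reproduces the worked examples", {
  expect_equal(aic(102.99, 4), -197.98)
  expect_equal(aic(103.45, 5), -196.9)
  expect_equal(aic(0, 0), 0)
  expect_error(aic(1, -1))
})

test_that("the likelihood-ratio test matches its chi-squared form", {
  out <- lrt(102.99, 4, 103.45, 5)
  expect_equal(out$statistic, 0.92, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_gt(out$p_value, 0.05) # not significant at the 5% level
  same <- lrt(50, 2, 50, 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  boundary <- lrt(0, 1, qchisq(0.95, 1) / 2, 2)
  expect_equal(boundary$p_value, 0.05, tolerance = 1e-10)
  expect_error(lrt(10, 5, 12, 5), class = "motifcompare_not_nested")
  expect_error(lrt(10, 5, 12, 4), class = "motifcompare_not_nested")
  expect_error(lrt(10, 2, 5, 3), "worse")
})

test_that("Bayes factors carry the conventional interpretation", {
  eq <- bayes_factor(3, 3)
  expect_equal(eq$bf, 1)
  expect_equal(eq$category, "weak")
  expect_equal(bayes_factor(log(58.55), 0)$category, "decisive")
  expect_equal(bayes_factor(log(120), 0)$category, "overwhelming")
  expect_equal(bayes_factor(log(5), 0)$category, "substantial")
  expect_equal(bayes_factor(0, log(5))$category, "favours other model")
  rec <- bayes_factor(1, 0)$bf * bayes_factor(0, 1)$bf
  expect_equal(rec, 1, tolerance = 1e-12)
  inf <- bayes_factor(-3, -Inf)
  expect_identical(inf$bf, Inf)
  expect_equal(inf$category, "overwhelming")
})

test_that("constant-likelihood archives have zero effective parameters", {
  sf <- small_sim_fit()
  tab <- as.data.frame(sf$fit)
  i <- which.max(tab$log_lik)
  const <- sf$fit[rep(i, 100), ]
  for (a in c("param_names", "model", "solver")) {
    attr(const, a) <- attr(sf$fit, a)
  }
  out <- dic_pd(const, sf$data)
  expect_equal(out$pd, 0, tolerance = 1e-6)
  expect_equal(out$dic, out$mean_deviance, tolerance = 1e-6)
  out_joint <- dic_pd(const, sf$data, deviance = "joint")
  expect_equal(out_joint$pd, 0, tolerance = 1e-6)
})

test_that("comparison reports satisfy their internal identities", {
  sf <- small_sim_fit()
  cfg <- chain_config(n_chains = 3, n_iterations = 4000, burn_in = 2000,
                      thinning = 5)
  ff <- fit_cache("ff_small_on_sim", function() {
    run_metropolis(sf$data, "FF", config = cfg, seed = 6)
  })
  report <- rank_models(list(SIM = sf$fit, FF = ff), sf$data)
  expect_equal(nrow(report), 2)
  # AIC identity row by row
  expect_equal(report$aic, -2 * report$max_loglik + 2 * report$n_params)
  # DIC = mean deviance + pD, recomputed independently per row
  for (m in report$model) {
    fit <- if (m == "SIM") sf$fit else ff
    d <- dic_pd(fit, sf$data, m)
    row <- report[report$model == m, ]
    expect_equal(row$dic, d$mean_deviance + d$pd, tolerance = 1e-9)
    expect_equal(row$pd, d$pd, tolerance = 1e-9)
  }
  expect_true(attr(report, "best") %in% report$model)
  lt <- attr(report, "lrt")
  expect_equal(nrow(lt), 1)
  expect_equal(lt$simple, "SIM")
  expect_equal(lt$complex, "FF")
  expect_gte(lt$statistic, 0)
  expect_equal(lt$df, 1)
})

test_that("a missing fit yields a flagged gap row, not a failure", {
  sf <- small_sim_fit()
  expect_warning(
    report <- rank_models(list(SIM = sf$fit, FF = NULL), sf$data),
    "gap row"
  )
  expect_true(is.na(report$log_evidence[report$model == "FF"]))
  expect_equal(attr(report, "best"), "SIM")
})
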