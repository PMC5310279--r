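# One moderate simulated dataset shared across the strategy tests.
strong_ds <- local({
  cfg <- strong_signal_config(n = 200, p = 120, seed = 71)
  list(ds = simulate_dataset(cfg)$dataset,
       support = sprintf("G%05d", cfg$support))
})

test_that("CoxLasso selects the strong support and refits unpenalized", {
  res <- run_coxlasso(strong_ds$ds, n_folds = 5, seed = 71)
  expect_s3_class(res, "strategy_result")
  expect_true(all(strong_ds$support %in% res$selected_ids))
  expect_identical(res$refit$feature_ids, res$selected_ids)
  expect_true(all(res$provenance == "lasso_prior"))
  expect_true(res$r2 > 0 && res$r2 < 1)
  expect_true(res$concordance > 0.5)
  # refit metrics recompute identically from the stored selection
  refit <- fit_cox(strong_ds$ds, res$selected_ids)
  expect_equal(generalized_r2(refit), res$r2, tolerance = 1e-12)
  # determinism under the seed
  res2 <- run_coxlasso(strong_ds$ds, n_folds = 5, seed = 71)
  expect_identical(res$selected_ids, res2$selected_ids)
  expect_identical(res$refit$beta, res2$refit$beta)
})

test_that("CoxSis with d = p coincides with CoxLasso at the same seed", {
  ds <- strong_ds$ds
  a <- run_coxlasso(ds, n_folds = 5, seed = 3)
  b <- run_coxsis(ds, d = ds$p, n_folds = 5, seed = 3)
  expect_identical(a$selected_ids, b$selected_ids)
  expect_equal(a$refit$beta, b$refit$beta, tolerance = 1e-10)
})

test_that("CoxSis screens then selects within the survivors", {
  res <- run_coxsis(strong_ds$ds, d = 30, n_folds = 5, seed = 71)
  expect_lte(length(res$selected_ids), 30)
  expect_true(all(strong_ds$support %in% res$selected_ids))
  expect_true(all(res$provenance == "screened"))
})

test_that("CoxSisLasso augments the lasso prior via conditional screening", {
  cfg <- hidden_variable_config(n = 250, p = 120, rho = 0.5, beta0 = 1,
                                seed = 81)
  ds <- simulate_dataset(cfg)$dataset
  sis <- run_coxsis(ds, n_folds = 5, seed = 81)
  csl <- run_coxsislasso(ds, n_folds = 5, seed = 81)
  # the marginally hidden covariate is missed by marginal screening but
  # recovered through conditioning
  expect_false("G00004" %in% sis$selected_ids)
  expect_true("G00004" %in% csl$selected_ids)
  expect_true(all(csl$provenance %in% c("lasso_prior", "augmented")))
  expect_identical(names(csl$provenance), csl$selected_ids)
  # gamma defaults to 1/p
  expect_equal(csl$config_snapshot$gamma, 1 / ds$p)
  # supplying the CoxLasso selection as the prior set reproduces the result
  cl <- run_coxlasso(ds, n_folds = 5, seed = 81)
  csl2 <- run_coxsislasso(ds, n_folds = 5, seed = 81,
                          prior_set = cl$selected_idx)
  expect_identical(csl2$selected_ids, csl$selected_ids)
})

test_that("compare_strategies reports three comparable blocks", {
  cfg <- strong_signal_config(n = 260, p = 80, seed = 91)
  ds <- simulate_dataset(cfg)$dataset
  sp <- train_test_split(ds, n_train = 170, seed = 91)
  cmp <- compare_strategies(sp$train, sp$test, n_folds = 5, seed = 91)
  expect_named(cmp$strategies, c("CoxLasso", "CoxSis", "CoxSisLasso"))
  for (b in cmp$strategies) {
    expect_gte(b$test_concordance, 0)
    expect_lte(b$test_concordance, 1)
    expect_true(all(b$auc$auc >= 0 & b$auc$auc <= 1, na.rm = TRUE))
  }
  # provenance covers every selected feature
  for (b in cmp$strategies) {
    expect_identical(names(b$result$provenance), b$result$selected_ids)
  }
  # overlap summary covers the union of the selections
  expect_equal(sum(cmp$overlap$count),
               length(unique(unlist(lapply(cmp$strategies,
                                           function(b) b$result$selected_ids)))))
  expect_error(compare_strategies(sp$train, sp$train), "disjoint")
})

test_that("overlap_summary partitions the union into Venn regions", {
  sel <- list(A = c("x", "y", "z"), B = c("y", "z", "w"), C = c("z"))
  ov <- overlap_summary(sel)
  expect_equal(sum(ov$count), 4)
  expect_equal(ov$count[ov$region == "A&B&C"], 1L, ignore_attr = TRUE)
  expect_identical(ov$ids[ov$region == "A&B&C"], "z")
  expect_equal(ov$count[ov$region == "A&B"], 1L, ignore_attr = TRUE)
})
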