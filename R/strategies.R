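# The three end-to-end selection strategies and their comparison. Each
# strategy produces a strategy_result: the selected feature set, an
# UNPENALIZED Cox refit on that set (so standard errors, Wald tests,
# R-squared and concordance are all well defined), and a provenance tag per
# feature. The same cross-validation seed is reused across strategies so
# that differences are attributable to the selection logic, not fold noise.

strategy_result <- function(strategy, ds, selected_idx, provenance, config,
                            warnings = character(0)) {
  selected_idx <- sort(unname(selected_idx))
  refit <- fit_cox(ds, selected_idx)
  score <- risk_score(ds, refit)
  cidx <- if (length(selected_idx)) {
    concordance_index(score, ds$time, ds$event)
  } else 0.5
  structure(
    list(strategy = strategy,
         selected_ids = ds$feature_ids[selected_idx],
         selected_idx = selected_idx,
         refit = refit,
         wald = wald_report(refit),
         r2 = generalized_r2(refit),
         concordance = cidx,
         provenance = provenance[ds$feature_ids[selected_idx]],
         config_snapshot = config,
         warnings = warnings),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(x$strategy, "selected", length(x$selected_ids), "feature(s):",
      paste(utils::head(x$selected_ids, 12), collapse = ", "),
      if (length(x$selected_ids) > 12) "..." else "", "\n")
  cat(sprintf("refit R^2 = %.3f, concordance = %.3f\n", x$r2, x$concordance))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' CoxLasso: cross-validated lasso selection with unpenalized refit
#'
#' Fits the L1-penalized Cox model over the full feature set, selects the
#' nonzero coefficients at the cross-validated penalty, and refits an
#' unpenalized Cox model on the selection to obtain coefficients, standard
#' errors, Wald tests, generalized R-squared and concordance. An empty
#' lasso selection yields a null-model result with a warning flag.
#'
#' @param ds A [survival_dataset].
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed governing the fold assignment.
#' @param ... Further arguments to [cv_select_lambda()].
#' @return A `strategy_result`.
#' @export
run_coxlasso <- function(ds, n_folds = 10L, seed = 1L, ...) {
  warns <- character(0)
  sel <- withCallingHandlers(
    lasso_select(ds, n_folds = n_folds, seed = seed, ...),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  prov <- stats::setNames(rep("lasso_prior", length(sel)), names(sel))
  strategy_result("CoxLasso", ds, sel, prov,
                  config = list(n_folds = n_folds, seed = seed,
                                lambda_selected = attr(sel, "cv")$lambda_selected),
                  warnings = warns)
}

#' CoxSis: marginal screening, then the lasso on the survivors
#'
#' Step 1-2: rank all features by the absolute coefficient of their
#' one-covariate Cox fit and keep the top `d`. Step 3: run the
#' cross-validated lasso restricted to those `d` features, then refit
#' unpenalized on the final selection. At `d = p` the screen is a no-op and
#' the result coincides with [run_coxlasso()] under the same seed.
#'
#' @param ds A [survival_dataset].
#' @param d Screening budget; default `floor(n / log n)`.
#' @param n_folds,seed As in [run_coxlasso()].
#' @param ... Further arguments to [cv_select_lambda()].
#' @return A `strategy_result`.
#' @export
run_coxsis <- function(ds, d = default_d(ds$n), n_folds = 10L, seed = 1L, ...) {
  warns <- character(0)
  screen <- withCallingHandlers(
    marginal_screen(ds, d = d),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  theta <- resolve_features(ds, screen$selected_ids)
  ds_theta <- subset_features(ds, theta)
  sel_within <- withCallingHandlers(
    lasso_select(ds_theta, n_folds = n_folds, seed = seed, ...),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  sel <- sort(theta)[sel_within]
  prov <- stats::setNames(rep("screened", length(sel)), ds$feature_ids[sel])
  strategy_result("CoxSis", ds, sel, prov,
                  config = list(d = d, n_folds = n_folds, seed = seed,
                                lambda_selected = attr(sel_within, "cv")$lambda_selected),
                  warnings = warns)
}

#' CoxSisLasso: lasso-conditioned screening, then the lasso on the union
#'
#' The lasso-conditioned sure-independence-screening strategy:
#' \enumerate{
#'   \item Lasso over all features gives the prior set C0.
#'   \item Every feature outside C0 is tested in a Cox model jointly with
#'     C0; those with conditional Wald p-value below `gamma` (default
#'     `1/p`) form the augmentation C1.
#'   \item The cross-validated lasso restricted to `C0 + C1` picks the
#'     final selection, which is refit unpenalized.
#' }
#' The conditional step is what recovers covariates that are jointly but
#' not marginally associated with survival. If C0 comes back empty (the
#' conditioning step requires a nonempty prior) the marginal screen at
#' [default_d()] stands in for it, with a prominent warning.
#'
#' @param ds A [survival_dataset].
#' @param n_folds,seed As in [run_coxlasso()].
#' @param gamma Conditional screening threshold; default [gamma_rule()] of
#'   the full feature count.
#' @param prior_set Optional feature ids/indices to use as the lasso prior
#'   set C0 instead of recomputing it — typically the selection of a
#'   [run_coxlasso()] call with the same seed, which is what Step 1 would
#'   produce. Saves the duplicate full-data cross-validation when both
#'   strategies are run side by side.
#' @param ... Further arguments to [cv_select_lambda()].
#' @return A `strategy_result`; `provenance` distinguishes `"lasso_prior"`
#'   (C0) from `"augmented"` (C1) members.
#' @export
run_coxsislasso <- function(ds, n_folds = 10L, seed = 1L, gamma = NULL,
                            prior_set = NULL, ...) {
  warns <- character(0)
  catch_warn <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  c0 <- if (is.null(prior_set)) {
    unname(catch_warn(lasso_select(ds, n_folds = n_folds, seed = seed, ...)))
  } else {
    resolve_features(ds, prior_set)
  }
  c0 <- sort(c0)
  if (length(c0) == 0L) {
    warns <- c(warns, paste("empty lasso prior set; falling back to the",
                            "marginal screen as conditioning set"))
    warning("empty lasso prior set; conditioning on the marginal screen instead")
    c0 <- sort(resolve_features(ds, marginal_screen(ds)$selected_ids))
  }
  gamma <- gamma %||% gamma_rule(ds$p)
  cond <- catch_warn(conditional_screen(ds, c0, gamma = gamma))
  c1 <- sort(resolve_features(ds, cond$selected_ids))
  pool <- sort(union(c0, c1))
  ds_pool <- subset_features(ds, pool)
  sel_within <- catch_warn(lasso_select(ds_pool, n_folds = n_folds,
                                        seed = seed, ...))
  sel <- pool[sel_within]
  prov <- stats::setNames(
    ifelse(sel %in% c0, "lasso_prior", "augmented"),
    ds$feature_ids[sel]
  )
  strategy_result("CoxSisLasso", ds, sel, prov,
                  config = list(n_folds = n_folds, seed = seed, gamma = gamma,
                                c0_ids = ds$feature_ids[c0],
                                c1_ids = ds$feature_ids[c1],
                                lambda_selected = attr(sel_within, "cv")$lambda_selected),
                  warnings = warns)
}

#' Run and compare the three strategies on a train/test pair
#'
#' Runs CoxLasso, CoxSis and CoxSisLasso on the training set (sharing one
#' cross-validation seed so fold noise cannot drive the comparison), scores
#' every test sample by the refit linear predictor `x^T beta`, and reports
#' per-strategy training fit (R-squared, concordance), test concordance and
#' the test AUC(t) curve on a common time grid.
#'
#' @param ds_train,ds_test Disjoint [survival_dataset]s over the same
#'   features; the test set needs at least 2 events.
#' @param n_folds,seed,d,gamma Strategy controls, shared across strategies.
#' @param eval_times Optional increasing evaluation times for AUC(t);
#'   default: deciles (10%-70%) of the observed test event times.
#' @param estimator ROC estimator, `"km_cd"` (default) or `"naive"`.
#' @return An object of class `strategy_comparison`: per-strategy blocks
#'   (`result`, `test_concordance`, `auc`, `mean_auc`) plus the shared
#'   `eval_times` and the three-way selection [overlap_summary()].
#' @export
compare_strategies <- function(ds_train, ds_test, n_folds = 10L, seed = 1L,
                               d = default_d(ds_train$n), gamma = NULL,
                               eval_times = NULL,
                               estimator = c("km_cd", "naive")) {
  stopifnot(is_survival_dataset(ds_train), is_survival_dataset(ds_test))
  estimator <- match.arg(estimator)
  if (!identical(ds_train$feature_ids, ds_test$feature_ids)) {
    stop("train and test datasets must share the same features")
  }
  if (length(intersect(ds_train$sample_ids, ds_test$sample_ids)) > 0) {
    stop("train and test sample sets must be disjoint")
  }
  if (sum(ds_test$event) < 2) stop("test set must contain at least 2 events")
  if (is.null(eval_times)) {
    ev_times <- ds_test$time[ds_test$event == 1]
    eval_times <- unname(stats::quantile(ev_times, seq(0.1, 0.7, by = 0.1),
                                         type = 7))
  }
  coxlasso <- run_coxlasso(ds_train, n_folds = n_folds, seed = seed)
  results <- list(
    CoxLasso = coxlasso,
    CoxSis = run_coxsis(ds_train, d = d, n_folds = n_folds, seed = seed),
    CoxSisLasso = run_coxsislasso(ds_train, n_folds = n_folds, seed = seed,
                                  gamma = gamma,
                                  prior_set = coxlasso$selected_idx)
  )
  blocks <- lapply(results, function(res) {
    score <- risk_score(ds_test, res$refit)
    tc <- if (length(res$selected_idx)) {
      concordance_index(score, ds_test$time, ds_test$event)
    } else 0.5
    auc <- if (length(res$selected_idx)) {
      auc_over_time(score, ds_test$time, ds_test$event, eval_times, estimator)
    } else {
      data.frame(time = eval_times, auc = 0.5, n_cases = NA, n_controls = NA,
                 reason = "null model")
    }
    list(result = res, test_concordance = tc, auc = auc,
         mean_auc = mean(auc$auc, na.rm = TRUE))
  })
  structure(
    list(strategies = blocks, eval_times = eval_times,
         overlap = overlap_summary(lapply(results, `[[`, "selected_ids")),
         seed = seed),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  for (nm in names(x$strategies)) {
    b <- x$strategies[[nm]]
    cat(sprintf("%-12s train R^2 %.3f  train C %.3f  test C %.3f  mean AUC %.3f  (%d features)\n",
                nm, b$result$r2, b$result$concordance, b$test_concordance,
                b$mean_auc, length(b$result$selected_ids)))
  }
  invisible(x)
}

#' Three-way selection overlap summary
#'
#' Counts of features per intersection region of up to three selections —
#' the textual analogue of a Venn diagram.
#'
#' @param selections Named list of character vectors of feature ids.
#' @return Data frame with columns `region` (e.g. `"CoxLasso&CoxSis"`),
#'   `count` and `ids`.
#' @export
overlap_summary <- function(selections) {
  stopifnot(is.list(selections), !is.null(names(selections)))
  all_ids <- unique(unlist(selections))
  membership <- vapply(selections, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L)
  region <- apply(membership, 1L, function(m) {
    paste(names(selections)[m], collapse = "&")
  })
  agg <- split(all_ids, region)
  out <- data.frame(
    region = names(agg),
    count = lengths(agg),
    ids = vapply(agg, function(v) paste(sort(v), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$count, out$region), ]
}
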