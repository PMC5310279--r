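# L1-penalized Cox partial likelihood: the regularization path, cross-
# validated lambda selection and sparse coefficient extraction. The convex
# solver is glmnet's coordinate descent (Breslow ties, matching cox_core);
# this module fixes the grid, the fold construction and the KKT verification
# around it, and reports everything on the original covariate scale.

# glmnet-convention standardization: center by the mean, scale by the
# population (1/n) standard deviation.
standardize_design <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colMeans(Xc^2))
  if (any(scl == 0)) {
    stop("constant feature(s) cannot be standardized: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  }
  list(X = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}

#' Smallest penalty with an all-zero solution
#'
#' By the KKT stationarity conditions of the L1-penalized partial likelihood,
#' the all-zero coefficient vector is optimal exactly when
#' \eqn{\lambda \ge \max_j |g_j(0)| / n}, with \eqn{g(0)} the
#' partial-likelihood gradient at zero on the standardized design. This value
#' anchors the top of every lambda grid.
#'
#' @param ds A [survival_dataset].
#' @return Positive scalar `lambda_max`.
#' @export
lambda_max <- function(ds) {
  stopifnot(is_survival_dataset(ds))
  std <- standardize_design(ds$X)
  prep <- cox_prep(ds$time, ds$event)
  g0 <- cox_pl_core(std$X, prep, numeric(ds$p))$gradient
  max(abs(g0)) / ds$n
}

# Log-spaced grid from lambda_max down to lambda_max * lambda_min_ratio.
lambda_grid <- function(ds, n_lambda, lambda_min_ratio = NULL) {
  lmax <- lambda_max(ds)
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (ds$p > ds$n) 0.01 else 1e-4
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit the lasso regularization path for the Cox model
#'
#' Solves the L1-penalized negative log partial likelihood over a log-spaced
#' grid of `n_lambda` penalties from [lambda_max()] down to
#' `lambda_max * lambda_min_ratio`, by cyclic coordinate descent on the
#' internally standardized design with warm starts along the grid.
#' Coefficients are reported back on the original covariate scale. Every
#' solution can be audited against the KKT stationarity conditions with
#' [lasso_kkt()].
#'
#' @param ds A [survival_dataset] with at least 10 samples and 2 events.
#' @param n_lambda Grid length (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest grid penalty;
#'   default 0.01 when `p > n`, else 1e-4.
#' @param thresh Coordinate-descent convergence threshold (default `1e-12`,
#'   tight enough that KKT residuals sit well below `1e-5`).
#' @return An object of class `lasso_path`: `lambdas` (decreasing), `coefs`
#'   (`n_lambda` x p, original scale), `nonzero_counts`, `standardization`.
#' @export
fit_lasso_path <- function(ds, n_lambda = 100L, lambda_min_ratio = NULL,
                           thresh = 1e-12) {
  stopifnot(is_survival_dataset(ds))
  if (ds$n < 10) stop("need at least 10 samples for a penalized path")
  grid <- lambda_grid(ds, n_lambda, lambda_min_ratio)
  y <- survival::Surv(ds$time, ds$event)
  fit <- glmnet::glmnet(ds$X, y, family = "cox", lambda = grid,
                        standardize = TRUE, thresh = thresh,
                        maxit = 10^6)
  if (length(fit$lambda) < length(grid)) {
    missing_l <- setdiff(signif(grid, 10), signif(fit$lambda, 10))
    stop("penalized solver did not return solutions at lambda = ",
         paste(signif(missing_l, 4), collapse = ", "))
  }
  coefs <- t(as.matrix(fit$beta))          # n_lambda x p, original scale
  dimnames(coefs) <- list(NULL, ds$feature_ids)
  std <- standardize_design(ds$X)
  # clamp floating-point dust at the KKT boundary to exact zeros
  coefs[abs(sweep(coefs, 2L, std$scale, "*")) < 1e-12] <- 0
  structure(
    list(lambdas = grid, coefs = coefs,
         nonzero_counts = as.integer(rowSums(coefs != 0)),
         standardization = list(center = std$center, scale = std$scale)),
    class = "lasso_path"
  )
}

#' KKT residuals along a lasso path
#'
#' Independent optimality audit of a [fit_lasso_path()] result: at each grid
#' penalty, the exact partial-likelihood gradient `g/n` on the standardized
#' design must satisfy `|g_j/n| <= lambda` for zero coefficients and
#' `g_j/n = lambda * sign(beta_j)` for active ones. Returns the worst
#' violation of each kind per lambda (0 when the condition holds).
#'
#' @param ds The [survival_dataset] the path was fit on.
#' @param path A `lasso_path`.
#' @return Data frame with columns `lambda`, `max_violation_zero`,
#'   `max_violation_active`, `nonzero`.
#' @export
lasso_kkt <- function(ds, path) {
  stopifnot(is_survival_dataset(ds), inherits(path, "lasso_path"))
  std <- standardize_design(ds$X)
  prep <- cox_prep(ds$time, ds$event)
  out <- lapply(seq_along(path$lambdas), function(i) {
    lam <- path$lambdas[i]
    beta_std <- path$coefs[i, ] * std$scale   # back to the standardized scale
    g <- cox_pl_core(std$X, prep, beta_std)$gradient / ds$n
    active <- beta_std != 0
    data.frame(
      lambda = lam,
      max_violation_zero = if (any(!active)) max(pmax(abs(g[!active]) - lam, 0)) else 0,
      max_violation_active = if (any(active)) max(abs(g[active] - lam * sign(beta_std[active]))) else 0,
      nonzero = sum(active)
    )
  })
  do.call(rbind, out)
}

# Seeded fold assignment stratified by event status, so no fold can be
# event-free whenever n_folds <= n_events.
make_folds <- function(event, n_folds, seed) {
  local_seed(seed, {
    ev <- sample(which(event == 1))
    cs <- sample(which(event == 0))
    foldid <- integer(length(event))
    foldid[ev] <- rep_len(seq_len(n_folds), length(ev))
    foldid[cs] <- rep_len(seq_len(n_folds), length(cs))
    foldid
  })
}

#' Cross-validated selection of the lasso penalty
#'
#' Assigns samples to `n_folds` folds by a seeded permutation stratified by
#' event status, then computes the cross-validated partial-likelihood
#' deviance per grid penalty with the Verweij-van Houwelingen construction
#' (the deviance contribution of fold k is
#' \eqn{-2[\ell_{full}(\hat\beta_{-k}) - \ell_{-k}(\hat\beta_{-k})]}).
#' The selected penalty minimizes the mean deviance ("lambda.min"); the more
#' conservative one-standard-error rule is available via `rule = "1se"`.
#'
#' @param ds A [survival_dataset].
#' @param n_folds Fold count, between 3 and the event count (default 10).
#' @param seed Integer seed for the fold permutation.
#' @param n_lambda,lambda_min_ratio Grid controls, as in [fit_lasso_path()].
#' @param rule `"min"` (default) or `"1se"`.
#' @param thresh Coordinate-descent threshold for the cross-validation fits
#'   (default `1e-6`): selecting a penalty needs far less coefficient
#'   precision than auditing a path, and the chosen lambda is stable well
#'   above this tolerance. Use [fit_lasso_path()] when tightly converged
#'   coefficients are needed.
#' @return An object of class `cv_result`: `lambdas`, `cv_deviance`,
#'   `cv_se`, `lambda_selected`, `fold_assignment_seed`, `foldid`, and the
#'   full-data `path`.
#' @export
cv_select_lambda <- function(ds, n_folds = 10L, seed = 1L, n_lambda = 100L,
                             lambda_min_ratio = NULL, rule = c("min", "1se"),
                             thresh = 1e-6) {
  stopifnot(is_survival_dataset(ds))
  rule <- match.arg(rule)
  n_events <- sum(ds$event == 1)
  if (n_folds < 3 || n_folds > n_events) {
    stop("n_folds must lie between 3 and the number of events (", n_events, ")")
  }
  foldid <- make_folds(ds$event, n_folds, seed)
  if (any(tabulate(foldid[ds$event == 1], n_folds) == 0L)) {
    foldid <- make_folds(ds$event, n_folds, seed + 1L)
    if (any(tabulate(foldid[ds$event == 1], n_folds) == 0L)) {
      stop("could not build folds with at least one event each")
    }
  }
  grid <- lambda_grid(ds, n_lambda, lambda_min_ratio)
  y <- survival::Surv(ds$time, ds$event)
  cv <- glmnet::cv.glmnet(ds$X, y, family = "cox", lambda = grid,
                          foldid = foldid, grouped = TRUE,
                          type.measure = "deviance", standardize = TRUE,
                          thresh = thresh, maxit = 10^6)
  sel <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  structure(
    list(lambdas = cv$lambda, cv_deviance = cv$cvm, cv_se = cv$cvsd,
         lambda_selected = sel, fold_assignment_seed = seed, foldid = foldid,
         glmnet_fit = cv$glmnet.fit, rule = rule),
    class = "cv_result"
  )
}

#' Lasso-selected feature set
#'
#' The nonzero-coefficient features at the cross-validated penalty of
#' [cv_select_lambda()] — the prior set C0 of the conditional-screening
#' strategy. An empty selection is returned as an empty index vector with
#' `attr(, "empty") = TRUE` and a warning; downstream strategies must handle
#' it.
#'
#' @inheritParams cv_select_lambda
#' @param ... Passed on to [cv_select_lambda()].
#' @return Sorted integer column indices into `ds$X`, named by feature id,
#'   with the `cv_result` attached as `attr(, "cv")`.
#' @export
lasso_select <- function(ds, n_folds = 10L, seed = 1L, ...) {
  cv <- cv_select_lambda(ds, n_folds = n_folds, seed = seed, ...)
  cf <- as.numeric(glmnet::coef.glmnet(cv$glmnet_fit, s = cv$lambda_selected,
                                       exact = FALSE))
  idx <- which(cf != 0)
  if (length(idx) == 0L) {
    warning("lasso selected no features at the cross-validated penalty")
    attr(idx, "empty") <- TRUE
  }
  names(idx) <- ds$feature_ids[idx]
  attr(idx, "cv") <- cv
  idx
}

#' Serialize a lasso path or CV result to TSV
#'
#' `write_lasso_path()` emits one row per grid penalty (lambda, nonzero
#' count); `write_cv_result()` emits the cross-validation curve (lambda,
#' mean deviance, its standard error, a flag at the selected penalty).
#'
#' @param x A `lasso_path` or `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lasso_path <- function(x, path) {
  stopifnot(inherits(x, "lasso_path"))
  df <- data.frame(lambda = x$lambdas, nonzero = x$nonzero_counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lasso_path
#' @export
write_cv_result <- function(x, path) {
  stopifnot(inherits(x, "cv_result"))
  df <- data.frame(lambda = x$lambdas, cv_deviance = x$cv_deviance,
                   cv_se = x$cv_se,
                   selected = x$lambdas == x$lambda_selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
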