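# Unpenalized Cox proportional hazards machinery: partial likelihood and its
# exact derivatives, Newton-Raphson fitting, Wald tests, Harrell's concordance
# and the generalized R-squared. These primitives power the marginal and
# conditional screens as well as the final refits of every strategy.

# Precompute the risk-set bookkeeping for a (time, event) pair. Samples are
# sorted by decreasing time so risk-set aggregates become cumulative sums; tied
# times share one risk set (Breslow convention), realised by pointing every
# member of a tie group at the group's last sorted position.
cox_prep <- function(time, event) {
  n <- length(time)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  es <- event[ord]
  runs <- rle(ts)
  tie_end <- rep.int(cumsum(runs$lengths), runs$lengths)
  list(
    n = n, ord = ord, time_sorted = ts, event_sorted = es,
    tie_end = tie_end, event_pos = which(es == 1L),
    n_events = sum(es == 1L)
  )
}

# Log partial likelihood, gradient and (optionally) the observed information
# at beta, for a design X already subset to the features of interest.
# Exponentials are shifted by the running maximum of the linear predictor so
# the risk-set sums cannot overflow.
cox_pl_core <- function(X, prep, beta, information = FALSE) {
  n <- prep$n
  p <- ncol(X)
  eta <- if (p == 0L) numeric(n) else drop(X %*% beta)
  es <- eta[prep$ord]
  Xs <- X[prep$ord, , drop = FALSE]
  M <- max(es)
  w <- exp(es - M)
  cs0 <- cumsum(w)
  ev <- prep$event_pos
  if (length(ev) == 0L) stop("dataset has no observed events")
  re <- prep$tie_end[ev]              # risk-set end position per event
  s0 <- cs0[re]
  value <- sum(es[ev]) - sum(log(s0) + M)
  if (p == 0L) {
    out <- list(value = value, gradient = numeric(0))
    if (information) out$information <- matrix(0, 0, 0)
    return(out)
  }
  cs1 <- apply(w * Xs, 2L, cumsum)
  if (is.null(dim(cs1))) cs1 <- matrix(cs1, nrow = n)
  U <- cs1[re, , drop = FALSE] / s0     # S1/S0 per event
  gradient <- colSums(Xs[ev, , drop = FALSE]) - colSums(U)
  out <- list(value = value, gradient = gradient)
  if (information) {
    # sum_k S2_k/S0_k collapses to a single weighted crossproduct: sample j
    # (sorted) appears in the risk set of every event whose tie_end >= j, so
    # its weight is w_j times the reverse-cumulated sum of 1/S0 over events.
    inv_acc <- numeric(n)
    contrib <- rowsum(1 / s0, re)
    inv_acc[as.integer(rownames(contrib))] <- contrib
    a <- rev(cumsum(rev(inv_acc)))
    out$information <- crossprod(Xs * sqrt(w * a)) - crossprod(U)
  }
  out
}

#' Cox log partial likelihood and its gradient
#'
#' Evaluates the log partial likelihood
#' \deqn{\ell(\beta) = \sum_{k \in D} \big[x_k^T\beta -
#'   \log \sum_{j \in R_k} \exp(x_j^T\beta)\big]}
#' over the event set \eqn{D} with risk sets \eqn{R_k} (all samples whose
#' follow-up time is at least the k-th event time), together with its exact
#' analytic gradient. Tied event times are handled with the Breslow
#' convention: ties share one risk set and each event contributes its own
#' term. The linear predictor is max-shifted before exponentiation, so the
#' computation is overflow-safe.
#'
#' @param ds A [survival_dataset].
#' @param features Integer indices or feature ids selecting columns of
#'   `ds$X`. May be empty, giving the null model.
#' @param beta Numeric coefficient vector, one entry per feature.
#' @return A list with elements `value` (scalar log partial likelihood) and
#'   `gradient` (numeric vector, one entry per feature).
#' @seealso [fit_cox()] which maximizes this objective.
#' @export
partial_loglik <- function(ds, features, beta) {
  stopifnot(is_survival_dataset(ds))
  idx <- resolve_features(ds, features)
  if (length(beta) != length(idx)) {
    stop("`beta` must have one entry per feature (got ", length(beta),
         " for ", length(idx), " features)")
  }
  prep <- cox_prep(ds$time, ds$event)
  res <- cox_pl_core(ds$X[, idx, drop = FALSE], prep, beta)
  if (!is.finite(res$value)) {
    stop("partial likelihood is non-finite; center/rescale the covariates")
  }
  res[c("value", "gradient")]
}

# Newton-Raphson with step-halving on the partial likelihood, from beta = 0.
# Returns the pieces needed by fit_cox(); shared by the screening loops which
# call it directly with a precomputed `prep` to avoid re-sorting.
cox_newton <- function(X, prep, beta_init = NULL, max_iter = 100L,
                       grad_tol = 1e-8, loglik_tol = 1e-10) {
  p <- ncol(X)
  null_val <- cox_pl_core(X[, 0L, drop = FALSE], prep, numeric(0))$value
  if (p == 0L) {
    return(list(beta = numeric(0), se = numeric(0), loglik = null_val,
                loglik_null = null_val, converged = TRUE, iterations = 0L,
                information = matrix(0, 0, 0)))
  }
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  cur <- cox_pl_core(X, prep, beta, information = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$information, cur$gradient), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("singular information matrix: collinear features ",
           paste(collinear_columns(X), collapse = ", "))
    }
    # step-halving: insist the log partial likelihood does not decrease
    halved <- 0L
    repeat {
      cand_beta <- beta + step
      cand <- cox_pl_core(X, prep, cand_beta, information = TRUE)
      if (is.finite(cand$value) && cand$value >= cur$value - 1e-12) break
      step <- step / 2
      halved <- halved + 1L
      if (halved > 30L) break
    }
    if (halved > 30L) break
    rel_change <- abs(cand$value - cur$value) / (abs(cur$value) + 1e-12)
    beta <- cand_beta
    cur <- cand
    if (max(abs(cur$gradient)) < grad_tol || rel_change < loglik_tol) {
      converged <- TRUE
      break
    }
  }
  cov <- tryCatch(solve(cur$information), error = function(e) NULL)
  if (is.null(cov)) {
    stop("singular information matrix: collinear features ",
         paste(collinear_columns(X), collapse = ", "))
  }
  se <- sqrt(pmax(diag(cov), 0))
  list(beta = beta, se = se, loglik = cur$value, loglik_null = null_val,
       converged = converged, iterations = iter, information = cur$information)
}

# Name the columns involved in a rank deficiency, for error messages.
collinear_columns <- function(X) {
  qrX <- qr(X)
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("column ", seq_len(ncol(X)))
  if (qrX$rank < ncol(X)) cols[qrX$pivot[(qrX$rank + 1L):ncol(X)]] else cols
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Maximizes the log partial likelihood over the requested feature subset by
#' Newton-Raphson with step-halving, started from `beta = 0`. Iteration stops
#' when the gradient max-norm drops below `1e-8` or the relative change in
#' log-likelihood falls below `1e-10`; standard errors come from the inverse
#' observed information at the maximum. With `features = integer(0)` the null
#' model is returned (`loglik == loglik_null`).
#'
#' A monotone (perfectly separating) likelihood does not converge within
#' `max_iter` iterations and is flagged via `converged = FALSE` rather than
#' raising an error; exactly collinear features raise an error naming them.
#'
#' @param ds A [survival_dataset].
#' @param features Column indices or feature ids; must number fewer than the
#'   event count and contain no constant column.
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `cox_fit`: `feature_ids`, `beta`, `se`,
#'   `loglik`, `loglik_null`, `n_samples`, `n_events`, `converged`,
#'   `iterations`.
#' @export
fit_cox <- function(ds, features, max_iter = 100L) {
  stopifnot(is_survival_dataset(ds))
  idx <- resolve_features(ds, features)
  n_events <- sum(ds$event == 1)
  if (length(idx) > 0 && length(idx) >= n_events) {
    stop("cannot fit ", length(idx), " coefficients with only ", n_events,
         " events; reduce the feature set")
  }
  X <- ds$X[, idx, drop = FALSE]
  if (length(idx) > 0) {
    const <- apply(X, 2L, function(col) max(col) == min(col))
    if (any(const)) {
      stop("constant feature(s) in design: ",
           paste(ds$feature_ids[idx][const], collapse = ", "))
    }
  }
  prep <- cox_prep(ds$time, ds$event)
  nt <- cox_newton(X, prep, max_iter = max_iter)
  structure(
    list(feature_ids = ds$feature_ids[idx], feature_idx = idx,
         beta = stats::setNames(nt$beta, ds$feature_ids[idx]),
         se = stats::setNames(nt$se, ds$feature_ids[idx]),
         loglik = nt$loglik, loglik_null = nt$loglik_null,
         n_samples = ds$n, n_events = n_events,
         converged = nt$converged, iterations = nt$iterations),
    class = "cox_fit"
  )
}

#' Wald tests and hazard ratios for a Cox fit
#'
#' @param fit A converged [fit_cox()] result with finite standard errors.
#' @return A data frame with one row per feature: `feature`, `coef`,
#'   `hazard_ratio` (`exp(coef)`), `se`, `z` (`coef/se`) and the two-sided
#'   normal `p_value`.
#' @export
wald_report <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (length(fit$beta) > 0 && any(!is.finite(fit$se))) {
    stop("non-finite standard errors; the fit is not valid for Wald testing")
  }
  z <- if (length(fit$beta)) fit$beta / fit$se else numeric(0)
  data.frame(
    feature = fit$feature_ids,
    coef = unname(fit$beta),
    hazard_ratio = exp(unname(fit$beta)),
    se = unname(fit$se),
    z = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
}

#' Harrell's concordance index
#'
#' Fraction of permissible sample pairs whose risk-score ordering agrees with
#' their survival ordering. A pair is permissible when its times differ and
#' the sample with the earlier time experienced the event (so the ordering of
#' the pair is known despite censoring). The pair is concordant when the
#' shorter survivor carries the higher risk score; tied scores earn half
#' credit.
#'
#' @param risk_score Numeric vector, higher = predicted shorter survival.
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk_score, time, event) {
  risk_score <- as.numeric(risk_score)
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- length(risk_score)
  stopifnot(length(time) == n, length(event) == n)
  earlier <- outer(time, time, "<")                      # [i,j]: t_i < t_j
  permissible <- earlier & (event == 1)                  # earlier member is an event
  n_perm <- sum(permissible)
  if (n_perm == 0) stop("no permissible pairs: concordance is undefined")
  higher <- outer(risk_score, risk_score, ">")           # s_i > s_j
  tied <- outer(risk_score, risk_score, "==")
  (sum(higher & permissible) + 0.5 * sum(tied & permissible)) / n_perm
}

#' Generalized (Cox-Snell) R-squared of a Cox fit
#'
#' \deqn{R^2 = 1 - \exp\{-\tfrac{2}{n}(\ell(\hat\beta) - \ell(0))\}}
#' with \eqn{n} the number of samples — the likelihood-ratio-based
#' goodness-of-fit statistic printed by standard Cox model summaries.
#'
#' @param fit A [fit_cox()] result.
#' @return A value in `[0, 1)`; 0 for the null model.
#' @export
generalized_r2 <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  1 - exp(-(2 / fit$n_samples) * (fit$loglik - fit$loglik_null))
}

#' Model-fit report for a Cox fit
#'
#' Formats the per-feature coefficient table (coef, exp(coef), se(coef), z,
#' p-value with significance stars at 0.001/0.01/0.05) followed by the
#' generalized R-squared and concordance lines, in the layout familiar from
#' Cox regression summaries.
#'
#' @param fit A [fit_cox()] result.
#' @param ds The [survival_dataset] the fit was computed on (for the
#'   concordance of the fitted risk score).
#' @return Character vector of report lines, invisibly printed by
#'   [print.cox_fit()].
#' @export
cox_report <- function(fit, ds) {
  w <- wald_report(fit)
  stars <- cut(w$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  tab <- sprintf("%-12s %9.5f %9.5f %9.5f %7.3f %10.3g %s",
                 w$feature, w$coef, w$hazard_ratio, w$se, w$z, w$p_value,
                 as.character(stars))
  header <- sprintf("%-12s %9s %9s %9s %7s %10s", "feature", "coef",
                    "exp(coef)", "se(coef)", "z", "p-value")
  score <- risk_score(ds, fit)
  cidx <- if (length(fit$beta)) concordance_index(score, ds$time, ds$event) else 0.5
  c(header, tab,
    sprintf("R^2 = %.3f, Concordance = %.3f", generalized_r2(fit), cidx),
    "Significance codes: 0 '***' 0.001 '**' 0.01 '*' 0.05")
}

# Linear risk score x_i^T beta on the fit's features.
risk_score <- function(ds, fit) {
  if (length(fit$beta) == 0L) return(numeric(ds$n))
  drop(ds$X[, fit$feature_idx, drop = FALSE] %*% unname(fit$beta))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit:", length(x$beta), "feature(s),", x$n_samples, "samples,",
      x$n_events, "events\n")
  cat("loglik", format(x$loglik), "(null", format(x$loglik_null), ")",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  if (length(x$beta)) {
    print(data.frame(coef = x$beta, se = x$se))
  }
  invisible(x)
}
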