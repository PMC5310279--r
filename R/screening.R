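# Sure independence screening for the Cox model: the marginal screen (rank
# one-covariate fits by |beta|, keep the top d) and the conditional screen
# (test each remaining covariate jointly with a prior set C0 and keep those
# with Wald p-value below gamma). The conditional screen is what lets the
# lasso-conditioned strategy recover covariates whose marginal association
# with survival is nulled by correlation with the active set.

#' Default screening size d = floor(n / log n)
#'
#' The customary sure-independence-screening budget: retain on the order of
#' `n / log(n)` covariates (natural log), enough for the subsequent lasso to
#' work in a moderate dimension without losing the sure-screening property.
#'
#' @param n Sample count, at least 8.
#' @return Integer `floor(n / log(n))`.
#' @export
default_d <- function(n) {
  if (n < 8) stop("default_d requires n >= 8")
  as.integer(floor(n / log(n)))
}

#' Conditional screening threshold gamma = 1/p
#'
#' The operating rule for the conditional screen: a candidate enters the
#' augmented set when its conditional Wald p-value falls below the
#' reciprocal of the total number of covariates — a Bonferroni-flavoured
#' threshold that tightens automatically with the dimension.
#'
#' @param p_total Total covariate count, at least 1.
#' @return `1 / p_total`.
#' @export
gamma_rule <- function(p_total) {
  if (p_total < 1) stop("p_total must be >= 1")
  1 / p_total
}

screening_result <- function(mode, candidate_ids, statistic, selected_ids,
                             d_or_gamma, conditioning_ids = character(0),
                             failed_ids = character(0)) {
  structure(
    list(mode = mode, candidate_ids = candidate_ids, statistic = statistic,
         selected_ids = selected_ids, d_or_gamma = d_or_gamma,
         conditioning_ids = conditioning_ids, failed_ids = failed_ids),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result (", x$mode, "): ", length(x$selected_ids), " of ",
      length(x$candidate_ids), " candidates selected (",
      if (x$mode == "marginal") paste0("d = ", x$d_or_gamma)
      else paste0("gamma = ", signif(x$d_or_gamma, 4)), ")\n", sep = "")
  invisible(x)
}

#' Write a screening report as TSV
#'
#' One row per candidate: feature id, statistic (`|beta_m|` or conditional
#' p-value), rank, selected flag, mode and the conditioning set.
#'
#' @param res A `screening_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(res, path) {
  stopifnot(inherits(res, "screening_result"))
  stat <- res$statistic
  rk <- if (res$mode == "marginal") rank(-stat, ties.method = "first")
        else rank(stat, ties.method = "first")
  df <- data.frame(
    feature = res$candidate_ids,
    statistic = unname(stat),
    rank = unname(rk),
    selected = res$candidate_ids %in% res$selected_ids,
    mode = res$mode,
    conditioning_set = paste(res$conditioning_ids, collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marginal sure independence screening
#'
#' Fits the one-covariate Cox model for every feature, ranks the absolute
#' marginal coefficients in decreasing order and retains the top `d` (ties
#' broken by original feature order). A feature whose marginal fit fails to
#' converge gets statistic 0 — it cannot be selected — and is recorded in
#' `failed_ids`.
#'
#' @param ds A [survival_dataset].
#' @param d Number of features to keep, `1 <= d <= p`; default
#'   [default_d()] of the sample count.
#' @return A `screening_result` with `mode = "marginal"`, the per-feature
#'   `statistic` (`|beta_m|`), and `selected_ids` of size `d`.
#' @export
marginal_screen <- function(ds, d = default_d(ds$n)) {
  stopifnot(is_survival_dataset(ds))
  if (d < 1 || d > ds$p) stop("d must lie in 1..p")
  prep <- cox_prep(ds$time, ds$event)
  stat <- numeric(ds$p)
  failed <- logical(ds$p)
  for (j in seq_len(ds$p)) {
    fit <- tryCatch(
      cox_newton(ds$X[, j, drop = FALSE], prep, max_iter = 50L),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      failed[j] <- TRUE                   # statistic stays 0: unselectable
    } else {
      stat[j] <- abs(fit$beta)
    }
  }
  if (any(failed)) {
    warning(sum(failed), " marginal fit(s) did not converge and were ",
            "assigned statistic 0")
  }
  ord <- order(stat, decreasing = TRUE)   # stable: ties keep original order
  sel <- sort(ord[seq_len(d)])
  screening_result(
    mode = "marginal", candidate_ids = ds$feature_ids,
    statistic = stats::setNames(stat, ds$feature_ids),
    selected_ids = ds$feature_ids[sel], d_or_gamma = d,
    failed_ids = ds$feature_ids[failed]
  )
}

#' Conditional screening given a prior feature set
#'
#' For every candidate feature m outside the conditioning set C0, fits the
#' Cox model on `C0 + {m}` (refitting the C0 coefficients jointly with
#' `beta_m`, warm-started at the C0-only fit) and records the Wald z-test
#' p-value of `beta_m`. The augmented set C1 collects the candidates with
#' p-value below `gamma`; the default threshold follows [gamma_rule()] on
#' the full covariate count. A candidate whose conditional fit is singular
#' (for instance, a duplicate of a C0 member) or fails to converge is
#' excluded and logged in `failed_ids`.
#'
#' With `statistic = "magnitude"` the retention rule `|beta_m| >= gamma` is
#' applied instead of the p-value rule.
#'
#' @param ds A [survival_dataset].
#' @param conditioning_set Nonempty feature ids or indices (the set C0);
#'   `|C0| + 1` must stay below the event count.
#' @param gamma Threshold in `(0, 1)`; default `1/p`.
#' @param statistic `"pvalue"` (default, the operational rule) or
#'   `"magnitude"`.
#' @return A `screening_result` with `mode = "conditional"`, the per-
#'   candidate `statistic` (p-value or `|beta_m|`), and `selected_ids` (the
#'   set C1, never intersecting C0).
#' @export
conditional_screen <- function(ds, conditioning_set, gamma = gamma_rule(ds$p),
                               statistic = c("pvalue", "magnitude")) {
  stopifnot(is_survival_dataset(ds))
  statistic <- match.arg(statistic)
  c0 <- sort(resolve_features(ds, conditioning_set))
  if (length(c0) == 0L) stop("conditioning set must be nonempty")
  if (!(gamma > 0 && gamma < 1)) stop("gamma must lie in (0, 1)")
  n_events <- sum(ds$event == 1)
  if (length(c0) + 1L >= n_events) {
    stop("conditioning set too large: |C0| + 1 must be below the event count (",
         n_events, ")")
  }
  prep <- cox_prep(ds$time, ds$event)
  X0 <- ds$X[, c0, drop = FALSE]
  base <- tryCatch(cox_newton(X0, prep), error = function(e)
    stop("conditioning set is not identifiable: ", conditionMessage(e)))
  if (!base$converged) stop("Cox fit on the conditioning set did not converge")
  candidates <- setdiff(seq_len(ds$p), c0)
  stat <- rep(NA_real_, length(candidates))
  failed <- logical(length(candidates))
  warm <- c(base$beta, 0)
  for (i in seq_along(candidates)) {
    m <- candidates[i]
    fit <- tryCatch(
      cox_newton(cbind(X0, ds$X[, m, drop = FALSE]), prep,
                 beta_init = warm, max_iter = 50L),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || !is.finite(fit$se[length(fit$se)]) ||
        fit$se[length(fit$se)] == 0) {
      failed[i] <- TRUE
      next
    }
    k <- length(fit$beta)
    stat[i] <- if (statistic == "pvalue") {
      2 * stats::pnorm(-abs(fit$beta[k] / fit$se[k]))
    } else {
      abs(fit$beta[k])
    }
  }
  keep <- if (statistic == "pvalue") {
    !failed & !is.na(stat) & stat < gamma
  } else {
    !failed & !is.na(stat) & stat >= gamma
  }
  screening_result(
    mode = "conditional", candidate_ids = ds$feature_ids[candidates],
    statistic = stats::setNames(stat, ds$feature_ids[candidates]),
    selected_ids = ds$feature_ids[candidates[keep]], d_or_gamma = gamma,
    conditioning_ids = ds$feature_ids[c0],
    failed_ids = ds$feature_ids[candidates[failed]]
  )
}
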