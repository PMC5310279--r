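# Time-dependent ROC/AUC for censored survival outcomes, cumulative-case /
# dynamic-control: at evaluation time t, cases are the subjects with an
# observed event by t and controls the subjects still event-free at t.
# The default estimator reweights cases by the inverse Kaplan-Meier estimate
# of the censoring distribution; the naive estimator simply drops subjects
# censored before t and is exactly testable against a brute-force pairwise
# count.

# Kaplan-Meier estimate of the censoring survival function G(t) = P(C > t),
# evaluated left-continuously: G(u-) = surv at the largest censoring time
# strictly below u, else 1.
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(u, left = TRUE) {
    vapply(u, function(ui) {
      keep <- if (left) sf$time < ui else sf$time <= ui
      if (!any(keep)) 1 else min(sf$surv[keep])
    }, 0)
  }
}

#' Time-dependent ROC curve for censored data
#'
#' Sweeps a cutoff c over the observed risk scores and reports the
#' cumulative/dynamic sensitivity `P(score > c | event by t)` against
#' `1 - specificity` with `specificity = P(score <= c | event-free at t)`.
#' Subjects censored before t have unknown case status; the `"km_cd"`
#' estimator (default) reweights the observed cases by the inverse
#' Kaplan-Meier censoring survival `1/G(T_i-)` (controls share the common
#' weight `1/G(t)`, which cancels), while the `"naive"` estimator drops
#' those subjects outright. With no censoring before t the two coincide.
#' The AUC is the trapezoidal area under the empirical ROC polyline, which
#' awards tied scores half credit.
#'
#' @param score Numeric risk scores, higher = shorter predicted survival.
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param t Evaluation time within the observed follow-up range.
#' @param estimator `"km_cd"` (default) or `"naive"`.
#' @return An object of class `roc_result`: `eval_time`, `cutoffs`
#'   (decreasing, `+Inf` to `-Inf`), `sensitivity`,
#'   `one_minus_specificity`, `auc`, `estimator`, `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(score, time, event, t,
                               estimator = c("km_cd", "naive")) {
  estimator <- match.arg(estimator)
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (t < min(time) || t > max(time)) {
    stop("evaluation time ", t, " lies outside the observed follow-up range")
  }
  is_case <- time <= t & event == 1
  is_control <- time > t
  if (!any(is_case)) stop("no cases (events by time ", t, ")")
  if (!any(is_control)) stop("no controls (subjects event-free at time ", t, ")")
  w_case <- if (estimator == "km_cd") {
    G <- censoring_km(time, event)
    g <- G(time[is_case])
    if (any(g <= 0)) stop("censoring survival reaches 0 before an event time")
    1 / g
  } else {
    rep(1, sum(is_case))
  }
  cutoffs <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  case_scores <- score[is_case]
  control_scores <- score[is_control]
  sens <- vapply(cutoffs, function(cc) {
    sum(w_case[case_scores > cc]) / sum(w_case)
  }, 0)
  oms <- vapply(cutoffs, function(cc) mean(control_scores > cc), 0)
  auc <- sum(diff(oms) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(
    list(eval_time = t, cutoffs = cutoffs, sensitivity = sens,
         one_minus_specificity = oms, auc = auc, estimator = estimator,
         n_cases = sum(is_case), n_controls = sum(is_control)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("time-dependent ROC at t =", x$eval_time, "(", x$estimator, "):",
      "AUC =", round(x$auc, 4), "with", x$n_cases, "cases /",
      x$n_controls, "controls\n")
  invisible(x)
}

#' AUC(t) over a time grid
#'
#' Applies [time_dependent_roc()] at each grid time. Grid points without at
#' least one case and one control are reported as `NA` with the reason
#' rather than failing the whole curve.
#'
#' @inheritParams time_dependent_roc
#' @param t_grid Increasing evaluation times.
#' @return Data frame with columns `time`, `auc`, `n_cases`, `n_controls`,
#'   `reason` (`NA` when usable).
#' @export
auc_over_time <- function(score, time, event, t_grid,
                          estimator = c("km_cd", "naive")) {
  estimator <- match.arg(estimator)
  rows <- lapply(t_grid, function(t) {
    res <- tryCatch(time_dependent_roc(score, time, event, t, estimator),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(time = t, auc = NA_real_, n_cases = NA_integer_,
                 n_controls = NA_integer_, reason = res)
    } else {
      data.frame(time = t, auc = res$auc, n_cases = res$n_cases,
                 n_controls = res$n_controls, reason = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$auc))) stop("no usable evaluation time in the grid")
  out
}

#' Seeded train/test split of a survival dataset
#'
#' Draws `n_train` samples uniformly without replacement; the test set is
#' the complement. Both sides must retain at least two events; if a draw
#' violates this it is redrawn (up to 20 times) before erroring.
#'
#' @param ds A [survival_dataset].
#' @param n_train Training-set size, between 2 and `n - 2`.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with elements `train` and `test`, both [survival_dataset]s.
#' @export
train_test_split <- function(ds, n_train, seed = 1L) {
  stopifnot(is_survival_dataset(ds))
  if (n_train < 2 || n_train > ds$n - 2) {
    stop("n_train must lie between 2 and n - 2")
  }
  local_seed(seed, {
    for (attempt in 1:20) {
      idx <- sort(sample.int(ds$n, n_train))
      ev_train <- sum(ds$event[idx])
      ev_test <- sum(ds$event[-idx])
      if (ev_train >= 2 && ev_test >= 2) {
        return(list(train = subset_samples(ds, idx),
                    test = subset_samples(ds, setdiff(seq_len(ds$n), idx))))
      }
    }
    stop("could not draw a split with at least 2 events on each side")
  })
}
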