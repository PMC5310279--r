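# Brute-force oracle: log partial likelihood by direct summation over event
# times, risk sets recomputed per event. Independent of the package's
# sorted/cumulative implementation.
naive_partial_loglik <- function(X, time, event, beta) {
  eta <- drop(X %*% beta)
  sum(vapply(which(event == 1), function(k) {
    eta[k] - log(sum(exp(eta[time >= time[k]])))
  }, 0))
}

test_that("partial likelihood matches the direct risk-set sum", {
  ds <- make_raw_dataset(n = 25, p = 3, seed = 5)
  beta <- c(0.4, -0.7, 0.1)
  got <- partial_loglik(ds, 1:3, beta)
  expect_equal(got$value,
               naive_partial_loglik(ds$X, ds$time, ds$event, beta),
               tolerance = 1e-12)

  # null value is minus the sum of log risk-set sizes; with 3 distinct-time
  # events and no censoring that is -log(3!) = -log 6
  ds3 <- survival_dataset(matrix(rnorm(3), 3, 1), time = c(1, 2, 3),
                          event = c(1, 1, 1))
  expect_equal(partial_loglik(ds3, 1, 0)$value, -log(6), tolerance = 1e-12)

  # ... and in general for any censoring pattern
  ds2 <- make_raw_dataset(n = 40, p = 2, seed = 9)
  ll0 <- -sum(vapply(which(ds2$event == 1),
                     function(k) log(sum(ds2$time >= ds2$time[k])), 0))
  expect_equal(partial_loglik(ds2, 1:2, c(0, 0))$value, ll0, tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  for (seed in c(3, 17, 23)) {
    ds <- make_raw_dataset(n = 20, p = 3, seed = seed)
    beta <- sin(seed + 1:3)    # arbitrary deterministic point
    got <- partial_loglik(ds, 1:3, beta)
    h <- 1e-5
    fd <- vapply(1:3, function(j) {
      e <- replace(numeric(3), j, h)
      (partial_loglik(ds, 1:3, beta + e)$value -
         partial_loglik(ds, 1:3, beta - e)$value) / (2 * h)
    }, 0)
    expect_lt(max(abs(got$gradient - fd)) / max(1, max(abs(fd))), 1e-6)
  }
})

test_that("fit_cox reproduces coxph (Breslow) and satisfies optimality", {
  ds <- make_raw_dataset(n = 80, p = 4, seed = 11)
  fit <- fit_cox(ds, 1:4)
  expect_true(fit$converged)
  ref <- survival::coxph(survival::Surv(ds$time, ds$event) ~ ds$X,
                         ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-10)
  expect_gte(fit$loglik, fit$loglik_null)
  # first-order optimality at the maximizer
  g <- partial_loglik(ds, 1:4, unname(fit$beta))$gradient
  expect_lt(max(abs(g)), 1e-6)
})

test_that("fit_cox handles the degenerate contracts", {
  ds <- make_raw_dataset(n = 30, p = 2, seed = 2)
  null_fit <- fit_cox(ds, integer(0))
  expect_identical(null_fit$loglik, null_fit$loglik_null)
  expect_length(null_fit$beta, 0)
  expect_equal(generalized_r2(null_fit), 0)

  # exact collinearity: the same covariate twice
  ds_dup <- survival_dataset(cbind(a = ds$X[, 1], b = ds$X[, 1]),
                             ds$time, ds$event)
  expect_error(fit_cox(ds_dup, 1:2), "collinear|singular")

  # constant column rejected up front
  ds_const <- survival_dataset(cbind(a = ds$X[, 1], c = rep(1, ds$n)),
                               ds$time, ds$event)
  expect_error(fit_cox(ds_const, 1:2), "constant")

  # identifiability guard
  tiny <- survival_dataset(matrix(rnorm(12), 4, 3), time = c(1, 2, 3, 4),
                           event = c(1, 1, 0, 0))
  expect_error(fit_cox(tiny, 1:3), "events")
})

test_that("loglik is invariant to affine covariate rescaling", {
  ds <- make_raw_dataset(n = 50, p = 2, seed = 7)
  f1 <- fit_cox(ds, 1:2)
  X2 <- ds$X
  X2[, 1] <- X2[, 1] * 10 + 3
  ds2 <- survival_dataset(X2, ds$time, ds$event)
  f2 <- fit_cox(ds2, 1:2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(unname(f2$beta[1]), unname(f1$beta[1]) / 10, tolerance = 1e-6)
})

test_that("wald_report computes z, p and hazard ratios correctly", {
  ds <- make_test_dataset(n = 200, p = 1, beta = 1, seed = 31)
  fit <- fit_cox(ds, 1)
  w <- wald_report(fit)
  # independent evaluation of the two-sided normal tail
  expect_equal(w$p_value, 2 * pnorm(-abs(fit$beta / fit$se)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(w$hazard_ratio, exp(w$coef))
  expect_equal(w$z, w$coef / w$se)
  # z at the 5% two-sided critical value
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
})

test_that("concordance matches an explicit pairwise loop on censored data", {
  loop_concordance <- function(score, time, event) {
    num <- den <- 0
    n <- length(score)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      short <- if (time[i] < time[j]) i else j
      long <- if (time[i] < time[j]) j else i
      if (event[short] != 1) next
      den <- den + 1
      if (score[short] > score[long]) num <- num + 1
      else if (score[short] == score[long]) num <- num + 0.5
    }
    num / den
  }
  set.seed(404)
  for (rep in 1:25) {
    n <- 30
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1L
    score <- rnorm(n)
    expect_identical(concordance_index(score, time, event),
                     loop_concordance(score, time, event))
  }
  # agreement with the survival package on tie-free times
  time <- rexp(40); event <- rbinom(40, 1, 0.6); score <- rnorm(40)
  if (sum(event) < 2) event[1:2] <- 1L
  ref <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)$concordance
  expect_equal(concordance_index(score, time, event), ref, tolerance = 1e-12)
})

test_that("concordance trivial cases and antisymmetry", {
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  expect_identical(concordance_index(-time, time, event), 1)
  expect_identical(concordance_index(rep(0, 4), time, event), 0.5)
  s <- c(0.3, -1, 2, 0.7)
  expect_equal(concordance_index(s, time, event),
               1 - concordance_index(-s, time, event))
  expect_error(concordance_index(1, 5, 0), "no permissible pairs")
})

test_that("generalized R2 follows its closed form and monotonicity", {
  ds <- make_test_dataset(n = 100, p = 2, beta = c(1.2, 0), seed = 77)
  fit <- fit_cox(ds, 1:2)
  expect_equal(generalized_r2(fit),
               1 - exp(-(2 / fit$n_samples) * (fit$loglik - fit$loglik_null)),
               tolerance = 1e-12)
  # loglik - loglik_null = n/2  =>  R2 = 1 - exp(-1)
  mock <- fit
  mock$loglik <- mock$loglik_null + mock$n_samples / 2
  expect_equal(generalized_r2(mock), 1 - exp(-1), tolerance = 1e-12)
  # strictly increasing in the loglik gap
  mock2 <- fit
  mock2$loglik <- fit$loglik + 1
  expect_gt(generalized_r2(mock2), generalized_r2(fit))
})

test_that("cox_report prints the standard model-fit layout", {
  ds <- make_test_dataset(n = 120, p = 2, beta = c(1, 0), seed = 13)
  fit <- fit_cox(ds, 1:2)
  rep_lines <- cox_report(fit, ds)
  expect_match(rep_lines[1], "coef.*exp\\(coef\\).*se\\(coef\\).*z.*p-value")
  expect_match(rep_lines[length(rep_lines) - 1], "R\\^2 = .*Concordance = ")
  expect_match(rep_lines[length(rep_lines)], "Significance codes")
})
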