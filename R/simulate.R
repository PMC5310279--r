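# Synthetic high-dimensional expression + survival data from a known sparse
# Cox model, for parameter-recovery testing of every strategy. Includes the
# "marginally hidden, jointly important" covariate design whose recovery
# separates conditional from marginal screening, and a companion gene-set
# generator so the enrichment stage is testable end to end.

#' Specify a survival simulation
#'
#' A full generative specification: Gaussian covariates with a chosen
#' correlation structure, event times drawn from a Cox model with a sparse
#' true coefficient vector and an exponential or Weibull baseline hazard,
#' and independent uniform censoring calibrated to a target censoring rate.
#'
#' @param n,p Sample and feature counts.
#' @param support Integer indices of the truly active features.
#' @param beta_true Numeric effects, one per support member.
#' @param correlation `"independent"`, `"ar1"` (Corr(X_i, X_j) = rho^|i-j|)
#'   or `"equicorrelated"` (constant off-diagonal rho).
#' @param rho Correlation parameter in `[0, 1)`; ignored for
#'   `"independent"`.
#' @param baseline `"exponential"` or `"weibull"`.
#' @param rate Exponential baseline rate (default 1).
#' @param shape,scale Weibull baseline parameters.
#' @param censoring_rate Target fraction of censored samples in `[0, 1)`;
#'   0 disables censoring.
#' @param seed Integer seed; the draw is fully deterministic given the
#'   configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n, p, support, beta_true,
                              correlation = c("independent", "ar1", "equicorrelated"),
                              rho = 0,
                              baseline = c("exponential", "weibull"),
                              rate = 1, shape = 1.5, scale = 1,
                              censoring_rate = 0, seed = 1L) {
  correlation <- match.arg(correlation)
  baseline <- match.arg(baseline)
  support <- as.integer(support)
  if (length(support) != length(beta_true)) {
    stop("support and beta_true must have equal length")
  }
  if (any(support < 1L | support > p)) stop("support indices must lie in 1..p")
  if (anyDuplicated(support)) stop("support indices must be unique")
  if (!(rho >= 0 && rho < 1)) stop("rho must lie in [0, 1)")
  if (!(censoring_rate >= 0 && censoring_rate < 1)) {
    stop("censoring_rate must lie in [0, 1)")
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), support = support,
         beta_true = as.numeric(beta_true), correlation = correlation,
         rho = rho, baseline = baseline, rate = rate, shape = shape,
         scale = scale, censoring_rate = censoring_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Strong-signal simulation scenario
#'
#' Five active features with alternating effects of magnitude `beta0`,
#' spread evenly across the feature range so the AR(1) dependence does not
#' couple them, under 25% censoring — the benign regime in which all three
#' selection strategies should recover the full support.
#'
#' @param n,p Sample and feature counts.
#' @param beta0 Effect magnitude (default 1).
#' @param rho AR(1) correlation (default 0.5).
#' @param censoring_rate Target censoring fraction (default 0.25).
#' @param seed Integer seed.
#' @return A [simulation_config].
#' @export
strong_signal_config <- function(n, p, beta0 = 1, rho = 0.5,
                                 censoring_rate = 0.25, seed = 1L) {
  support <- unique(as.integer(round(seq(1, p, length.out = 5))))
  if (length(support) < 5) stop("p too small for 5 spaced active features")
  simulation_config(
    n = n, p = p, support = support,
    beta_true = beta0 * c(1, -1, 1, -1, 1),
    correlation = "ar1", rho = rho,
    baseline = "exponential", rate = 1,
    censoring_rate = censoring_rate, seed = seed
  )
}

#' Hidden-variable simulation scenario
#'
#' Equicorrelated covariates (constant correlation `rho`) with active set
#' {1, 2, 3, 4} and effects `(beta0, beta0, beta0, -3 * rho * beta0)`. The
#' fourth coefficient is chosen so that
#' `Cov(X_4, X^T beta_true) = beta_4 + rho * 3 * beta0 = 0`: covariate 4 is
#' jointly active yet marginally uncorrelated with the linear predictor, the
#' failure mode of purely marginal screening. Its marginal Cox coefficient
#' is approximately (not exactly) zero, the marginal slope not being a pure
#' covariance.
#'
#' @param n,p Sample and feature counts.
#' @param rho Equicorrelation in `(0, 1)`.
#' @param beta0 Nonzero base effect.
#' @param censoring_rate Target censoring fraction (default 0.25).
#' @param seed Integer seed.
#' @return A [simulation_config].
#' @export
hidden_variable_config <- function(n, p, rho = 0.5, beta0 = 1,
                                   censoring_rate = 0.25, seed = 1L) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)")
  if (beta0 == 0) stop("beta0 must be nonzero")
  simulation_config(
    n = n, p = p, support = 1:4,
    beta_true = c(beta0, beta0, beta0, -3 * rho * beta0),
    correlation = "equicorrelated", rho = rho,
    baseline = "exponential", rate = 1,
    censoring_rate = censoring_rate, seed = seed
  )
}

# Draw the n x p Gaussian design. AR(1) and equicorrelation are generated by
# exact recursions rather than a p x p Cholesky factor.
simulate_design <- function(n, p, correlation, rho) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  switch(correlation,
    independent = Z,
    ar1 = {
      X <- Z
      if (p > 1) {
        for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * Z[, j]
      }
      X
    },
    equicorrelated = {
      common <- stats::rnorm(n)
      sqrt(rho) * common + sqrt(1 - rho) * Z
    }
  )
}

# Upper censoring bound c* such that C ~ U(0, c*) censors the given latent
# event times at the target rate: P(censored_i) = min(T_i / c*, 1), solved by
# bisection in mean.
calibrate_censoring_bound <- function(latent_times, target) {
  rate_at <- function(cstar) mean(pmin(latent_times / cstar, 1))
  lo <- min(latent_times) / 2
  hi <- max(latent_times) * 2
  # rate_at is decreasing in c*; widen until the target is bracketed
  for (i in 1:60) {
    if (rate_at(hi) <= target) break
    hi <- hi * 2
  }
  if (rate_at(hi) > target) stop("censoring target ", target, " not achievable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a dataset from a sparse Cox model
#'
#' Covariates are zero-mean unit-variance Gaussian with the configured
#' correlation; latent event times come from the Cox model by inverse
#' transform — exponential baseline: `T = -log(U) / (rate * exp(x^T beta))`;
#' Weibull baseline: `T = scale * (-log(U) / exp(x^T beta))^(1/shape)`.
#' Censoring times are independent `U(0, c*)` with `c*` calibrated by
#' bisection so the expected censoring fraction matches the target; the
#' observed time is `min(T, C)` with `event = [T <= C]`. The draw is fully
#' deterministic given the configuration (including its seed).
#'
#' @param cfg A [simulation_config].
#' @return An object of class `simulated_dataset`: `dataset` (a
#'   [survival_dataset] with feature ids `G00001...` and sample ids
#'   `S0001...`), `truth` (the config), `latent` (the true linear predictor
#'   per sample) and `realized_censoring_rate`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  local_seed(cfg$seed, {
    X <- simulate_design(cfg$n, cfg$p, cfg$correlation, cfg$rho)
    eta <- drop(X[, cfg$support, drop = FALSE] %*% cfg$beta_true)
    u <- stats::runif(cfg$n)
    latent_T <- switch(cfg$baseline,
      exponential = -log(u) / (cfg$rate * exp(eta)),
      weibull = cfg$scale * (-log(u) / exp(eta))^(1 / cfg$shape)
    )
    if (cfg$censoring_rate > 0) {
      cstar <- calibrate_censoring_bound(latent_T, cfg$censoring_rate)
      cens <- stats::runif(cfg$n, 0, cstar)
      time <- pmin(latent_T, cens)
      event <- as.integer(latent_T <= cens)
    } else {
      time <- latent_T
      event <- rep(1L, cfg$n)
    }
    ds <- survival_dataset(
      X, time, event,
      feature_ids = sprintf("G%05d", seq_len(cfg$p)),
      sample_ids = sprintf("S%04d", seq_len(cfg$n))
    )
    structure(
      list(dataset = ds, truth = cfg, latent = eta,
           realized_censoring_rate = mean(event == 0)),
      class = "simulated_dataset"
    )
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset: n =", x$truth$n, ", p =", x$truth$p,
      ", |support| =", length(x$truth$support),
      ", censoring", round(100 * x$realized_censoring_rate, 1), "%\n")
  invisible(x)
}

#' Generate a companion gene-set collection
#'
#' Emits `n_sets` synthetic gene sets over the given feature universe, with
#' the first set ("signal_set") built around `enriched_genes` (padded with
#' random members up to `set_size`) and the rest drawn at random — enough
#' structure for the over-representation test to have a planted positive.
#'
#' @param feature_ids Universe of gene labels.
#' @param enriched_genes Genes to plant into the first set.
#' @param n_sets Number of sets (default 20).
#' @param set_size Members per set (default 15).
#' @param seed Integer seed.
#' @return A `gene_set_collection`.
#' @export
simulate_gene_sets <- function(feature_ids, enriched_genes, n_sets = 20L,
                               set_size = 15L, seed = 1L) {
  stopifnot(all(enriched_genes %in% feature_ids),
            length(enriched_genes) <= set_size)
  local_seed(seed, {
    sets <- vector("list", n_sets)
    pad <- sample(setdiff(feature_ids, enriched_genes),
                  set_size - length(enriched_genes))
    sets[[1L]] <- list(description = "planted signal set",
                       genes = c(enriched_genes, pad))
    for (i in seq_len(n_sets - 1L) + 1L) {
      sets[[i]] <- list(description = "random background set",
                        genes = sample(feature_ids, set_size))
    }
    names(sets) <- c("signal_set",
                     sprintf("random_set_%02d", seq_len(n_sets - 1L)))
    structure(sets, class = "gene_set_collection")
  })
}
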