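# Shared fixture builders: all synthetic, generated at test time.

# Small censored dataset with independent Gaussian covariates and a known
# sparse effect, via the package simulator.
make_test_dataset <- function(n = 60, p = 4, beta = c(1, rep(0, p - 1)),
                              censoring = 0.2, seed = 101) {
  cfg <- simulation_config(
    n = n, p = p, support = seq_along(beta), beta_true = beta,
    correlation = "independent", baseline = "exponential", rate = 1,
    censoring_rate = censoring, seed = seed
  )
  simulate_dataset(cfg)$dataset
}

# Hand-rolled dataset (not via the simulator) for oracle tests.
make_raw_dataset <- function(n = 30, p = 3, seed = 1, censor_frac = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  time <- rexp(n)
  event <- as.integer(runif(n) > censor_frac)
  if (sum(event) < 2) event[1:2] <- 1L
  survival_dataset(X, time, event)
}

write_tiny_expression <- function(path, sep = "\t") {
  lines <- c(
    paste(c("feature_id", "SA", "SB"), collapse = sep),
    paste(c("G1", "1.5", "2.25"), collapse = sep),
    paste(c("G2", "-0.5", "0"), collapse = sep),
    paste(c("G3", "3", "4.125"), collapse = sep)
  )
  writeLines(lines, path)
  path
}
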