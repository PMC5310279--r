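# Hypergeometric over-representation testing of a selected gene set against
# a gene-set collection, the local counterpart of querying a pathway
# database with a signature. The pmf is evaluated in log-space; the
# enrichment p-value is the upper tail P(X >= k).

#' Hypergeometric probability mass function
#'
#' \deqn{P(X = k) = \binom{K}{k}\binom{N-K}{n-k} \Big/ \binom{N}{n}}
#' where N is the population size, K the number of success states, n the
#' number of draws and k the observed successes. Evaluated via log-binomial
#' coefficients for overflow safety; values of `k` outside the support
#' return 0 (not an error), which keeps tail sums simple.
#'
#' @param N,K,n Population size, success states, draws
#'   (`0 <= K <= N`, `0 <= n <= N`).
#' @param k Observed successes; may be a vector.
#' @return `P(X = k)`, vectorized over `k`.
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    stop("require 0 <= K <= N and 0 <= n <= N")
  }
  out <- numeric(length(k))
  ok <- k >= max(0, n + K - N) & k <= min(K, n) & k == round(k)
  out[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  out
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' The over-representation p-value: the probability of observing `k` or more
#' successes, by direct summation of [hypergeom_pmf()] over the support.
#'
#' @inheritParams hypergeom_pmf
#' @param k Scalar threshold.
#' @return `P(X >= k)` in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  lo <- max(k, max(0, n + K - N))
  min(sum(hypergeom_pmf(N, K, n, lo:hi)), 1)
}

#' Multiple-testing adjustment of p-values
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni, capped at 1, input
#' order preserved.
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return Adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = switch(method,
    benjamini_hochberg = "BH", bonferroni = "bonferroni"))
}

#' Gene-set over-representation test
#'
#' For each set in the collection, counts `K` (set members in the universe),
#' `n` (selected genes in the universe) and `k` (their overlap) and reports
#' the upper-tail hypergeometric p-value `P(X >= k)` with a
#' multiple-testing adjustment across the tested sets. Sets with no member
#' in the universe are skipped; selected genes outside the universe are
#' dropped with a warning. Results are sorted by p-value, ties by set name.
#'
#' @param selected Character vector of selected gene ids (nonempty).
#' @param sets A `gene_set_collection` from [read_gmt()] or
#'   [simulate_gene_sets()].
#' @param universe Character vector of all candidate gene ids — typically
#'   the features that survived the variance filter, i.e. the space the
#'   selection was made from.
#' @param method Adjustment method for [adjust_pvalues()].
#' @return Data frame of class `enrichment_result` with columns `set_name`,
#'   `N`, `K`, `n`, `k`, `p_value`, `p_adjusted`, `overlap_ids`
#'   (comma-separated).
#' @export
enrich <- function(selected, sets, universe,
                   method = c("benjamini_hochberg", "bonferroni")) {
  stopifnot(inherits(sets, "gene_set_collection"))
  method <- match.arg(method)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be nonempty")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " selected gene(s) outside the ",
            "universe: ", paste(utils::head(outside, 5), collapse = ", "))
    selected <- intersect(selected, universe)
  }
  if (length(selected) == 0L) stop("no selected genes within the universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- intersect(members, selected)
    k <- length(overlap)
    data.frame(set_name = nm, N = N, K = K, n = n, k = k,
               p_value = hypergeom_tail(N, K, n, k),
               overlap_ids = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no gene set intersects the universe")
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, method)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "N", "K", "n", "k", "p_value", "p_adjusted",
               "overlap_ids")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
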