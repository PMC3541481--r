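#' Exact hypergeometric enrichment test (log-space)
#'
#' Tail probability for the overlap `k` of a sample of size `n` with `K`
#' successes in a population of size `N`, computed by summing exact log-scale
#' hypergeometric probability masses (log-binomial coefficients combined with
#' a numerically stable log-sum-exp); no normal approximation. The default
#' `strict` tail is `P(X > k)` — the convention of common statistical
#' software's over-representation tests; `inclusive` gives `P(X >= k)`.
#'
#' @param k Observed overlap.
#' @param n Sample size.
#' @param K Successes in the population.
#' @param N Population size.
#' @param tail_mode `"strict"` (`P(X > k)`, default) or `"inclusive"`
#'   (`P(X >= k)`).
#' @return An `enrichment_result` list: `k`, `n`, `K`, `N`, `tail_mode`,
#'   `p_value`, `log10_p` (finite even when `p_value` underflows; `-Inf` for
#'   an exactly empty tail).
#' @examples
#' hypergeom_enrichment(506, 2278, 2794, 17498)
#' @export
hypergeom_enrichment <- function(k, n, K, N,
                                 tail_mode = c("strict", "inclusive")) {
  tail_mode <- match.arg(tail_mode)
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N ||
      k < max(0, n + K - N)) {
    stop("inconsistent hypergeometric counts (need k <= min(n, K) <= N, ",
         "k >= max(0, n + K - N))")
  }
  lo <- if (tail_mode == "strict") k + 1 else k
  hi <- min(n, K)
  if (lo > hi) {
    return(structure(list(k = k, n = n, K = K, N = N, tail_mode = tail_mode,
                          p_value = 0, log10_p = -Inf),
                     class = "enrichment_result"))
  }
  j <- lo:hi
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(logp)
  log_tail <- mx + log(sum(exp(logp - mx)))
  p <- exp(log_tail)
  structure(list(k = k, n = n, K = K, N = N, tail_mode = tail_mode,
                 p_value = min(p, 1), log10_p = min(log_tail, 0) / log(10)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric enrichment (%s tail): overlap %d of sample %d; %d/%d successes in population\n  p = %.4g (log10 p = %.3f)\n",
    x$tail_mode, x$k, x$n, x$K, x$N, x$p_value, x$log10_p))
  invisible(x)
}
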