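#' Genome-wide permutation p-value threshold (Churchill-Doerge)
#'
#' Estimates the genome-wide significance threshold for a single trait by
#' permuting line labels of the expression values while keeping genotypes
#' fixed. Each permutation draws one gene from the panel, permutes its
#' line-mean values, scans all markers, and records the genome-wide minimum
#' p-value; the threshold is the empirical `alpha`-quantile of that minimum-p
#' distribution.
#'
#' @param dataset An `expression_dataset` or a genes x lines line-mean matrix.
#' @param genotypes A `genotype_matrix`.
#' @param map A `genetic_map`.
#' @param n_permutations Number of permutations (>= 100; default 10000).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param seed Integer seed.
#' @param environment Environment label when `dataset` holds several.
#' @return List: `p_threshold` (p scale), `neg_log10_threshold`, `alpha`,
#'   `n_permutations`, and the vector `min_p` of per-permutation minima.
#' @export
permutation_threshold <- function(dataset, genotypes, map,
                                  n_permutations = 10000, alpha = 0.05,
                                  seed = 1, environment = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_permutations < 100) stop("need at least 100 permutations")
  map <- validate_map(map)
  Y <- if (inherits(dataset, "expression_dataset")) {
    line_means(dataset, environment = environment, ril_only = TRUE)
  } else dataset
  X <- genotype_numeric(genotypes)[colnames(Y), map$marker, drop = FALSE]
  set.seed(as.integer(seed))
  genes <- sample.int(nrow(Y), n_permutations, replace = TRUE)
  L <- ncol(Y)
  # build the permuted trait matrix in chunks to bound memory
  chunk <- 2000L
  min_p <- numeric(n_permutations)
  for (start in seq(1L, n_permutations, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_permutations)
    P <- matrix(0, length(idx), L)
    for (i in seq_along(idx)) {
      P[i, ] <- Y[genes[idx[i]], sample.int(L)]
    }
    min_p[idx] <- apply(scan_matrix(P, X)$p_value, 1, min)
  }
  thr <- stats::quantile(min_p, probs = alpha, type = 1, names = FALSE)
  list(p_threshold = thr, neg_log10_threshold = -log10(thr),
       alpha = alpha, n_permutations = n_permutations, min_p = min_p)
}

#' Assemble the final genome-wide significance threshold
#'
#' Combines the permutation threshold and the FDR-derived pooled threshold:
#' the final mapping threshold is `-log10` of the smaller (stricter) of the
#' p-scale thresholds in use. Either may be `NULL`/`NA` to use the other
#' alone.
#'
#' @param permutation_p Permutation genome-wide p threshold (or NULL).
#' @param fdr_p FDR-derived pooled p threshold (or NULL).
#' @param alpha,n_permutations,nominal_fdr,correction_factor Bookkeeping
#'   fields recorded in the result.
#' @return A `threshold_set` list with `permutation_p_threshold`,
#'   `fdr_p_threshold`, `final_p_threshold`, `final_neg_log10_threshold` and
#'   the bookkeeping fields.
#' @export
threshold_set <- function(permutation_p = NULL, fdr_p = NULL,
                          alpha = 0.05, n_permutations = NA_integer_,
                          nominal_fdr = 0.05, correction_factor = 1L) {
  cand <- c(permutation_p, fdr_p)
  cand <- cand[!is.na(cand)]
  if (!length(cand)) stop("need at least one threshold")
  final_p <- min(cand)
  structure(list(
    alpha = alpha, n_permutations = n_permutations,
    permutation_p_threshold = if (is.null(permutation_p)) NA_real_ else permutation_p,
    fdr_p_threshold = if (is.null(fdr_p)) NA_real_ else fdr_p,
    nominal_fdr = nominal_fdr, correction_factor = correction_factor,
    final_p_threshold = final_p,
    final_neg_log10_threshold = -log10(final_p)
  ), class = "threshold_set")
}
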