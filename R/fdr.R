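#' Thin markers by genotype correlation
#'
#' Neighboring markers on a dense map represent largely the same test.
#' Greedy left-to-right thinning per chromosome: a marker is kept only if the
#' squared genotype correlation with the last kept marker is `<= r2_max`.
#' Deterministic.
#'
#' @param map A `genetic_map`.
#' @param genotypes A `genotype_matrix`.
#' @param r2_max Maximum allowed adjacent r-squared among kept markers,
#'   in (0, 1] (default 0.95).
#' @return Character vector of kept marker ids (map order).
#' @export
thin_markers <- function(map, genotypes, r2_max = 0.95) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  map <- validate_map(map)
  X <- genotype_numeric(genotypes)[, map$marker, drop = FALSE]
  kept <- character(0)
  for (chr in unique(map$chrom)) {
    mk <- map$marker[map$chrom == chr]
    last <- mk[1]
    kept <- c(kept, last)
    for (m in mk[-1]) {
      r2 <- suppressWarnings(stats::cor(X[, last], X[, m]))^2
      if (is.na(r2) || r2 <= r2_max) {
        kept <- c(kept, m)
        last <- m
      }
    }
  }
  kept
}

#' FDR-derived genome-wide p-value threshold from a pooled p-value set
#'
#' Applies [storey_qvalues] to the pooled gene-by-marker p-values and returns
#' the largest p whose q-value is below the corrected FDR target
#' `nominal_fdr / correction_factor` (the correction compensates for the
#' anti-conservative effect of correlated marker tests). The final mapping
#' threshold is `-log10` of this value.
#'
#' @param p_pool Pooled p-values (ideally from thinned markers; see
#'   [thin_markers]).
#' @param nominal_fdr Nominal FDR target (default 0.05).
#' @param correction_factor Integer >= 1 dividing the target (default 5).
#' @param ... Passed to [storey_qvalues] (e.g. `pi0_mode`).
#' @return List: `p_threshold` (NA if no discovery qualifies),
#'   `neg_log10_threshold`, `effective_fdr_target`, `n_discoveries`, `pi0`.
#' @export
pooled_threshold <- function(p_pool, nominal_fdr = 0.05, correction_factor = 5,
                             ...) {
  if (!length(p_pool)) stop("empty p-value pool")
  if (correction_factor < 1) stop("correction_factor must be >= 1")
  target <- nominal_fdr / correction_factor
  qv <- storey_qvalues(p_pool, ...)
  hit <- qv$q <= target
  if (!any(hit)) {
    return(list(p_threshold = NA_real_, neg_log10_threshold = NA_real_,
                effective_fdr_target = target, n_discoveries = 0L,
                pi0 = qv$pi0))
  }
  thr <- max(p_pool[hit])
  list(p_threshold = thr, neg_log10_threshold = -log10(thr),
       effective_fdr_target = target, n_discoveries = sum(hit), pi0 = qv$pi0)
}

#' Simulate the inflation of the gene-level FDR under marker correlation
#'
#' Storey's q-values computed on the pooled gene-by-marker p-values control
#' the FDR among gene-marker tests. An eQTL discovery, however, is claimed
#' per gene, and linked markers break the equivalence between the two
#' levels: each truly regulated gene drags a whole block of correlated
#' markers over the pair-level threshold (loosening it), while every null
#' gene gets one chance per effectively independent marker to cross it. The
#' realized gene-level FDR therefore exceeds the nominal pair-level target,
#' increasingly so on denser maps; with one marker per chromosome the two
#' levels coincide and the inflation is ~1.
#'
#' Per replicate, `n_null_genes` null genes and `n_true_genes` genes with a
#' genuine additive effect (`beta` at a random marker) are simulated on the
#' given genotypes, all genes are scanned at all markers, Storey q-values
#' are computed on the pooled p-values, and a gene is declared when any of
#' its markers has `q <= nominal_fdr`. The per-replicate gene-level
#' false-discovery proportion is (#null genes declared)/(#genes declared)
#' (0 when nothing is declared); its average over replicates is the realized
#' FDR and `inflation_factor = realized FDR / nominal_fdr`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param map A `genetic_map`.
#' @param n_null_genes Null genes per replicate (>= 100).
#' @param nominal_fdr Nominal FDR target (default 0.05).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed; replicate r uses `seed + r` so that replicate
#'   noise is shared across calls that compare marker densities.
#' @param noise_sd Residual SD of the expression noise (default 1).
#' @param n_true_genes Genes with a real effect per replicate (default 10%
#'   of `n_null_genes`, mirroring a realistic eQTL fraction).
#' @param beta Additive effect of the true genes (default 1.5).
#' @param ... Passed to [storey_qvalues].
#' @return An `fdr_correction_report` list: `inflation_factor`,
#'   `correction_factor` (= `ceiling(inflation_factor)`, min 1),
#'   `nominal_fdr`, `effective_fdr_target`, `realized_fdr`, `n_reps`.
#' @export
estimate_fdr_inflation <- function(genotypes, map, n_null_genes = 100,
                                   nominal_fdr = 0.05, n_reps = 100, seed = 1,
                                   noise_sd = 1,
                                   n_true_genes = ceiling(n_null_genes / 10),
                                   beta = 1.5, ...) {
  if (n_null_genes < 100) stop("need at least 100 null genes")
  map <- validate_map(map)
  X <- genotype_numeric(genotypes)[, map$marker, drop = FALSE]
  n_genes <- n_true_genes + n_null_genes
  fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    src <- sample.int(ncol(X), n_true_genes, replace = TRUE)
    Y <- matrix(stats::rnorm(n_genes * nrow(X), sd = noise_sd),
                n_genes, nrow(X))
    for (i in seq_len(n_true_genes)) Y[i, ] <- Y[i, ] + beta * X[, src[i]]
    p <- scan_matrix(Y, X)$p_value
    qv <- storey_qvalues(as.vector(p), ...)
    q <- matrix(qv$q, nrow(p), ncol(p))
    declared <- rowSums(q <= nominal_fdr) > 0
    n_false <- sum(declared[seq_len(n_null_genes) + n_true_genes])
    fdp[r] <- if (any(declared)) n_false / sum(declared) else 0
  }
  realized <- mean(fdp)
  inflation <- realized / nominal_fdr
  structure(list(
    inflation_factor = inflation,
    correction_factor = max(1L, as.integer(ceiling(inflation))),
    nominal_fdr = nominal_fdr,
    effective_fdr_target = nominal_fdr / max(1L, as.integer(ceiling(inflation))),
    realized_fdr = realized, n_reps = n_reps
  ), class = "fdr_correction_report")
}
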