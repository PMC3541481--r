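#' Signed -log10(P) eQTL profiles
#'
#' Per gene and marker, the linkage significance multiplied by the sign of
#' the additive effect: `s_m = (-log10 p_m) * sign(a_m)`. Markers with
#' `p = 1` (or zero effect) contribute 0. Correlating these profiles between
#' experiments separates shared, experiment-specific and opposite-effect
#' regulation.
#'
#' @param scan A `scan_result`.
#' @param genes Optional gene subset.
#' @return Genes x markers matrix of signed scores.
#' @export
signed_profiles <- function(scan, genes = NULL) {
  s <- scan$neg_log10_p * sign(scan$additive_effect)
  if (!is.null(genes)) s <- s[genes, , drop = FALSE]
  s
}

#' Correlate two signed profiles for one gene
#'
#' Pearson correlation of the two experiments' signed profiles. If either
#' profile is constant, or fewer than 3 markers are available, the
#' correlation is undefined: `r` is NA and the class is `weak`. Class bounds
#' follow strict inequalities: `strong_positive` iff `r > 0.5`,
#' `strong_negative` iff `r < -0.5`.
#'
#' @param s1,s2 Numeric signed-profile vectors on the same marker ordering.
#' @return List with `r` and `corr_class`.
#' @export
profile_correlation <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("profile length mismatch")
  if (length(s1) < 3 || stats::sd(s1) == 0 || stats::sd(s2) == 0) {
    return(list(r = NA_real_, corr_class = "weak"))
  }
  r <- stats::cor(s1, s2)
  cls <- if (is.na(r)) "weak" else if (r > 0.5) "strong_positive" else if (r < -0.5) "strong_negative" else "weak"
  list(r = r, corr_class = cls)
}

#' Per-gene plasticity records across two experiments
#'
#' Combines profile correlations with eQTL presence per experiment. The
#' eQTL-class strata are `neither`, `exp1_only`, `exp2_only`, `both`,
#' depending on whether the gene has at least one called eQTL in each
#' experiment.
#'
#' @param scan1,scan2 `scan_result`s for the two experiments over the same
#'   genes and markers.
#' @param records1,records2 Peak records ([call_peaks]) for the two
#'   experiments.
#' @param genes Optional gene subset (default: genes present in both scans).
#' @return Data frame `gene_id`, `r`, `eqtl_class`, `corr_class`.
#' @export
plasticity_records <- function(scan1, scan2, records1, records2, genes = NULL) {
  g1 <- rownames(scan1$neg_log10_p); g2 <- rownames(scan2$neg_log10_p)
  if (is.null(genes)) genes <- intersect(g1, g2)
  s1 <- signed_profiles(scan1, genes)
  s2 <- signed_profiles(scan2, genes)
  r <- vapply(seq_along(genes), function(i) {
    profile_correlation(s1[i, ], s2[i, ])$r
  }, numeric(1))
  corr_class <- ifelse(is.na(r), "weak",
                ifelse(r > 0.5, "strong_positive",
                ifelse(r < -0.5, "strong_negative", "weak")))
  in1 <- genes %in% records1$gene_id
  in2 <- genes %in% records2$gene_id
  eqtl_class <- ifelse(in1 & in2, "both",
                ifelse(in1, "exp1_only", ifelse(in2, "exp2_only", "neither")))
  data.frame(gene_id = genes, r = r, eqtl_class = eqtl_class,
             corr_class = corr_class, stringsAsFactors = FALSE)
}

#' Match eQTL records between two experiments
#'
#' Per gene, greedy best-pair matching of peaks: candidate pairs lie on the
#' same chromosome with peak-to-peak genetic distance `<=
#' max_peak_distance_cM` (inclusive) and are matched closest-first; matched
#' pairs are `overlapping`. An overlapping pair has `opposite_effect` when
#' the additive effects at the two peaks have strictly opposite signs.
#' Unmatched records are flagged experiment-specific.
#'
#' @param records1,records2 Classified or raw peak records sharing the map.
#' @param max_peak_distance_cM Overlap radius in cM (default 10).
#' @return List with `matches` (data frame `gene_id`, `peak1`, `peak2`,
#'   `effect1`, `effect2`, `distance_cM`, `overlapping`, `opposite_effect`)
#'   and `specific` (data frame `gene_id`, `experiment`, `peak_marker` of
#'   unmatched records).
#' @export
match_eqtls <- function(records1, records2, max_peak_distance_cM = 10) {
  out <- list(); spec <- list(); no <- 0L; ns <- 0L
  genes <- union(records1$gene_id, records2$gene_id)
  for (g in genes) {
    r1 <- records1[records1$gene_id == g, , drop = FALSE]
    r2 <- records2[records2$gene_id == g, , drop = FALSE]
    used1 <- rep(FALSE, nrow(r1)); used2 <- rep(FALSE, nrow(r2))
    if (nrow(r1) && nrow(r2)) {
      cand <- expand.grid(i = seq_len(nrow(r1)), j = seq_len(nrow(r2)))
      cand$d <- ifelse(r1$chrom[cand$i] == r2$chrom[cand$j],
                       abs(r1$peak_cm[cand$i] - r2$peak_cm[cand$j]), Inf)
      cand <- cand[cand$d <= max_peak_distance_cM, , drop = FALSE]
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (used1[i] || used2[j]) next
        used1[i] <- TRUE; used2[j] <- TRUE
        e1 <- r1$additive_effect[i]; e2 <- r2$additive_effect[j]
        no <- no + 1L
        out[[no]] <- data.frame(
          gene_id = g, peak1 = r1$peak_marker[i], peak2 = r2$peak_marker[j],
          effect1 = e1, effect2 = e2, distance_cM = cand$d[k],
          overlapping = TRUE,
          opposite_effect = (e1 * e2) < 0, stringsAsFactors = FALSE
        )
      }
    }
    for (i in which(!used1)) {
      ns <- ns + 1L
      spec[[ns]] <- data.frame(gene_id = g, experiment = 1L,
                               peak_marker = r1$peak_marker[i],
                               stringsAsFactors = FALSE)
    }
    for (j in which(!used2)) {
      ns <- ns + 1L
      spec[[ns]] <- data.frame(gene_id = g, experiment = 2L,
                               peak_marker = r2$peak_marker[j],
                               stringsAsFactors = FALSE)
    }
  }
  empty_m <- data.frame(gene_id = character(0), peak1 = character(0),
                        peak2 = character(0), effect1 = numeric(0),
                        effect2 = numeric(0), distance_cM = numeric(0),
                        overlapping = logical(0), opposite_effect = logical(0),
                        stringsAsFactors = FALSE)
  empty_s <- data.frame(gene_id = character(0), experiment = integer(0),
                        peak_marker = character(0), stringsAsFactors = FALSE)
  list(matches = if (no) do.call(rbind, out) else empty_m,
       specific = if (ns) do.call(rbind, spec) else empty_s)
}

#' Summarize plasticity records and eQTL matches
#'
#' Counts and fractions per eQTL-class x correlation-class stratum, a
#' histogram of profile correlations binned at 0.05, and overlap/opposite
#' counts from the matches.
#'
#' @param records Data frame from [plasticity_records].
#' @param matches Optional result of [match_eqtls].
#' @return List with `table` (counts per eqtl_class x corr_class),
#'   `fractions`, `histogram` (data frame `bin_lo`, `bin_hi`, `count`), and,
#'   when matches are given, `n_overlapping` and `n_opposite`.
#' @export
plasticity_summary <- function(records, matches = NULL) {
  tab <- table(eqtl_class = records$eqtl_class, corr_class = records$corr_class)
  breaks <- seq(-1, 1, by = 0.05)
  r <- records$r[!is.na(records$r)]
  bin <- pmin(pmax(findInterval(r, breaks, rightmost.closed = TRUE), 1),
              length(breaks) - 1)
  out <- list(table = tab, fractions = prop.table(tab, margin = 1),
              histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                     bin_hi = breaks[-1],
                                     count = tabulate(bin, length(breaks) - 1)))
  if (!is.null(matches)) {
    out$n_overlapping <- sum(matches$matches$overlapping)
    out$n_opposite <- sum(matches$matches$opposite_effect)
  }
  out
}
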