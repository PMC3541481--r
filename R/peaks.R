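#' Call eQTL peaks from a genome scan
#'
#' Per gene and chromosome, every maximal run of consecutive markers with
#' `neg_log10_p >= threshold` yields one eQTL record. The peak is the marker
#' with the largest `neg_log10_p` in the run (leftmost on ties); the support
#' interval is the run itself.
#'
#' @param scan A `scan_result` from [genome_scan].
#' @param neg_log10_threshold Significance threshold on the -log10(p) scale.
#' @param genes Optional subset of gene ids to call.
#' @return Data frame of eQTL records: `gene_id`, `chrom`, `peak_marker`,
#'   `peak_bp`, `peak_cm`, `peak_neg_log10_p`, `additive_effect`,
#'   `interval_start`, `interval_end` (marker ids), `locality` (NA until
#'   [classify_local_distant]).
#' @export
call_peaks <- function(scan, neg_log10_threshold, genes = NULL) {
  if (neg_log10_threshold < 0) stop("threshold must be >= 0")
  map <- scan$map
  nlp <- scan$neg_log10_p
  eff <- scan$additive_effect
  if (!is.null(genes)) {
    nlp <- nlp[genes, , drop = FALSE]
    eff <- eff[genes, , drop = FALSE]
  }
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  recs <- list(); nr <- 0L
  push <- function(r) {
    nr <<- nr + 1L
    recs[[nr]] <<- r
  }
  for (g in seq_len(nrow(nlp))) {
    sig <- nlp[g, ] >= neg_log10_threshold
    if (!any(sig)) next
    for (chr in names(chrom_idx)) {
      idx <- chrom_idx[[chr]]
      s <- sig[idx]
      if (!any(s)) next
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- idx[starts[k]:ends[k]]
        peak <- run[which.max(nlp[g, run])]
        push(data.frame(
          gene_id = rownames(nlp)[g], chrom = as.integer(chr),
          peak_marker = map$marker[peak], peak_bp = map$bp[peak],
          peak_cm = map$cm[peak],
          peak_neg_log10_p = unname(nlp[g, peak]),
          additive_effect = unname(eff[g, peak]),
          interval_start = map$marker[run[1]],
          interval_end = map$marker[run[length(run)]],
          locality = NA_character_, stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (nr == 0L) {
    return(data.frame(gene_id = character(0), chrom = integer(0),
                      peak_marker = character(0), peak_bp = integer(0),
                      peak_cm = numeric(0), peak_neg_log10_p = numeric(0),
                      additive_effect = numeric(0),
                      interval_start = character(0),
                      interval_end = character(0),
                      locality = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs[seq_len(nr)])
  rownames(out) <- NULL
  out
}

#' Classify eQTL records as local (cis) or distant (trans)
#'
#' A record is local iff its peak marker lies on the regulated gene's own
#' chromosome and within `window_bp` (inclusive) of the gene's annotated
#' physical position; otherwise distant. The window accounts for the broad
#' linkage disequilibrium of a small RIL population.
#'
#' @param records eQTL records from [call_peaks].
#' @param annotation Data frame with `gene_id`, `chrom`, `bp` covering every
#'   gene in `records`.
#' @param window_bp Local window in bp (default 2e6).
#' @return `records` with `locality` filled in ("local"/"distant").
#' @export
classify_local_distant <- function(records, annotation, window_bp = 2e6) {
  if (!nrow(records)) return(records)
  i <- match(records$gene_id, annotation$gene_id)
  if (anyNA(i)) {
    stop("unannotated gene(s): ",
         paste(unique(records$gene_id[is.na(i)]), collapse = ", "))
  }
  same_chr <- annotation$chrom[i] == records$chrom
  close <- abs(annotation$bp[i] - records$peak_bp) <= window_bp
  records$locality <- ifelse(same_chr & close, "local", "distant")
  records
}

#' Per-gene roll-up of eQTL locality
#'
#' Summarizes classified records into the per-gene categories used in eQTL
#' bookkeeping tables: genes with only local, only distant, or both kinds of
#' eQTL.
#'
#' @param records Classified eQTL records.
#' @return List with `per_gene` (data frame `gene_id`, `category`) and
#'   `counts` (named vector: n_eqtl, n_genes, only_local, only_distant, both,
#'   distant_eqtl).
#' @export
locality_summary <- function(records) {
  if (!nrow(records)) {
    return(list(per_gene = data.frame(gene_id = character(0),
                                      category = character(0)),
                counts = c(n_eqtl = 0, n_genes = 0, only_local = 0,
                           only_distant = 0, both = 0, distant_eqtl = 0)))
  }
  has_local <- tapply(records$locality == "local", records$gene_id, any)
  has_dist <- tapply(records$locality == "distant", records$gene_id, any)
  category <- ifelse(has_local & has_dist, "both",
                     ifelse(has_local, "only_local", "only_distant"))
  per_gene <- data.frame(gene_id = names(category),
                         category = unname(category),
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       counts = c(n_eqtl = nrow(records),
                  n_genes = length(category),
                  only_local = sum(category == "only_local"),
                  only_distant = sum(category == "only_distant"),
                  both = sum(category == "both"),
                  distant_eqtl = sum(records$locality == "distant")))
}
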