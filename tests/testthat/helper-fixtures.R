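# Shared small fixtures, built once per test run.

fix_map <- ggxe::generate_map(5, 20, 95)
fix_geno <- ggxe::simulate_ril_genotypes(fix_map, 160, seed = 11)

# One-chromosome map with arbitrary positions, for hand-built scans.
manual_map <- function(cm, chrom = 1L, bp = NULL) {
  # seq_along offset keeps bp strictly increasing for near-coincident markers
  if (is.null(bp)) bp <- as.integer(round(cm * 250000) + seq_along(cm))
  ggxe::validate_map(data.frame(
    marker = sprintf("m%02d", seq_along(cm)), chrom = chrom, cm = cm, bp = bp,
    stringsAsFactors = FALSE))
}

# A scan_result for a single gene from explicit profiles.
manual_scan <- function(map, neg_log10_p, effect, gene = "G1") {
  p <- 10^(-neg_log10_p)
  structure(list(
    p_value = matrix(p, 1, dimnames = list(gene, map$marker)),
    neg_log10_p = matrix(neg_log10_p, 1, dimnames = list(gene, map$marker)),
    additive_effect = matrix(effect, 1, dimnames = list(gene, map$marker)),
    map = map), class = "scan_result")
}
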