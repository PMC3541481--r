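#!/usr/bin/env Rscript
# Cross-environment comparison: signed -log10(P) profile correlations per
# gene, the four eQTL-presence strata, and matched/opposite-effect eQTLs.

suppressPackageStartupMessages(library(ggxe))

out <- "results/analysis"
sc1 <- readRDS("results/scan_GG1.rds")
sc2 <- readRDS("results/scan_GG2.rds")
rec1 <- read_tsv_table(file.path(out, "eqtl_GG1.tsv"))
rec2 <- read_tsv_table(file.path(out, "eqtl_GG2.tsv"))

pr <- plasticity_records(sc1, sc2, rec1, rec2)
write_results(pr, file.path(out, "plasticity.tsv"))
mt <- match_eqtls(rec1, rec2, max_peak_distance_cM = 10)
write_results(mt$matches, file.path(out, "eqtl_matches.tsv"))
summ <- plasticity_summary(pr, mt)
write_results(summ$histogram, file.path(out, "plasticity_histogram.tsv"))

both <- pr[pr$eqtl_class == "both", ]
cat(sprintf("genes with an eQTL in both environments: %d\n", nrow(both)))
cat(sprintf("  strong positive profile correlation (r > 0.5): %d (%.0f%%)\n",
            sum(both$corr_class == "strong_positive"),
            100 * mean(both$corr_class == "strong_positive")))
cat(sprintf("  strong negative profile correlation (r < -0.5): %d (%.0f%%)\n",
            sum(both$corr_class == "strong_negative"),
            100 * mean(both$corr_class == "strong_negative")))
cat(sprintf("overlapping eQTL pairs (peaks <= 10 cM apart): %d, of which %d with opposing additive effects\n",
            summ$n_overlapping, summ$n_opposite))
print(summ$table)
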