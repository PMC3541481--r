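#!/usr/bin/env Rscript
# Genome scans per environment and the two-stage genome-wide significance
# threshold: Churchill-Doerge permutation (alpha = 0.05) and the Storey
# pooled-FDR threshold (nominal 0.05 corrected by factor 5 for marker
# correlation); the mapping threshold is the stricter of the two.

suppressPackageStartupMessages(library(ggxe))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

log <- list()
for (env in c("GG1", "GG2")) {
  dat <- load_dataset("results/data", env)
  scan <- genome_scan(dat$dataset, dat$genotypes, dat$map, environment = env)
  saveRDS(scan, file.path("results", sprintf("scan_%s.rds", env)))
  perm <- permutation_threshold(dat$dataset, dat$genotypes, dat$map,
                                n_permutations = 1000, alpha = 0.05,
                                seed = seed + 100, environment = env)
  kept <- thin_markers(dat$map, dat$genotypes, r2_max = 0.95)
  fdr <- pooled_threshold(as.vector(scan$p_value[, kept]),
                          nominal_fdr = 0.05, correction_factor = 5)
  ts <- threshold_set(perm$p_threshold, fdr$p_threshold,
                      n_permutations = 1000, correction_factor = 5)
  log[[env]] <- list(permutation_p = perm$p_threshold,
                     fdr_p = fdr$p_threshold,
                     final_neg_log10 = ts$final_neg_log10_threshold)
  cat(sprintf("%s: permutation p = %.3g, pooled-FDR p = %.3g, -log10(P) threshold = %.2f\n",
              env, perm$p_threshold, fdr$p_threshold,
              ts$final_neg_log10_threshold))
}
yaml::write_yaml(log, file.path(out, "thresholds.yaml"))
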