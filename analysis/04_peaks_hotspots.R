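#!/usr/bin/env Rscript
# Peak calling at the mapping threshold, local/distant classification,
# per-gene locality bookkeeping, and hotspot detection, with the two
# standard figures (gene-vs-peak scatter, per-marker counts).

suppressPackageStartupMessages(library(ggxe))

out <- "results/analysis"
fig <- "results/figures"
dir.create(fig, recursive = TRUE, showWarnings = FALSE)
thr <- yaml::read_yaml(file.path(out, "thresholds.yaml"))

for (env in c("GG1", "GG2")) {
  dat <- load_dataset("results/data", env)
  scan <- readRDS(file.path("results", sprintf("scan_%s.rds", env)))
  rec <- call_peaks(scan, thr[[env]]$final_neg_log10)
  rec <- classify_local_distant(rec, dat$dataset$annotation, window_bp = 2e6)
  write_results(rec, file.path(out, sprintf("eqtl_%s.tsv", env)))
  ls <- locality_summary(rec)
  cat(sprintf("%s: %d eQTLs for %d genes (%d only local, %d only distant, %d both; %.1f%% distant)\n",
              env, ls$counts["n_eqtl"], ls$counts["n_genes"],
              ls$counts["only_local"], ls$counts["only_distant"],
              ls$counts["both"],
              100 * ls$counts["distant_eqtl"] / ls$counts["n_eqtl"]))

  hs <- hotspot_scan(rec, dat$map, alpha = 0.05)
  write_results(hs, file.path(out, sprintf("hotspots_%s.tsv", env)))
  cat(sprintf("%s: hotspot threshold %d peaks/marker; %d hotspot marker(s)\n",
              env, hs$threshold[1], sum(hs$is_hotspot)))

  png(file.path(fig, sprintf("eqtl_positions_%s.png", env)), 900, 900)
  plot_eqtl_positions(rec, dat$dataset$annotation, dat$map,
                      main = sprintf("eQTL peak vs gene position (%s)", env))
  dev.off()
  png(file.path(fig, sprintf("hotspots_%s.png", env)), 1200, 500)
  plot_hotspots(hs, main = sprintf("eQTL peaks per marker (%s)", env))
  dev.off()
}
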