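#!/usr/bin/env Rscript
# Parental differential expression, broad-sense heritability in parents and
# RILs, and transgressive segregation, on the GG2-like environment.

suppressPackageStartupMessages(library(ggxe))

dat <- load_dataset("results/data", "GG2")
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- dat$dataset
par1 <- ds$expr[, ds$samples$line_id == "Ler", drop = FALSE]
par2 <- ds$expr[, ds$samples$line_id == "Cvi", drop = FALSE]

de <- differential_expression(par1, par2)
write_results(de, file.path(out, "parents_de.tsv"))
cat(sprintf("differentially abundant transcripts (q < 0.05): %d of %d\n",
            sum(de$q_value < 0.05), nrow(de)))

h2p <- h2_parents(cbind(par1, par2),
                  c(rep("Ler", ncol(par1)), rep("Cvi", ncol(par2))))
rils <- line_means(ds, ril_only = TRUE)
h2r <- h2_ril(rils, h2p$var_error)
write_results(h2p, file.path(out, "heritability_parents.tsv"))
write_results(h2r, file.path(out, "heritability_rils.tsv"))
cat(sprintf("median broad-sense heritability: parents %.2f, RILs %.2f\n",
            median(h2p$H2), median(h2r$H2)))

# n_min = 20: with ~160 lines and a ~4.6% per-line chance of exceeding a
# parental mean +- 2 SD bound by noise alone, only a sizeable fraction of
# extreme lines indicates real transgressive segregation
tg <- transgression_stats(rils, par1, par2, n_min = 20)
write_results(tg, file.path(out, "transgression.tsv"))
cat(sprintf("transgressive genes (>= 20 RILs beyond parental mean +- 2 SD): %d (%.1f%%)\n",
            sum(tg$is_transgressive), 100 * mean(tg$is_transgressive)))
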