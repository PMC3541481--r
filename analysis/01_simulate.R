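#!/usr/bin/env Rscript
# Simulate the study design: a RIL population genotyped on a 5-chromosome
# map, expression-profiled in two environments (GG1-like and GG2-like) with
# a known effect architecture that mixes constitutive, environment-specific
# and sign-flip (GxE) regulation.

suppressPackageStartupMessages(library(ggxe))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

map <- generate_map(n_chrom = 5, markers_per_chrom = 20, chrom_length = 95)
geno <- simulate_ril_genotypes(map, n_lines = 160, seed = seed)

# 2000 genes: 120 cis + 60 trans drivers; the effect genes split evenly into
# shared (same effect both environments), environment-2-specific and
# sign-flip patterns
arch <- build_architecture(map, n_genes = 2000, n_cis = 120, n_trans = 60,
                           beta = 1.5,
                           beta2 = rep(c(1.5, 0, -1.5), length.out = 180),
                           noise_sd = 1, seed = seed + 1)
# an environment-2-specific trans hotspot: 30 of the trans genes share one
# driver marker (inside the first NIL introgression on chromosome 1) and
# respond in GG2 only -- the analogue of a treatment-induced HTR
hub <- map$marker[map$chrom == 1 & map$bp == 5000000]
hub_genes <- which(arch$kind == "trans")[1:30]
arch$source_marker[hub_genes] <- hub
arch$beta_env1[hub_genes] <- 0
arch$beta_env2[hub_genes] <- 1.5
for (env in c("GG1", "GG2")) {
  sim <- simulate_expression(geno, map, arch, env,
                             ril_replicates = 1, parent_replicates = 9,
                             noise_seed = seed + match(env, c("GG1", "GG2")))
  write_dataset(map, geno, sim, out)
  cat(sprintf("%s: %d genes x %d samples\n", env, nrow(sim$dataset$expr),
              ncol(sim$dataset$expr)))
}

x <- genotype_numeric(geno)
cat(sprintf("markers: %d on %d chromosomes; allele-A frequency %.3f\n",
            nrow(map), max(map$chrom), mean(x == 1)))
cat(sprintf("architecture: %d cis, %d trans, %d null genes\n",
            sum(arch$kind == "cis"), sum(arch$kind == "trans"),
            sum(arch$kind == "null")))
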