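test_that("marker regression equals the pooled two-sample t-test", {
  x <- c(1, 1, 1, 1, -1, -1, -1, -1)
  y <- c(5, 6, 5, 6, 1, 2, 1, 2)
  res <- marker_regression(y, x)
  tt <- t.test(y[x == 1], y[x == -1], var.equal = TRUE)
  expect_equal(res$additive_effect, 2.0)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(unname(tt$statistic), 9.797959, tolerance = 1e-6)

  # sign symmetry under label swap
  swapped <- marker_regression(y, -x)
  expect_equal(swapped$additive_effect, -res$additive_effect)
  expect_equal(swapped$p_value, res$p_value)

  # degenerate conventions
  flat <- marker_regression(rep(3, 8), x)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$additive_effect, 0)
  sep <- marker_regression(c(2, 2, 2, 2, 0, 0, 0, 0), x)
  expect_equal(sep$neg_log10_p, 300)
  expect_error(marker_regression(y, rep(1, 8)), "monomorphic")

  # oracle equivalence on 1000 random instances
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(6:40, 1)
    xi <- c(rep(1, 2), rep(-1, 2), sample(c(1, -1), n - 4, replace = TRUE))
    yi <- rnorm(n)
    r <- marker_regression(yi, xi)
    o <- t.test(yi[xi == 1], yi[xi == -1], var.equal = TRUE)
    expect_lt(abs(r$p_value - o$p.value), 1e-10)
    expect_lt(abs(r$additive_effect -
                    (mean(yi[xi == 1]) - mean(yi[xi == -1])) / 2), 1e-12)
  }
})

test_that("vectorized genome scan matches the per-cell regression", {
  map <- manual_map(seq(0, 40, by = 10))
  geno <- simulate_ril_genotypes(map, 60, seed = 21)
  sim <- simulate_null_dataset(geno, map, n_genes = 20, seed = 22)
  scan <- genome_scan(sim$dataset, geno, map)
  x <- genotype_numeric(geno)
  Y <- line_means(sim$dataset)
  for (g in c(1, 7, 20)) {
    for (m in c(1, 3, 5)) {
      ref <- marker_regression(Y[g, ], x[, m])
      expect_equal(scan$p_value[g, m], ref$p_value, tolerance = 1e-10)
      expect_equal(scan$additive_effect[g, m], ref$additive_effect,
                   tolerance = 1e-12)
    }
  }
  expect_error(genome_scan(Y[, 1:10, drop = FALSE][, ], geno[1:5, ], map),
               "absent from genotype")
})

test_that("null scans produce uniform p-values", {
  sim <- simulate_null_dataset(fix_geno, fix_map, n_genes = 2000, seed = 23)
  scan <- genome_scan(sim$dataset, fix_geno, fix_map)
  frac <- mean(scan$p_value < 0.05)
  # markers are correlated within a gene, so the effective number of
  # independent tests is smaller than genes x markers; bound via per-gene
  # averaging (2000 independent genes, within-gene mean has variance
  # inflated by marker correlation <= 1)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("cis effects are recovered at or next to the source marker", {
  arch <- build_architecture(fix_map, 100, n_cis = 100, beta = 1.5,
                             noise_sd = 1, seed = 24)
  sim <- simulate_expression(fix_geno, fix_map, arch, "GG1", noise_seed = 25)
  scan <- genome_scan(sim$dataset, fix_geno, fix_map, environment = "GG1")
  src_i <- match(arch$source_marker, fix_map$marker)
  top <- apply(scan$neg_log10_p, 1, which.max)
  expect_gte(sum(abs(top - src_i) <= 1), 95)
})

test_that("a cofactor at the source marker absorbs the whole signal", {
  arch <- build_architecture(fix_map, 60, n_cis = 60, beta = 1.5, noise_sd = 1,
                             seed = 26)
  sim <- simulate_expression(fix_geno, fix_map, arch, "GG1", noise_seed = 27)
  cof <- as.list(arch$source_marker)
  names(cof) <- arch$gene_id
  scan <- genome_scan(sim$dataset, fix_geno, fix_map, environment = "GG1",
                      cofactors = cof)
  # permutation threshold for this design
  thr <- permutation_threshold(sim$dataset, fix_geno, fix_map,
                               n_permutations = 500, seed = 28,
                               environment = "GG1")$neg_log10_threshold
  clean <- sum(apply(scan$neg_log10_p, 1, max) < thr)
  expect_gte(clean, 57)  # >= 95% of 60 genes
})

test_that("forward cofactor selection finds true loci and ignores noise", {
  map <- manual_map(seq(0, 70, by = 10), chrom = 1L)
  map2 <- validate_map(rbind(map, within(manual_map(seq(0, 70, by = 10)), {
    chrom <- 2L; marker <- sub("m", "n", marker)
  })))
  geno <- simulate_ril_genotypes(map2, 160, seed = 29)
  x <- genotype_numeric(geno)
  src <- c("m03", "n05")
  hits <- 0
  for (s in 1:50) {
    set.seed(300 + s)
    y <- 2 * x[, src[1]] + 2 * x[, src[2]] + rnorm(160, sd = 0.5)
    sel <- select_cofactors(y, geno, map2, max_cofactors = 4, entry_p = 1e-4)
    near <- function(m, target) {
      i <- match(m, map2$marker); j <- match(target, map2$marker)
      any(map2$chrom[i] == map2$chrom[j] & abs(map2$cm[i] - map2$cm[j]) <= 10)
    }
    ok1 <- any(vapply(sel, near, logical(1), target = src[1]))
    ok2 <- any(vapply(sel, near, logical(1), target = src[2]))
    hits <- hits + (ok1 && ok2)
  }
  expect_gte(hits, 45)  # >= 90%

  empty <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    y <- rnorm(160)
    sel <- select_cofactors(y, geno, map2, max_cofactors = 4, entry_p = 1e-6)
    empty <- empty + (length(sel) == 0)
  }
  expect_gte(empty, 99)
  expect_identical(select_cofactors(rnorm(160), geno, map2, max_cofactors = 0),
                   character(0))
})

test_that("permutation thresholds are calibrated and monotone", {
  # single marker: genome-wide = pointwise, threshold ~ alpha
  m1 <- validate_map(data.frame(marker = "m1", chrom = 1L, cm = 0, bp = 0))
  g1 <- simulate_ril_genotypes(manual_map(c(0, 200)), 100, seed = 31)[, 1,
                                                                      drop = FALSE]
  colnames(g1) <- "m1"
  class(g1) <- c("genotype_matrix", class(g1))
  set.seed(32)
  Y <- matrix(rnorm(3 * 100), 3, 100, dimnames = list(paste0("G", 1:3),
                                                      rownames(g1)))
  pt <- permutation_threshold(Y, g1, m1, n_permutations = 10000, seed = 33)
  expect_lt(abs(pt$p_threshold - 0.05), 3 * sqrt(0.05 * 0.95 / 10000) + 0.01)

  # quantile monotonicity in alpha
  pa <- permutation_threshold(Y, g1, m1, n_permutations = 1000, seed = 34,
                              alpha = 0.01)$p_threshold
  pb <- permutation_threshold(Y, g1, m1, n_permutations = 1000, seed = 34,
                              alpha = 0.10)$p_threshold
  expect_lte(pa, pb)
  expect_error(permutation_threshold(Y, g1, m1, alpha = 1.2), "alpha")

  # many-marker null: Bonferroni < threshold < pointwise
  map <- generate_map(5, 35, 85)
  geno <- simulate_ril_genotypes(map, 120, seed = 35)
  sim <- simulate_null_dataset(geno, map, n_genes = 50, seed = 36)
  pm <- permutation_threshold(sim$dataset, geno, map, n_permutations = 1000,
                              seed = 37)
  expect_gt(pm$p_threshold, 0.05 / 175)
  expect_lt(pm$p_threshold, 0.05)
})

test_that("peak calling splits supra-threshold runs per chromosome", {
  map <- manual_map(seq(0, 50, by = 10))
  sc <- manual_scan(map, c(0.5, 4.0, 5.2, 4.1, 0.3, 3.9),
                    c(0.2, 0.5, 0.6, 0.4, -0.1, -0.3))
  rec <- call_peaks(sc, 3.62)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$peak_marker, c("m03", "m06"))
  expect_equal(rec$interval_start, c("m02", "m06"))
  expect_equal(rec$interval_end, c("m04", "m06"))
  expect_equal(rec$additive_effect, c(0.6, -0.3))

  expect_equal(nrow(call_peaks(sc, 10)), 0)
  all_hi <- manual_scan(map, rep(4, 6), rep(1, 6))
  rec2 <- call_peaks(all_hi, 3.62)
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$interval_start, "m01")
  expect_equal(rec2$interval_end, "m06")
  # tie -> leftmost peak
  expect_equal(rec2$peak_marker, "m01")
})

test_that("local/distant classification uses an inclusive physical window", {
  map <- manual_map(c(0, 10, 20))
  sc <- manual_scan(map, c(4, 0, 0), c(1, 0, 0))
  rec <- call_peaks(sc, 3.62)
  ann0 <- data.frame(gene_id = "G1", chrom = 1L, bp = rec$peak_bp)
  expect_equal(classify_local_distant(rec, ann0)$locality, "local")
  ann_far <- data.frame(gene_id = "G1", chrom = 4L, bp = rec$peak_bp)
  expect_equal(classify_local_distant(rec, ann_far)$locality, "distant")
  ann_3mb <- data.frame(gene_id = "G1", chrom = 1L, bp = rec$peak_bp + 3e6)
  expect_equal(classify_local_distant(rec, ann_3mb, window_bp = 2e6)$locality,
               "distant")
  ann_edge <- data.frame(gene_id = "G1", chrom = 1L, bp = rec$peak_bp + 2e6)
  expect_equal(classify_local_distant(rec, ann_edge, window_bp = 2e6)$locality,
               "local")
  expect_error(classify_local_distant(rec, data.frame(gene_id = "GX",
                                                      chrom = 1L, bp = 0)),
               "unannotated")
})

test_that("positive simulated betas give positive effects at the source", {
  map <- manual_map(seq(0, 40, by = 10))
  geno <- simulate_ril_genotypes(map, 40, seed = 38)
  arch <- build_architecture(map, 3, n_cis = 3, beta = 1, noise_sd = 1e-9,
                             seed = 39)
  sim <- simulate_expression(geno, map, arch, "GG1", noise_seed = 40)
  scan <- genome_scan(sim$dataset, geno, map)
  for (i in 1:3) {
    expect_gt(scan$additive_effect[i, arch$source_marker[i]], 0)
  }
})
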