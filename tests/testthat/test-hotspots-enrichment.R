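test_that("hotspot threshold is the Bonferroni-corrected Poisson tail", {
  map <- manual_map(seq(0, 49, by = 1))  # 50 markers
  set.seed(81)
  rec <- data.frame(gene_id = paste0("G", 1:100), chrom = 1L,
                    peak_marker = sample(map$marker, 100, replace = TRUE),
                    peak_cm = 0, peak_bp = 0, peak_neg_log10_p = 5,
                    additive_effect = 1, interval_start = "m01",
                    interval_end = "m01", locality = NA_character_,
                    stringsAsFactors = FALSE)
  h <- hotspot_scan(rec, map, alpha = 0.05)
  # T=100, M=50: lambda=2; P(X>=9)=2.37e-4 <= 0.001 < P(X>=8)=1.10e-3 -> c=9
  expect_equal(h$threshold[1], 9)
  expect_equal(h$expected[1], 2)
  expect_equal(sum(h$n_total), 100)

  # all peaks at one marker -> exactly one hotspot
  rec1 <- rec; rec1$peak_marker <- "m07"
  h1 <- hotspot_scan(rec1, map, alpha = 0.05)
  expect_equal(sum(h1$is_hotspot), 1)
  expect_true(h1$is_hotspot[h1$marker == "m07"])
  expect_error(hotspot_scan(rec, map, alpha = 2), "alpha")
})

test_that("uniform peak placement rarely triggers a hotspot call", {
  map <- manual_map(seq(0, 49, by = 1))
  set.seed(82)
  flagged <- 0
  for (i in 1:200) {
    rec <- data.frame(gene_id = paste0("G", 1:100), chrom = 1L,
                      peak_marker = sample(map$marker, 100, replace = TRUE),
                      peak_cm = 0, peak_bp = 0, peak_neg_log10_p = 5,
                      additive_effect = 1, interval_start = "m01",
                      interval_end = "m01", locality = NA_character_,
                      stringsAsFactors = FALSE)
    flagged <- flagged + any(hotspot_scan(rec, map, alpha = 0.05)$is_hotspot)
  }
  expect_lte(flagged / 200, 0.05)
})

test_that("hypergeometric tails reproduce printed enrichment bounds", {
  e1 <- hypergeom_enrichment(506, 2278, 2794, 17498)
  expect_lt(e1$p_value, 1.8e-17)
  expect_gt(e1$p_value, 1.8e-18)  # same order as the printed bound
  e2 <- hypergeom_enrichment(913, 4297, 1230, 6676)
  expect_lt(e2$p_value, 1.3e-16)
  expect_gt(e2$p_value, 1.3e-17)
})

test_that("hypergeometric tails are exact", {
  # enumeration over C(10,4) = 210 outcomes
  e <- hypergeom_enrichment(3, 4, 5, 10)
  expect_equal(e$p_value, 5 / 210, tolerance = 1e-14)
  ei <- hypergeom_enrichment(3, 4, 5, 10, tail_mode = "inclusive")
  expect_equal(ei$p_value, 55 / 210, tolerance = 1e-14)

  # degenerate: all of the population are successes
  expect_equal(hypergeom_enrichment(4, 4, 10, 10)$p_value, 0)

  # frozen exact-rational oracle values (N <= 60)
  oracle <- data.frame(
    N = c(10, 60, 60, 57, 60, 45, 60, 33, 60, 50),
    K = c(5, 30, 25, 40, 10, 20, 1, 16, 59, 25),
    n = c(4, 30, 18, 12, 55, 20, 30, 17, 30, 25),
    k = c(3, 20, 10, 9, 9, 12, 1, 0, 29, 5),
    strict = c(0.023809523809523808, 0.002058683969578904,
               0.04362997366188832, 0.22645636684848655, 0.38794385144626614,
               0.014201195784753996, 0, 0.9999999991429573, 0.5,
               0.9999763611605845),
    inclusive = c(0.2619047619047619, 0.009691594130894984,
                  0.1267980688584654, 0.489346575206977, 0.8096219508443816,
                  0.0571827587731059, 0.5, 1, 1, 0.9999986915407603))
  for (i in seq_len(nrow(oracle))) {
    s <- hypergeom_enrichment(oracle$k[i], oracle$n[i], oracle$K[i],
                              oracle$N[i])$p_value
    ic <- hypergeom_enrichment(oracle$k[i], oracle$n[i], oracle$K[i],
                               oracle$N[i], tail_mode = "inclusive")$p_value
    expect_equal(s, oracle$strict[i], tolerance = 1e-10)
    expect_equal(ic, oracle$inclusive[i], tolerance = 1e-10)
  }

  # strict + pmf(k) = inclusive, exhaustively for small populations
  for (N in c(6, 9, 12, 15)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          s <- hypergeom_enrichment(k, n, K, N)$p_value
          ic <- hypergeom_enrichment(k, n, K, N, tail_mode = "inclusive")$p_value
          expect_equal(s + dhyper(k, K, N - K, n), ic, tolerance = 1e-12)
        }
      }
    }
  }

  # agreement with stats::phyper for larger populations
  set.seed(83)
  for (i in 1:50) {
    N <- sample(100:2000, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    s <- hypergeom_enrichment(k, n, K, N)$p_value
    expect_equal(s, phyper(k, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_enrichment(10, 5, 5, 20), "inconsistent")
})

test_that("interval membership is closed and 1-based", {
  iv <- nil_introgressions()
  items <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = c(1L, 1L, 2L, 1L),
                      bp = c(6000000, 8200000, 6000000, 20000000))
  m <- interval_membership(items, iv)
  expect_equal(unname(m$counts), c(2, 0))
  expect_true(m$membership[1, "introgression1"])
  expect_true(m$membership[2, "introgression1"])   # exactly at the end
  expect_false(any(m$membership[3, ]))              # wrong chromosome
  expect_false(any(m$membership[4, ]))              # between intervals

  empty <- interval_membership(items, iv[0, ])
  expect_equal(sum(empty$membership), 0)
  expect_error(interval_membership(items, rbind(iv, iv)), "unique")
})

test_that("binned counts follow the marker-locus midpoint bins", {
  map <- manual_map(c(0, 10, 20, 30))
  at_markers <- data.frame(chrom = 1L, bp = map$bp)
  bc <- binned_counts(map, at_markers)
  expect_equal(bc$count, rep(1, 4))

  expect_warning(bc2 <- binned_counts(map, data.frame(chrom = 9L, bp = 1)),
                 "unmapped")
  expect_equal(sum(bc2$count), 0)

  # uniform positions distribute proportionally to bin widths
  set.seed(84)
  pos <- data.frame(chrom = 1L, bp = round(runif(2000, 0, max(map$bp))))
  bc3 <- binned_counts(map, pos)
  mids <- c(0, (map$bp[-1] + map$bp[-4]) / 2, max(map$bp))
  widths <- diff(mids)
  expect_gt(chisq.test(bc3$count, p = widths / sum(widths))$p.value, 0.01)

  # weights are summed
  bcw <- binned_counts(map, at_markers, weights = c(0.5, 1, 1, 2))
  expect_equal(bcw$count, c(0.5, 1, 1, 2))
})

test_that("distribution correlation uses the t-test on r", {
  res <- distribution_correlation(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_equal(res$r, 0.9)
  expect_equal(res$t_statistic, 3.576237, tolerance = 1e-6)
  expect_equal(res$p_value, 0.03738607, tolerance = 1e-6)

  same <- distribution_correlation(1:5, 1:5 * 2)
  expect_equal(same$r, 1)
  expect_lt(same$p_value, 1e-200)
  expect_equal(distribution_correlation(1:5, -(1:5))$r, -1)
  expect_error(distribution_correlation(1:5, rep(2, 5)), "constant")
  expect_error(distribution_correlation(1:4, 1:5), "mismatch")
})

test_that("a simulated trans hotspot is detected end to end", {
  map <- manual_map(seq(0, 95, by = 5))
  geno <- simulate_ril_genotypes(map, 160, seed = 85)
  hub <- "m10"
  hits <- 0
  for (s in 1:30) {
    arch <- build_architecture(map, 100, n_cis = 0, n_trans = 30, beta = 1.5,
                               noise_sd = 1, seed = 86)
    arch$source_marker[arch$kind == "trans"] <- hub
    sim <- simulate_expression(geno, map, arch, "GG1", noise_seed = 900 + s)
    scan <- genome_scan(sim$dataset, geno, map, environment = "GG1")
    rec <- call_peaks(scan, 3.62)
    h <- hotspot_scan(rec, map, alpha = 0.05)
    hits <- hits + h$is_hotspot[h$marker == hub]
  }
  expect_gte(hits, 29)  # >= 95%
})
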