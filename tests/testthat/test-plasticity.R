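test_that("signed profiles combine significance and effect sign", {
  map <- manual_map(c(0, 10, 20))
  flat <- manual_scan(map, c(0, 0, 0), c(0, 0.5, -0.5))
  expect_equal(as.vector(signed_profiles(flat)), c(0, 0, 0))

  sc <- manual_scan(map, c(4, 1, 2), c(-0.3, 0.2, 0))
  expect_equal(as.vector(signed_profiles(sc)), c(-4, 1, 0))

  neg <- manual_scan(map, c(4, 1, 2), -c(-0.3, 0.2, 0))
  expect_equal(signed_profiles(neg), -signed_profiles(sc))
})

test_that("profile correlation classes use strict 0.5 bounds", {
  s <- c(0, 3, -2, 5, 1)
  expect_equal(profile_correlation(s, s), list(r = 1, corr_class = "strong_positive"))
  expect_equal(profile_correlation(s, -s), list(r = -1, corr_class = "strong_negative"))
  # r exactly 0.5 -> weak ("higher than 0.5" is strict)
  a <- c(2, 1, 0); b <- c(1, 2, 0)
  expect_equal(cor(a, b), 0.5)
  expect_equal(profile_correlation(a, b)$corr_class, "weak")
  # undefined r
  expect_true(is.na(profile_correlation(c(0, 0, 0), s[1:3])$r))
  expect_equal(profile_correlation(c(0, 0, 0), s[1:3])$corr_class, "weak")
  expect_error(profile_correlation(1:4, 1:5), "mismatch")
  # invariance under positive rescaling, negation under flip
  expect_equal(profile_correlation(2.5 * s, s)$r, 1)
  expect_equal(profile_correlation(s, 0.1 * s)$r, 1)
})

test_that("eQTL matching pairs nearby peaks and flags opposite effects", {
  map <- validate_map(data.frame(
    marker = c("a1", "a2", "b1"), chrom = c(1L, 1L, 2L),
    cm = c(0, 10, 0), bp = c(0, 2500000, 0), stringsAsFactors = FALSE))
  rec <- function(gene, marker, eff) {
    i <- match(marker, map$marker)
    data.frame(gene_id = gene, chrom = map$chrom[i], peak_marker = marker,
               peak_bp = map$bp[i], peak_cm = map$cm[i],
               peak_neg_log10_p = 5, additive_effect = eff,
               interval_start = marker, interval_end = marker,
               locality = NA_character_, stringsAsFactors = FALSE)
  }
  # different chromosomes: never overlapping
  m1 <- match_eqtls(rec("G1", "a1", 0.4), rec("G1", "b1", -0.2))
  expect_equal(nrow(m1$matches), 0)
  expect_equal(nrow(m1$specific), 2)

  # exactly 10 cM apart with max 10 (inclusive) and opposite signs
  m2 <- match_eqtls(rec("G1", "a1", 0.4), rec("G1", "a2", -0.2),
                    max_peak_distance_cM = 10)
  expect_true(m2$matches$overlapping)
  expect_true(m2$matches$opposite_effect)

  # same signs
  m3 <- match_eqtls(rec("G1", "a1", 0.4), rec("G1", "a2", 0.2))
  expect_false(m3$matches$opposite_effect)

  # opposite_effect implies overlapping, exhaustively on random record sets
  set.seed(71)
  for (i in 1:20) {
    r1 <- do.call(rbind, lapply(1:3, function(k) {
      rec(paste0("G", k), sample(map$marker, 1), rnorm(1))
    }))
    r2 <- do.call(rbind, lapply(1:3, function(k) {
      rec(paste0("G", k), sample(map$marker, 1), rnorm(1))
    }))
    m <- match_eqtls(r1, r2, max_peak_distance_cM = sample(c(0, 5, 10), 1))
    expect_true(all(!m$matches$opposite_effect | m$matches$overlapping))
  }
})

test_that("profile correlation separates shared, flipped and null genes", {
  map <- manual_map(seq(0, 95, by = 5))
  geno <- simulate_ril_genotypes(map, 160, seed = 72)
  arch <- build_architecture(map, 300, n_cis = 200, beta = 2,
                             beta2 = rep(c(2, -2), 100), noise_sd = 0.5,
                             seed = 73)
  s1 <- simulate_expression(geno, map, arch, "GG1", noise_seed = 74)
  s2 <- simulate_expression(geno, map, arch, "GG2", noise_seed = 75)
  sc1 <- genome_scan(s1$dataset, geno, map, environment = "GG1")
  sc2 <- genome_scan(s2$dataset, geno, map, environment = "GG2")
  thr <- 3.62
  rec1 <- call_peaks(sc1, thr); rec2 <- call_peaks(sc2, thr)
  pr <- plasticity_records(sc1, sc2, rec1, rec2)

  shared <- arch$gene_id[arch$beta_env1 == 2 & arch$beta_env2 == 2]
  flip <- arch$gene_id[arch$beta_env2 == -2]
  null <- arch$gene_id[arch$kind == "null"]
  expect_gte(mean(pr$corr_class[pr$gene_id %in% shared] == "strong_positive"),
             0.9)
  expect_gte(mean(pr$corr_class[pr$gene_id %in% flip] == "strong_negative"),
             0.9)
  rn <- pr$r[pr$gene_id %in% null]
  expect_lt(abs(mean(rn, na.rm = TRUE)), 3 * sd(rn, na.rm = TRUE) / sqrt(sum(!is.na(rn))) + 0.1)
  expect_equal(sort(unique(pr$eqtl_class[pr$gene_id %in% shared])), "both")

  summ <- plasticity_summary(pr, match_eqtls(rec1, rec2))
  expect_equal(sum(summ$histogram$count), sum(!is.na(pr$r)))
  expect_gte(summ$n_opposite, 0.9 * length(flip))
})

test_that("environment-specific architectures land in the right class", {
  map <- manual_map(seq(0, 95, by = 5))
  geno <- simulate_ril_genotypes(map, 160, seed = 76)
  # scenario A: effect in environment 2 only
  arch <- build_architecture(map, 60, n_cis = 60, beta = 0, beta2 = 2,
                             noise_sd = 0.5, seed = 77)
  s1 <- simulate_expression(geno, map, arch, "GG1", noise_seed = 78)
  s2 <- simulate_expression(geno, map, arch, "GG2", noise_seed = 79)
  sc1 <- genome_scan(s1$dataset, geno, map, environment = "GG1")
  sc2 <- genome_scan(s2$dataset, geno, map, environment = "GG2")
  rec1 <- call_peaks(sc1, 3.62); rec2 <- call_peaks(sc2, 3.62)
  pr <- plasticity_records(sc1, sc2, rec1, rec2)
  expect_gte(mean(pr$eqtl_class == "exp2_only"), 0.9)
})
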