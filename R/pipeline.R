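#' Default pipeline configuration
#'
#' All thresholds and sizes of the end-to-end demo pipeline, mirroring the
#' study design at desk scale: two environments on one RIL population,
#' genome-wide permutation threshold at alpha = 0.05, Storey FDR at a
#' nominal 0.05 corrected by a factor 5 (effective q <= 0.01), a 2 Mb
#' local/distant window and a 10 cM eQTL overlap radius.
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    n_lines = 160, n_chrom = 5, markers_per_chrom = 20, chrom_length_cM = 95,
    bp_per_cM = 250000,
    n_genes = 2000, n_cis = 120, n_trans = 60,
    beta = 1.5, beta2 = NULL,  # NULL: mix of shared / specific / sign-flip
    noise_sd = 1, ril_replicates = 1, parent_replicates = 9,
    env_labels = c("GG1", "GG2"),
    alpha = 0.05, n_permutations = 1000,
    nominal_fdr = 0.05, correction_factor = 5,
    window_bp = 2e6, max_peak_distance_cM = 10, n_min = 20, r2_max = 0.95
  )
}

#' Run the genetical-genomics pipeline
#'
#' Executes the analysis stages in dependency order on simulated data:
#' `simulate` (RIL genotypes + two-environment expression),
#' `popstats` (parental differential expression, heritability,
#' transgression), `scan` (genome scans per environment), `thresholds`
#' (permutation + pooled-FDR thresholds), `peaks` (peak calling and
#' local/distant classification), `hotspots`, and `plasticity`
#' (signed-profile correlations and eQTL matching). Every stage writes its
#' tables under `out_dir`; a manifest records the configuration hash, seed,
#' stage timings and row counts. Same config and seed give identical result
#' files.
#'
#' @param config List from [default_config] (possibly modified).
#' @param out_dir Output directory.
#' @param stages Subset of stages to run (default all, in order).
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "popstats", "scan",
                                    "thresholds", "peaks", "hotspots",
                                    "plasticity")) {
  all_stages <- c("simulate", "popstats", "scan", "thresholds", "peaks",
                  "hotspots", "plasticity")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(popstats = "simulate", scan = "simulate", thresholds = "scan",
               peaks = "thresholds", hotspots = "peaks", plasticity = "peaks")
  for (s in stages) {
    for (d in deps[[s]]) {
      if (!d %in% stages) stop("stage '", s, "' requires stage '", d, "'")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(config = config)
  timings <- list(); rowcounts <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if ("simulate" %in% stages) {
    state <- tick("simulate", stage_simulate(state, out_dir))
  }
  if ("popstats" %in% stages) {
    state <- tick("popstats", stage_popstats(state, out_dir))
    rowcounts$parents_de <- nrow(state$parents_de)
  }
  if ("scan" %in% stages) {
    state <- tick("scan", stage_scan(state))
  }
  if ("thresholds" %in% stages) {
    state <- tick("thresholds", stage_thresholds(state, out_dir))
  }
  if ("peaks" %in% stages) {
    state <- tick("peaks", stage_peaks(state, out_dir))
    rowcounts$peaks <- vapply(state$peaks, nrow, integer(1))
  }
  if ("hotspots" %in% stages) {
    state <- tick("hotspots", stage_hotspots(state, out_dir))
  }
  if ("plasticity" %in% stages) {
    state <- tick("plasticity", stage_plasticity(state, out_dir))
    rowcounts$plasticity <- nrow(state$plasticity)
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = config$seed, stages = stages,
                   thresholds_used = state$thresholds_log,
                   timings_s = timings, row_counts = rowcounts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(state)
}

stage_simulate <- function(state, out_dir) {
  cfg <- state$config
  map <- generate_map(cfg$n_chrom, cfg$markers_per_chrom, cfg$chrom_length_cM,
                      cfg$bp_per_cM)
  geno <- simulate_ril_genotypes(map, cfg$n_lines, seed = cfg$seed)
  beta2 <- cfg$beta2
  if (is.null(beta2)) {
    # equal thirds of shared, env2-specific and sign-flip effect genes
    beta2 <- rep(c(cfg$beta, 0, -cfg$beta), length.out = cfg$n_cis + cfg$n_trans)
  }
  arch <- build_architecture(map, cfg$n_genes, cfg$n_cis, cfg$n_trans,
                             beta = cfg$beta, beta2 = beta2,
                             noise_sd = cfg$noise_sd, seed = cfg$seed + 1,
                             env_labels = cfg$env_labels)
  sims <- lapply(seq_along(cfg$env_labels), function(i) {
    simulate_expression(geno, map, arch, cfg$env_labels[i],
                        ril_replicates = cfg$ril_replicates,
                        parent_replicates = cfg$parent_replicates,
                        noise_seed = cfg$seed + 10 + i)
  })
  names(sims) <- cfg$env_labels
  for (env in cfg$env_labels) write_dataset(map, geno, sims[[env]], out_dir)
  c(state, list(map = map, genotypes = geno, architecture = arch, sims = sims))
}

stage_popstats <- function(state, out_dir) {
  cfg <- state$config
  env <- cfg$env_labels[2]  # the "current experiment" environment
  ds <- state$sims[[env]]$dataset
  par1 <- ds$expr[, ds$samples$line_id == "Ler", drop = FALSE]
  par2 <- ds$expr[, ds$samples$line_id == "Cvi", drop = FALSE]
  de <- differential_expression(par1, par2)
  write_results(de, file.path(out_dir, "parents_de.tsv"))
  h2p <- h2_parents(cbind(par1, par2),
                    c(rep("Ler", ncol(par1)), rep("Cvi", ncol(par2))))
  rils <- line_means(ds, ril_only = TRUE)
  h2r <- h2_ril(rils, h2p$var_error)
  write_results(h2p, file.path(out_dir, "heritability_parents.tsv"))
  write_results(h2r, file.path(out_dir, "heritability_rils.tsv"))
  tg <- transgression_stats(rils, par1, par2, n_min = cfg$n_min)
  write_results(tg, file.path(out_dir, "transgression.tsv"))
  c(state, list(parents_de = de, h2_parents = h2p, h2_ril = h2r,
                transgression = tg))
}

stage_scan <- function(state) {
  cfg <- state$config
  scans <- lapply(cfg$env_labels, function(env) {
    genome_scan(state$sims[[env]]$dataset, state$genotypes, state$map,
                environment = env)
  })
  names(scans) <- cfg$env_labels
  c(state, list(scans = scans))
}

stage_thresholds <- function(state, out_dir) {
  cfg <- state$config
  thr <- list(); log <- list()
  kept <- thin_markers(state$map, state$genotypes, cfg$r2_max)
  for (env in cfg$env_labels) {
    perm <- permutation_threshold(state$sims[[env]]$dataset, state$genotypes,
                                  state$map, n_permutations = cfg$n_permutations,
                                  alpha = cfg$alpha, seed = cfg$seed + 100,
                                  environment = env)
    pool <- as.vector(state$scans[[env]]$p_value[, kept])
    fdr <- pooled_threshold(pool, nominal_fdr = cfg$nominal_fdr,
                            correction_factor = cfg$correction_factor)
    ts <- threshold_set(perm$p_threshold, fdr$p_threshold,
                        alpha = cfg$alpha, n_permutations = cfg$n_permutations,
                        nominal_fdr = cfg$nominal_fdr,
                        correction_factor = cfg$correction_factor)
    thr[[env]] <- ts
    log[[env]] <- list(permutation_p = perm$p_threshold,
                       fdr_p = fdr$p_threshold,
                       final_neg_log10 = ts$final_neg_log10_threshold)
  }
  yaml::write_yaml(log, file.path(out_dir, "thresholds.yaml"))
  c(state, list(thresholds = thr, thresholds_log = log))
}

stage_peaks <- function(state, out_dir) {
  cfg <- state$config
  ann <- state$sims[[1]]$dataset$annotation
  peaks <- list()
  for (env in cfg$env_labels) {
    rec <- call_peaks(state$scans[[env]],
                      state$thresholds[[env]]$final_neg_log10_threshold)
    rec <- classify_local_distant(rec, ann, window_bp = cfg$window_bp)
    write_results(rec, file.path(out_dir, sprintf("eqtl_%s.tsv", env)))
    peaks[[env]] <- rec
  }
  c(state, list(peaks = peaks))
}

stage_hotspots <- function(state, out_dir) {
  cfg <- state$config
  hs <- list()
  for (env in cfg$env_labels) {
    if (!nrow(state$peaks[[env]])) next
    h <- hotspot_scan(state$peaks[[env]], state$map, alpha = cfg$alpha)
    write_results(h, file.path(out_dir, sprintf("hotspots_%s.tsv", env)))
    hs[[env]] <- h
  }
  c(state, list(hotspots = hs))
}

stage_plasticity <- function(state, out_dir) {
  cfg <- state$config
  e1 <- cfg$env_labels[1]; e2 <- cfg$env_labels[2]
  pr <- plasticity_records(state$scans[[e1]], state$scans[[e2]],
                           state$peaks[[e1]], state$peaks[[e2]])
  mt <- match_eqtls(state$peaks[[e1]], state$peaks[[e2]],
                    max_peak_distance_cM = cfg$max_peak_distance_cM)
  write_results(pr, file.path(out_dir, "plasticity.tsv"))
  write_results(mt$matches, file.path(out_dir, "eqtl_matches.tsv"))
  summ <- plasticity_summary(pr, mt)
  c(state, list(plasticity = pr, matches = mt, plasticity_summary = summ))
}
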