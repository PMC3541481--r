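#' Construct an effect architecture for expression simulation
#'
#' An effect architecture is one row per simulated gene: its kind (`cis`,
#' `trans` or `null`), the marker whose genotype drives it, the additive
#' effect per +1/-1 genotype unit in each of two environments, a baseline and
#' a noise SD, plus the gene's own annotated position. `cis` genes are placed
#' at (up to jitter within half the marker spacing) their source marker, so
#' the source marker is the nearest marker to the gene; `trans` and `null`
#' genes get uniform random positions.
#'
#' Genotype-by-environment patterns are expressed through the two betas:
#' equal betas give constitutive effects, a zero beta in one environment gives
#' an environment-specific eQTL (plastic regulation in one parent), and betas
#' of opposite sign give the sign-flip pattern in which the allele raising
#' expression differs between environments.
#'
#' @param map A `genetic_map`.
#' @param n_genes Total number of genes.
#' @param n_cis,n_trans Numbers of cis- and trans-acting genes (the rest are
#'   null). Trans genes draw a source marker uniformly; cis genes sit on it.
#' @param beta Additive effect size used for env 1 (recycled over effect genes).
#' @param beta2 Effect for env 2; default equal to `beta`. May be a vector
#'   (recycled) to mix constitutive, specific and sign-flip genes.
#' @param baseline Baseline log-expression (default 8, a typical microarray
#'   log2 intensity).
#' @param noise_sd Residual SD (default 1).
#' @param seed Integer seed for marker/position assignment.
#' @param env_labels Labels of the two environments (default `c("GG1","GG2")`).
#' @return An `effect_table` data frame with columns `gene_id`, `kind`,
#'   `source_marker`, `beta_env1`, `beta_env2`, `baseline`, `noise_sd`,
#'   `chrom`, `bp`, and attribute `env_labels`.
#' @export
build_architecture <- function(map, n_genes, n_cis = 0, n_trans = 0,
                               beta = 1.5, beta2 = beta,
                               baseline = 8, noise_sd = 1, seed = 1,
                               env_labels = c("GG1", "GG2")) {
  map <- validate_map(map)
  stopifnot(n_cis + n_trans <= n_genes, noise_sd > 0)
  set.seed(as.integer(seed))
  n_null <- n_genes - n_cis - n_trans
  kind <- c(rep("cis", n_cis), rep("trans", n_trans), rep("null", n_null))
  src <- map$marker[sample.int(nrow(map), n_genes, replace = TRUE)]
  b1 <- b2 <- numeric(n_genes)
  n_eff <- n_cis + n_trans
  if (n_eff > 0) {
    b1[seq_len(n_eff)] <- rep_len(beta, n_eff)
    b2[seq_len(n_eff)] <- rep_len(beta2, n_eff)
  }
  # gene positions: cis genes jittered around their source marker, the rest uniform
  chrom_len <- tapply(map$bp, map$chrom, max)
  src_i <- match(src, map$marker)
  spacing <- stats::median(diff(map$bp[map$chrom == map$chrom[1]]))
  chrom <- map$chrom[src_i]
  bp <- map$bp[src_i] + round(stats::runif(n_genes, -0.4, 0.4) * spacing)
  rnd <- kind != "cis"
  chroms <- as.integer(names(chrom_len))
  chrom[rnd] <- chroms[sample.int(length(chroms), sum(rnd), replace = TRUE)]
  bp[rnd] <- round(stats::runif(sum(rnd)) * chrom_len[as.character(chrom[rnd])])
  bp <- as.integer(pmax(bp, 0))
  arch <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    kind = kind, source_marker = src,
    beta_env1 = b1, beta_env2 = b2,
    baseline = baseline, noise_sd = noise_sd,
    chrom = chrom, bp = bp, stringsAsFactors = FALSE
  )
  arch$source_marker[arch$kind == "null"] <- NA_character_
  attr(arch, "env_labels") <- env_labels
  class(arch) <- c("effect_table", "data.frame")
  arch
}

#' Simulate an expression dataset from genotypes and an effect architecture
#'
#' For gene g and a sample of line l in the chosen environment,
#' `value = baseline + beta_env * x(l, source_marker) + N(0, noise_sd)`,
#' with `x` the +1/-1 genotype. The parents are included as pseudo-lines of
#' constant genotype (Ler all `A` = +1, Cvi all `B` = -1) so every downstream
#' operation treats parents and RILs uniformly.
#'
#' @param genotypes A `genotype_matrix` for the RILs.
#' @param map A `genetic_map` (marker order reference).
#' @param architecture An `effect_table` (see [build_architecture]).
#' @param environment One of the architecture's environment labels; selects
#'   `beta_env1` or `beta_env2`.
#' @param ril_replicates Samples per RIL (default 1: the study design pools
#'   plants into one profile per RIL).
#' @param parent_replicates Samples per parent (default 3).
#' @param noise_seed Integer seed for the residual noise.
#' @return List with `dataset` (an `expression_dataset`: `expr` genes x
#'   samples matrix, `samples` sheet with `sample_id`, `line_id`,
#'   `environment`, `replicate`, and `annotation` with `gene_id`, `chrom`,
#'   `bp`) and `truth` (a `truth_table`: the architecture, environment labels
#'   and seed).
#' @export
simulate_expression <- function(genotypes, map, architecture, environment,
                                ril_replicates = 1, parent_replicates = 3,
                                noise_seed = 1) {
  map <- validate_map(map)
  env_labels <- attr(architecture, "env_labels")
  if (is.null(env_labels)) env_labels <- c("GG1", "GG2")
  if (!environment %in% env_labels) {
    stop("unknown environment '", environment, "'; architecture defines: ",
         paste(env_labels, collapse = ", "))
  }
  src <- architecture$source_marker
  known <- is.na(src) | src %in% colnames(genotypes)
  if (!all(known)) {
    stop("unknown source marker(s): ", paste(unique(src[!known]), collapse = ", "))
  }
  if (any(architecture$noise_sd <= 0)) stop("noise_sd must be > 0")
  beta <- if (environment == env_labels[1]) architecture$beta_env1 else architecture$beta_env2

  x <- genotype_numeric(genotypes)
  n_lines <- nrow(x)
  lines <- c(rep(rownames(x), each = ril_replicates),
             rep(c("Ler", "Cvi"), each = parent_replicates))
  reps <- c(rep(seq_len(ril_replicates), n_lines),
            rep(seq_len(parent_replicates), 2))
  samples <- data.frame(
    sample_id = sprintf("%s_%s_r%d", environment, lines, reps),
    line_id = lines, environment = environment, replicate = reps,
    stringsAsFactors = FALSE
  )
  # genotype value per gene x sample: RILs from the matrix, parents constant +1/-1
  n_genes <- nrow(architecture)
  gx <- matrix(0, n_genes, nrow(samples))
  eff <- which(!is.na(src))
  if (length(eff)) {
    ril_part <- t(x[samples$line_id[samples$line_id %in% rownames(x)],
                    src[eff], drop = FALSE])
    gx[eff, samples$line_id %in% rownames(x)] <- ril_part
    gx[eff, samples$line_id == "Ler"] <- 1
    gx[eff, samples$line_id == "Cvi"] <- -1
  }
  set.seed(as.integer(noise_seed))
  expr <- architecture$baseline + beta * gx +
    matrix(stats::rnorm(n_genes * nrow(samples), sd = architecture$noise_sd),
           n_genes, nrow(samples))
  dimnames(expr) <- list(architecture$gene_id, samples$sample_id)
  dataset <- structure(
    list(expr = expr, samples = samples,
         annotation = data.frame(gene_id = architecture$gene_id,
                                 chrom = architecture$chrom,
                                 bp = architecture$bp,
                                 stringsAsFactors = FALSE),
         parents = c("Ler", "Cvi")),
    class = "expression_dataset"
  )
  eff_plain <- architecture
  attributes(eff_plain) <- list(names = names(architecture),
                                row.names = seq_len(nrow(architecture)),
                                class = "data.frame")
  truth <- structure(
    list(effects = eff_plain, env_labels = env_labels,
         environment = environment, seed = as.integer(noise_seed)),
    class = "truth_table"
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate an all-null expression dataset
#'
#' Every gene has zero effect everywhere: pure N(baseline, noise_sd) noise on
#' the given genotype scaffold. Used for permutation-threshold calibration and
#' FDR-inflation simulations.
#'
#' @inheritParams simulate_expression
#' @param n_genes Number of null genes.
#' @param noise_sd Residual SD (> 0).
#' @param seed Integer seed (drives both gene placement and noise).
#' @return As [simulate_expression]: list with `dataset` and `truth` (all
#'   entries `kind = "null"`).
#' @export
simulate_null_dataset <- function(genotypes, map, n_genes, noise_sd = 1, seed = 1,
                                  ril_replicates = 1, parent_replicates = 3,
                                  environment = "GG1") {
  arch <- build_architecture(map, n_genes, n_cis = 0, n_trans = 0,
                             noise_sd = noise_sd, seed = seed)
  simulate_expression(genotypes, map, arch, environment,
                      ril_replicates = ril_replicates,
                      parent_replicates = parent_replicates,
                      noise_seed = seed)
}

#' Average replicate samples to one value per line
#'
#' @param dataset An `expression_dataset`.
#' @param environment Optional environment label to subset to.
#' @param ril_only Drop parental pseudo-lines (default TRUE).
#' @return Genes x lines matrix of replicate means.
#' @export
line_means <- function(dataset, environment = NULL, ril_only = TRUE) {
  s <- dataset$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(environment)) keep <- keep & s$environment == environment
  if (ril_only) keep <- keep & !(s$line_id %in% dataset$parents)
  s <- s[keep, , drop = FALSE]
  expr <- dataset$expr[, keep, drop = FALSE]
  lines <- unique(s$line_id)
  grp <- factor(s$line_id, levels = lines)
  # rowsum over samples of the same line, divided by replicate count
  out <- t(rowsum(t(expr), grp)) / rep(tabulate(grp), each = nrow(expr))
  colnames(out) <- lines
  out
}
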