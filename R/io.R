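# Single TSV dialect everywhere: header row, tab separator, "NA" for missing,
# no quoting; floats at 6 significant digits.

format_num_cols <- function(df, digits = 6) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  df
}

#' Write a data frame as TSV (deterministic dialect)
#'
#' Header row, tab-separated, `NA` for missing, no quotes, doubles rounded to
#' 6 significant digits. Two writes of the same records are byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(format_num_cols(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_table]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Emits the map (`map.tsv`: marker, chrom, cm, bp), genotypes
#' (`genotypes.tsv`: line x marker, "A"/"B"), expression matrix
#' (`expression_<env>.tsv`: gene x sample), sample sheet
#' (`samples_<env>.tsv`), gene annotation (`annotation.tsv`: BED-like chrom,
#' start, end, gene_id) and the truth table (`truth_<env>.yaml`).
#'
#' @param map A `genetic_map`.
#' @param genotypes A `genotype_matrix`.
#' @param sim Result of [simulate_expression] (list `dataset`, `truth`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(map, genotypes, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- sim$truth$environment
  write_tsv_table(as.data.frame(map), file.path(dir, "map.tsv"))
  g <- data.frame(line = rownames(genotypes), unclass(genotypes),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(g, file.path(dir, "genotypes.tsv"))
  e <- data.frame(gene_id = rownames(sim$dataset$expr), sim$dataset$expr,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(e, file.path(dir, sprintf("expression_%s.tsv", env)))
  write_tsv_table(sim$dataset$samples, file.path(dir, sprintf("samples_%s.tsv", env)))
  ann <- sim$dataset$annotation
  bed <- data.frame(chrom = ann$chrom, start = ann$bp, end = ann$bp,
                    gene_id = ann$gene_id, stringsAsFactors = FALSE)
  write_tsv_table(bed, file.path(dir, "annotation.tsv"))
  write_truth(sim$truth, file.path(dir, sprintf("truth_%s.yaml", env)))
  invisible(dir)
}

#' Serialize a truth table to YAML
#' @param truth A `truth_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(list(
    env_labels = truth$env_labels, environment = truth$environment,
    seed = truth$seed,
    effects = lapply(seq_len(nrow(truth$effects)), function(i) {
      as.list(truth$effects[i, ])
    })), path)
  invisible(path)
}

#' Read a truth table written by [write_truth]
#' @param path YAML path.
#' @return A `truth_table` equal to the one written.
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  eff <- do.call(rbind, lapply(x$effects, function(e) {
    e$source_marker <- if (is.null(e$source_marker)) NA_character_ else e$source_marker
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  structure(list(effects = eff, env_labels = unlist(x$env_labels),
                 environment = x$environment, seed = as.integer(x$seed)),
            class = "truth_table")
}

#' Load and validate a dataset directory
#'
#' Reads the files written by [write_dataset], re-validates all invariants
#' (unique sorted markers, genotype codes in {A, B, NA}, every sample's line
#' known) and cross-references objects.
#'
#' @param dir Directory written by [write_dataset].
#' @param environment Environment label of the expression files to load.
#' @return List with `map`, `genotypes`, `dataset`.
#' @export
load_dataset <- function(dir, environment) {
  map <- validate_map(read_tsv_table(file.path(dir, "map.tsv")))
  g <- read_tsv_table(file.path(dir, "genotypes.tsv"))
  geno <- as.matrix(g[, -1, drop = FALSE])
  rownames(geno) <- g$line
  bad <- which(!(geno %in% c("A", "B") | is.na(geno)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(geno))
    stop(sprintf("invalid genotype code '%s' at line %s, marker %s",
                 geno[bad[1]], rownames(geno)[rc[1]], colnames(geno)[rc[2]]))
  }
  if (!identical(colnames(geno), map$marker)) {
    stop("genotype markers do not match the map")
  }
  class(geno) <- c("genotype_matrix", class(geno))
  e <- read_tsv_table(file.path(dir, sprintf("expression_%s.tsv", environment)))
  expr <- as.matrix(e[, -1, drop = FALSE])
  rownames(expr) <- e$gene_id
  samples <- read_tsv_table(file.path(dir, sprintf("samples_%s.tsv", environment)))
  bed <- read_tsv_table(file.path(dir, "annotation.tsv"))
  ann <- data.frame(gene_id = bed$gene_id, chrom = bed$chrom, bp = bed$start,
                    stringsAsFactors = FALSE)
  parents <- setdiff(unique(samples$line_id), rownames(geno))
  orphan <- setdiff(parents, c("Ler", "Cvi"))
  if (length(orphan)) {
    stop("samples from unknown line(s): ", paste(orphan, collapse = ", "))
  }
  if (!identical(colnames(expr), samples$sample_id)) {
    stop("expression columns do not match the sample sheet")
  }
  dataset <- structure(list(expr = expr, samples = samples, annotation = ann,
                            parents = parents),
                       class = "expression_dataset")
  list(map = map, genotypes = geno, dataset = dataset)
}

#' Write analysis records deterministically
#'
#' Sorts rows by the first columns among (`gene_id`, `chrom`, `bp`,
#' `peak_bp`, `marker`) that exist, then writes with [write_tsv_table].
#'
#' @param records Data frame of any module's records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  keys <- intersect(c("gene_id", "chrom", "bp", "peak_bp", "marker"),
                    names(records))
  if (length(keys) && nrow(records)) {
    records <- records[do.call(order, records[keys]), , drop = FALSE]
  }
  write_tsv_table(records, path)
}
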