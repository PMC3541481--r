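#' Build an equally spaced genetic map
#'
#' Creates a marker scaffold of `n_chrom` chromosomes with `markers_per_chrom`
#' equally spaced markers each. Genetic positions run from 0 to `chrom_length`
#' cM; physical positions are obtained by a constant cM-to-bp scaling, which is
#' adequate for simulation scaffolds where only marker order and spacing matter.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers per chromosome (>= 2).
#' @param chrom_length Chromosome length in cM (> 0).
#' @param bp_per_cM Physical bp per cM (default 250000, roughly the
#'   Arabidopsis genome-wide average).
#' @param seed Unused; accepted for interface symmetry with the stochastic
#'   generators so a pipeline can pass one seed everywhere.
#' @return A `genetic_map`: data frame with columns `marker`, `chrom`, `cm`,
#'   `bp`, ordered by (chrom, cm), with unique marker ids.
#' @examples
#' gmap <- generate_map(5, 20, 100)
#' table(gmap$chrom)
#' @export
generate_map <- function(n_chrom, markers_per_chrom, chrom_length,
                         bp_per_cM = 250000, seed = NULL) {
  if (n_chrom < 1 || markers_per_chrom < 2 || chrom_length <= 0) {
    stop("invalid map dimensions: need n_chrom >= 1, markers_per_chrom >= 2, chrom_length > 0")
  }
  cm <- seq(0, chrom_length, length.out = markers_per_chrom)
  map <- data.frame(
    marker = sprintf("M%d_%02d", rep(seq_len(n_chrom), each = markers_per_chrom),
                     rep(seq_len(markers_per_chrom), n_chrom)),
    chrom  = rep(seq_len(n_chrom), each = markers_per_chrom),
    cm     = rep(cm, n_chrom),
    bp     = as.integer(round(rep(cm, n_chrom) * bp_per_cM)),
    stringsAsFactors = FALSE
  )
  validate_map(map)
}

#' Validate a genetic map
#'
#' Checks the `genetic_map` invariants: unique marker ids and strictly
#' increasing genetic and physical positions within every chromosome.
#'
#' @param map Data frame with columns `marker`, `chrom`, `cm`, `bp`.
#' @return The map, classed as `genetic_map`, invisibly usable downstream.
#' @export
validate_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "cm", "bp") %in% names(map)))
  if (anyDuplicated(map$marker)) {
    stop("duplicate marker ids: ", paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  for (chr in unique(map$chrom)) {
    sub <- map[map$chrom == chr, ]
    if (is.unsorted(sub$cm, strictly = TRUE)) {
      stop("genetic positions not strictly increasing on chromosome ", chr)
    }
    if (is.unsorted(sub$bp, strictly = TRUE)) {
      stop("physical positions not strictly increasing on chromosome ", chr)
    }
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Genetic distance between two mapped markers
#'
#' @param map A `genetic_map`.
#' @param m1,m2 Marker ids. Markers on different chromosomes give `Inf`.
#' @return Distance in cM.
#' @export
marker_distance <- function(map, m1, m2) {
  i <- match(m1, map$marker); j <- match(m2, map$marker)
  if (anyNA(c(i, j))) stop("unknown marker id")
  ifelse(map$chrom[i] == map$chrom[j], abs(map$cm[i] - map$cm[j]), Inf)
}
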