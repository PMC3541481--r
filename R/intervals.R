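#' Assign genomic items to intervals
#'
#' Closed-interval, 1-based containment: an item at (chromosome, bp) is
#' assigned to every interval whose `[start, end]` contains it (ends
#' inclusive). Typical intervals are NIL introgression segments.
#'
#' @param items Data frame with columns `chrom` and `bp` (and optionally an
#'   id column, kept in the output).
#' @param intervals Data frame with `chrom`, `start`, `end`, `label`
#'   (labels unique, `start <= end`).
#' @return List with `membership` (items x intervals logical matrix, columns
#'   named by label) and `counts` (named vector of items per interval).
#' @export
interval_membership <- function(items, intervals) {
  stopifnot(all(c("chrom", "bp") %in% names(items)),
            all(c("chrom", "start", "end", "label") %in% names(intervals)))
  if (anyDuplicated(intervals$label)) stop("interval labels must be unique")
  if (any(intervals$start > intervals$end)) stop("interval start > end")
  mem <- matrix(FALSE, nrow(items), nrow(intervals),
                dimnames = list(NULL, intervals$label))
  for (j in seq_len(nrow(intervals))) {
    mem[, j] <- items$chrom == intervals$chrom[j] &
      items$bp >= intervals$start[j] & items$bp <= intervals$end[j]
  }
  list(membership = mem, counts = colSums(mem))
}

#' Default NIL introgression intervals (LCN1-10-like design)
#'
#' Two chromosome-1 segments of the donor parent in the recurrent background,
#' at approximately 5-8.2 Mbp and 26.5-30.4 Mbp.
#'
#' @return An interval data frame usable with [interval_membership].
#' @export
nil_introgressions <- function() {
  data.frame(chrom = c(1L, 1L),
             start = c(5000000, 26500000),
             end = c(8200000, 30400000),
             label = c("introgression1", "introgression2"),
             stringsAsFactors = FALSE)
}

#' Count genomic positions per marker locus
#'
#' The bin of a marker is the midpoint-to-midpoint region between its
#' flanking markers (chromosome ends extend to the chromosome bounds), so
#' counting SNPs or genes "between the flanking markers" of each marker.
#' Positions on chromosomes absent from the map are dropped with a warning.
#'
#' @param map A `genetic_map`.
#' @param positions Data frame with `chrom` and `bp`.
#' @param weights Optional per-position weights (e.g. 1/number of sampled
#'   sequences); default 1 each. Indels collapsed to one polymorphism must be
#'   pre-collapsed by the caller.
#' @return Data frame `marker`, `chrom`, `bp`, `count` (weighted).
#' @export
binned_counts <- function(map, positions, weights = NULL) {
  map <- validate_map(map)
  if (is.null(weights)) weights <- rep(1, nrow(positions))
  stopifnot(length(weights) == nrow(positions))
  count <- numeric(nrow(map))
  unmapped <- !(positions$chrom %in% map$chrom)
  if (any(unmapped)) {
    warning(sum(unmapped), " position(s) on unmapped chromosome(s) dropped")
  }
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    bp <- map$bp[idx]
    cuts <- c(-Inf, (bp[-1] + bp[-length(bp)]) / 2, Inf)
    sel <- which(positions$chrom == chr)
    if (!length(sel)) next
    bin <- findInterval(positions$bp[sel], cuts, left.open = TRUE)
    for (b in seq_along(idx)) {
      count[idx[b]] <- sum(weights[sel][bin == b])
    }
  }
  data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
             count = count, stringsAsFactors = FALSE)
}

#' Pearson correlation between two per-marker distributions with a t-test
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom,
#' two-sided. Used to compare e.g. eQTL counts with SNP or gene density per
#' marker locus.
#'
#' @param counts_a,counts_b Equal-length numeric vectors (length >= 3),
#'   neither constant.
#' @return List `r`, `n`, `t_statistic`, `p_value`.
#' @export
distribution_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("length mismatch")
  n <- length(counts_a)
  if (n < 3) stop("need at least 3 bins")
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    stop("undefined correlation: constant vector")
  }
  r <- stats::cor(counts_a, counts_b)
  if (1 - r^2 < 1e-12) {  # numerically collinear: p capped at machine minimum
    return(list(r = r, n = n, t_statistic = sign(r) * Inf,
                p_value = .Machine$double.xmin))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * stats::pt(-abs(t), n - 2), .Machine$double.xmin)
  list(r = r, n = n, t_statistic = t, p_value = p)
}
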