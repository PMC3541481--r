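#' Detect hotspots of transcript regulation
#'
#' Counts eQTL peaks per marker and flags markers carrying significantly more
#' peaks than expected if the `T` peaks fell uniformly over the `M` markers
#' (null: multinomial, approximated per marker by Poisson with
#' `lambda = T/M`). The hotspot threshold is the smallest count `c` with
#' `P(X >= c) <= alpha / M` (Bonferroni over markers).
#'
#' @param records Peak records from [call_peaks] (classified or not).
#' @param map A `genetic_map`.
#' @param alpha Family-wise error target in (0, 1) (default 0.05).
#' @param count_mode Count `"total"` peaks per marker or `"distant"` only
#'   (requires classified records).
#' @return A `hotspot_table` data frame: per marker `marker`, `chrom`, `cm`,
#'   `bp`, `n_local`, `n_distant`, `n_total`, `expected`, `threshold`,
#'   `is_hotspot`.
#' @export
hotspot_scan <- function(records, map, alpha = 0.05,
                         count_mode = c("total", "distant")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!nrow(records)) stop("no peaks to scan")
  count_mode <- match.arg(count_mode)
  map <- validate_map(map)
  M <- nrow(map)
  cnt <- function(sub) {
    tab <- table(factor(sub$peak_marker, levels = map$marker))
    as.integer(tab)
  }
  n_total <- cnt(records)
  has_loc <- !all(is.na(records$locality))
  n_local <- if (has_loc) cnt(records[records$locality %in% "local", , drop = FALSE]) else rep(NA_integer_, M)
  n_dist <- if (has_loc) cnt(records[records$locality %in% "distant", , drop = FALSE]) else rep(NA_integer_, M)
  counts <- if (count_mode == "total") n_total else {
    if (!has_loc) stop("count_mode 'distant' needs classified records")
    n_dist
  }
  total <- sum(counts)
  lambda <- total / M
  # smallest c with upper tail P(X >= c) <= alpha/M
  thr <- stats::qpois(alpha / M, lambda, lower.tail = FALSE) + 1L
  data.frame(marker = map$marker, chrom = map$chrom, cm = map$cm, bp = map$bp,
             n_local = n_local, n_distant = n_dist, n_total = n_total,
             expected = lambda, threshold = thr,
             is_hotspot = counts >= thr, stringsAsFactors = FALSE)
}
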