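#' Plot eQTL peak position against regulated-gene position
#'
#' The classic genome-wide eQTL scatter: local (cis) regulation appears as
#' the diagonal, trans-bands (hotspots) as vertical stripes. Points are
#' colored by the sign of the additive effect (positive = allele A raises
#' expression).
#'
#' @param records Classified eQTL records.
#' @param annotation Gene annotation (`gene_id`, `chrom`, `bp`).
#' @param map A `genetic_map` (for chromosome offsets).
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, the plotted data frame with cumulative coordinates.
#' @export
plot_eqtl_positions <- function(records, annotation, map, ...) {
  chrom_len <- tapply(map$bp, map$chrom, max)
  offset <- c(0, cumsum(as.numeric(chrom_len)))[seq_along(chrom_len)]
  names(offset) <- names(chrom_len)
  i <- match(records$gene_id, annotation$gene_id)
  x <- records$peak_bp + offset[as.character(records$chrom)]
  y <- annotation$bp[i] + offset[as.character(annotation$chrom[i])]
  col <- ifelse(records$locality %in% "local", "gray",
                ifelse(records$additive_effect > 0, "darkgreen", "red"))
  graphics::plot(x, y, col = col, pch = 20,
                 xlab = "eQTL peak position (bp, cumulative)",
                 ylab = "gene position (bp, cumulative)", ...)
  graphics::abline(v = cumsum(as.numeric(chrom_len)), col = "lightgray")
  invisible(data.frame(x = x, y = y, col = col))
}

#' Plot per-marker eQTL counts with the hotspot threshold
#'
#' Barplot of local and distant peak counts per marker with the hotspot
#' significance threshold as a horizontal line.
#'
#' @param hotspots A `hotspot_table` from [hotspot_scan].
#' @param ... Passed to [graphics::barplot].
#' @return Invisibly, the hotspot table.
#' @export
plot_hotspots <- function(hotspots, ...) {
  h <- hotspots
  counts <- rbind(local = ifelse(is.na(h$n_local), 0, h$n_local),
                  distant = ifelse(is.na(h$n_distant), h$n_total, h$n_distant))
  graphics::barplot(counts, names.arg = h$marker, las = 2, cex.names = 0.5,
                    col = c("purple", "blue"),
                    ylab = "eQTL peaks per marker", ...)
  graphics::abline(h = h$threshold[1], col = "red")
  invisible(h)
}
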