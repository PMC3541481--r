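#' Haldane recombination fraction for a map distance
#'
#' `r = (1 - exp(-2d/100))/2` for a distance `d` in cM (no interference).
#'
#' @param d_cM Map distance in cM.
#' @return Recombination fraction per meiosis, in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Selfing-RIL switch probability between adjacent markers
#'
#' In fully inbred selfed RILs the probability that two linked markers carry
#' different parental alleles is `R = 2r/(1 + 2r)` (infinite-selfing limit),
#' where `r` is the per-meiosis recombination fraction.
#'
#' @param d_cM Map distance in cM.
#' @return Switch probability `R`, in `[0, 0.5)`.
#' @export
ril_switch_prob <- function(d_cM) {
  r <- haldane_r(d_cM)
  2 * r / (1 + 2 * r)
}

#' Simulate RIL genotypes on a genetic map
#'
#' Generates fully inbred biallelic genotypes for `n_lines` recombinant inbred
#' lines, marker by marker as a Markov chain per chromosome: the first marker
#' is `A` or `B` with probability 1/2; between adjacent markers at distance
#' `d` cM the allele switches with probability [ril_switch_prob]`(d)`. `A` is
#' the Ler-like parent-1 allele, `B` the Cvi-like parent-2 allele; the numeric
#' view codes `A` as +1 and `B` as -1.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of RILs (>= 2).
#' @param seed Integer seed; identical seeds reproduce the matrix exactly.
#' @return A `genotype_matrix`: character matrix of "A"/"B", rows = line ids
#'   ("RIL001", ...), columns = marker ids.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed) {
  map <- validate_map(map)
  if (n_lines < 2) stop("need at least 2 lines")
  set.seed(as.integer(seed))
  n_mark <- nrow(map)
  geno <- matrix(NA_integer_, n_lines, n_mark)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    sw <- ril_switch_prob(diff(map$cm[idx]))
    state <- ifelse(stats::runif(n_lines) < 0.5, 1L, -1L)
    geno[, idx[1]] <- state
    for (k in seq_along(sw)) {
      flip <- stats::runif(n_lines) < sw[k]
      state <- ifelse(flip, -state, state)
      geno[, idx[k + 1]] <- state
    }
  }
  out <- matrix(ifelse(geno == 1L, "A", "B"), n_lines, n_mark,
                dimnames = list(sprintf("RIL%03d", seq_len(n_lines)), map$marker))
  class(out) <- c("genotype_matrix", class(out))
  out
}

#' Numeric (+1/-1) view of a genotype matrix
#'
#' @param genotypes A `genotype_matrix` ("A"/"B" codes).
#' @return Numeric matrix, `A` mapped to +1 and `B` to -1, dimnames kept.
#' @export
genotype_numeric <- function(genotypes) {
  x <- ifelse(unclass(genotypes) == "A", 1, -1)
  dimnames(x) <- dimnames(genotypes)
  x
}
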