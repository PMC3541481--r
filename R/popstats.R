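#' Differential expression between two groups of replicate samples
#'
#' Per-gene two-sided pooled-variance linear-model test (equivalent to the
#' pooled two-sample t-test) of a two-level contrast, with Storey q-values
#' computed over the full gene set. Typical uses: parental lines Ler vs Cvi,
#' or a NIL vs its recurrent parent.
#'
#' @param group1,group2 Genes x replicates matrices with identical row order
#'   (>= 2 replicates each).
#' @param ... Passed to [storey_qvalues].
#' @return Data frame `gene_id`, `mean1`, `mean2`, `difference`
#'   (= mean1 - mean2), `p_value`, `q_value`.
#' @export
differential_expression <- function(group1, group2, ...) {
  if (ncol(group1) < 2 || ncol(group2) < 2) stop("need >= 2 replicates per group")
  stopifnot(nrow(group1) == nrow(group2))
  n1 <- ncol(group1); n2 <- ncol(group2)
  m1 <- rowMeans(group1); m2 <- rowMeans(group2)
  ss <- rowSums((group1 - m1)^2) + rowSums((group2 - m2)^2)
  df <- n1 + n2 - 2
  diff <- m1 - m2
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0 & diff == 0] <- 1
  p[se == 0 & diff != 0] <- .Machine$double.xmin
  p[!is.finite(p)] <- 1
  p <- pmax(p, .Machine$double.xmin)
  qv <- storey_qvalues(p, ...)
  ids <- rownames(group1)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(group1)))
  data.frame(gene_id = ids, mean1 = unname(m1), mean2 = unname(m2),
             difference = unname(diff), p_value = unname(p),
             q_value = qv$q, stringsAsFactors = FALSE)
}

#' Broad-sense heritability in the parents
#'
#' One-way ANOVA decomposition over the parental replicate samples:
#' `var_error` is the pooled within-line replicate variance (MS within) and
#' `var_genetic` the between-line variance component `(MSB - MSW) / r`
#' (floored at 0), with `r` the per-line replicate count. `H2 =
#' var_genetic / (var_genetic + var_error)`, in [0, 1].
#'
#' @param values Genes x samples matrix of parental replicates.
#' @param line Character vector assigning each sample to a parent line.
#' @return Data frame `gene_id`, `var_genetic`, `var_error`, `H2`.
#' @export
h2_parents <- function(values, line) {
  stopifnot(ncol(values) == length(line))
  grp <- factor(line)
  if (nlevels(grp) < 2) stop("need >= 2 parental lines")
  counts <- tabulate(grp)
  if (all(counts < 2)) stop("no replicated line: error variance not estimable")
  n <- ncol(values); k <- nlevels(grp)
  gm <- t(rowsum(t(values), grp)) / rep(counts, each = nrow(values))
  grand <- rowMeans(values)
  ssb <- as.vector((gm - grand)^2 %*% counts)
  ssw <- rowSums((values - gm[, as.integer(grp), drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  r_eff <- (n - sum(counts^2) / n) / (k - 1)  # unequal-n ANOVA replicate count
  var_g <- pmax((msb - msw) / r_eff, 0)
  var_e <- msw
  h2 <- ifelse(var_g + var_e > 0, var_g / (var_g + var_e), 0)
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(values)))
  data.frame(gene_id = ids, var_genetic = unname(var_g),
             var_error = unname(var_e), H2 = unname(pmin(pmax(h2, 0), 1)),
             stringsAsFactors = FALSE)
}

#' Broad-sense heritability in the RILs
#'
#' The among-line variance of the RIL line means is taken as the total
#' (genetic + error) variance; the error variance is supplied externally,
#' normally as the pooled parental replicate variance (`var_error` from
#' [h2_parents]). `var_genetic = total - var_error`, floored at 0, and
#' `H2 = var_genetic / total`.
#'
#' @param line_values Genes x lines matrix of per-line values (replicate
#'   means).
#' @param var_error Per-gene error variance vector (recycled if scalar).
#' @return Data frame `gene_id`, `var_genetic`, `var_error`, `H2`.
#' @export
h2_ril <- function(line_values, var_error) {
  total <- apply(line_values, 1, stats::var)
  var_error <- rep_len(var_error, nrow(line_values))
  var_g <- pmax(total - var_error, 0)
  h2 <- ifelse(var_g + var_error > 0, var_g / (var_g + var_error), 0)
  ids <- rownames(line_values)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(line_values)))
  data.frame(gene_id = ids, var_genetic = unname(var_g),
             var_error = unname(var_error),
             H2 = unname(pmin(pmax(h2, 0), 1)), stringsAsFactors = FALSE)
}

#' Transgressive segregation statistics
#'
#' Counts, per gene, the RILs whose value exceeds the higher parent's mean
#' plus two parental SDs (`mu_max + 2*sd_max`) or falls below the lower
#' parent's mean minus two SDs (`mu_min - 2*sd_min`). A gene is called
#' transgressive when `n_above + n_below >= n_min`.
#'
#' @param ril_values Genes x lines matrix of RIL values (line means).
#' @param parent1,parent2 Genes x replicates matrices for the two parents
#'   (>= 2 replicates each).
#' @param n_min Minimum number of extreme RILs to call transgression
#'   (default 2: one extreme line is not transgression).
#' @return Data frame `gene_id`, `mu_max`, `sd_max`, `mu_min`, `sd_min`,
#'   `n_above`, `n_below`, `is_transgressive`.
#' @export
transgression_stats <- function(ril_values, parent1, parent2, n_min = 2) {
  if (ncol(parent1) < 2 || ncol(parent2) < 2) stop("need >= 2 parental replicates")
  m1 <- rowMeans(parent1); m2 <- rowMeans(parent2)
  s1 <- apply(parent1, 1, stats::sd); s2 <- apply(parent2, 1, stats::sd)
  hi <- m1 >= m2
  mu_max <- ifelse(hi, m1, m2); sd_max <- ifelse(hi, s1, s2)
  mu_min <- ifelse(hi, m2, m1); sd_min <- ifelse(hi, s2, s1)
  upper <- mu_max + 2 * sd_max
  lower <- mu_min - 2 * sd_min
  n_above <- rowSums(ril_values > upper)
  n_below <- rowSums(ril_values < lower)
  ids <- rownames(ril_values)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(ril_values)))
  data.frame(gene_id = ids, mu_max = unname(mu_max), sd_max = unname(sd_max),
             mu_min = unname(mu_min), sd_min = unname(sd_min),
             n_above = unname(n_above), n_below = unname(n_below),
             is_transgressive = unname(n_above + n_below >= n_min),
             stringsAsFactors = FALSE)
}
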