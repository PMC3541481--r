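#' Single-marker regression of a trait on a biallelic genotype
#'
#' Fits `y = mu + a*x + e` for `x` in {+1, -1}. The additive effect `a` is
#' half the difference between the two genotype-class means (positive = the
#' A/Ler allele raises the trait); the p-value is the two-sided test of
#' `a = 0`, identical to the pooled two-sample t-test.
#'
#' Degenerate inputs follow fixed conventions so null bookkeeping stays
#' well-defined: zero residual variance with `a = 0` (a flat trait) gives
#' `p = 1, a = 0`; zero residual variance with `a != 0` (perfect separation)
#' gives the machine-minimum p with `neg_log10_p` capped.
#'
#' @param y Numeric trait vector, one value per line.
#' @param x Genotype vector in {+1, -1}, same length (>= 4), both classes
#'   present.
#' @param neg_log10_cap Ceiling for `-log10(p)` (default 300).
#' @return List with `p_value`, `neg_log10_p`, `additive_effect`.
#' @examples
#' marker_regression(c(5, 6, 5, 6, 1, 2, 1, 2), c(1, 1, 1, 1, -1, -1, -1, -1))
#' @export
marker_regression <- function(y, x, neg_log10_cap = 300) {
  if (length(y) != length(x) || length(y) < 4) stop("need length(y) == length(x) >= 4")
  a_grp <- x > 0
  n1 <- sum(a_grp); n2 <- sum(!a_grp)
  if (n1 == 0 || n2 == 0) stop("monomorphic marker")
  m1 <- mean(y[a_grp]); m2 <- mean(y[!a_grp])
  ss <- sum((y[a_grp] - m1)^2) + sum((y[!a_grp] - m2)^2)
  df <- n1 + n2 - 2
  diff <- m1 - m2
  if (ss <= 0) {
    if (diff == 0) return(list(p_value = 1, neg_log10_p = 0, additive_effect = 0))
    return(list(p_value = .Machine$double.xmin,
                neg_log10_p = neg_log10_cap, additive_effect = diff / 2))
  }
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  p <- max(p, .Machine$double.xmin)
  list(p_value = p,
       neg_log10_p = min(-log10(p), neg_log10_cap),
       additive_effect = diff / 2)
}

# Vectorized all-genes x all-markers marker regression on a line-mean matrix.
# Y: genes x lines, X: lines x markers in +1/-1. Returns list of matrices.
scan_matrix <- function(Y, X, neg_log10_cap = 300) {
  ind_a <- (X > 0) * 1
  ind_b <- 1 - ind_a
  n1 <- colSums(ind_a); n2 <- colSums(ind_b)
  if (any(n1 == 0 | n2 == 0)) stop("monomorphic marker in genotype matrix")
  s1 <- Y %*% ind_a; s2 <- Y %*% ind_b
  q1 <- (Y^2) %*% ind_a; q2 <- (Y^2) %*% ind_b
  m1 <- sweep(s1, 2, n1, "/"); m2 <- sweep(s2, 2, n2, "/")
  ss <- (q1 - sweep(s1^2, 2, n1, "/")) + (q2 - sweep(s2^2, 2, n2, "/"))
  df <- n1 + n2 - 2
  diff <- m1 - m2
  se <- sqrt(sweep(pmax(ss, 0), 2, df, "/") *
             rep(1 / n1 + 1 / n2, each = nrow(Y)))
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df = rep(df, each = nrow(Y)))
  flat <- ss <= .Machine$double.eps * abs(q1 + q2)
  p[flat & abs(diff) > 1e-12] <- .Machine$double.xmin
  p[flat & abs(diff) <= 1e-12] <- 1
  diff[flat & abs(diff) <= 1e-12] <- 0
  p[!is.finite(p)] <- 1
  p <- pmax(p, .Machine$double.xmin)
  nlp <- pmin(-log10(p), neg_log10_cap)
  list(p_value = p, neg_log10_p = nlp, additive_effect = diff / 2)
}

#' Genome scan: marker regression of every gene at every marker
#'
#' Replicate samples are averaged per line first, then [marker_regression] is
#' applied at every marker for every gene (vectorized). If `cofactors` are
#' supplied for a gene, the scan for that gene is conditional: cofactor
#' genotype columns enter the linear model as covariates, and markers within
#' `cofactor_window_cM` of any cofactor are skipped (returned as `p = 1`) to
#' avoid testing a marker against itself.
#'
#' @param dataset An `expression_dataset`, or a genes x lines matrix of line
#'   means (then `environment` is ignored).
#' @param genotypes A `genotype_matrix`.
#' @param map A `genetic_map`.
#' @param environment Environment label to scan (required when `dataset`
#'   holds more than one).
#' @param cofactors Optional named list: gene_id -> character vector of
#'   cofactor marker ids.
#' @param cofactor_window_cM Exclusion window around cofactors (default 10).
#' @param neg_log10_cap Cap for `-log10(p)` (default 300).
#' @return A `scan_result`: list of genes x markers matrices `p_value`,
#'   `neg_log10_p`, `additive_effect`, plus the `map`.
#' @export
genome_scan <- function(dataset, genotypes, map, environment = NULL,
                        cofactors = NULL, cofactor_window_cM = 10,
                        neg_log10_cap = 300) {
  map <- validate_map(map)
  if (inherits(dataset, "expression_dataset")) {
    Y <- line_means(dataset, environment = environment, ril_only = TRUE)
  } else {
    Y <- dataset
  }
  missing_lines <- setdiff(colnames(Y), rownames(genotypes))
  if (length(missing_lines)) {
    stop("expression lines absent from genotype matrix: ",
         paste(missing_lines, collapse = ", "))
  }
  X <- genotype_numeric(genotypes)[colnames(Y), map$marker, drop = FALSE]
  res <- scan_matrix(Y, X, neg_log10_cap)
  if (!is.null(cofactors)) {
    for (g in intersect(names(cofactors), rownames(Y))) {
      cf <- cofactors[[g]]
      if (!length(cf)) next
      row <- conditional_scan_row(Y[g, ], X, map, cf, cofactor_window_cM,
                                  neg_log10_cap)
      res$p_value[g, ] <- row$p_value
      res$neg_log10_p[g, ] <- row$neg_log10_p
      res$additive_effect[g, ] <- row$additive_effect
    }
  }
  structure(list(p_value = res$p_value, neg_log10_p = res$neg_log10_p,
                 additive_effect = res$additive_effect, map = map),
            class = "scan_result")
}

# Conditional scan of one gene given cofactor markers.
conditional_scan_row <- function(y, X, map, cofactor_markers, window_cM,
                                 neg_log10_cap = 300) {
  stopifnot(all(cofactor_markers %in% colnames(X)))
  M <- ncol(X)
  p <- rep(1, M); a <- rep(0, M)
  cf_i <- match(cofactor_markers, map$marker)
  near <- vapply(seq_len(M), function(m) {
    any(map$chrom[m] == map$chrom[cf_i] & abs(map$cm[m] - map$cm[cf_i]) <= window_cM)
  }, logical(1))
  Xc <- X[, cofactor_markers, drop = FALSE]
  for (m in which(!near)) {
    fit <- stats::lm(y ~ X[, m] + Xc)
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2 || rownames(sm)[2] != "X[, m]") next
    p[m] <- max(sm[2, 4], .Machine$double.xmin)
    a[m] <- sm[2, 1]
  }
  list(p_value = p, neg_log10_p = pmin(-log10(p), neg_log10_cap),
       additive_effect = a)
}

#' Forward selection of cofactor markers for one gene
#'
#' Greedy stand-in for multiple-QTL-model cofactor selection: repeatedly add
#' the marker with the smallest conditional p-value (t-test of its
#' coefficient given the markers already selected), while that p-value is
#' below `entry_p`, up to `max_cofactors`. Ties are broken deterministically
#' by (chromosome, position).
#'
#' @param y Trait vector (one value per line, in genotype row order).
#' @param genotypes A `genotype_matrix` (rows must cover `names(y)` if named).
#' @param map A `genetic_map`.
#' @param max_cofactors Maximum number selected (default 5).
#' @param entry_p Entry p-value threshold (default 1e-4, roughly a Bonferroni
#'   bound at 0.05 over a few hundred markers).
#' @return Character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(y, genotypes, map, max_cofactors = 5,
                             entry_p = 1e-4) {
  if (max_cofactors <= 0) return(character(0))
  map <- validate_map(map)
  X <- genotype_numeric(genotypes)
  if (!is.null(names(y))) X <- X[names(y), , drop = FALSE]
  X <- X[, map$marker, drop = FALSE]
  ord <- order(map$chrom, map$cm)  # deterministic tie-break order
  selected <- character(0)
  repeat {
    best_p <- Inf; best_m <- NA_character_
    for (m in map$marker[ord]) {
      if (m %in% selected) next
      xs <- cbind(X[, m], X[, selected, drop = FALSE])
      fit <- stats::lm(y ~ xs)
      sm <- summary(fit)$coefficients
      if (nrow(sm) < 2 || is.na(sm[2, 4])) next
      if (sm[2, 4] < best_p) { best_p <- sm[2, 4]; best_m <- m }
    }
    if (!is.finite(best_p) || best_p >= entry_p) break
    selected <- c(selected, best_m)
    if (length(selected) >= max_cofactors) break
  }
  selected
}
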