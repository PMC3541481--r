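#' Storey q-values
#'
#' Computes q-values `q_i = min_{p_(j) >= p_i} pi0 * m * p_(j) / j` with the
#' null proportion `pi0` estimated from the upper tail of the p-value
#' distribution. With `pi0_mode = "one"` the q-values coincide exactly with
#' Benjamini-Hochberg adjusted p-values.
#'
#' `pi0` modes:
#' * `"smoother"` (default): `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#'   over `lambda_grid`, smoothed by a natural cubic spline (df = 3) and
#'   evaluated at the largest lambda, then clipped to (0, 1].
#' * `"fixed"`: single-lambda estimate at `lambda_fixed`.
#' * `"one"`: `pi0 = 1` (deterministic; equals BH).
#'
#' @param p Vector of p-values in (0, 1].
#' @param lambda_grid Grid in [0, 0.95] for pi0 estimation
#'   (default `seq(0.05, 0.90, 0.05)`).
#' @param pi0_mode One of `"smoother"`, `"fixed"`, `"one"`.
#' @param lambda_fixed Lambda for `pi0_mode = "fixed"` (default 0.5).
#' @return List with `q` (aligned to `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.90, by = 0.05),
                           pi0_mode = c("smoother", "fixed", "one"),
                           lambda_fixed = 0.5) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must be in (0, 1]")
  if (any(lambda_grid < 0 | lambda_grid > 0.95)) stop("lambda_grid must lie in [0, 0.95]")
  pi0_mode <- match.arg(pi0_mode)
  m <- length(p)
  pi0 <- switch(pi0_mode,
    one = 1,
    fixed = mean(p > lambda_fixed) / (1 - lambda_fixed),
    smoother = {
      lam <- sort(lambda_grid)
      pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      if (length(lam) >= 4 && stats::var(pi0l) > 0) {
        fit <- stats::smooth.spline(lam, pi0l, df = 3)
        stats::predict(fit, x = max(lam))$y
      } else {
        pi0l[length(pi0l)]
      }
    })
  pi0 <- min(max(pi0, 1 / m), 1)  # clip to (0, 1]
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)[ro]
  list(q = q, pi0 = pi0)
}
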