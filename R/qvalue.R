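#' Storey-Tibshirani q-values
#'
#' Converts p-values to FDR q-values with the proportion of true nulls
#' pi0 estimated by a natural-cubic-spline smoother of pi0(lambda) over
#' the grid lambda = 0.05, 0.10, ..., 0.95, evaluated at the largest
#' lambda. q-values are monotone non-decreasing in p and capped at 1.
#' With fewer than 100 p-values pi0 is fixed at 1 (plain
#' Benjamini-Hochberg) with a warning, since the spline estimate is
#' unstable on small sets. `NA` p-values propagate to `NA` q-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
storey_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  if (m < 100L) {
    warning("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg)")
    pi0 <- 1
  } else {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lam))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pv, decreasing = TRUE)
  q <- pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]
  q <- pmin(cummin(pmin(q, 1)), 1)
  res <- numeric(m)
  res[o] <- q
  out[ok] <- res
  attr(out, "pi0") <- pi0
  out
}
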