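#' Standardized genomic relationship matrix
#'
#' Builds G = W W' / m where each column of W is a SNP dosage centered at
#' 2p and scaled by sqrt(2p(1-p)), i.e. the standardized GRM used as the
#' covariance of the polygenic random effect in the scans. Missing
#' dosages are mean-imputed per SNP first; monomorphic SNPs and SNPs at
#' or below `maf_min` are excluded from `m_used`. The eigendecomposition
#' is computed once and cached on the object because every REML fit and
#' scan reuses it.
#'
#' @param geno a [genotypes] object.
#' @param maf_min minor-allele-frequency threshold (default 0.01);
#'   SNPs with MAF <= `maf_min` are excluded.
#' @param missing_max drop SNPs with missingness above this fraction
#'   (default 0.1).
#' @param center_only if `TRUE`, columns are centered but not scaled
#'   (VanRaden-style denominator sum(2p(1-p)) is applied globally).
#' @return object of class `gpsm_grm`: `matrix` (n x n), `values`,
#'   `vectors` (eigendecomposition, descending), `m_used`, `samples`.
#' @export
compute_grm <- function(geno, maf_min = 0.01, missing_max = 0.1,
                        center_only = FALSE) {
  X <- geno$dosage
  miss <- colMeans(is.na(X))
  p <- col_freq(X)
  maf <- pmin(p, 1 - p)
  v <- col_vars(X)
  keep <- !is.na(maf) & maf > maf_min & miss <= missing_max & v > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 polymorphic SNPs at MAF > ", maf_min)
  X <- mean_impute(X[, keep, drop = FALSE])
  p <- p[keep]
  m <- ncol(X)
  if (center_only) {
    W <- sweep(X, 2L, 2 * p)
    G <- tcrossprod(W) / sum(2 * p * (1 - p))
  } else {
    W <- sweep(sweep(X, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(W) / m
  }
  ed <- eigen(G, symmetric = TRUE)
  structure(list(matrix = G, values = ed$values, vectors = ed$vectors,
                 m_used = m, samples = geno$samples),
            class = "gpsm_grm")
}

#' @export
print.gpsm_grm <- function(x, ...) {
  cat(sprintf("gpsm_grm: %d samples, %d SNPs used, trace = %.2f\n",
              nrow(x$matrix), x$m_used, sum(diag(x$matrix))))
  invisible(x)
}

# guard used by every consumer of a GRM
check_grm_samples <- function(grm, samples) {
  if (!identical(grm$samples, samples))
    stop("GRM sample order does not match the supplied samples")
}
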