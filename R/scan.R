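#' Scan configuration
#'
#' @param maf_min minor-allele-frequency threshold for tested SNPs
#'   (default 0.01, i.e. only MAF > 0.01 is tested).
#' @param test only `"wald"` is implemented.
#' @param covariates optional n x c fixed-effect matrix; the overall mean
#'   is always fitted.
#' @param missing_max SNPs with missingness above this fraction are
#'   dropped (default 0.1).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(maf_min = 0.01, test = "wald", covariates = NULL,
                        missing_max = 0.1) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  test <- match.arg(test, "wald")
  structure(list(maf_min = maf_min, test = test, covariates = covariates,
                 missing_max = missing_max), class = "scan_config")
}

# Precompute everything that does not depend on the phenotype: SNP
# filtering, mean imputation, and the eigen-rotation of the dosage matrix
# and covariates. Permutation analyses and envGWAS reuse one engine for
# many phenotypes, which makes repeated scans cheap.
scan_engine <- function(geno, grm, config = scan_config()) {
  check_grm_samples(grm, geno$samples)
  X <- geno$dosage
  miss <- colMeans(is.na(X))
  p <- col_freq(X)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > config$maf_min & miss <= config$missing_max &
    col_vars(X) > 0
  if (!any(keep)) stop("no SNPs pass the MAF/missingness filters")
  S <- mean_impute(X[, keep, drop = FALSE])
  Xc <- cbind(`(Intercept)` = rep(1, length(geno$samples)), config$covariates)
  if (qr(Xc)$rank < ncol(Xc)) stop("covariate matrix is rank deficient")
  U <- grm$vectors
  list(d = pmax(grm$values, 0), U = U,
       Ss = crossprod(U, S), Xs = crossprod(U, Xc),
       snps = geno$snps[keep, , drop = FALSE], af = maf[keep],
       keep = keep, n = length(geno$samples), grm = grm)
}

# GLS Wald test of every SNP at the null-model variance ratio.
scan_with_y <- function(engine, y, vc = NULL) {
  n <- engine$n
  if (length(y) != n) stop("phenotype length mismatch")
  ys <- drop(crossprod(engine$U, y))
  if (is.null(vc)) {
    grid <- seq(-10, 10, length.out = 101)
    ll <- vapply(grid, reml_loglik_lambda, numeric(1),
                 ys = ys, Xs = engine$Xs, d = engine$d)
    i <- which.max(ll)
    opt <- stats::optimize(reml_loglik_lambda,
                           c(grid[max(1L, i - 1L)], grid[min(101L, i + 1L)]),
                           maximum = TRUE, ys = ys, Xs = engine$Xs,
                           d = engine$d, tol = 1e-10)
    lam <- exp(opt$maximum)
    v <- lam * engine$d + 1
    w <- 1 / v
    XtWX <- crossprod(engine$Xs, engine$Xs * w)
    bh <- solve(XtWX, crossprod(engine$Xs, ys * w))
    r <- ys - engine$Xs %*% bh
    se2 <- sum(w * r * r) / (n - ncol(engine$Xs))
    vc <- list(lambda = lam, sigma_e2 = se2, sigma_a2 = lam * se2,
               pve = lam / (1 + lam), loglik = opt$objective)
  }
  lam <- vc$lambda
  w <- 1 / (lam * engine$d + 1)

  Xs <- engine$Xs; Ss <- engine$Ss
  c_ <- ncol(Xs)
  XtWX <- crossprod(Xs, Xs * w)
  XtWXi <- solve(XtWX)
  # P v = W v - W X (X'WX)^-1 X' W v, applied without forming P
  Py <- w * ys - (Xs * w) %*% (XtWXi %*% crossprod(Xs, ys * w))
  yPy <- sum(ys * Py)
  TXS <- crossprod(Xs, Ss * w)                       # c x m
  sPs <- colSums(Ss * Ss * w) - colSums(TXS * (XtWXi %*% TXS))
  sPy <- drop(crossprod(Ss, Py))

  ok <- sPs > 1e-10
  beta <- ifelse(ok, sPy / sPs, NA_real_)
  df <- n - c_ - 1L
  rss <- yPy - ifelse(ok, beta * sPy, 0)
  sigma2 <- rss / df
  se <- ifelse(ok, sqrt(sigma2 / sPs), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)

  assoc <- data.frame(chrom = as.character(engine$snps$chrom),
                      pos_bp = engine$snps$pos_bp, id = engine$snps$id,
                      af = engine$af, beta = beta, se = se, p_wald = p,
                      q = NA_real_, stringsAsFactors = FALSE)
  attr(assoc, "vc") <- vc
  assoc
}

#' Per-SNP Wald association scan under a linear mixed model
#'
#' Tests each SNP for association with `y` under the model
#' y = mu + x g + u + e with u ~ N(0, sigma_a2 G). The variance ratio
#' lambda is estimated once at the null model and reused for every SNP
#' (the standard EMMAX/GEMMA-Wald compromise, an approximation that makes
#' large scans tractable); conditional on lambda, each SNP gets an exact
#' GLS effect and standard error, with a Wald t-test on n - c - 1 degrees
#' of freedom. SNPs collinear with the covariates get `p = NA`.
#'
#' @param geno a [genotypes] object.
#' @param y numeric phenotype (e.g. birth date age, an environmental
#'   variable, or a 0/1 region indicator).
#' @param grm a [compute_grm()] object, same samples and order.
#' @param config a [scan_config()].
#' @return association data.frame (`chrom`, `pos_bp`, `id`, `af`, `beta`,
#'   `se`, `p_wald`, `q`), with the fitted null variance components in
#'   `attr(, "vc")`.
#' @export
assoc_scan <- function(geno, y, grm, config = scan_config()) {
  engine <- scan_engine(geno, grm, config)
  scan_with_y(engine, y)
}
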