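# Multivariate linear mixed model: Y (n x d) = 1 mu' + U + E with
# rows of U ~ N(0, Vg) scaled by the GRM and rows of E ~ N(0, Ve).
# After rotating samples by the GRM eigenvectors, sample i has
# covariance Sigma_i = d_i Vg + Ve. The d x d pair (Vg, Ve) is
# simultaneously diagonalized each EM iteration (Q' Ve Q = I,
# Q' Vg Q = Lambda), which turns every E-step quantity into elementwise
# operations on n x d arrays -- the same device GEMMA's mvLMM uses.

mv_em_reml <- function(Ys, dvals, xs, max_iter = 5000L, tol = 1e-8) {
  # xs is the rotated intercept U'1 (not constant after rotation)
  n <- nrow(Ys); d <- ncol(Ys)
  S <- stats::cov(Ys)
  Vg <- S / 2
  Ve <- S / 2
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    L <- t(chol(Ve))
    M <- solve(L, t(solve(L, Vg)))
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    Q <- t(solve(L)) %*% eg$vectors     # Q'VeQ = I, Q'VgQ = diag(lam)
    Qi <- solve(Q)
    Yt <- Ys %*% Q                      # transformed traits
    Dm <- outer(dvals, lam) + 1         # n x d channel variances
    B <- 1 / Dm
    cb <- colSums(xs^2 * B)
    beta_t <- colSums(xs * B * Yt) / cb # GLS intercept per channel
    Rt <- Yt - outer(xs, beta_t)
    vb <- 1 / cb                        # diagonal of transformed Var(beta)

    ll <- -0.5 * sum(log(Dm)) + n * as.numeric(determinant(Q)$modulus) -
      0.5 * sum(Rt * Rt * B)

    # REML-EM updates; rr' is augmented with Var(beta) (diagonal here)
    A <- sweep(B, 2L, lam, "*")                 # lam_j / Dm_ij
    sq <- sqrt(dvals)
    RA <- Rt * A * sq
    inner_g <- crossprod(RA) +
      diag(vb, d) * crossprod(A * sq) -
      diag(colSums(sweep(A, 2L, lam, "*") * dvals), d)
    Vg_new <- Vg + t(Qi) %*% inner_g %*% Qi / n

    RB <- Rt * B
    inner_e <- crossprod(RB) + diag(vb, d) * crossprod(B) -
      diag(colSums(B), d)
    Ve_new <- Ve + t(Qi) %*% inner_e %*% Qi / n

    Vg_new <- (Vg_new + t(Vg_new)) / 2
    Ve_new <- (Ve_new + t(Ve_new)) / 2
    # keep Ve positive definite
    ee <- eigen(Ve_new, symmetric = TRUE)
    if (min(ee$values) < 1e-8) {
      Ve_new <- ee$vectors %*% diag(pmax(ee$values, 1e-8), d) %*% t(ee$vectors)
    }
    eg2 <- eigen(Vg_new, symmetric = TRUE)
    if (min(eg2$values) < 0) {
      Vg_new <- eg2$vectors %*% diag(pmax(eg2$values, 0), d) %*% t(eg2$vectors)
    }
    moved <- max(abs(Vg_new - Vg), abs(Ve_new - Ve)) /
      (max(abs(Vg), abs(Ve)) + 1e-12)
    Vg <- Vg_new; Ve <- Ve_new
    if (is.finite(loglik) && abs(ll - loglik) < tol && moved < sqrt(tol)) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  list(Vg = Vg, Ve = Ve, loglik = loglik, n_iter = it)
}

#' Multivariate linear mixed model scan
#'
#' Joint test of each SNP against d phenotypes (e.g. temperature,
#' precipitation and elevation in a combined envGWAS). Trait genetic and
#' residual covariance matrices are estimated at the null by EM-based
#' REML on the eigen-rotated data; each SNP's d-vector of effects is then
#' tested by a Wald chi-square with d degrees of freedom under those null
#' covariances. With a single column, the scan reduces to the univariate
#' [assoc_scan()] (and is delegated to it). Fixed effects are the
#' per-trait means.
#'
#' @param geno a [genotypes] object.
#' @param Y n x d numeric matrix, d <= 5, no duplicated or collinear
#'   columns. Columns are standardized internally.
#' @param grm a [compute_grm()] object.
#' @param config a [scan_config()] (covariates are not supported in the
#'   multivariate scan).
#' @return association data.frame with per-trait effect columns
#'   `beta.<trait>`, the joint `p_wald`, and attributes `Vg`, `Ve`,
#'   `genetic_cor`, `residual_cor`.
#' @export
mv_scan <- function(geno, Y, grm, config = scan_config()) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  if (d > 5L) stop("at most 5 phenotypes are supported")
  if (!is.null(config$covariates))
    stop("covariates beyond the mean are not supported in mv_scan")
  if (d == 1L) {
    out <- assoc_scan(geno, drop(Y), grm, config)
    return(out)
  }
  cn <- colnames(Y) %||% paste0("y", seq_len(d))
  dup <- duplicated(t(Y))
  if (any(dup)) stop("duplicated phenotype column(s): ",
                     paste(cn[dup], collapse = ", "))
  qrY <- qr(scale(Y))
  if (qrY$rank < d) {
    bad <- cn[-qrY$pivot[seq_len(qrY$rank)]]
    stop("rank-deficient phenotype matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- scale(Y)
  engine <- scan_engine(geno, grm, config)
  n <- engine$n
  Ys <- crossprod(engine$U, Y)
  xs <- drop(engine$Xs[, 1L])               # rotated intercept
  fit <- mv_em_reml(Ys, engine$d, xs)

  # final simultaneous diagonalization for the per-SNP tests
  L <- t(chol(fit$Ve))
  M <- solve(L, t(solve(L, fit$Vg)))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Q <- t(solve(L)) %*% eg$vectors
  Yt <- Ys %*% Q
  Dm <- outer(engine$d, lam) + 1
  B <- 1 / Dm                               # channel weights
  Ss <- engine$Ss
  m0 <- colSums(xs^2 * B)                   # per-channel, intercept block
  M1 <- crossprod(Ss, xs * B)               # m x d: sum_i x_i s_i b_ij
  M2 <- crossprod(Ss^2, B)                  # m x d: sum_i s_i^2 b_ij
  R1 <- crossprod(Ss, B * Yt)               # m x d: sum_i s_i b_ij y_ij
  Y1 <- colSums(xs * B * Yt)                # per-channel intercept RHS

  # per channel j, jointly fit (intercept, snp): 2x2 normal equations
  det2 <- sweep(M2, 2L, m0, "*") - M1^2
  num <- sweep(M1, 2L, Y1, "*")
  bt <- (sweep(R1, 2L, m0, "*") - num) / det2    # transformed snp effects
  varb <- sweep(1 / det2, 2L, m0, "*")           # Var(bt_j)
  chi2 <- rowSums(bt^2 / varb)
  ok <- apply(det2 > 1e-10, 1L, all)
  chi2[!ok] <- NA_real_
  # F calibration of the Wald statistic: asymptotically chi2/d, but the
  # F reference keeps type-I error honest at moderate n
  p <- stats::pf(chi2 / d, d, n - 1 - d, lower.tail = FALSE)

  # effects back on the (standardized) trait scale: b = Q'^{-1} bt
  Bmat <- t(solve(t(Q), t(bt)))
  colnames(Bmat) <- paste0("beta.", cn)

  assoc <- data.frame(chrom = as.character(engine$snps$chrom),
                      pos_bp = engine$snps$pos_bp, id = engine$snps$id,
                      af = engine$af, stringsAsFactors = FALSE)
  assoc <- cbind(assoc, as.data.frame(Bmat))
  assoc$chisq <- chi2
  assoc$p_wald <- p
  assoc$q <- NA_real_
  attr(assoc, "Vg") <- fit$Vg
  attr(assoc, "Ve") <- fit$Ve
  attr(assoc, "genetic_cor") <- stats::cov2cor(fit$Vg + diag(1e-12, d))
  attr(assoc, "residual_cor") <- stats::cov2cor(fit$Ve)
  attr(assoc, "vc") <- list(loglik = fit$loglik, n_iter = fit$n_iter)
  assoc
}
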