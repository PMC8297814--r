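# Profiled REML on the eigen-rotated single-GRM model.
#
# Model: y = X b + u + e, u ~ N(0, sigma_a2 G), e ~ N(0, sigma_e2 I).
# With G = U D U', rotating by U' gives independent errors with variance
# sigma_e2 (lambda d_i + 1), lambda = sigma_a2 / sigma_e2. sigma_e2 is
# profiled out in closed form, leaving a 1-D REML criterion in log lambda
# that is swept on a grid and refined by Brent's method.

# REML log-likelihood (up to an additive constant) at a given lambda,
# for pre-rotated ys = U'y, Xs = U'X and eigenvalues d.
reml_loglik_lambda <- function(loglam, ys, Xs, d) {
  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  bh <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% bh
  rss <- sum(w * r * r)
  nc <- length(ys) - ncol(Xs)
  -0.5 * (nc * log(rss / nc) + sum(log(v)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus))
}

# full REML log-likelihood at (sigma_a2, sigma_e2), used for the
# observed-information standard error of PVE
reml_loglik_theta <- function(sa2, se2, ys, Xs, d) {
  v <- sa2 * d + se2
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  bh <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% bh
  -0.5 * (sum(log(v)) + sum(w * r * r) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus))
}

#' Single-component REML variance estimation
#'
#' Estimates additive and residual variance for a phenotype given a GRM,
#' by profiled REML over the variance ratio on the eigen-rotated model
#' (101-point grid on log lambda in \[-10, 10\] followed by Brent
#' refinement). PVE = sigma_a2 / (sigma_a2 + sigma_e2); its standard
#' error comes from the observed information via the delta method.
#'
#' @param y numeric phenotype vector, length n, finite.
#' @param grm a [compute_grm()] object for the same samples, same order.
#' @param covariates optional n x c fixed-effect matrix; an intercept is
#'   always included.
#' @return object of class `variance_components` with `sigma_a2`,
#'   `sigma_e2`, `lambda`, `pve`, `pve_se`, `loglik` and a
#'   `non_identifiable` flag.
#' @export
reml_single <- function(y, grm, covariates = NULL) {
  n <- length(y)
  if (n != nrow(grm$matrix)) stop("length(y) != GRM dimension")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("y is constant; variance components undefined")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")

  d <- pmax(grm$values, 0)
  non_ident <- stats::sd(d) < 1e-8
  if (non_ident)
    warning("GRM eigenvalues are (near) constant; ",
            "the variance ratio is not identifiable")

  U <- grm$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  grid <- seq(-10, 10, length.out = 101)
  ll <- vapply(grid, reml_loglik_lambda, numeric(1), ys = ys, Xs = Xs, d = d)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(reml_loglik_lambda, c(lo, hi), maximum = TRUE,
                         ys = ys, Xs = Xs, d = d, tol = 1e-10)
  if (!is.finite(opt$objective))
    stop("non-finite REML likelihood at lambda = ", exp(opt$maximum))
  loglam <- opt$maximum
  lam <- exp(loglam)

  v <- lam * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  bh <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% bh
  se2 <- sum(w * r * r) / (n - ncol(Xs))
  sa2 <- lam * se2
  pve <- sa2 / (sa2 + se2)

  pve_se <- tryCatch({
    h <- pmax(c(sa2, se2), 1e-4 * stats::var(y)) * 1e-3
    f <- function(a, e) reml_loglik_theta(a, e, ys, Xs, d)
    H <- matrix(NA_real_, 2, 2)
    H[1, 1] <- (f(sa2 + h[1], se2) - 2 * f(sa2, se2) + f(sa2 - h[1], se2)) / h[1]^2
    H[2, 2] <- (f(sa2, se2 + h[2]) - 2 * f(sa2, se2) + f(sa2, se2 - h[2])) / h[2]^2
    H[1, 2] <- H[2, 1] <-
      (f(sa2 + h[1], se2 + h[2]) - f(sa2 + h[1], se2 - h[2]) -
         f(sa2 - h[1], se2 + h[2]) + f(sa2 - h[1], se2 - h[2])) / (4 * h[1] * h[2])
    V <- solve(-H)
    g <- c(se2, -sa2) / (sa2 + se2)^2
    sqrt(max(drop(t(g) %*% V %*% g), 0))
  }, error = function(e) NA_real_)

  structure(list(sigma_a2 = sa2, sigma_e2 = se2, lambda = lam,
                 pve = pve, pve_se = pve_se,
                 loglik = opt$objective, non_identifiable = non_ident),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma_a2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_e2))
  cat(sprintf("  PVE = %.3f (SE %.3f)\n", x$pve,
              if (is.na(x$pve_se)) NA else x$pve_se))
  invisible(x)
}
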