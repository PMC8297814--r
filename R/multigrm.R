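#' Multi-component REML variance partitioning
#'
#' Average-information REML for a phenotype with 2-4 GRM random effects
#' plus a residual, the design used to partition birth-date variance
#' among classes of SNPs (e.g. genome-wide significant, suggestive and
#' randomly drifting markers). EM steps replace AI steps that would leave
#' the parameter space, and variances are kept non-negative by
#' projection. Standard errors come from the inverse AI matrix, with the
#' PVE standard errors by the delta method.
#'
#' @param y numeric phenotype.
#' @param grms list of 2-4 [compute_grm()] objects (or plain matrices),
#'   all with the same sample order as `y`.
#' @param covariates optional fixed-effect matrix; intercept always
#'   included.
#' @param max_iter,tol iteration cap and relative convergence tolerance.
#' @return object of class `multi_vc`: `components` table with one
#'   variance/PVE/SE row per GRM plus residual and total, `loglik`,
#'   `n_iter`.
#' @export
multi_component_reml <- function(y, grms, covariates = NULL,
                                 max_iter = 200L, tol = 1e-8) {
  k <- length(grms)
  if (k < 2L || k > 4L) stop("need 2-4 GRMs")
  Gs <- lapply(grms, function(g) if (inherits(g, "gpsm_grm")) g$matrix else g)
  n <- length(y)
  if (any(vapply(Gs, nrow, 0L) != n)) stop("GRM dimensions do not match y")
  if (stats::sd(y) == 0) stop("y is constant")
  X <- cbind(rep(1, n), covariates)
  vy <- stats::var(y)
  theta <- rep(vy / (k + 1), k + 1L)      # k genetic + residual
  floor_v <- 1e-8 * vy

  Glist <- c(Gs, list(diag(n)))

  # REML log-likelihood at theta (NULL when V is not positive definite)
  reml_ll <- function(th) {
    V <- matrix(0, n, n)
    for (j in seq_len(k + 1L)) V <- V + th[j] * Glist[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    list(ll = -0.5 * (2 * sum(log(diag(ch))) +
                        as.numeric(determinant(XtViX)$modulus) +
                        sum(y * Py)),
         P = P, Py = Py)
  }

  state <- reml_ll(theta)
  if (is.null(state)) stop("covariance matrix not positive definite")
  AI <- NULL
  grad <- rep(Inf, k + 1L)
  for (it in seq_len(max_iter)) {
    P <- state$P; Py <- state$Py
    PGy <- lapply(Glist, function(G) G %*% Py)    # G_j P y
    grad <- vapply(seq_len(k + 1L), function(j)
      -0.5 * (sum(P * Glist[[j]]) - sum(Py * PGy[[j]])), numeric(1))

    AI <- matrix(0, k + 1L, k + 1L)
    PPGy <- lapply(PGy, function(v) P %*% v)
    for (i in seq_len(k + 1L)) for (j in i:(k + 1L)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(PGy[[i]] * PPGy[[j]])
    }

    # active set: a component pinned at the floor with a non-positive
    # gradient is a boundary (KKT) solution and is held fixed there
    fixed <- theta <= floor_v * 1.01 & grad <= 0
    free <- which(!fixed)
    if (length(free) == 0L) break
    if (rcond(AI[free, free, drop = FALSE]) < 1e-12)
      stop("AI matrix is singular: variance components are not ",
           "identifiable (are two GRMs identical?)")

    # AI step over the free components, with halving: accept the first
    # candidate inside the parameter space that does not decrease the
    # likelihood
    delta <- numeric(k + 1L)
    delta[free] <- solve(AI[free, free, drop = FALSE], grad[free])
    accepted <- FALSE
    for (h in 2^-(0:5)) {
      prop <- pmax(theta + h * delta, floor_v)
      cand <- reml_ll(prop)
      if (!is.null(cand) && cand$ll >= state$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # EM fallback step, guaranteed uphill and inside the space
      prop <- vapply(seq_len(k + 1L), function(j)
        theta[j] + theta[j]^2 * (sum(Py * PGy[[j]]) - sum(P * Glist[[j]])) / n,
        numeric(1))
      prop[fixed] <- floor_v
      prop <- pmax(prop, floor_v)
      cand <- reml_ll(prop)
      if (is.null(cand)) stop("covariance matrix not positive definite")
    }
    moved <- max(abs(prop - theta)[free] / (abs(theta[free]) + 0.1 * vy))
    dll <- cand$ll - state$ll
    theta <- prop
    state <- cand
    if (moved < tol * 100 || abs(dll) < tol) break
    if (it == max_iter)
      stop(sprintf("AI-REML did not converge in %d iterations (|grad| = %.3g)",
                   max_iter, sqrt(sum(grad^2))))
  }
  loglik <- state$ll

  Vtheta <- tryCatch(solve(AI),
                     error = function(e) matrix(NA_real_, k + 1L, k + 1L))
  tot <- sum(theta)
  pve <- theta / tot
  # delta-method SE of theta_j / sum(theta)
  pve_se <- vapply(seq_len(k + 1L), function(j) {
    g <- -theta[j] / tot^2 + (seq_len(k + 1L) == j) / tot
    sqrt(max(drop(t(g) %*% Vtheta %*% g), 0))
  }, numeric(1))
  gsum <- sum(theta[seq_len(k)])
  g <- c(rep(1, k), 0) / tot - gsum / tot^2
  pve_tot_se <- sqrt(max(drop(t(g) %*% Vtheta %*% g), 0))

  nm <- names(grms) %||% paste0("grm", seq_len(k))
  if (is.null(names(grms)) || any(!nzchar(nm))) nm <- paste0("grm", seq_len(k))
  comp <- data.frame(
    component = c(nm, "residual", "total_genetic"),
    variance = c(theta, gsum),
    se = c(sqrt(pmax(diag(Vtheta), 0)), NA),
    pve = c(pve, gsum / tot),
    pve_se = c(pve_se, pve_tot_se),
    stringsAsFactors = FALSE)
  structure(list(components = comp, loglik = loglik, n_iter = it,
                 theta = theta, cov_theta = Vtheta),
            class = "multi_vc")
}

#' @export
print.multi_vc <- function(x, ...) {
  cat("multi-component REML fit (", x$n_iter, " iterations)\n", sep = "")
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}
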