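#' Environmental phenotype table
#'
#' Assembles the per-sample environmental dependent variables used by
#' envGWAS: 30-year normal temperature (degrees C, mean of daily
#' high/low), precipitation (mm/yr) and elevation (m), plus the discrete
#' ecoregion label and the multi-region-zip exclusion flag produced by
#' [assign_ecoregion()].
#'
#' @param samples data.frame with `id` plus `temp`, `precip`, `elev`
#'   columns and optionally `zip`, `ecoregion`, `excluded_discrete`.
#' @return data.frame of class `env_phenotypes`.
#' @export
env_phenotypes <- function(samples) {
  need <- c("id", "temp", "precip", "elev")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(out$excluded_discrete)) out$excluded_discrete <- FALSE
  class(out) <- c("env_phenotypes", "data.frame")
  out
}

env_vars <- c("temp", "precip", "elev")

align_env <- function(geno, env) {
  idx <- match(geno$samples, env$id)
  if (anyNA(idx)) stop("environment table is missing genotyped samples")
  env[idx, , drop = FALSE]
}

#' envGWAS with continuous climate variables
#'
#' Runs the GPSM linear mixed model with standardized temperature,
#' precipitation and elevation as the dependent variables, either as
#' three univariate scans or one joint multivariate scan. The PVE here
#' measures how strongly genome-wide genotypes track the environmental
#' gradient, not heritability of an inherited trait.
#'
#' @param geno a [genotypes] object.
#' @param env an [env_phenotypes()] table.
#' @param grm optional [compute_grm()] object (computed when `NULL`).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param config a [scan_config()].
#' @return univariate: named list of association tables (with per-variable
#'   PVE in `attr(, "vc")`); multivariate: one [mv_scan()] table.
#' @export
env_scan_continuous <- function(geno, env, grm = NULL,
                                mode = c("univariate", "multivariate"),
                                config = scan_config()) {
  mode <- match.arg(mode)
  env <- align_env(geno, env)
  Y <- scale(as.matrix(env[, env_vars]))
  if (is.null(grm)) grm <- compute_grm(geno, maf_min = config$maf_min,
                                       missing_max = config$missing_max)
  if (mode == "multivariate") return(mv_scan(geno, Y, grm, config))
  engine <- scan_engine(geno, grm, config)
  out <- lapply(env_vars, function(v) scan_with_y(engine, Y[, v]))
  names(out) <- env_vars
  out
}

#' envGWAS with discrete ecoregion membership
#'
#' Case-control scans of 0/1 region-membership indicators, analyzed with
#' the same linear (not logistic) mixed model as the continuous scans.
#' Only regions with at least `min_n` samples are analyzed; animals whose
#' zip straddles multiple regions (`excluded_discrete`) are dropped here
#' but retained in continuous analyses. In the multivariate mode the
#' largest region is dropped as the reference to avoid linearly dependent
#' indicators.
#'
#' @inheritParams env_scan_continuous
#' @param min_n minimum region sample size (default 600).
#' @return univariate: named list of association tables per region;
#'   multivariate: one [mv_scan()] table over the included indicators.
#' @export
env_scan_discrete <- function(geno, env, grm = NULL,
                              mode = c("univariate", "multivariate"),
                              min_n = 600L, config = scan_config()) {
  mode <- match.arg(mode)
  env <- align_env(geno, env)
  if (is.null(env$ecoregion)) stop("env table has no 'ecoregion' column")
  use <- !env$excluded_discrete & !is.na(env$ecoregion)
  tab <- table(env$ecoregion[use])
  small <- names(tab)[tab < min_n]
  if (length(small))
    message("env_scan_discrete: excluding region(s) below min_n = ", min_n,
            ": ", paste(small, collapse = ", "))
  regions <- names(tab)[tab >= min_n]
  if (length(regions) == 0L) stop("no region reaches min_n = ", min_n)
  if (length(regions) == 1L && all(use & env$ecoregion %in% regions))
    stop("all samples belong to one region; membership is constant")
  ind <- sapply(regions, function(r)
    as.numeric(use & !is.na(env$ecoregion) & env$ecoregion == r))
  colnames(ind) <- regions
  if (any(apply(ind, 2L, stats::sd) == 0))
    stop("constant membership indicator; cannot scan")
  if (is.null(grm)) grm <- compute_grm(geno, maf_min = config$maf_min,
                                       missing_max = config$missing_max)
  if (mode == "multivariate") {
    if (length(regions) < 2L) stop("multivariate mode needs >= 2 regions")
    ref <- regions[which.max(tab[regions])]
    keep <- setdiff(regions, ref)
    message("env_scan_discrete: using largest region '", ref,
            "' as the reference")
    return(mv_scan(geno, ind[, keep, drop = FALSE], grm, config))
  }
  engine <- scan_engine(geno, grm, config)
  out <- lapply(regions, function(r) scan_with_y(engine, ind[, r]))
  names(out) <- regions
  out
}

#' Permute environmental phenotypes
#'
#' Two permutation schemes for the envGWAS negative control:
#' `by_animal` shuffles whole environment rows across animals;
#' `by_zip` shuffles the zip-to-environment mapping so that all animals
#' from one zip move together (testing whether over-sampling of
#' particular zips drives signal).
#'
#' @param env an [env_phenotypes()] table.
#' @param scheme `"by_animal"` or `"by_zip"`.
#' @param seed RNG seed.
#' @return permuted `env_phenotypes` table, same row order.
#' @export
permute_environment <- function(env, scheme = c("by_animal", "by_zip"),
                                seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  cols <- intersect(c(env_vars, "ecoregion", "excluded_discrete"), names(env))
  if (scheme == "by_animal") {
    perm <- sample(nrow(env))
    env[cols] <- env[perm, cols, drop = FALSE]
  } else {
    if (is.null(env$zip)) stop("by_zip permutation requires a 'zip' column")
    zips <- unique(env$zip)
    new_zip <- stats::setNames(sample(zips), zips)
    donor <- match(new_zip[as.character(env$zip)],
                   env$zip)  # first row of the donor zip
    env[cols] <- env[donor, cols, drop = FALSE]
  }
  env
}

#' Empirical p-value significance threshold from permutations
#'
#' Given the minimum scan p-value from each permutation round, selects
#' the largest power-of-ten threshold strictly below every permuted
#' minimum, capped at 1e-5 (the tier used when permutations are clean at
#' that level).
#'
#' @param min_ps numeric vector of per-permutation minimum p-values.
#' @return the p-value threshold (a power of ten).
#' @export
empirical_threshold <- function(min_ps) {
  if (length(min_ps) == 0L) stop("no permutation minima supplied")
  if (length(min_ps) == 1L)
    warning("threshold from a single permutation is unstable")
  mn <- min(min_ps, na.rm = TRUE)
  min(1e-5, 10^(ceiling(log10(mn)) - 1))
}
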