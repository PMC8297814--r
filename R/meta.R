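#' Region-stratified GPSM scans
#'
#' Runs an independent GPSM scan (region-specific GRM, birth-date
#' phenotype) inside every ecoregion with at least `min_n` genotyped
#' animals. Regions below the threshold are excluded with a message.
#' Per-region GRMs (rather than slices of the global GRM) keep each
#' region's SNP standardization self-consistent.
#'
#' @param geno a [genotypes] object.
#' @param samples data.frame with `id`, `birthdate_age` and `ecoregion`
#'   (NA / excluded animals are skipped).
#' @param min_n minimum per-region sample size (default 600; a stricter
#'   1,000 profile is common for trajectory follow-up).
#' @param config a [scan_config()].
#' @return named list of per-region association tables (each with the
#'   region's variance components in `attr(, "vc")`).
#' @export
within_region_scans <- function(geno, samples, min_n = 600L,
                                config = scan_config()) {
  idx <- match(geno$samples, samples$id)
  if (anyNA(idx)) stop("samples table is missing genotyped IDs")
  sam <- samples[idx, , drop = FALSE]
  if (is.null(sam$ecoregion)) stop("samples need an 'ecoregion' column")
  excl <- sam$excluded_discrete %||% rep(FALSE, nrow(sam))
  excl[is.na(excl)] <- FALSE
  ok <- !is.na(sam$ecoregion) & !excl
  tab <- table(sam$ecoregion[ok])
  small <- names(tab)[tab < min_n]
  if (length(small))
    message("within_region_scans: excluding region(s) below min_n = ",
            min_n, ": ", paste(small, collapse = ", "))
  regions <- names(tab)[tab >= min_n]
  if (length(regions) == 0L) stop("no region reaches min_n = ", min_n)
  out <- lapply(regions, function(r) {
    keep <- which(ok & sam$ecoregion == r)
    g <- subset_genotypes(geno, samples = keep)
    grm <- compute_grm(g, maf_min = config$maf_min,
                       missing_max = config$missing_max)
    assoc_scan(g, sam$birthdate_age[keep], grm, config)
  })
  names(out) <- regions
  out
}

# align per-region association tables on the union of SNP ids
region_summary_matrices <- function(scans) {
  ids <- Reduce(union, lapply(scans, function(a) a$id))
  k <- length(scans)
  B <- SE <- P <- matrix(NA_real_, length(ids), k,
                         dimnames = list(ids, names(scans)))
  for (j in seq_len(k)) {
    i <- match(scans[[j]]$id, ids)
    B[i, j] <- scans[[j]]$beta
    SE[i, j] <- scans[[j]]$se
    P[i, j] <- scans[[j]]$p_wald
  }
  meta_pos <- do.call(rbind, lapply(scans, function(a)
    a[, c("id", "chrom", "pos_bp")]))
  meta_pos <- meta_pos[!duplicated(meta_pos$id), ]
  list(ids = ids, beta = B, se = SE, p = P,
       pos = meta_pos[match(ids, meta_pos$id), ])
}

#' Fixed-effects meta-analysis with Cochran's Q
#'
#' Inverse-variance weighted combination of per-region effects:
#' w_i = 1/se_i^2, beta_FE = sum(w b)/sum(w), Q = sum(w (b - beta_FE)^2),
#' with p_Q from a chi-square on k - 1 degrees of freedom under
#' homogeneity. High Q flags SNPs whose selection differs between
#' ecoregions. Accepts vectors (one SNP) or matrices (SNPs x regions);
#' with a single region Q is `NA`.
#'
#' @param betas,ses numeric vectors of length k, or m x k matrices.
#' @return data.frame `beta_fe`, `se_fe`, `q_stat`, `df`, `p_q`.
#' @export
meta_fixed_effects <- function(betas, ses) {
  B <- rbind(betas)
  if (is.matrix(betas)) B <- betas
  SE <- rbind(ses)
  if (is.matrix(ses)) SE <- ses
  if (!all(dim(B) == dim(SE))) stop("betas and ses must have equal shape")
  if (any(SE <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  W <- 1 / SE^2
  W[is.na(B)] <- NA
  k_eff <- rowSums(!is.na(W))
  sw <- rowSums(W, na.rm = TRUE)
  beta_fe <- rowSums(W * B, na.rm = TRUE) / sw
  q <- rowSums(W * (B - beta_fe)^2, na.rm = TRUE)
  df <- k_eff - 1L
  p_q <- ifelse(df >= 1L, stats::pchisq(q, df, lower.tail = FALSE), NA_real_)
  q[df < 1L] <- NA_real_
  data.frame(beta_fe = beta_fe, se_fe = sqrt(1 / sw), q_stat = q,
             df = df, p_q = p_q)
}

#' Posterior probability of a region-specific effect (m-values)
#'
#' Binary-effects meta-analysis posterior: every effect/no-effect
#' configuration over the k regions is enumerated (2^k); in a
#' configuration, effect regions share one true effect with prior
#' N(0, `prior_var`) (integrated in closed form), no-effect regions have
#' mean zero, and configurations get independent Bernoulli(`prior_p`)
#' priors. The m-value for region i is the posterior mass of
#' configurations in which region i has an effect.
#'
#' @param betas,ses per-region effect estimates and standard errors
#'   (vectors of length k <= 12, or m x k matrices).
#' @param prior_var prior variance of the shared true effect
#'   (default 0.04).
#' @param prior_p per-region prior probability of an effect
#'   (default 0.5).
#' @return vector (or m x k matrix) of m-values in \[0, 1\].
#' @export
compute_mvalues <- function(betas, ses, prior_var = 0.04, prior_p = 0.5) {
  vec_in <- !is.matrix(betas)
  B <- if (vec_in) rbind(betas) else betas
  SE <- if (vec_in) rbind(ses) else ses
  k <- ncol(B)
  if (k > 12L) stop("k = ", k, " regions would enumerate 2^", k,
                    " configurations; analyze a subset")
  if (any(SE <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  m <- nrow(B)
  configs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))  # 2^k x k

  # per-SNP log-likelihood pieces
  lnull <- stats::dnorm(B, 0, SE, log = TRUE)       # m x k, no-effect terms
  W <- 1 / SE^2
  nconf <- nrow(configs)
  logpost <- matrix(NA_real_, m, nconf)
  for (cix in seq_len(nconf)) {
    cfg <- configs[cix, ] == 1L
    ll <- rowSums(lnull[, !cfg, drop = FALSE])
    if (any(cfg)) {
      Wc <- W[, cfg, drop = FALSE]
      Bc <- B[, cfg, drop = FALSE]
      sw <- rowSums(Wc)
      mu <- rowSums(Wc * Bc) / sw
      # integral of prod N(b_i; mu, 1/w_i) N(mu; 0, prior_var) dmu
      ll_eff <- rowSums(0.5 * log(Wc / (2 * pi))) -
        0.5 * (rowSums(Wc * Bc^2) - sw * mu^2) +
        0.5 * log(2 * pi / sw) +
        stats::dnorm(mu, 0, sqrt(prior_var + 1 / sw), log = TRUE)
      ll <- ll + ll_eff
    }
    lprior <- sum(cfg) * log(prior_p) + sum(!cfg) * log(1 - prior_p)
    logpost[, cix] <- ll + lprior
  }
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  mv <- post %*% configs
  colnames(mv) <- colnames(B)
  if (vec_in) drop(mv) else mv
}

#' Meta-analysis of region-stratified GPSM scans
#'
#' Combines per-region effects and standard errors into fixed-effects
#' summaries with Cochran's Q and per-region m-values, aligned on SNP.
#'
#' @param scans named list of per-region association tables from
#'   [within_region_scans()].
#' @param prior_var,prior_p m-value priors (see [compute_mvalues()]).
#' @param mvalue_max_p m-values are only computed for SNPs with
#'   `p_q` below this (they are read for heterogeneous SNPs; skipping the
#'   rest keeps the enumeration cheap). Use `1` to compute all.
#' @return object of class `meta_result`: `table` (per-SNP summaries with
#'   per-region beta/se/p columns), `mvalues` (matrix, NA where not
#'   computed), `regions`.
#' @export
meta_region_scans <- function(scans, prior_var = 0.04, prior_p = 0.5,
                              mvalue_max_p = 1e-3) {
  if (length(scans) < 2L) stop("need at least 2 region scans")
  al <- region_summary_matrices(scans)
  fe <- meta_fixed_effects(al$beta, al$se)
  tab <- data.frame(id = al$ids, chrom = al$pos$chrom,
                    pos_bp = al$pos$pos_bp, fe,
                    stringsAsFactors = FALSE)
  mv <- matrix(NA_real_, nrow(tab), ncol(al$beta),
               dimnames = list(al$ids, colnames(al$beta)))
  sel <- which(!is.na(tab$p_q) & tab$p_q <= mvalue_max_p &
                 rowSums(is.na(al$beta)) == 0L)
  if (length(sel))
    mv[sel, ] <- compute_mvalues(al$beta[sel, , drop = FALSE],
                                 al$se[sel, , drop = FALSE],
                                 prior_var = prior_var, prior_p = prior_p)
  structure(list(table = tab, mvalues = mv, beta = al$beta, se = al$se,
                 p = al$p, regions = names(scans)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("region meta-analysis:", nrow(x$table), "SNPs x",
      length(x$regions), "regions\n")
  invisible(x)
}

#' Loci under region-specific selection
#'
#' Applies the conjunction filter: a SNP qualifies when its Cochran's Q
#' heterogeneity p-value and at least one within-region scan p-value both
#' fall below their thresholds (default 1e-5 for both). Qualifying SNPs
#' are clumped into loci at `merge_bp`, and each locus carries its lead
#' SNP's per-region m-value profile.
#'
#' @param meta a [meta_region_scans()] result.
#' @param p_q_threshold Cochran's Q p-value cutoff (default 1e-5).
#' @param p_region_threshold within-region p cutoff (default 1e-5).
#' @param merge_bp clumping gap (default 1 Mb).
#' @return locus data.frame (see [clump_loci()]) with appended m-value
#'   columns `m.<region>` for the lead SNP.
#' @export
region_specific_loci <- function(meta, p_q_threshold = 1e-5,
                                 p_region_threshold = 1e-5,
                                 merge_bp = 1e6) {
  tab <- meta$table
  any_region <- rowSums(meta$p < p_region_threshold, na.rm = TRUE) > 0L
  sig <- !is.na(tab$p_q) & tab$p_q < p_q_threshold & any_region
  assoc <- data.frame(chrom = tab$chrom, pos_bp = tab$pos_bp, id = tab$id,
                      p_wald = tab$p_q, q = NA_real_,
                      stringsAsFactors = FALSE)
  loci <- clump_loci(assoc, significant = sig, merge_bp = merge_bp)
  if (nrow(loci) == 0L) return(loci)
  mvlead <- meta$mvalues[match(loci$lead_id, rownames(meta$mvalues)), ,
                         drop = FALSE]
  # lead SNPs inside loci always get m-values, even if skipped earlier
  need <- which(rowSums(is.na(mvlead)) > 0L)
  if (length(need)) {
    ridx <- match(loci$lead_id[need], meta$table$id)
    mvlead[need, ] <- compute_mvalues(meta$beta[ridx, , drop = FALSE],
                                      meta$se[ridx, , drop = FALSE])
  }
  colnames(mvlead) <- paste0("m.", colnames(meta$mvalues))
  cbind(loci, as.data.frame(mvlead, row.names = NULL))
}

#' Classify a region's allele-frequency trajectory
#'
#' Decides whether a SNP's frequency inside one ecoregion is converging
#' to or diverging from the pooled population trajectory: both
#' trajectories are smoothed ([allele_frequency_trajectory()]), the
#' region's observed time range is split into terciles, and the mean
#' absolute region-pooled gap over the last tercile is compared with the
#' first. Shrinking gap = "convergent" (the decay of region-specific
#' frequencies towards the population mean); growing gap = "divergent"
#' (ongoing region-specific selection). Exact ties resolve to
#' convergent.
#'
#' @param dosage,birthdate,region per-sample dosage (0/1/2), birth date
#'   (years) and region label for the pooled sample.
#' @param target_region region to classify (default: each region in
#'   turn).
#' @param span loess span passed to the trajectory smoother.
#' @param min_span_years regions observed for less than this are
#'   `"unclassified"` (default 3).
#' @return data.frame `region`, `gap_first`, `gap_last`, `class`.
#' @export
classify_region_trajectory <- function(dosage, birthdate, region,
                                       target_region = NULL, span = 0.75,
                                       min_span_years = 3) {
  regions <- target_region %||% sort(unique(stats::na.omit(region)))
  pooled <- allele_frequency_trajectory(dosage, birthdate, span = span)
  out <- lapply(regions, function(r) {
    sel <- !is.na(region) & region == r
    tspan <- diff(range(birthdate[sel], na.rm = TRUE))
    if (sum(sel) < 30L || tspan < min_span_years)
      return(data.frame(region = r, gap_first = NA_real_,
                        gap_last = NA_real_, class = "unclassified",
                        stringsAsFactors = FALSE))
    rt <- allele_frequency_trajectory(dosage[sel], birthdate[sel],
                                      span = span, min_span_years = 0)
    tr <- range(birthdate[sel], na.rm = TRUE)
    grid <- seq(tr[1], tr[2], length.out = 30L)
    fr <- stats::approx(rt$curve$time, rt$curve$freq, xout = grid,
                        rule = 2)$y
    fp <- stats::approx(pooled$curve$time, pooled$curve$freq, xout = grid,
                        rule = 2)$y
    gap <- abs(fr - fp)
    terc <- cut(grid, breaks = stats::quantile(grid, c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE, labels = FALSE)
    g1 <- mean(gap[terc == 1L]); g3 <- mean(gap[terc == 3L])
    cls <- if (g3 <= g1) "convergent" else "divergent"
    if (g3 == g1) message("classify_region_trajectory: tie for region ", r,
                          "; resolved as convergent")
    data.frame(region = r, gap_first = g1, gap_last = g3, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write per-region summaries in METASOFT input layout
#'
#' One row per SNP: the SNP id followed by beta/se pairs for each region,
#' whitespace-delimited, for cross-validation against the reference
#' meta-analysis implementation.
#'
#' @param meta a [meta_region_scans()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metasoft_input <- function(meta, path) {
  k <- length(meta$regions)
  cols <- matrix(NA_real_, nrow(meta$table), 2L * k)
  cols[, 2 * seq_len(k) - 1L] <- meta$beta
  cols[, 2 * seq_len(k)] <- meta$se
  df <- data.frame(id = meta$table$id, cols)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}
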