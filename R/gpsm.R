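#' Generation Proxy Selection Mapping
#'
#' The full GPSM pipeline: standardized GRM, null REML fit with birth
#' date (continuous age) as the dependent variable, per-SNP Wald scan,
#' Storey q-values, and single-linkage clumping of significant SNPs into
#' loci. SNPs whose allele frequencies track birth date beyond what
#' relatedness and drift explain are the signal of ongoing selection.
#'
#' @param geno a [genotypes] object.
#' @param samples data.frame from [read_sample_table()] (needs `id` and
#'   `birthdate_age`); rows are matched to `geno` by `id` and every
#'   retained sample must have a finite age.
#' @param config a [scan_config()]; the overall mean is the only fixed
#'   effect by default.
#' @param q_threshold q-value significance cutoff (default 0.1).
#' @param merge_bp significant SNPs closer than this join one locus
#'   (default 1 Mb).
#' @param n_perm number of birth-date permutations run as a negative
#'   control (default 0; the conventional check uses 10).
#' @param seed RNG seed for the permutations.
#' @return object of class `gpsm_result`: `assoc` (with `q`), `pve`
#'   ([reml_single] fit), `loci`, `thresholds` (significant counts at
#'   q < 0.1, q < 0.05, Bonferroni 0.05 and p < 1e-5), and
#'   `permutation_summaries` when `n_perm > 0`.
#' @export
run_gpsm <- function(geno, samples, config = scan_config(),
                     q_threshold = 0.1, merge_bp = 1e6,
                     n_perm = 0L, seed = 1L) {
  idx <- match(geno$samples, samples$id)
  if (anyNA(idx))
    stop("samples table is missing IDs present in the genotypes: ",
         paste(utils::head(geno$samples[is.na(idx)], 3), collapse = ", "))
  y <- samples$birthdate_age[idx]
  if (anyNA(y) || !all(is.finite(y)))
    stop("birthdate_age must be present and finite for all samples")
  if (length(y) < 3L) stop("too few samples for a GRM-based scan")

  grm <- compute_grm(geno, maf_min = config$maf_min,
                     missing_max = config$missing_max)
  engine <- scan_engine(geno, grm, config)
  assoc <- scan_with_y(engine, y)
  vc <- attr(assoc, "vc")
  pve_fit <- reml_single(y, grm, covariates = config$covariates)
  assoc$q <- storey_qvalues(assoc$p_wald)
  loci <- clump_loci(assoc, q_threshold = q_threshold, merge_bp = merge_bp)

  m <- sum(!is.na(assoc$p_wald))
  thresholds <- data.frame(
    threshold = c(sprintf("q < %g", q_threshold), "q < 0.05",
                  "Bonferroni 0.05", "p < 1e-5"),
    n_significant = c(sum(assoc$q < q_threshold, na.rm = TRUE),
                      sum(assoc$q < 0.05, na.rm = TRUE),
                      sum(assoc$p_wald < 0.05 / m, na.rm = TRUE),
                      sum(assoc$p_wald < 1e-5, na.rm = TRUE)))

  perms <- NULL
  if (n_perm > 0L) {
    perms <- permutation_null_engine(engine, y, n_perm = n_perm, seed = seed)
  }
  structure(list(assoc = assoc, pve = pve_fit, vc_scan = vc, loci = loci,
                 thresholds = thresholds, permutation_summaries = perms,
                 q_threshold = q_threshold),
            class = "gpsm_result")
}

#' @export
print.gpsm_result <- function(x, ...) {
  cat("GPSM scan:", nrow(x$assoc), "SNPs,",
      sum(x$assoc$q < x$q_threshold, na.rm = TRUE), "significant (q <",
      x$q_threshold, ") in", nrow(x$loci), "loci\n")
  cat(sprintf("  birth-date PVE = %.3f (SE %.3f)\n", x$pve$pve, x$pve$pve_se))
  invisible(x)
}

permutation_null_engine <- function(engine, y, n_perm = 10L, seed = 1L) {
  if (n_perm == 0L)
    return(data.frame(perm = integer(), seed = integer(), pve = numeric(),
                      min_p = numeric(), n_sig_q10 = integer()))
  res <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    s <- seed + i - 1L
    set.seed(s)
    yp <- sample(y)
    a <- scan_with_y(engine, yp)
    vc <- attr(a, "vc")
    qq <- storey_qvalues(a$p_wald)
    res[[i]] <- data.frame(perm = i, seed = s, pve = vc$pve,
                           min_p = min(a$p_wald, na.rm = TRUE),
                           n_sig_q10 = sum(qq < 0.1, na.rm = TRUE))
  }
  do.call(rbind, res)
}

#' Permutation negative control for GPSM
#'
#' Permutes birth dates against the genotypes and re-runs the scan; with
#' the generation proxy detached from the genomes, the PVE should
#' collapse to ~0 and no SNPs should reach significance. One GRM and one
#' rotated dosage matrix are shared across permutations.
#'
#' @inheritParams run_gpsm
#' @param n_perm number of permutations (default 10).
#' @return data.frame with one row per permutation: `perm`, `seed`,
#'   `pve`, `min_p`, `n_sig_q10`.
#' @export
permutation_null <- function(geno, samples, config = scan_config(),
                             n_perm = 10L, seed = 1L) {
  idx <- match(geno$samples, samples$id)
  y <- samples$birthdate_age[idx]
  grm <- compute_grm(geno, maf_min = config$maf_min,
                     missing_max = config$missing_max)
  engine <- scan_engine(geno, grm, config)
  permutation_null_engine(engine, y, n_perm = n_perm, seed = seed)
}

#' Clump significant SNPs into loci
#'
#' Single-linkage grouping: consecutive significant SNPs on a chromosome
#' join one locus whenever the gap to the nearest significant neighbour
#' is at most `merge_bp` (so a chain of sub-threshold spacings can span
#' many megabases). The lead SNP is the smallest p, ties broken by
#' position.
#'
#' @param assoc association table with `chrom`, `pos_bp`, `p_wald` and
#'   (unless `significant` is given) `q`.
#' @param q_threshold SNPs with `q` below this are clumped (default 0.1).
#' @param merge_bp maximum gap joining two SNPs into one locus
#'   (default 1 Mb, i.e. loci are > 1 Mb apart).
#' @param significant optional logical vector overriding the q filter
#'   (used by the meta-analysis conjunction filter).
#' @return data.frame with one row per locus: `locus`, `chrom`, `start`,
#'   `end`, `span_bp`, `lead_id`, `lead_pos`, `lead_p`, `n_snps`.
#' @export
clump_loci <- function(assoc, q_threshold = 0.1, merge_bp = 1e6,
                       significant = NULL) {
  sig <- significant %||% (!is.na(assoc$q) & assoc$q < q_threshold)
  sig[is.na(sig)] <- FALSE
  hits <- assoc[sig, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(locus = integer(), chrom = character(),
                      start = integer(), end = integer(), span_bp = integer(),
                      lead_id = character(), lead_pos = integer(),
                      lead_p = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  hits <- hits[order(hits$chrom, hits$pos_bp), , drop = FALSE]
  newgrp <- c(TRUE, hits$chrom[-1] != hits$chrom[-nrow(hits)] |
                diff(hits$pos_bp) > merge_bp)
  grp <- cumsum(newgrp)
  out <- lapply(split(hits, grp), function(h) {
    lead <- h[order(h$p_wald, h$pos_bp), ][1, ]
    data.frame(chrom = h$chrom[1], start = min(h$pos_bp),
               end = max(h$pos_bp), span_bp = max(h$pos_bp) - min(h$pos_bp),
               lead_id = lead$id, lead_pos = lead$pos_bp, lead_p = lead$p_wald,
               n_snps = nrow(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(locus = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
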