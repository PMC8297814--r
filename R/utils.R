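#' @keywords internal
#' @useDynLib gpsmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# allele frequency of allele1 per SNP column, NA-aware
col_freq <- function(dosage) {
  colMeans(dosage, na.rm = TRUE) / 2
}

# minor allele frequency per SNP column
col_maf <- function(dosage) {
  p <- col_freq(dosage)
  pmin(p, 1 - p)
}

# mean-impute missing dosages per SNP, in place on a copy
mean_impute <- function(dosage) {
  nas <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    mu <- 2 * col_freq(dosage)
    dosage[nas] <- mu[nas[, 2L]]
  }
  dosage
}

# half-away-from-zero rounding to `digits` decimals (base round() is
# round-half-even, which would send 39.95 to 39.9)
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

chrom_order <- function(chrom) {
  suppressWarnings(num <- as.numeric(chrom))
  order(is.na(num), num, as.character(chrom))
}

# calendar-aware age in fractional years: whole years between
# anniversaries plus the fraction of the current anniversary year, so a
# birthday exactly n years before the reference gives n.0
years_between <- function(from, to) {
  vapply(seq_along(from), function(i) {
    f <- from[i]; t <- to
    if (is.na(f)) return(NA_real_)
    sgn <- 1
    if (f > t) { tmp <- f; f <- t; t <- tmp; sgn <- -1 }
    y <- as.integer(format(t, "%Y")) - as.integer(format(f, "%Y"))
    anniv <- seq(f, by = "year", length.out = y + 2L)
    last <- max(which(anniv <= t))
    frac <- as.numeric(t - anniv[last]) /
      as.numeric(anniv[last + 1L] - anniv[last])
    sgn * (last - 1L + frac)
  }, numeric(1))
}

# NA-aware column variances without an extra dependency
col_vars <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  colMeans(sweep(X, 2L, mu)^2, na.rm = TRUE)
}

# labels PLINK and GFF use for non-autosomal records; numeric codes are kept
# because autosome counts differ by species (cattle have 29)
NON_AUTOSOMES <- c("X", "Y", "XY", "MT", "M", "chrX", "chrY", "chrM", "0")
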