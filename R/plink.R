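#' Genotype container
#'
#' A `genotypes` object holds an n x m dosage matrix (samples x SNPs,
#' counting copies of allele1, `NA` for missing) together with per-SNP
#' metadata and sample IDs.
#'
#' @param dosage numeric or integer n x m matrix with values in \[0, 2\] or
#'   `NA`; rows are samples, columns SNPs.
#' @param samples character vector of unique sample IDs, length n.
#' @param snps data.frame with columns `chrom`, `pos_bp` (1-based),
#'   `id`, `allele1`, `allele0`; one row per SNP. Positions must be
#'   strictly increasing within each chromosome.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, samples, snps) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2L) stop("need at least 2 samples")
  if (ncol(dosage) < 1L) stop("need at least 1 SNP")
  if (length(samples) != nrow(dosage)) stop("length(samples) != nrow(dosage)")
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  if (nrow(snps) != ncol(dosage)) stop("nrow(snps) != ncol(dosage)")
  need <- c("chrom", "pos_bp", "id", "allele1", "allele0")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snps table missing columns: ", paste(miss, collapse = ", "))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosage values must lie in [0, 2]")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos_bp[snps$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("pos_bp not strictly increasing within chromosome ", ch)
  }
  rownames(dosage) <- samples
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, samples = as.character(samples),
                 snps = as.data.frame(snps, stringsAsFactors = FALSE)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$snps), length(unique(x$snps$chrom))))
  nmiss <- sum(is.na(x$dosage))
  if (nmiss > 0) cat(sprintf("  %d missing calls\n", nmiss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Subset a genotype panel by sample and/or SNP
#'
#' @param x a `genotypes` object.
#' @param samples sample IDs or indices to keep (default all).
#' @param snps SNP indices or logical mask to keep (default all).
#' @return a `genotypes` object.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(x$samples) else {
    if (is.character(samples)) match(samples, x$samples) else samples
  }
  if (anyNA(si)) stop("unknown sample IDs in subset")
  vi <- if (is.null(snps)) seq_len(nrow(x$snps))
        else if (is.logical(snps)) which(snps) else snps
  genotypes(x$dosage[si, vi, drop = FALSE], x$samples[si],
            x$snps[vi, , drop = FALSE])
}

# 256 x 4 lookup: byte value -> dosage of allele1 for the 4 packed samples.
# PLINK 2-bit codes (low bits = first sample): 00 hom A1, 01 missing,
# 10 het, 11 hom A2; dosage counts copies of A1.
plink_lut <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  sapply(0:3, function(s) codes[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L])
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes the SNP-major PLINK 1 binary format. Dosage counts copies of
#' allele1 (BIM column 5), matching PLINK's convention, so downstream
#' effect signs refer to allele1. Missing genotypes are preserved as `NA`
#' (mean imputation happens only at GRM/scan time). Non-autosomal records
#' (chromosome codes X, Y, XY, MT, 0) are excluded with a message.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   must all exist.
#' @param autosomes_only drop non-autosomal SNPs (default `TRUE`).
#' @return a [genotypes] object; sample order follows the fam file.
#' @export
read_plink <- function(prefix, autosomes_only = TRUE) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing PLINK file: ", p)

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", paths[3])
  n <- length(ids)

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos_bp",
                                         "allele1", "allele0"))
  m <- nrow(bim)

  sz <- file.info(paths[1])$size
  bpf <- ceiling(n / 4)
  if (sz != 3 + as.double(bpf) * m)
    stop("truncated or mis-sized bed file ", paths[1],
         sprintf(" (expected %d bytes, found %d)", 3 + bpf * m, sz))
  con <- file(paths[1], "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("bad magic bytes in ", paths[1], " (not a SNP-major PLINK bed file)")
  raw <- readBin(con, "raw", bpf * m)

  lut <- plink_lut()                      # 256 x 4
  vals <- t(lut[as.integer(raw) + 1L, , drop = FALSE])  # 4 x (bpf*m)
  dim(vals) <- c(4L * bpf, m)
  dosage <- vals[seq_len(n), , drop = FALSE]

  snps <- bim[, c("chrom", "pos_bp", "id", "allele1", "allele0")]
  snps$chrom <- as.character(snps$chrom)
  if (autosomes_only) {
    drop <- snps$chrom %in% NON_AUTOSOMES
    if (any(drop)) {
      message("read_plink: excluding ", sum(drop), " non-autosomal SNP(s)")
      snps <- snps[!drop, , drop = FALSE]
      dosage <- dosage[, !drop, drop = FALSE]
    }
  }
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing))
    message("read_plink: ", sum(all_missing), " SNP(s) have no called genotypes")
  genotypes(dosage, ids, snps)
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' Dosages are rounded to hard calls \{0, 1, 2\}; `NA` is written as the
#' PLINK missing code. Output is byte-for-byte deterministic.
#'
#' @param geno a [genotypes] object.
#' @param prefix output path prefix.
#' @param generation optional numeric vector written as the fam phenotype
#'   column (useful for generation labels from simulations).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, generation = NULL) {
  n <- length(geno$samples)
  m <- nrow(geno$snps)
  fam <- data.frame(fid = geno$samples, iid = geno$samples, pat = 0L, mat = 0L,
                    sex = 0L, pheno = if (is.null(generation)) -9 else generation)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chrom = geno$snps$chrom, id = geno$snps$id, cm = 0,
                    pos = geno$snps$pos_bp, a1 = geno$snps$allele1,
                    a0 = geno$snps$allele0)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  # dosage -> 2-bit codes: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2] <- 0L
    out[!is.na(d) & d == 1] <- 2L
    out[!is.na(d) & d == 0] <- 3L
    out
  }
  bpf <- ceiling(n / 4)
  pad <- 4L * bpf - n
  hard <- round(geno$dosage)
  codes <- matrix(0L, 4L * bpf, m)
  codes[seq_len(n), ] <- apply(hard, 2L, code_of)
  shifts <- rep(c(1L, 4L, 16L, 64L), bpf)
  packed <- codes * shifts
  dim(packed) <- c(4L, bpf * m)
  bytes <- as.raw(colSums(packed))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}
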