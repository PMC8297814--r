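#' Candidate genes near significant SNPs
#'
#' Reports every annotated gene within `window` bp of each SNP. Distance
#' is 0 for a SNP inside a gene, otherwise the absolute base-pair
#' difference between the SNP position and the nearest gene edge; SNPs
#' farther than `window` from a gene edge are not reported.
#'
#' @param snps data.frame with `chrom`, `pos_bp` (1-based) and `id`
#'   columns (e.g. significant rows of an association table, or the lead
#'   SNPs of a locus table renamed accordingly).
#' @param genes `GRanges` from [read_gene_annotation()].
#' @param window maximum distance in bp (default 10,000).
#' @return data.frame `snp`, `gene`, `distance_bp`, sorted by SNP then
#'   distance.
#' @export
annotate_candidates <- function(snps, genes, window = 10000L) {
  if (nrow(snps) == 0L || length(genes) == 0L)
    return(data.frame(snp = character(), gene = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos_bp, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, genes, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(snp = character(), gene = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  pos <- snps$pos_bp[i]
  gs <- GenomicRanges::start(genes)[j]
  ge <- GenomicRanges::end(genes)[j]
  dist <- ifelse(pos < gs, gs - pos, ifelse(pos > ge, pos - ge, 0L))
  keep <- dist <= window
  out <- data.frame(snp = as.character(snps$id[i[keep]]),
                    gene = as.character(genes$name[j[keep]]),
                    distance_bp = as.integer(dist[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$snp, out$distance_bp), , drop = FALSE]
}
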