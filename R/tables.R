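#' Read a sample table with birth dates and locations
#'
#' Parses a delimited text file with a header and at least an `id` and a
#' `birth_date` column (ISO `YYYY-MM-DD`). The generation proxy used by
#' the scans is continuous age at a fixed reference date, in fractional
#' years. Optional columns `zip`, `lat`, `lon` and `ecoregion` are carried
#' through when present.
#'
#' @param path delimited text file (tab or comma separated, with header).
#' @param reference_date the date age is measured at (`Date` or
#'   `YYYY-MM-DD` string).
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return data.frame with columns `id`, `birthdate_age` (years), plus any
#'   optional location columns found.
#' @export
read_sample_table <- function(path, reference_date, sep = NULL) {
  if (!file.exists(path)) stop("missing sample table: ", path)
  ref <- as.Date(reference_date)
  if (is.na(ref)) stop("unparseable reference_date: ", reference_date)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl(",", hdr)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("id", "birth_date") %in% names(tab)))
    stop("sample table needs 'id' and 'birth_date' columns")
  if (anyDuplicated(tab$id)) stop("duplicate sample IDs in ", path)
  bd <- as.Date(as.character(tab$birth_date), format = "%Y-%m-%d")
  bad <- which(is.na(bd) & !is.na(tab$birth_date) & tab$birth_date != "")
  if (length(bad))
    stop("unparseable birth date at line ", bad[1] + 1L, " of ", path,
         " ('", tab$birth_date[bad[1]], "')")
  age <- years_between(bd, ref)
  if (any(age < 0, na.rm = TRUE))
    warning(sum(age < 0, na.rm = TRUE),
            " birth date(s) after the reference date give negative ages")
  out <- data.frame(id = as.character(tab$id), birthdate_age = age,
                    stringsAsFactors = FALSE)
  for (col in c("zip", "lat", "lon", "ecoregion"))
    if (col %in% names(tab)) out[[col]] <- tab[[col]]
  out
}

assoc_cols <- c("chr", "rs", "ps", "af", "beta", "se", "p_wald", "q")

#' Write an association table
#'
#' Tab-delimited columnar output with fixed column order
#' `chr rs ps af beta se p_wald q`, mirroring the layout of common LMM
#' association tools. Values round-trip through [read_assoc_table()] at
#' 12 significant digits. A missing `q` column is written as `NA`.
#'
#' @param assoc association data.frame as produced by [assoc_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(assoc, path) {
  out <- data.frame(chr = assoc$chrom, rs = assoc$id, ps = assoc$pos_bp,
                    af = assoc$af, beta = assoc$beta, se = assoc$se,
                    p_wald = assoc$p_wald,
                    q = if ("q" %in% names(assoc)) assoc$q else NA_real_,
                    stringsAsFactors = FALSE)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "ps"
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_assoc_table()]
#'
#' @param path tab-delimited association file.
#' @return data.frame with columns `chrom`, `id`, `pos_bp`, `af`, `beta`,
#'   `se`, `p_wald`, `q`.
#' @export
read_assoc_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab$chr), id = tab$rs, pos_bp = tab$ps,
             af = tab$af, beta = tab$beta, se = tab$se, p_wald = tab$p_wald,
             q = tab$q, stringsAsFactors = FALSE)
}

#' Read gene annotation from GFF3 or BED
#'
#' Genes are returned as a `GRanges`; `rtracklayer` handles the
#' coordinate conventions (GFF3 1-based inclusive, BED 0-based
#' half-open), so downstream interval arithmetic is unambiguous. For GFF3,
#' only rows whose `type` matches `feature` are kept (BED files carry no
#' feature type and are used as-is). Lines that fail to parse are skipped
#' with a message giving the count.
#'
#' @param path a `.gff`/`.gff3` or `.bed` file.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return `GRanges` with a `name` metadata column.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("missing annotation file: ", path)
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  ok <- if (is_bed) nf >= 3L else nf == 9L
  if (any(!ok)) {
    message("read_gene_annotation: skipped ", sum(!ok), " malformed line(s)")
    body <- body[ok]
  }
  tmp <- tempfile(fileext = if (is_bed) ".bed" else ".gff3")
  on.exit(unlink(tmp))
  writeLines(c(if (!is_bed) "##gff-version 3", body), tmp)
  gr <- rtracklayer::import(tmp)
  if (!is_bed && length(gr) > 0) {
    gr <- gr[as.character(gr$type) == feature]
    nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = as.character(nm %||% seq_along(gr)))
  } else if (is_bed && length(gr) > 0) {
    nm <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm)
  }
  drop <- as.character(GenomicRanges::seqnames(gr)) %in% NON_AUTOSOMES
  if (any(drop)) {
    message("read_gene_annotation: excluding ", sum(drop),
            " non-autosomal record(s)")
    gr <- gr[!drop]
  }
  gr
}
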