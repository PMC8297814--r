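#' Synthetic multi-generation pedigree
#'
#' Random-mating pedigree generator with configurable sire reuse (heavy
#' reuse mimics artificial-insemination sires and depresses the realized
#' effective population size below the census) and optional generational
#' overlap (parents drawn from earlier generations). Output is
#' topologically sorted: parents always precede offspring.
#'
#' @param n_founders founder individuals (generation 0, unknown parents).
#' @param n_generations generations below the founders.
#' @param offspring_per_generation individuals born per generation
#'   (default `n_founders`).
#' @param overlap probability a parent is drawn from two generations back
#'   rather than the previous generation (default 0).
#' @param top_sire_frac,top_sire_mass fraction of sires classed as
#'   "popular" and the probability mass they receive (defaults 1 and 1 =
#'   uniform use; e.g. 0.01 and 0.5 makes the top 1% of sires father
#'   half the offspring).
#' @param seed RNG seed.
#' @return data.frame of class `pedigree`: `id`, `sire`, `dam`
#'   (`"0"` = unknown), `sex`, `generation`.
#' @export
synthetic_pedigree <- function(n_founders, n_generations,
                               offspring_per_generation = n_founders,
                               overlap = 0, top_sire_frac = 1,
                               top_sire_mass = 1, seed = 1L) {
  set.seed(seed)
  stopifnot(n_founders >= 4, n_generations >= 1, overlap >= 0, overlap < 1)
  ids <- sprintf("f%05d", seq_len(n_founders))
  ped <- data.frame(id = ids, sire = "0", dam = "0",
                    sex = rep(c("M", "F"), length.out = n_founders),
                    generation = 0L, stringsAsFactors = FALSE)
  for (g in seq_len(n_generations)) {
    pool_gen <- function(gg) ped[ped$generation == gg, , drop = FALSE]
    n_off <- offspring_per_generation
    prev <- pool_gen(g - 1L)
    older <- if (g >= 2L && overlap > 0) pool_gen(g - 2L) else prev
    draw_parent <- function(sexcode, weighted) {
      src <- if (overlap > 0 && stats::runif(1) < overlap) older else prev
      cand <- src$id[src$sex == sexcode]
      if (length(cand) == 0L) cand <- prev$id[prev$sex == sexcode]
      if (weighted && top_sire_frac < 1) {
        ntop <- max(1L, floor(top_sire_frac * length(cand)))
        w <- rep((1 - top_sire_mass) / max(length(cand) - ntop, 1),
                 length(cand))
        w[seq_len(ntop)] <- top_sire_mass / ntop
        sample(cand, 1L, prob = w)
      } else sample(cand, 1L)
    }
    sire <- vapply(seq_len(n_off), function(i) draw_parent("M", TRUE),
                   character(1))
    dam <- vapply(seq_len(n_off), function(i) draw_parent("F", FALSE),
                  character(1))
    ped <- rbind(ped, data.frame(
      id = sprintf("g%02d_%05d", g, seq_len(n_off)),
      sire = sire, dam = dam,
      sex = sample(rep(c("M", "F"), length.out = n_off)),
      generation = g, stringsAsFactors = FALSE))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree from 3-column text
#'
#' Whitespace-delimited `id sire dam` with `0` for unknown parents.
#' Generation numbers are derived as the longest path from a founder;
#' cycles and self-parenting raise errors.
#'
#' @param path pedigree file.
#' @return `pedigree` data.frame, topologically sorted.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sire", "dam"))
  tab[] <- lapply(tab, as.character)
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs in pedigree")
  if (any(tab$id == tab$sire | tab$id == tab$dam))
    stop("self-parenting in pedigree")
  gen <- stats::setNames(rep(NA_integer_, nrow(tab)), tab$id)
  depth <- function(id, seen = character()) {
    if (id == "0") return(-1L)
    if (id %in% seen) stop("pedigree contains a cycle involving ", id)
    if (!is.na(gen[id])) return(gen[id])
    row <- match(id, tab$id)
    if (is.na(row)) return(-1L)   # parent not in the table: treat as founder
    g <- 1L + max(depth(tab$sire[row], c(seen, id)),
                  depth(tab$dam[row], c(seen, id)))
    gen[id] <<- g
    g
  }
  for (id in tab$id) depth(id)
  ped <- data.frame(id = tab$id, sire = tab$sire, dam = tab$dam,
                    sex = NA_character_, generation = gen[tab$id],
                    stringsAsFactors = FALSE)
  ped <- ped[order(ped$generation), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write a pedigree as 3-column text
#' @param ped a `pedigree` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam")], path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

#' Founder haplotypes for a gene drop
#'
#' Independent-site haplotypes with a 1/x frequency spectrum on the same
#' map layout as the forward simulator (LD then accrues through pedigree
#' transmission).
#'
#' @param n_founders founder count (pairs of haplotypes).
#' @param n_chrom,sites_per_chrom,chrom_length_mb map layout.
#' @param seed RNG seed.
#' @return `founder_pool`-style list (`H`, m x 2n site-major haplotypes;
#'   `map`, `chrom_index`, `len_bp`).
#' @export
founder_haplotypes <- function(n_founders, n_chrom = 10L,
                               sites_per_chrom = 2000L,
                               chrom_length_mb = 100, seed = 1L) {
  set.seed(seed)
  m <- n_chrom * sites_per_chrom
  map <- sim_map(n_chrom, sites_per_chrom, chrom_length_mb)
  p0 <- 0.01 * 99^stats::runif(m)
  # site-major: m sites x 2*n_founders haplotype columns
  H <- matrix(stats::rbinom(m * 2L * n_founders, 1L, p0),
              nrow = m, ncol = 2L * n_founders)
  chrom_index <- split(seq_len(m), map$chrom)[as.character(seq_len(n_chrom))]
  list(H = H, map = map, p_init = p0, chrom_index = chrom_index,
       len_bp = rep(chrom_length_mb * 1e6, n_chrom))
}

#' Drop founder haplotypes through a pedigree
#'
#' Mendelian gene drop: founders receive haplotype pairs from the pool in
#' order; every transmission recombines with a Poisson crossover count at
#' `crossover_rate_per_mb` per Mb (the default null uses a literal
#' rate of 1 crossover per Mb; `biological_map = TRUE` switches to the
#' ~1 cM/Mb rate of 0.01) with uniform positions and random start phase.
#' Genotypes are emitted for `emit` individuals (default: the final
#' generation).
#'
#' @param ped a `pedigree` (topologically sorted).
#' @param pool founder haplotypes ([founder_haplotypes()] or
#'   [generate_founders()]); must cover the pedigree's founders.
#' @param crossover_rate_per_mb crossovers per Mb per transmission
#'   (default 1.0).
#' @param biological_map if `TRUE`, use 0.01 crossovers per Mb instead.
#' @param emit IDs to emit (default final-generation individuals).
#' @param seed RNG seed.
#' @return list: `geno` (a [genotypes] panel for `emit`), `samples`
#'   (data.frame `id`, `generation`, `birthdate_age`).
#' @export
gene_drop <- function(ped, pool, crossover_rate_per_mb = 1.0,
                      biological_map = FALSE, emit = NULL, seed = 1L) {
  set.seed(seed)
  rate <- if (biological_map) 0.01 else crossover_rate_per_mb
  # make_gamete scales Poisson rate by len_bp/1e8 * factor; convert a
  # per-Mb rate into that factor: rate/Mb * len_mb = len_bp/1e8 * f
  factor <- rate * 100
  founders <- ped$id[ped$sire == "0" & ped$dam == "0"]
  if (ncol(pool$H) < 2L * length(founders))
    stop("founder pool has ", ncol(pool$H) / 2, " individuals but the ",
         "pedigree has ", length(founders), " founders")
  m <- nrow(pool$H)
  H <- matrix(0L, m, 2L * nrow(ped))
  rowof <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    if (ped$sire[i] == "0" || ped$dam[i] == "0") {
      if (xor(ped$sire[i] == "0", ped$dam[i] == "0"))
        stop("individual ", ped$id[i], " has exactly one known parent; ",
             "non-founders need both")
      fi <- match(ped$id[i], founders)
      H[, 2L * i - 1L] <- pool$H[, 2L * fi - 1L]
      H[, 2L * i] <- pool$H[, 2L * fi]
    } else {
      si <- rowof[ped$sire[i]]; di <- rowof[ped$dam[i]]
      if (is.na(si) || is.na(di) || si >= i || di >= i)
        stop("parent of ", ped$id[i], " is missing or appears later ",
             "in the pedigree")
      H[, 2L * i - 1L] <- make_gamete(H, 2L * si - 1L, 2L * si,
                                      pool$map$pos_bp, pool$chrom_index,
                                      pool$len_bp, factor)
      H[, 2L * i] <- make_gamete(H, 2L * di - 1L, 2L * di,
                                 pool$map$pos_bp, pool$chrom_index,
                                 pool$len_bp, factor)
    }
  }
  emit <- emit %||% ped$id[ped$generation == max(ped$generation)]
  ei <- rowof[emit]
  if (anyNA(ei)) stop("unknown IDs in emit")
  dosage <- t(H[, 2L * ei - 1L, drop = FALSE] + H[, 2L * ei, drop = FALSE])
  geno <- genotypes(dosage, emit,
                    data.frame(chrom = pool$map$chrom,
                               pos_bp = pool$map$pos_bp, id = pool$map$id,
                               allele1 = "A", allele0 = "B",
                               stringsAsFactors = FALSE))
  list(geno = geno,
       samples = data.frame(id = emit,
                            generation = ped$generation[ei],
                            birthdate_age = as.numeric(ped$generation[ei]),
                            stringsAsFactors = FALSE))
}

#' Gene-drop null rate for the generation-proxy scan
#'
#' Repeatedly drops founder haplotypes through a pedigree, runs the
#' generation-proxy scan with generation number as the dependent
#' variable, and counts significant loci (q < `q_threshold`, clumped at
#' 1 Mb), normalized per 200,000 markers. This measures how much
#' apparent selection signal pedigree structure alone generates.
#'
#' @param ped a `pedigree`; individuals of generation >= 1 are scanned.
#' @param pool founder haplotypes.
#' @param n_replicates gene-drop replicates (default 10).
#' @param q_threshold locus significance cutoff (default 0.1).
#' @param crossover_rate_per_mb,biological_map see [gene_drop()].
#' @param seed base RNG seed; replicate r uses `seed + r - 1`.
#' @return data.frame: `replicate`, `seed`, `n_sig_snps`, `n_loci`,
#'   `loci_per_200k`, `pve`.
#' @export
genedrop_null_rate <- function(ped, pool, n_replicates = 10L,
                               q_threshold = 0.1,
                               crossover_rate_per_mb = 1.0,
                               biological_map = FALSE, seed = 1L) {
  if (n_replicates == 0L)
    return(data.frame(replicate = integer(), seed = integer(),
                      n_sig_snps = integer(), n_loci = integer(),
                      loci_per_200k = numeric(), pve = numeric()))
  emit <- ped$id[ped$generation >= 1L]
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- seed + r - 1L
    gd <- gene_drop(ped, pool, crossover_rate_per_mb = crossover_rate_per_mb,
                    biological_map = biological_map, emit = emit, seed = s)
    grm <- compute_grm(gd$geno)
    assoc <- assoc_scan(gd$geno, gd$samples$generation, grm)
    assoc$q <- storey_qvalues(assoc$p_wald)
    vc <- attr(assoc, "vc")
    loci <- clump_loci(assoc, q_threshold = q_threshold)
    out[[r]] <- data.frame(replicate = r, seed = s,
                           n_sig_snps = sum(assoc$q < q_threshold,
                                            na.rm = TRUE),
                           n_loci = nrow(loci),
                           loci_per_200k = nrow(loci) / nrow(assoc) * 2e5,
                           pve = vc$pve)
  }
  do.call(rbind, out)
}

#' Effective population size from family-size variance
#'
#' Crow-Denniston estimate Ne = (4 N k_bar - 2) / (k_bar (k_bar - 1) +
#' Vk) per parental sex pathway is overkill here; this uses the simple
#' variance-of-family-size form Ne = (N k_bar - 1) / (k_bar - 1 + Vk /
#' k_bar) applied to the combined parent pool, adequate for checking
#' that heavy sire reuse pushes realized Ne below the census.
#'
#' @param ped a `pedigree`.
#' @param generation which offspring generation to score (default 1).
#' @return list: `ne`, `census`, `k_bar`, `vk`.
#' @export
ne_from_family_sizes <- function(ped, generation = 1L) {
  off <- ped[ped$generation == generation, , drop = FALSE]
  parents <- ped$id[ped$generation == generation - 1L]
  k <- table(factor(c(off$sire, off$dam), levels = parents))
  k_bar <- mean(k)
  vk <- stats::var(as.numeric(k))
  ne <- (length(parents) * k_bar - 1) / (k_bar - 1 + vk / k_bar)
  list(ne = ne, census = length(parents), k_bar = k_bar, vk = vk)
}
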