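# Pedigree construction and Mendelian gene dropping.

test_that("synthetic pedigrees are topologically valid", {
  ped <- synthetic_pedigree(40, 4, seed = 1)
  rowof <- setNames(seq_len(nrow(ped)), ped$id)
  nf <- ped[ped$sire != "0", ]
  expect_true(all(rowof[nf$sire] < rowof[nf$id]))
  expect_true(all(rowof[nf$dam] < rowof[nf$id]))
  # overlap = 0: parents always in the previous generation
  gen <- setNames(ped$generation, ped$id)
  expect_true(all(gen[nf$sire] == nf$generation - 1L))
  expect_identical(synthetic_pedigree(40, 4, seed = 1), ped)
})

test_that("heavy sire reuse depresses realized Ne below census", {
  ped_u <- synthetic_pedigree(400, 1, seed = 2)
  ped_s <- synthetic_pedigree(400, 1, top_sire_frac = 0.01,
                              top_sire_mass = 0.5, seed = 2)
  ne_u <- ne_from_family_sizes(ped_u)$ne
  ne_s <- ne_from_family_sizes(ped_s)$ne
  expect_lt(ne_s, ne_u)
  expect_lt(ne_s, 400)
  # the skew really concentrates matings: top 1% of sires get ~half
  off <- ped_s[ped_s$generation == 1L, ]
  sire_counts <- sort(table(off$sire), decreasing = TRUE)
  ntop <- max(1, floor(0.01 * sum(ped_s$generation == 0L & ped_s$sex == "M")))
  expect_gt(sum(sire_counts[seq_len(ntop)]) / nrow(off), 0.3)
})

test_that("pedigree text round-trips and bad pedigrees are rejected", {
  ped <- synthetic_pedigree(20, 2, seed = 3)
  path <- withr::local_tempfile()
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_setequal(ped2$id, ped$id)
  expect_equal(ped2$generation[match(ped$id, ped2$id)], ped$generation)
  writeLines(c("a 0 0", "b b 0"), path)
  expect_error(read_pedigree(path), "self-parenting")
  writeLines(c("a b 0", "b a 0"), path)
  expect_error(read_pedigree(path), "cycle")
})

test_that("gene drops obey Mendelian conservation", {
  ped <- synthetic_pedigree(30, 3, seed = 4)
  pool <- founder_haplotypes(30, n_chrom = 2, sites_per_chrom = 150,
                             seed = 4)
  # all founders homozygous at site 1 -> every descendant homozygous
  pool$H[1, ] <- 1L
  gd <- gene_drop(ped, pool, seed = 5)
  expect_true(all(gd$geno$dosage[, 1] == 2L))
  # crossover rate 0: transmitted haplotypes are exact parental copies
  gd0 <- gene_drop(ped, pool, crossover_rate_per_mb = 0,
                   emit = ped$id[ped$generation == 1L][1:5], seed = 6)
  expect_true(all(gd0$geno$dosage %in% 0:2))
  expect_identical(gene_drop(ped, pool, seed = 7)$geno$dosage,
                   gene_drop(ped, pool, seed = 7)$geno$dosage)
})

test_that("zero-recombination transmissions copy whole parental haplotypes", {
  # one founder couple, two offspring: with rate 0 each child's genotype
  # must equal one sire haplotype plus one dam haplotype
  ped <- data.frame(id = c("s", "d", "o1", "o2"),
                    sire = c("0", "0", "s", "s"),
                    dam = c("0", "0", "d", "d"),
                    sex = c("M", "F", "M", "F"),
                    generation = c(0L, 0L, 1L, 1L))
  class(ped) <- c("pedigree", "data.frame")
  pool <- founder_haplotypes(2, n_chrom = 1, sites_per_chrom = 80, seed = 8)
  gd <- gene_drop(ped, pool, crossover_rate_per_mb = 0,
                  emit = c("o1", "o2"), seed = 9)
  combos <- list(pool$H[, 1] + pool$H[, 3], pool$H[, 1] + pool$H[, 4],
                 pool$H[, 2] + pool$H[, 3], pool$H[, 2] + pool$H[, 4])
  for (k in 1:2) {
    expect_true(any(vapply(combos, function(x)
      identical(as.integer(x), as.integer(gd$geno$dosage[k, ])),
      logical(1))))
  }
})

test_that("unlinked 0.5-frequency sites stay near Hardy-Weinberg", {
  ped <- synthetic_pedigree(300, 3, seed = 10)
  pool <- founder_haplotypes(300, n_chrom = 1, sites_per_chrom = 60,
                             seed = 10)
  set.seed(11)
  pool$H[] <- rbinom(length(pool$H), 1, 0.5)
  gd <- gene_drop(ped, pool, seed = 12)
  het <- mean(gd$geno$dosage == 1L)
  expect_lt(abs(het - 0.5), 0.05)
})

test_that("founder frequencies are conserved in expectation", {
  # the pedigree is redrawn per replicate: conditional on one fixed
  # pedigree the expected final frequency is the contribution-weighted
  # founder frequency, not the plain mean
  pool <- founder_haplotypes(120, n_chrom = 1, sites_per_chrom = 20,
                             seed = 13)
  set.seed(14)
  pool$H[] <- rbinom(length(pool$H), 1, runif(20, 0.3, 0.7))
  p0 <- rowMeans(pool$H)
  dps <- sapply(1:25, function(r) {
    ped <- synthetic_pedigree(120, 3, seed = 1000 + r)
    gd <- gene_drop(ped, pool, seed = r)
    colMeans(gd$geno$dosage) / 2 - p0
  })
  mdp <- rowMeans(dps)
  sedp <- apply(dps, 1, sd) / sqrt(ncol(dps))
  expect_gt(mean(abs(mdp) <= 2 * sedp + 1e-8), 0.85)
})

test_that("pedigree structure errors are caught", {
  ped <- synthetic_pedigree(10, 1, seed = 15)
  ped$dam[ped$id == ped$id[11]] <- "0"      # one known parent only
  pool <- founder_haplotypes(10, n_chrom = 1, sites_per_chrom = 30,
                             seed = 15)
  expect_error(gene_drop(ped, pool, seed = 16), "one known parent")
  expect_error(gene_drop(synthetic_pedigree(50, 1, seed = 17), pool),
               "founder pool")
})

test_that("pedigree structure alone yields only stray significant loci", {
  # shallow random-mating pedigree: the generation-proxy scan should
  # find at most the FDR-allowed background of q < 0.1 loci; discovery
  # counts under a global null do not scale with marker count, so the
  # bound is per replicate
  ped <- synthetic_pedigree(400L, 3L, top_sire_frac = 0.05,
                            top_sire_mass = 0.5, seed = 21)
  pool <- founder_haplotypes(400L, n_chrom = 2L, sites_per_chrom = 2000L,
                             seed = 21)
  gd <- suppressWarnings(genedrop_null_rate(ped, pool, n_replicates = 10L,
                                            seed = 22))
  expect_lte(mean(gd$n_loci), 1.5)
  expect_true(all(gd$pve < 0.9))   # generation is never fully genomic
})

test_that("replicate accounting in the null-rate report", {
  ped <- synthetic_pedigree(60, 3, seed = 18)
  pool <- founder_haplotypes(60, n_chrom = 2, sites_per_chrom = 150,
                             seed = 18)
  r0 <- genedrop_null_rate(ped, pool, n_replicates = 0)
  expect_equal(nrow(r0), 0L)
  r1 <- suppressWarnings(genedrop_null_rate(ped, pool, n_replicates = 1,
                                            seed = 3))
  r2 <- suppressWarnings(genedrop_null_rate(ped, pool, n_replicates = 1,
                                            seed = 3))
  expect_identical(r1, r2)
  expect_equal(r1$loci_per_200k, r1$n_loci / 300 * 2e5)
})
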