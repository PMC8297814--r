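# In-code fixtures shared across the suite.

# random genotype panel with independent sites
make_panel <- function(n, m, seed = 1L, maf_range = c(0.05, 0.5),
                       n_chrom = 1L) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  D <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  per <- m %/% n_chrom
  chrom <- rep(as.character(seq_len(n_chrom)), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(1e8, length(ix)))))
  genotypes(D, sprintf("ind%04d", seq_len(n)),
            data.frame(chrom = chrom, pos_bp = pos,
                       id = sprintf("snp%05d", seq_len(m)),
                       allele1 = "A", allele0 = "B",
                       stringsAsFactors = FALSE))
}

# phenotype with a given PVE on a panel's GRM
make_heritable_y <- function(grm, pve, seed = 1L) {
  set.seed(seed)
  n <- nrow(grm$matrix)
  L <- grm$vectors %*% diag(sqrt(pmax(grm$values, 0)))
  u <- drop(L %*% rnorm(n))
  u <- u / sd(u) * sqrt(pve)
  e <- rnorm(n)
  e <- e / sd(e) * sqrt(1 - pve)
  u + e
}

# tiny forward-sim scenario used by several property tests
desk_scenario <- function(seed = 1L, ...) {
  args <- list(n_chrom = 2L, sites_per_chrom = 500L, n_founders = 200L,
               ne_target = 50L, n_qtl = 10L, n_crosses = 200L,
               n_generations = 5L, n_sampled = 400L,
               n_males_selected = 20L, n_females_selected = 80L,
               founder_burnin_generations = 10L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_scenario, args)
}
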