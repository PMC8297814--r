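# gpsmr

Selection leaves more than sweeps. When a population is under sustained
directional selection on complex traits, many alleles shift in frequency
by small amounts — too small for sweep statistics, but large enough to
create a genome-wide association between genotype and *when an
individual was born*. gpsmr maps that signal. It is aimed at anyone
with a temporally or spatially stratified SNP panel: livestock breed
databases spanning decades, experimental-evolution time courses, museum
or biobank series, landscape-genomics collections.

The package implements two complementary scans plus the validation
machinery to trust them:

* **GPSM** (generation proxy selection mapping) — a linear mixed model
  with birth date (continuous age, or generation number) as the
  *dependent* variable:

  `y = X g + Z u + e`, with `u ~ N(0, G sigma_a^2)`, `e ~ N(0, I sigma_e^2)`

  where `G` is the standardized genomic relationship matrix
  (`W W'/m`, SNPs scaled by `sqrt(2p(1-p))`). The polygenic term soaks
  up drift, relatedness and structure, so significant SNPs (Storey
  q < 0.1) are those whose frequencies track time beyond what kinship
  explains — ongoing selection.
* **envGWAS** — the same model with 30-year climate normals
  (temperature, precipitation, elevation) or discrete ecoregion
  membership as `y`, mapping allele-environment associations that
  suggest local adaptation, with permutation-derived significance
  (p < 1e-5 tier).

Around the core: single- and multi-GRM REML variance partitioning
(PVE), multivariate scans, K-means ecoregion derivation from climate
grids, region-stratified GPSM with fixed-effects meta-analysis
(Cochran's Q, per-region m-values), allele-frequency trajectories and
per-generation dAF, candidate-gene annotation, a forward-in-time
breeding simulator, and a pedigree gene-drop null.

## Worked example

Simulate a population under truncation selection, sample a genotype
panel across ten generations, and scan it:

```r
library(gpsmr)

sc <- sim_scenario(n_chrom = 2, sites_per_chrom = 2000,
                   n_founders = 1000, n_qtl = 20, n_crosses = 1000,
                   n_generations = 10, n_sampled = 1000, seed = 3)
truth <- simulate_scenario(sc)
panel <- sample_individuals(truth)

res <- run_gpsm(panel$geno, panel$samples, n_perm = 2)
res
#> GPSM scan: 1903 SNPs, 21 significant (q < 0.1 ) in 9 loci
#>   birth-date PVE = 0.676 (SE 0.029)
head(res$permutation_summaries[, c("perm", "pve", "n_sig_q10")])
#>   perm          pve n_sig_q10
#> 1    1 4.539788e-05         0
#> 2    2 4.539788e-05         0
```

The scan tests the 1,903 sites still polymorphic after selection and
finds 21 SNPs in 9 loci whose frequencies track birth date; the
birth-date PVE of 0.68 says the panel's genotypes are strongly
time-structured (selection plus drift in a small population). Permuting
birth dates collapses the PVE to ~0 and zero significant SNPs — the
negative control behind every GPSM claim. Scoring against the simulated
truth (`evaluate_gpsm_performance(panel, truth)`) shows which hits are
real QTL and reports false positives; on matched random-mating
simulations the scan returns essentially none.

For real data the entry points are `read_plink()`,
`read_sample_table()` (birth dates to continuous age at a reference
date), `fit_ecoregions()` / `assign_ecoregion()` for climate grids, and
`env_scan_continuous()` / `env_scan_discrete()` for envGWAS;
`inst/cli/gpsmr.R` wraps the two pipelines for shell use:

```sh
Rscript inst/cli/gpsmr.R gpsm --bfile data/herd --samples samples.tsv \
    --ref-date 2017-04-05 --q 0.1 --perm 10 --out out/
```

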