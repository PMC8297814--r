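---
title: "Mapping polygenic selection and environmental adaptation with gpsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygenic selection and environmental adaptation with gpsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Directional selection on complex traits moves many alleles by small
amounts. Those shifts are invisible to sweep-based selection scans, but
they leave a statistical trace: in a population sampled across multiple
generations, the frequency of a selected allele differs between early-
and late-born cohorts, creating an association between genotype and
birth date. gpsmr maps that trace. The same machinery, pointed at the
environment instead of the calendar, maps alleles whose frequencies
track climate gradients or discrete ecoregions — a signature of local
adaptation. Both ideas come out of large livestock genotype databases
(hundreds of thousands of cattle genotyped for breed improvement,
spanning ~10 generations and the whole continental US), but nothing in
the implementation is cattle-specific: any temporally or spatially
stratified diploid SNP panel fits.

# The model

Every scan in the package is the same univariate linear mixed model:

$$
\mathbf{y} = \mathbf{X}\mathbf{g} + \mathbf{Z}\mathbf{u} + \mathbf{e},
\qquad
\mathbf{u} \sim N(0, \mathbf{G}\sigma_a^2), \quad
\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2)
$$

with the *dependent variable reversed* relative to an ordinary GWAS:

* **GPSM** (generation proxy selection mapping): `y` is the
  individual's birth date, expressed as continuous age at a fixed
  reference date, or the true generation number in simulations.
* **envGWAS**: `y` is a 30-year climate normal (temperature,
  precipitation, elevation) attached to the individual's location, or a
  0/1 ecoregion-membership indicator. Binary indicators are analyzed
  with the same *linear* mixed model, not a logistic one.

`G` is the standardized genomic relationship matrix
(`compute_grm()`): each SNP column is centered at $2p$ and scaled by
$\sqrt{2p(1-p)}$, and $\mathbf{G} = \mathbf{W}\mathbf{W}'/m$. The
polygenic term absorbs family structure, relatedness and inbreeding, so
a SNP is only significant when its frequency change along `y` exceeds
what genome-wide kinship already explains. This is what separates
selection from drift: drift moves alleles in *related* individuals
together, and that co-movement is exactly what `G` captures.

Variance components are estimated by REML, profiled over
$\lambda = \sigma_a^2/\sigma_e^2$ on the eigen-rotated model
(`reml_single()`): a 101-point sweep of $\log\lambda \in [-10, 10]$
followed by Brent refinement, so the optimum is effectively global. PVE
is $\sigma_a^2/(\sigma_a^2+\sigma_e^2)$, with a delta-method standard
error from the observed information. For environmental phenotypes the
PVE is not a heritability — environments are not inherited — but a
measure of how strongly genome-wide genotype tracks the environmental
gradient.

## The per-SNP test

`assoc_scan()` estimates $\lambda$ once at the null model and holds it
fixed for every SNP (the EMMAX/GEMMA-Wald compromise). Conditional on
$\lambda$ each SNP gets an exact GLS effect and standard error in the
rotated coordinates, and a Wald t-test on $n - c - 1$ degrees of
freedom. Not re-optimizing $\lambda$ per SNP is an approximation; it is
what makes scans over hundreds of thousands of SNPs tractable, and for
the panel sizes here the difference from exact per-SNP REML is
negligible except at the very strongest associations, where it is
conservative.

The multivariate scan (`mv_scan()`, d traits jointly, $d \le 5$)
estimates per-trait genetic and residual covariance matrices at the
null by an EM-type REML on the rotated data. Each EM iteration
simultaneously diagonalizes $(\mathbf{V}_g, \mathbf{V}_e)$, which turns
the E-step into elementwise work on $n \times d$ arrays; the same
transform decouples the per-SNP 2x2 GLS systems per channel, so the
whole scan is a handful of matrix products. The joint d-df Wald
statistic is referred to an F distribution rather than the asymptotic
chi-square, which keeps the type-I error honest at moderate n (the two
agree at large n). With $d = 1$ the multivariate model is the
univariate model, and the implementation delegates accordingly.

Multi-GRM variance partitioning (`multi_component_reml()`, 2-4
components) uses average-information REML with EM fallback steps and
non-negativity projection; standard errors come from the inverse AI
matrix. Its canonical use is the three-way partition of birth-date
variance among genome-wide significant SNPs, suggestive SNPs, and
randomly drifting SNPs.

## Multiple testing and loci

P-values become Storey q-values (`storey_qvalues()`), with $\pi_0$
estimated by the natural-cubic-spline smoother over
$\lambda = 0.05, \dots, 0.95$; the conventional significance threshold
is q < 0.1. Below 100 p-values the spline is unstable and the function
falls back to $\pi_0 = 1$ (plain Benjamini-Hochberg) with a warning.
Significant SNPs are grouped into loci by single-linkage clumping at a
1 Mb gap (`clump_loci()`); the lead SNP is the smallest p, ties broken
by position so output is deterministic. Candidate genes are any
annotated gene within 10 kb of a significant SNP
(`annotate_candidates()`), with distance measured to the nearest gene
edge and 0 inside a gene.

## Allele-frequency trajectories

For visualization and effect-size conversion, genotypes are recoded as
within-individual frequencies (0, 0.5, 1) and regressed on birth date
(`allele_frequency_trajectory()`). The linear slope per year times a
generation interval gives $\Delta$AF per generation
(`delta_af_per_generation()`); the default interval is 5 years,
consistent with roughly ten generations in fifty years for cattle, and
is configurable because it is population-specific. The smoothed curve
is a tricube local *linear* regression (`loess`, degree 1, span 0.75 by
default) clipped to [0, 1] and evaluated only on the observed date
range; the span is exposed rather than hard-coded because no single
value suits every sampling density.

# Ecoregions

`fit_ecoregions()` clusters a climate grid (temperature, precipitation,
elevation per cell) into K discrete ecoregions by K-means with
k-means++ initialization and 25 restarts under a fixed seed. Variables
are standardized first — they differ by orders of magnitude in their
native units — and K is fixed at 9 by default: the downstream
region-specific analyses need stable region identities, so "optimal K"
diagnostics (an elbow curve) are reported but never change K. Region
labels are ordered by centroid temperature so refits are comparable.

Animals reach regions through their location: coordinates (or a zip
resolved through a user-supplied zip table, where one zip may map to
several grid cells) are rounded to the nearest 0.1 degree — half away
from zero, so 39.95 rounds to 40.0 — and looked up in the grid. A zip
whose cells fall in more than one region is flagged: its animals are
excluded from discrete-region analyses but keep cell-averaged
continuous values. Every sample ends in exactly one of three states:
assigned, excluded (multi-region zip), or off-grid.

In the discrete multivariate scan one region must be dropped to avoid
linearly dependent indicators; the package drops the largest region as
the reference (and says so in a message), since the choice is not
identifiable from the model itself.

## Permutation controls

Two permutation schemes guard the envGWAS results
(`permute_environment()`): shuffling whole environment rows across
animals (breaking the genotype-environment link) and shuffling the
zip-to-environment mapping so all animals of a zip move together
(testing whether over-sampled zips alone can generate signal). The
significance threshold for envGWAS is empirical: the largest power of
ten below every permuted minimum p, capped at the 1e-5 tier
(`empirical_threshold()`). GPSM has its own negative control
(`permutation_null()`): permuting birth dates must collapse the PVE to
~0 and leave no SNPs at q < 0.1.

# Region-stratified GPSM and meta-analysis

`within_region_scans()` reruns GPSM inside every ecoregion with at
least 600 genotyped animals (a 1,000 profile is a config switch; both
thresholds are in common use for this design). Each region gets its own
GRM rather than a slice of the global one, keeping the per-region SNP
standardization self-consistent; the global-GRM variant would mix
region allele frequencies into the standardization.

Per-region effects are combined by fixed-effects inverse-variance
meta-analysis (`meta_fixed_effects()`): Cochran's Q with k-1 degrees of
freedom flags SNPs whose selection differs among regions. Posterior
evidence per region comes from the binary-effects m-value
(`compute_mvalues()`): all $2^k$ effect/no-effect configurations are
enumerated; effect regions share one true effect with a N(0, 0.04)
prior (integrated in closed form), each region has a Bernoulli(0.5)
prior of having an effect, and the m-value is the posterior mass where
a region has one. The prior variance and probability are exposed
because binary-effects meta-analysis tools rarely document them;
0.04 corresponds to typical effect magnitudes on standardized
phenotypes, and results are insensitive to the prior for |beta/se| > 4.
Region-specific loci are SNPs passing the conjunction filter — Q
p < 1e-5 *and* at least one within-region p < 1e-5 — clumped at 1 Mb
(`region_specific_loci()`).

Whether a region's allele frequency is *diverging* from or *converging*
to the population mean is decided by
`classify_region_trajectory()`: both trajectories are smoothed, the
region's observed time range is cut into terciles, and the mean
absolute region-pooled gap over the last tercile is compared with the
first. A shrinking gap is "convergent" (decay of local adaptation under
germplasm exchange), a growing one "divergent" (ongoing local
selection). The tercile windows are one concrete operationalization of
"moves toward/away"; the window fractions are configurable, exact ties
resolve to convergent and are logged, and regions observed for under 3
years are left unclassified.

# Truth-known validation

## Forward breeding simulation

`sim_scenario()` + `simulate_scenario()` reproduce the validation
design: 10 chromosomes x 20,000 segregating sites for 2,000 founders at
full scale, 200/500/1,000 additive QTL with N(0,1) or gamma(0.42,
random sign) effects, five generations of burn-in truncation selection,
then 5/10/20 generations of either truncation selection on true
breeding value or random mating, with 50 sires and 500 dams kept per
generation and 1,000-8,000 crosses. Genotype panels are sampled evenly
over generations or with negative-exponential recency weighting
calibrated so ~60% of samples fall in the last three generations,
emulating the age structure of real genotype databases (the exact decay
rate was never printed for the real data, so it is solved from that 60%
anchor and exposed).

Founders are initialized from a 1/x site-frequency spectrum on
(0.01, 0.99) followed by 50 generations of random mating at the target
effective size, which builds the LD and relatedness structure the GRM
needs; a coalescent simulator would be more faithful to deep history,
and an importer accepts external haplotypes for such runs, but the
forward burn-in keeps the package dependency-free and reproduces the
drift variance Wright-Fisher theory predicts (checked in the tests
against $p(1-p)(1-(1-\tfrac{1}{2N_e})^t)$). Chromosomes are 100 Mb with
uniformly placed sites and Poisson(1) crossovers per meiosis (1 cM/Mb);
map length is a choice, not a datum. Gamma effects get random signs —
an unsigned gamma would force all QTL in one direction, which is not
what "a gamma distribution of effect sizes" means for a trait under
directional selection. Meiosis is a small C++ kernel; everything else
is plain R.

`evaluate_gpsm_performance()` scores a scan against the truth: true
positives are simulated QTL at q < 0.1; QTL fixed by burn-in or
selection are excluded from the detectable denominator (their detection
is impossible — there is no frequency left to change); in selection
arms, significant non-QTL sites within 1 Mb of a QTL are not counted as
false positives, because LD shadows of true signals are not errors of
the method; 1 Mb matches the locus-clumping scale. In
random-mating arms *every* significant site is a false positive.

## Pedigree gene drop

`gene_drop()` drops founder haplotypes through a (real or synthetic)
pedigree in Mendelian fashion. The default null uses a literal rate of
one crossover per Mb per transmission — about 100x
the biological map; a `biological_map` flag gives 1 cM/Mb — and
`genedrop_null_rate()` reports significant GPSM loci per replicate and
per 200,000 markers, measuring how much apparent selection signal
pedigree structure alone generates. When comparing across panel sizes
the per-replicate count is the right statistic: under a clean global
null, FDR procedures make at least one discovery with probability
alpha regardless of how many markers were tested, so a per-marker
normalization makes small panels look spuriously noisy. `synthetic_pedigree()` makes
random-mating pedigrees with configurable sire reuse (heavy reuse
mimics artificial-insemination sires and lowers realized Ne below the
census, which `ne_from_family_sizes()` quantifies).

# Problem sizes used in the tests

The package's own validation runs at desk scale, chosen once as the
smallest sizes at which the scientific contrasts are unambiguous:

* drift-arm false-positive control: 2 chromosomes x 2,000 sites, 1,000
  founders, 1,000 sampled, 5 replicate seeds x 4 random-mating
  scenarios;
* selection-arm power: 10 x 2,000 sites with 2,000 sampled for QTL
  recovery (20 QTL, so per-QTL selection is strong enough to detect at
  n = 2,000), and 2 x 2,000 sites over 20 generations for the ten
  matched even-vs-uneven sampling pairs — the generation count matters
  because recency-weighted sampling loses power exactly by starving the
  old cohorts, so the contrast grows with the sampled time depth;
* null calibration: one 2,000 x 20,000 panel with ten birth-date
  permutations and environment permutations under both schemes;
* REML recovery: n = 1,000, 5,000 SNPs, 20 replicates (single GRM at
  true PVE 0.5; two GRMs at 0.3/0.2).

Statements about real-data-scale behavior (e.g. hundreds of significant
SNPs in ~15,000-animal panels) are outside what these tests can show;
what they do show is that the estimators are unbiased at their scale,
that the null is clean, and that the selection/drift contrast is sharp.

## What the generators do not emulate

The synthetic data are idealized in ways real data are not: no
genotyping error or imputation uncertainty, random mating within the
selected parent pool (no assortative mating, no herd structure beyond
the pedigree), discrete non-overlapping generations in the forward
simulator, environments constant over a zip, and climate blobs far
cleaner than PRISM normals. Passing tests therefore demonstrate
correctness of the machinery and calibration under the stated models,
not robustness to every artifact of commercial genotype databases.

# Numerical choices

* GRM eigendecomposition is cached on the object; reconstruction error
  is checked below 1e-8 in the tests.
* Missing dosages are mean-imputed per SNP at GRM/scan time only; I/O
  is lossless. SNPs with > 10% missingness or MAF <= 0.01 are dropped
  from scans (thresholds configurable).
* Monomorphic and zero-variance dosage columns are excluded from the
  GRM denominator (`m_used`).
* A GRM proportional to the identity leaves $\lambda$ unidentifiable;
  `reml_single()` warns rather than fails, since permutation analyses
  legitimately hit near-identity structure.
* AI-REML: relative tolerance 1e-6 on parameters (1e-8 on likelihood),
  maximum 200 iterations, EM fallback when an AI step leaves the
  parameter space, hard error citing the gradient norm on
  non-convergence, and a singular-AI error when two GRMs are
  (near-)identical.
* Multivariate EM: at most 5,000 iterations, relative tolerance 1e-8,
  $\mathbf{V}_e$ floored at 1e-8 on its eigenvalues.
* Lead-SNP and nearest-centroid ties break deterministically (position;
  lowest region index).

# Known limitations

* The Wald test with null-model $\lambda$ is slightly conservative for
  very strong associations; exact per-SNP REML variants are out of
  scope.
* The m-value enumeration is exponential in the number of regions and
  is capped at 12.
* The PVE standard error uses the delta method on the observed
  information; reference implementations do not document their SE
  estimator, so small discrepancies are possible.
* Case-control (region membership) scans use a linear model on 0/1
  indicators; effect sizes are on the frequency-difference scale, not
  odds ratios.
* `read_plink()` targets the PLINK 1 SNP-major bed dialect only; VCF,
  BGEN and imputation dosage formats are out of scope.
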