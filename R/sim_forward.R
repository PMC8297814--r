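#' Forward simulation scenario
#'
#' Configuration of the truth-known breeding simulation used to validate
#' that the generation-proxy scan separates selection from drift:
#' founders with standing variation, additive QTL architectures, burn-in
#' selection, then either truncation selection on true breeding value or
#' random mating, with even or recency-weighted genotype sampling.
#'
#' @param n_chrom chromosomes (default 10).
#' @param sites_per_chrom segregating sites per chromosome
#'   (default 20,000).
#' @param n_founders founder individuals, half male half female
#'   (default 2,000).
#' @param ne_target effective size maintained during the founder burn-in
#'   (default 100; 50 and 250 probe stronger/weaker drift).
#' @param n_qtl additive QTL count (default 500).
#' @param qtl_dist `"normal"` (N(0,1)) or `"gamma"` (shape 0.42, random
#'   sign).
#' @param n_crosses matings (= offspring) per generation (default 2,000).
#' @param n_generations post-burn-in generations (default 10).
#' @param burn_in generations of burn-in selection (default 5).
#' @param selection `"tbv_truncation"` or `"random"`.
#' @param sampling `"even"` or `"uneven"` genotype sampling over
#'   generations.
#' @param n_sampled genotyped individuals in the panel (default 10,000).
#' @param n_males_selected,n_females_selected parents kept per generation
#'   (defaults 50 and 500).
#' @param chrom_length_mb physical length per chromosome (default
#'   100 Mb, i.e. ~1 Morgan at 1 cM/Mb).
#' @param recomb_factor multiplies the Poisson crossover rate of 1 per
#'   100 Mb (0 disables recombination).
#' @param uneven_rate decay rate of the negative-exponential sampling
#'   weights; `NULL` solves for the rate that puts ~60% of samples in
#'   the most recent 3 generations.
#' @param founder_burnin_generations random-mating generations that turn
#'   the independent-site founder draw into an LD-bearing population
#'   (default 50).
#' @param seed RNG seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_chrom = 10L, sites_per_chrom = 20000L,
                         n_founders = 2000L, ne_target = 100L,
                         n_qtl = 500L, qtl_dist = c("normal", "gamma"),
                         n_crosses = 2000L, n_generations = 10L,
                         burn_in = 5L,
                         selection = c("tbv_truncation", "random"),
                         sampling = c("even", "uneven"),
                         n_sampled = 10000L, n_males_selected = 50L,
                         n_females_selected = 500L,
                         chrom_length_mb = 100, recomb_factor = 1,
                         uneven_rate = NULL,
                         founder_burnin_generations = 50L, seed = 1L) {
  qtl_dist <- match.arg(qtl_dist)
  selection <- match.arg(selection)
  sampling <- match.arg(sampling)
  stopifnot(n_chrom >= 1, sites_per_chrom >= 1, n_founders >= 4,
            ne_target >= 4, n_qtl >= 0, n_crosses >= 2, n_generations >= 1,
            burn_in >= 0, n_sampled >= 1, n_males_selected >= 1,
            n_females_selected >= 1, recomb_factor >= 0)
  structure(list(n_chrom = n_chrom, sites_per_chrom = sites_per_chrom,
                 n_founders = n_founders, ne_target = ne_target,
                 n_qtl = n_qtl, qtl_dist = qtl_dist, n_crosses = n_crosses,
                 n_generations = n_generations, burn_in = burn_in,
                 selection = selection, sampling = sampling,
                 n_sampled = n_sampled, n_males_selected = n_males_selected,
                 n_females_selected = n_females_selected,
                 chrom_length_mb = chrom_length_mb,
                 recomb_factor = recomb_factor, uneven_rate = uneven_rate,
                 founder_burnin_generations = founder_burnin_generations,
                 seed = seed),
            class = "sim_scenario")
}

# genome map shared by the simulator and the gene drop
sim_map <- function(n_chrom, sites_per_chrom, chrom_length_mb) {
  m <- n_chrom * sites_per_chrom
  pos <- unlist(lapply(seq_len(n_chrom), function(ch)
    sort(sample.int(chrom_length_mb * 1e6 - 1L, sites_per_chrom)) ))
  data.frame(chrom = rep(as.character(seq_len(n_chrom)),
                         each = sites_per_chrom),
             pos_bp = pos,
             id = sprintf("snp_%d_%d",
                          rep(seq_len(n_chrom), each = sites_per_chrom),
                          unlist(lapply(seq_len(n_chrom),
                                        function(i) seq_len(sites_per_chrom)))),
             stringsAsFactors = FALSE)
}

# Batch meiosis: haplotypes are stored site-major (m sites x n
# haplotypes), one gamete per row of `parents` (two H column indices);
# output has one gamete per column. Crossover count per chromosome ~
# Poisson(length_mb / 100 * factor), uniform positions, random start
# phase; with factor 0 each gamete is an unmodified parental haplotype.
# The site walk lives in C++ (gametes_cpp); chromosome index ranges are
# contiguous by construction.
make_gametes <- function(H, parents, map_pos, chrom_index, len_bp, factor) {
  cs <- vapply(chrom_index, min, 0L)
  ce <- vapply(chrom_index, max, 0L)
  gametes_cpp(H, as.matrix(parents), as.numeric(map_pos),
              as.integer(cs), as.integer(ce), as.numeric(len_bp),
              as.numeric(factor))
}

make_gamete <- function(H, col1, col2, map_pos, chrom_index, len_bp, factor) {
  drop(make_gametes(H, cbind(col1, col2), map_pos, chrom_index, len_bp,
                    factor))
}

#' Founder haplotype pool with standing variation and LD
#'
#' Initializes site frequencies from a 1/x-shaped spectrum on
#' (0.01, 0.99) (the neutral standing-variation shape), draws independent
#' haplotypes, then runs `founder_burnin_generations` of random mating at
#' `ne_target` with recombination so linkage disequilibrium accumulates;
#' there is no new mutation. The final pool holds `n_founders`
#' individuals (half male, half female) bred from the burned-in
#' population.
#'
#' @param scenario a [sim_scenario()].
#' @return list of class `founder_pool`: `H` (m x 2n 0/1 haplotypes,
#'   sites in rows),
#'   `map`, `sex`, `p_init` (pre-burn-in frequencies), `chrom_index`,
#'   `len_bp`.
#' @export
generate_founders <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  m <- sc$n_chrom * sc$sites_per_chrom
  map <- sim_map(sc$n_chrom, sc$sites_per_chrom, sc$chrom_length_mb)
  chrom_index <- split(seq_len(m), map$chrom)[as.character(seq_len(sc$n_chrom))]
  len_bp <- rep(sc$chrom_length_mb * 1e6, sc$n_chrom)

  # 1/x frequency spectrum on (0.01, 0.99): p = 0.01 * 99^u
  p0 <- 0.01 * 99^stats::runif(m)
  ne <- sc$ne_target
  # site-major haplotypes: m sites x 2*ne haplotype columns (p0 recycles
  # down each column)
  H <- matrix(stats::rbinom(m * 2L * ne, 1L, p0), nrow = m, ncol = 2L * ne)
  sex <- rep(c("M", "F"), length.out = ne)
  for (g in seq_len(sc$founder_burnin_generations)) {
    males <- which(sex == "M"); females <- which(sex == "F")
    sires <- sample(males, ne, replace = TRUE)
    dams <- sample(females, ne, replace = TRUE)
    par_cols <- cbind(c(rbind(2L * sires - 1L, 2L * dams - 1L)),
                      c(rbind(2L * sires, 2L * dams)))
    H <- make_gametes(H, par_cols, map$pos_bp, chrom_index, len_bp,
                      sc$recomb_factor)
    sex <- rep(c("M", "F"), length.out = ne)
  }
  # expand to the founder census by random matings from the pool
  nf <- sc$n_founders
  males <- which(sex == "M"); females <- which(sex == "F")
  sires <- sample(males, nf, replace = TRUE)
  dams <- sample(females, nf, replace = TRUE)
  par_cols <- cbind(c(rbind(2L * sires - 1L, 2L * dams - 1L)),
                    c(rbind(2L * sires, 2L * dams)))
  Hf <- make_gametes(H, par_cols, map$pos_bp, chrom_index, len_bp,
                     sc$recomb_factor)
  seg <- rowMeans(Hf)
  if (mean(seg == 0 | seg == 1) > 0.5)
    warning("more than half of the sites are monomorphic after burn-in")
  structure(list(H = Hf, map = map,
                 sex = rep(c("M", "F"), length.out = nf),
                 p_init = p0, chrom_index = chrom_index, len_bp = len_bp,
                 scenario = sc),
            class = "founder_pool")
}

#' Assign an additive QTL architecture
#'
#' Samples `n_qtl` QTL uniformly from the sites segregating in the
#' founder pool and draws their additive effects from the scenario
#' distribution: standard normal, or gamma(shape 0.42) magnitudes with a
#' random sign. All other sites are neutral.
#'
#' @param pool a [generate_founders()] pool.
#' @param scenario a [sim_scenario()] (defaults to the pool's).
#' @return list of class `sim_truth` skeleton: `qtl_idx`, `qtl_effect`
#'   (length-m vector, zero off-QTL), `map`.
#' @export
assign_qtl_architecture <- function(pool, scenario = pool$scenario) {
  sc <- scenario
  set.seed(sc$seed + 1L)
  p <- rowMeans(pool$H)
  seg <- which(p > 0 & p < 1)
  if (sc$n_qtl > length(seg))
    stop("n_qtl = ", sc$n_qtl, " exceeds ", length(seg), " segregating sites")
  qtl_idx <- sort(sample(seg, sc$n_qtl))
  eff <- numeric(length(p))
  if (sc$n_qtl > 0L) {
    eff[qtl_idx] <- if (sc$qtl_dist == "normal") {
      stats::rnorm(sc$n_qtl)
    } else {
      stats::rgamma(sc$n_qtl, shape = 0.42) *
        sample(c(-1, 1), sc$n_qtl, replace = TRUE)
    }
  }
  list(qtl_idx = qtl_idx, qtl_effect = eff, map = pool$map)
}

tbv_of <- function(H_odd, H_even, eff) {
  drop(crossprod(H_odd + H_even, eff))
}

#' Run a forward breeding simulation
#'
#' After `burn_in` generations of truncation selection on true breeding
#' value (establishing the standing LD and fixing some large-effect QTL),
#' each post-burn-in generation selects the top `n_males_selected` males
#' and `n_females_selected` females by TBV (or uniformly at random under
#' the drift arm), mates uniformly sampled (sire, dam) pairs with
#' replacement for `n_crosses` single-offspring matings, and records per
#' generation the QTL allele frequencies, every individual's dosage
#' genotypes, TBV, sex and generation number.
#'
#' @param scenario a [sim_scenario()].
#' @param pool optional pre-built [generate_founders()] pool (reused to
#'   pair selection and drift arms on identical founders).
#' @param truth optional pre-built [assign_qtl_architecture()] skeleton.
#' @return list of class `sim_truth`: `scenario`, `map`, `qtl_idx`,
#'   `qtl_effect`, `qtl_freq` (generations x QTL), `generations` (list of
#'   per-generation dosage matrices, post-burn-in), `tbv`, `sex`,
#'   `parents_realized` (per-generation counts of distinct parents).
#' @export
simulate_scenario <- function(scenario, pool = NULL, truth = NULL) {
  sc <- scenario
  if (is.null(pool)) pool <- generate_founders(sc)
  if (is.null(truth)) truth <- assign_qtl_architecture(pool, sc)
  set.seed(sc$seed + 2L)
  eff <- truth$qtl_effect
  qtl <- truth$qtl_idx
  map <- pool$map
  H <- pool$H
  sex <- pool$sex
  n_prev <- ncol(H) / 2L

  pick_parents <- function(tbv, sex, random) {
    males <- which(sex == "M"); females <- which(sex == "F")
    nm <- sc$n_males_selected
    nf <- sc$n_females_selected
    if (length(males) < nm || length(females) < nf)
      stop("candidate pool (", length(males), " M / ", length(females),
           " F) smaller than the selection quota (", nm, " M / ", nf, " F)")
    if (random) {
      list(sires = sample(males, nm), dams = sample(females, nf))
    } else {
      list(sires = males[order(tbv[males], decreasing = TRUE)][seq_len(nm)],
           dams = females[order(tbv[females], decreasing = TRUE)][seq_len(nf)])
    }
  }
  breed <- function(H, sex, tbv, n_off, random) {
    sel <- pick_parents(tbv, sex, random)
    sires <- sample(sel$sires, n_off, replace = TRUE)
    dams <- sample(sel$dams, n_off, replace = TRUE)
    gam_s <- make_gametes(H, cbind(2L * sires - 1L, 2L * sires),
                          map$pos_bp, pool$chrom_index, pool$len_bp,
                          sc$recomb_factor)
    gam_d <- make_gametes(H, cbind(2L * dams - 1L, 2L * dams),
                          map$pos_bp, pool$chrom_index, pool$len_bp,
                          sc$recomb_factor)
    Hn <- matrix(0L, nrow(H), 2L * n_off)
    Hn[, seq(1L, 2L * n_off, by = 2L)] <- gam_s
    Hn[, seq(2L, 2L * n_off, by = 2L)] <- gam_d
    list(H = Hn, sex = sample(rep(c("M", "F"), length.out = n_off)),
         n_parents = c(length(unique(sires)), length(unique(dams))))
  }

  odd <- function(H) H[, seq(1L, ncol(H), by = 2L), drop = FALSE]
  even <- function(H) H[, seq(2L, ncol(H), by = 2L), drop = FALSE]
  tbv <- tbv_of(odd(H), even(H), eff)

  # burn-in: truncation selection on TBV regardless of arm
  for (g in seq_len(sc$burn_in)) {
    res <- breed(H, sex, tbv, sc$n_crosses, random = FALSE)
    H <- res$H; sex <- res$sex
    tbv <- tbv_of(odd(H), even(H), eff)
  }

  G <- sc$n_generations
  gens <- vector("list", G)
  tbv_list <- vector("list", G)
  sex_list <- vector("list", G)
  qtl_freq <- matrix(NA_real_, G + 1L, length(qtl))
  qtl_freq[1L, ] <- rowMeans(H[qtl, , drop = FALSE])
  parents_realized <- matrix(NA_integer_, G, 2L)
  random_arm <- sc$selection == "random"
  for (g in seq_len(G)) {
    res <- breed(H, sex, tbv, sc$n_crosses, random = random_arm)
    H <- res$H; sex <- res$sex
    tbv <- tbv_of(odd(H), even(H), eff)
    gens[[g]] <- odd(H) + even(H)          # dosage, m x n_crosses
    tbv_list[[g]] <- tbv
    sex_list[[g]] <- sex
    qtl_freq[g + 1L, ] <- rowMeans(H[qtl, , drop = FALSE])
    parents_realized[g, ] <- res$n_parents
  }
  structure(list(scenario = sc, map = map, qtl_idx = qtl,
                 qtl_effect = eff, qtl_freq = qtl_freq,
                 generations = gens, tbv = tbv_list, sex = sex_list,
                 parents_realized = parents_realized),
            class = "sim_truth")
}

# solve the uneven-sampling decay rate so the most recent 3 generations
# hold ~60% of the panel
solve_uneven_rate <- function(G, target = 0.6) {
  if (G <= 3L) return(1)
  f <- function(r) {
    w <- exp(-r * (G - seq_len(G)))
    sum(w[(G - 2L):G]) / sum(w) - target
  }
  # few generations: even sampling already concentrates >= target in the
  # last three, so the decay rate degenerates to ~0
  if (f(1e-6) >= 0) return(1e-6)
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Sample a genotype panel from a simulation
#'
#' Draws `n_sampled` individuals across the post-burn-in generations:
#' evenly, or with negative-exponential recency weighting (`uneven`,
#' emulating the age structure of real genotype databases, with ~60% of
#' samples in the most recent 3 generations). Individuals are sampled
#' uniformly within a generation and sampling never feeds back into who
#' becomes a parent.
#'
#' @param truth a [simulate_scenario()] result.
#' @param sampling `"even"` or `"uneven"` (default: the scenario's).
#' @param n_sampled panel size (default: the scenario's).
#' @param seed RNG seed (default: scenario seed + 3).
#' @return list: `geno` (a [genotypes] panel), `samples` (data.frame
#'   `id`, `generation`, `birthdate_age`), `index` (generation, row).
#' @export
sample_individuals <- function(truth, sampling = NULL, n_sampled = NULL,
                               seed = NULL) {
  sc <- truth$scenario
  sampling <- sampling %||% sc$sampling
  n_sampled <- n_sampled %||% sc$n_sampled
  set.seed(seed %||% (sc$seed + 3L))
  G <- length(truth$generations)
  avail <- vapply(truth$generations, ncol, 0L)
  if (sampling == "even") {
    counts <- rep(n_sampled %/% G, G)
    extra <- n_sampled - sum(counts)
    if (extra > 0L) counts[seq(G, G - extra + 1L)] <- counts[seq(G, G - extra + 1L)] + 1L
  } else {
    r <- sc$uneven_rate %||% solve_uneven_rate(G)
    w <- exp(-r * (G - seq_len(G)))
    counts <- round(n_sampled * w / sum(w))
    counts[G] <- counts[G] + (n_sampled - sum(counts))
  }
  over <- counts > avail
  if (any(over)) {
    warning("generation(s) ", paste(which(over), collapse = ", "),
            " exhausted; sampling all individuals there")
    counts <- pmin(counts, avail)
  }
  rows <- lapply(seq_len(G), function(g)
    if (counts[g] > 0L) sort(sample.int(avail[g], counts[g])) else integer())
  dosage <- t(do.call(cbind, lapply(seq_len(G), function(g)
    truth$generations[[g]][, rows[[g]], drop = FALSE])))
  gen_lab <- rep(seq_len(G), counts)
  ids <- sprintf("ind_g%02d_%05d", gen_lab, unlist(rows))
  geno <- genotypes(dosage, ids,
                    data.frame(chrom = truth$map$chrom,
                               pos_bp = truth$map$pos_bp,
                               id = truth$map$id,
                               allele1 = "A", allele0 = "B",
                               stringsAsFactors = FALSE))
  samples <- data.frame(id = ids, generation = gen_lab,
                        birthdate_age = as.numeric(gen_lab),
                        stringsAsFactors = FALSE)
  list(geno = geno, samples = samples,
       index = data.frame(generation = gen_lab, row = unlist(rows)))
}

#' Evaluate scan performance against simulation truth
#'
#' Runs the generation-proxy scan on a sampled panel with the true
#' generation number as the dependent variable and scores it against the
#' known QTL: true positives are simulated QTL with q below the
#' threshold; detectable QTL are those still segregating in the panel
#' (fixed QTL cannot be mapped); false positives are significant
#' non-QTL sites farther than `fp_window` from any QTL under selection
#' arms (LD shadows of true QTL are not penalized), or any significant
#' site under the drift arm.
#'
#' @param panel a [sample_individuals()] result.
#' @param truth the matching [simulate_scenario()] result.
#' @param q_threshold significance cutoff (default 0.1).
#' @param fp_window distance from a QTL inside which a significant site
#'   is not counted as a false positive in selection arms (default 1 Mb).
#' @param maf_min scan MAF threshold (default 0.01).
#' @return list of class `gpsm_eval`: `n_tp`, `n_fp`, `n_sig`,
#'   `n_detectable`, `prop_detected`, `fp_per_200k`, `pve`, `assoc`,
#'   `loci`.
#' @export
evaluate_gpsm_performance <- function(panel, truth, q_threshold = 0.1,
                                      fp_window = 1e6, maf_min = 0.01) {
  if (q_threshold < 0) {
    return(list(n_tp = 0L, n_fp = 0L, n_sig = 0L, n_detectable = NA_integer_,
                prop_detected = NA_real_, fp_per_200k = 0, pve = NA_real_,
                assoc = NULL, loci = NULL))
  }
  geno <- panel$geno
  y <- panel$samples$generation
  grm <- compute_grm(geno, maf_min = maf_min)
  assoc <- assoc_scan(geno, y, grm, scan_config(maf_min = maf_min))
  assoc$q <- storey_qvalues(assoc$p_wald)
  vc <- attr(assoc, "vc")

  m_all <- nrow(truth$map)
  qtl_ids <- truth$map$id[truth$qtl_idx]
  pf <- col_freq(geno$dosage[, truth$qtl_idx, drop = FALSE])
  detectable <- qtl_ids[pf > 0 & pf < 1]
  sig <- assoc[!is.na(assoc$q) & assoc$q < q_threshold, , drop = FALSE]
  n_tp <- sum(sig$id %in% qtl_ids)

  if (truth$scenario$selection == "random") {
    fp <- sig          # under pure drift every significant site is spurious
  } else {
    qtl_pos <- truth$map[truth$qtl_idx, c("chrom", "pos_bp")]
    near_qtl <- vapply(seq_len(nrow(sig)), function(i) {
      same <- qtl_pos$chrom == sig$chrom[i]
      any(same & abs(qtl_pos$pos_bp - sig$pos_bp[i]) <= fp_window)
    }, logical(1))
    fp <- sig[!(sig$id %in% qtl_ids) & !near_qtl, , drop = FALSE]
  }
  loci <- clump_loci(assoc, q_threshold = q_threshold)
  structure(list(n_tp = n_tp, n_fp = nrow(fp), n_sig = nrow(sig),
                 n_detectable = length(detectable),
                 prop_detected = if (length(detectable))
                   sum(sig$id %in% detectable) / length(detectable) else NA_real_,
                 fp_per_200k = nrow(fp) / nrow(assoc) * 2e5,
                 pve = vc$pve, assoc = assoc, loci = loci),
            class = "gpsm_eval")
}

#' @export
print.gpsm_eval <- function(x, ...) {
  cat(sprintf("scan evaluation: %d TP / %d detectable QTL, %d FP (%.2f per 200K), PVE %.3f\n",
              x$n_tp, x$n_detectable, x$n_fp, x$fp_per_200k, x$pve))
  invisible(x)
}

#' Meta-regression of PVE on scenario covariates
#'
#' Ordinary least squares of per-replicate PVE on simulation design
#' covariates (e.g. proportion of false/true positives, generations,
#' crosses, QTL count, QTL distribution, segregating sites), the model
#' used to ask which design factors drive the generation-proxy PVE.
#' Aliased (rank-deficient) covariates raise an error naming them.
#'
#' @param data data.frame of per-replicate results.
#' @param response response column name (default `"pve"`).
#' @param covariates character vector of covariate column names.
#' @return list: `coefficients` table, `f_statistic`, `f_p`, `fit`.
#' @export
pve_metaregression <- function(data, response = "pve",
                               covariates = setdiff(names(data), response)) {
  fml <- stats::reformulate(covariates, response)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased covariate(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  fs <- sm$fstatistic
  list(coefficients = co,
       f_statistic = unname(fs[1]),
       f_p = if (!is.null(fs))
         unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)) else NA,
       fit = fit)
}
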