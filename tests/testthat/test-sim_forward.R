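# Forward simulator: founder pool, QTL architecture, meiosis bookkeeping,
# selection response, sampling schemes.

test_that("founder heterozygosity matches the frequency expectation", {
  sc <- desk_scenario(seed = 1)
  pool <- generate_founders(sc)
  p <- rowMeans(pool$H)
  exp_het <- mean(2 * p * (1 - p))
  n2 <- ncol(pool$H)
  obs_het <- mean(
    pool$H[, seq(1, n2, 2), drop = FALSE] !=
      pool$H[, seq(2, n2, 2), drop = FALSE])
  expect_lt(abs(obs_het - exp_het) / exp_het, 0.2)
})

test_that("founder pools and effects are reproducible under a seed", {
  sc <- desk_scenario(seed = 2)
  p1 <- generate_founders(sc)
  p2 <- generate_founders(sc)
  expect_identical(p1$H, p2$H)
  expect_identical(assign_qtl_architecture(p1)$qtl_effect,
                   assign_qtl_architecture(p2)$qtl_effect)
})

test_that("smaller Ne drifts faster over the founder burn-in", {
  var_dp <- function(ne, seed) {
    sc <- desk_scenario(seed = seed, ne_target = ne, n_founders = 200L,
                        sites_per_chrom = 400L,
                        founder_burnin_generations = 25L)
    pool <- generate_founders(sc)
    p1 <- rowMeans(pool$H)
    keep <- pool$p_init > 0.2 & pool$p_init < 0.8
    mean((p1[keep] - pool$p_init[keep])^2)
  }
  v50 <- mean(vapply(1:3, function(s) var_dp(50L, s), numeric(1)))
  v250 <- mean(vapply(1:3, function(s) var_dp(250L, s), numeric(1)))
  expect_gt(v50, v250)
  # Wright-Fisher scale check: expected var of dp after t generations is
  # p(1-p)(1-(1-1/(2Ne))^t); the ratio between Ne arms should track it
  wf <- function(ne, t = 25) 1 - (1 - 1 / (2 * ne))^t
  expect_lt(abs(v50 / v250 - wf(50) / wf(250)) / (wf(50) / wf(250)), 0.5)
})

test_that("gamma architecture reproduces gamma(0.42) magnitude moments", {
  sc <- desk_scenario(seed = 3, n_qtl = 5000L, sites_per_chrom = 3000L,
                      n_founders = 60L, founder_burnin_generations = 2L)
  pool <- generate_founders(sc)
  sc$qtl_dist <- "gamma"
  tr <- assign_qtl_architecture(pool, sc)
  mag <- abs(tr$qtl_effect[tr$qtl_idx])
  expect_lt(abs(mean(mag) - 0.42) / 0.42, 0.1)       # mean = shape * scale
  expect_lt(abs(var(mag) - 0.42) / 0.42, 0.15)       # var  = shape * scale^2
  expect_gt(min(table(sign(tr$qtl_effect[tr$qtl_idx]))), 0.4 * 5000)
  # n_qtl = 0 -> all-neutral genome
  sc0 <- desk_scenario(seed = 3, n_qtl = 0L)
  tr0 <- assign_qtl_architecture(generate_founders(sc0), sc0)
  expect_true(all(tr0$qtl_effect == 0))
  sc_big <- desk_scenario(seed = 3, n_qtl = 10^6L)
  expect_error(assign_qtl_architecture(pool, sc_big), "exceeds")
})

test_that("meiosis conserves alleles and factor 0 copies a parent", {
  sc <- desk_scenario(seed = 4, recomb_factor = 0)
  pool <- generate_founders(sc)
  H <- pool$H
  gam <- gpsmr:::make_gamete(H, 1L, 2L, pool$map$pos_bp,
                             pool$chrom_index, pool$len_bp, 0)
  # with no recombination each chromosome is an unmodified parental copy
  for (ix in pool$chrom_index) {
    expect_true(identical(gam[ix], H[ix, 1]) || identical(gam[ix], H[ix, 2]))
  }
  # offspring dosage is the sum of transmitted alleles, always in 0..2
  tr <- simulate_scenario(desk_scenario(seed = 4))
  d <- tr$generations[[1]]
  expect_true(all(d %in% 0:2))
  expect_true(all(tr$qtl_freq >= 0 & tr$qtl_freq <= 1))
})

test_that("truncation selection raises mean TBV; random mating does not", {
  gains <- vapply(1:4, function(s) {
    tr <- simulate_scenario(desk_scenario(seed = s))
    mean(tr$tbv[[length(tr$tbv)]]) - mean(tr$tbv[[1]])
  }, numeric(1))
  expect_true(all(gains > 0))
  slopes <- vapply(1:4, function(s) {
    tr <- simulate_scenario(desk_scenario(seed = s, selection = "random"))
    gen_means <- vapply(tr$tbv, mean, numeric(1))
    coef(lm(gen_means ~ seq_along(gen_means)))[2]
  }, numeric(1))
  # drift slopes straddle zero rather than trending up
  expect_lt(mean(slopes), mean(gains) / 4)
})

test_that("selection quotas exceeding the candidate pool error", {
  sc <- desk_scenario(seed = 5, n_crosses = 30L, n_males_selected = 40L)
  expect_error(simulate_scenario(sc), "quota")
})

test_that("even sampling splits generations equally; uneven leans recent", {
  tr <- simulate_scenario(desk_scenario(seed = 6, n_crosses = 200L,
                                        n_generations = 5L,
                                        n_sampled = 500L))
  pe <- sample_individuals(tr, sampling = "even", n_sampled = 500L)
  expect_equal(unname(table(pe$samples$generation)), rep(100L, 5L),
               ignore_attr = TRUE)
  pu <- sample_individuals(tr, sampling = "uneven", n_sampled = 500L)
  cnt <- as.integer(table(factor(pu$samples$generation, levels = 1:5)))
  expect_true(all(diff(cnt) >= 0))          # non-decreasing toward recent
  expect_gte(sum(cnt[3:5]) / sum(cnt), 0.55) # ~60% in last 3 generations
  # exhausted generations are capped with a warning
  expect_warning(sample_individuals(tr, n_sampled = 10000L), "exhausted")
  # reproducible under seed
  expect_identical(sample_individuals(tr, seed = 9)$samples,
                   sample_individuals(tr, seed = 9)$samples)
})

test_that("simulated panels flow into the scan unchanged via PLINK", {
  tr <- simulate_scenario(desk_scenario(seed = 7))
  pan <- sample_individuals(tr, n_sampled = 100L)
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_plink(pan$geno, prefix, generation = pan$samples$generation)
  g2 <- read_plink(prefix)
  expect_equal(unname(g2$dosage), unname(pan$geno$dosage))
  expect_identical(g2$samples, pan$geno$samples)
})

test_that("PVE meta-regression recovers a planted linear effect", {
  set.seed(8)
  n <- 120
  df <- data.frame(n_generations = sample(c(5, 10, 20), n, TRUE),
                   n_crosses = sample(c(1000, 2000), n, TRUE),
                   n_qtl = sample(c(200, 500), n, TRUE))
  df$pve <- 0.02 * df$n_generations + rnorm(n, sd = 0.02)
  fit <- pve_metaregression(df, response = "pve",
                            covariates = c("n_generations", "n_crosses",
                                           "n_qtl"))
  expect_equal(fit$coefficients["n_generations", "estimate"], 0.02,
               tolerance = 0.005)
  expect_lt(fit$coefficients["n_generations", "p"], 0.01)
  # aliased covariate (single level) is reported by name
  df$constant <- 1
  expect_error(pve_metaregression(df, response = "pve",
                                  covariates = c("n_generations", "constant")),
               "constant")
  # zero-variance response: all slopes 0
  df$flat <- 0.5
  fit0 <- pve_metaregression(df, response = "flat",
                             covariates = c("n_generations", "n_qtl"))
  expect_equal(unname(fit0$coefficients[-1, "estimate"]), c(0, 0),
               tolerance = 1e-12)
})

test_that("q below zero yields no positives in the evaluation", {
  tr <- simulate_scenario(desk_scenario(seed = 9))
  pan <- sample_individuals(tr, n_sampled = 100L)
  ev <- evaluate_gpsm_performance(pan, tr, q_threshold = -1)
  expect_equal(ev$n_tp + ev$n_fp, 0L)
})
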