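# Fixed-effects meta-analysis, Cochran's Q, m-values, and trajectory
# convergence classification.

test_that("fixed-effects summaries match closed-form oracles", {
  # identical inputs: Q = 0, p_Q = 1
  fe0 <- meta_fixed_effects(rep(0.5, 4), rep(0.1, 4))
  expect_equal(fe0$q_stat, 0, tolerance = 1e-12)
  expect_equal(fe0$p_q, 1)
  expect_equal(fe0$beta_fe, 0.5)
  # betas (1, -1), ses (1, 1): beta_FE = 0, Q = 2, p = 0.1573
  fe <- meta_fixed_effects(c(1, -1), c(1, 1))
  expect_equal(fe$beta_fe, 0)
  expect_equal(fe$q_stat, 2, tolerance = 1e-12)
  expect_equal(fe$p_q, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(fe$p_q, 4), 0.1573)
  # duplicating one study's summary leaves beta_FE unchanged
  fe1 <- meta_fixed_effects(c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2))
  expect_equal(fe1$beta_fe, 0.3)
  # k = 1: Q undefined
  f1 <- meta_fixed_effects(0.2, 0.1)
  expect_true(is.na(f1$q_stat) && is.na(f1$p_q))
  expect_error(meta_fixed_effects(c(1, 2), c(0, 1)), "positive")
})

test_that("fixed-effects summaries agree with the reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(1)
  b <- rnorm(5, 0.2, 0.3); s <- runif(5, 0.05, 0.3)
  fe <- meta_fixed_effects(b, s)
  rma <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(fe$beta_fe, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(fe$se_fe, rma$se, tolerance = 1e-8)
  expect_equal(fe$q_stat, rma$QE, tolerance = 1e-8)
})

test_that("Q is invariant to a common positive rescaling", {
  set.seed(2)
  b <- rnorm(4); s <- runif(4, 0.1, 0.4)
  q1 <- meta_fixed_effects(b, s)$q_stat
  q2 <- meta_fixed_effects(3.7 * b, 3.7 * s)$q_stat
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("p_Q is uniform under a homogeneous simulated effect", {
  set.seed(3)
  nsim <- 5000; k <- 4
  s <- matrix(runif(nsim * k, 0.05, 0.2), nsim, k)
  b <- matrix(rnorm(nsim * k, mean = 0.3, sd = s), nsim, k)
  pq <- meta_fixed_effects(b, s)$p_q
  ks <- suppressWarnings(ks.test(pq, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("m-values match an exhaustive numerical-integration oracle", {
  oracle_mvalues <- function(b, s, pv, pp) {
    k <- length(b)
    cfg <- as.matrix(expand.grid(rep(list(0:1), k)))
    like <- apply(cfg, 1, function(cc) {
      ll <- prod(dnorm(b[cc == 0], 0, s[cc == 0]))
      if (any(cc == 1)) {
        f <- function(mu) vapply(mu, function(u)
          prod(dnorm(b[cc == 1], u, s[cc == 1])) * dnorm(u, 0, sqrt(pv)),
          numeric(1))
        ll <- ll * integrate(f, -5, 5, rel.tol = 1e-13)$value
      }
      ll * pp^sum(cc) * (1 - pp)^sum(cc == 0)
    })
    drop((like / sum(like)) %*% cfg)
  }
  b <- c(0.31, 0.27, 0.01); s <- c(0.07, 0.11, 0.08)
  mv <- compute_mvalues(b, s, prior_var = 0.04, prior_p = 0.5)
  expect_equal(unname(mv), unname(oracle_mvalues(b, s, 0.04, 0.5)),
               tolerance = 1e-12)
  # other priors too
  mv2 <- compute_mvalues(b, s, prior_var = 0.1, prior_p = 0.3)
  expect_equal(unname(mv2), unname(oracle_mvalues(b, s, 0.1, 0.3)),
               tolerance = 1e-10)
})

test_that("m-value limits behave: strong evidence, no evidence, k cap", {
  expect_gt(compute_mvalues(1, 0.1), 0.99)          # |b/se| = 10
  mv <- compute_mvalues(rep(0, 3), rep(100, 3))     # uninformative
  expect_equal(unname(mv), rep(0.5, 3), tolerance = 0.02)
  expect_error(compute_mvalues(rep(0, 13), rep(1, 13)), "subset")
})

test_that("posterior mass over configurations sums to one", {
  # re-derive the normalization through the public interface: the
  # m-vector of a configuration-symmetric input must be symmetric and
  # within [0, 1]
  set.seed(4)
  for (r in 1:5) {
    k <- sample(2:5, 1)
    b <- rnorm(k, 0, 0.3); s <- runif(k, 0.05, 0.3)
    mv <- compute_mvalues(b, s)
    expect_true(all(mv >= 0 & mv <= 1))
  }
  # matrix input matches row-wise vector calls
  B <- rbind(c(0.2, 0.1), c(0, 0.4)); S <- rbind(c(0.1, 0.1), c(0.2, 0.1))
  MV <- compute_mvalues(B, S)
  expect_equal(MV[1, ], compute_mvalues(B[1, ], S[1, ]), tolerance = 1e-12)
  expect_equal(MV[2, ], compute_mvalues(B[2, ], S[2, ]), tolerance = 1e-12)
})

test_that("conjunction filter requires both heterogeneity and a region hit", {
  scans <- list(
    A = data.frame(chrom = "1", pos_bp = c(1e6, 5e6), id = c("s1", "s2"),
                   af = 0.3, beta = c(2.0, 0.1), se = c(0.2, 0.2),
                   p_wald = c(1e-9, 0.5), q = NA),
    B = data.frame(chrom = "1", pos_bp = c(1e6, 5e6), id = c("s1", "s2"),
                   af = 0.3, beta = c(0.0, 0.1), se = c(0.2, 0.2),
                   p_wald = c(0.9, 0.6), q = NA))
  meta <- meta_region_scans(scans, mvalue_max_p = 1)
  # s1: heterogeneous (2.0 vs 0.0, se 0.2) and significant in region A
  i1 <- match("s1", meta$table$id)
  expect_lt(meta$table$p_q[i1], 1e-5)
  loci <- region_specific_loci(meta)
  expect_equal(loci$lead_id, "s1")
  expect_true(all(c("m.A", "m.B") %in% names(loci)))
  expect_gt(loci$m.A, 0.9)                  # effect lives in region A
  # s2 passes neither filter
  expect_false("s2" %in% loci$lead_id)
  # heterogeneity without a within-region hit is excluded
  scans2 <- scans
  scans2$A$p_wald <- c(1e-4, 0.5)            # below no threshold
  loci2 <- region_specific_loci(meta_region_scans(scans2, mvalue_max_p = 1))
  expect_equal(nrow(loci2), 0L)
})

test_that("identical regions give identical within-region scans", {
  g <- make_panel(90, 200, seed = 5)
  set.seed(6)
  sam <- data.frame(id = g$samples, birthdate_age = runif(90, 0, 10),
                    ecoregion = rep(c("A", "B"), length.out = 90))
  # duplicate the data so both regions hold identical animals
  g2 <- genotypes(rbind(g$dosage, g$dosage),
                  c(g$samples, paste0("dup_", g$samples)), g$snps)
  sam2 <- rbind(sam, transform(sam, id = paste0("dup_", id),
                               ecoregion = ifelse(sam$ecoregion == "A",
                                                  "B", "A")))
  scans <- within_region_scans(g2, sam2, min_n = 10)
  expect_equal(scans$A$p_wald, scans$B$p_wald, tolerance = 1e-8)
  expect_error(within_region_scans(g2, sam2, min_n = 181), "no region")
})

test_that("constructed trajectories classify as convergent or divergent", {
  set.seed(7)
  n <- 900
  t <- runif(n, 0, 12)
  region <- sample(c("focal", "other1", "other2"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
  # divergent: focal region frequency moves away from the pooled mean
  p <- ifelse(region == "focal", 0.5 + 0.025 * t, 0.5)
  d_div <- rbinom(n, 2, pmin(p, 1))
  cls_div <- classify_region_trajectory(d_div, t, region,
                                        target_region = "focal")
  expect_equal(cls_div$class, "divergent")
  # convergent: focal starts apart and decays towards the pooled mean
  p2 <- ifelse(region == "focal", 0.8 - 0.025 * t, 0.5)
  d_con <- rbinom(n, 2, pmax(pmin(p2, 1), 0))
  cls_con <- classify_region_trajectory(d_con, t, region,
                                        target_region = "focal")
  expect_equal(cls_con$class, "convergent")
  # region identical to pooled: distance ~0 everywhere -> convergent
  cls_id <- classify_region_trajectory(d_con, t, rep("focal", n),
                                       target_region = "focal")
  expect_equal(cls_id$class, "convergent")
  # short observation span -> unclassified
  short <- t < 2.6
  cls_short <- classify_region_trajectory(
    d_div[short], t[short], region[short], target_region = "focal")
  expect_equal(cls_short$class, "unclassified")
})

test_that("METASOFT-layout writer emits rsid plus beta/se pairs", {
  scans <- list(
    A = data.frame(chrom = "1", pos_bp = 1e6, id = "s1", af = 0.3,
                   beta = 0.5, se = 0.1, p_wald = 1e-6, q = NA),
    B = data.frame(chrom = "1", pos_bp = 1e6, id = "s1", af = 0.3,
                   beta = 0.2, se = 0.1, p_wald = 0.05, q = NA))
  meta <- meta_region_scans(scans, mvalue_max_p = 1)
  path <- withr::local_tempfile()
  write_metasoft_input(meta, path)
  fields <- strsplit(readLines(path), " ")[[1]]
  expect_equal(fields, c("s1", "0.5", "0.1", "0.2", "0.1"))
})
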