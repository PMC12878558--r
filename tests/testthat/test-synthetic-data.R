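test_that("configuration validation rejects invalid values", {
  expect_error(sim_config(Ne_1 = 0), "positive")
  expect_error(sim_config(m_12 = 1), "migration")
  expect_error(sim_config(T_div = -5), "T_div")
  expect_error(sim_config(n_loci = 0), "loci")
  expect_error(artifact_config(genotype_missing_rate = 1.5), "rates")
  expect_error(env_config(n_env_vars = 0), "n_env_vars")
  expect_error(env_config(noise_sd = -1), "noise")
})

test_that("identical seeds give bit-identical datasets; mu = 0 gives no variants", {
  cfg <- sim_config(n_samples_per_pop = 4, seq_length = 2000, n_loci = 5,
                    seed = 42)
  a <- simulate_coalescent_dataset(cfg)
  b <- simulate_coalescent_dataset(cfg)
  expect_identical(a$gt, b$gt)
  expect_identical(a$sites, b$sites)

  cfg0 <- sim_config(n_samples_per_pop = 4, mu = 0, seq_length = 2000,
                     n_loci = 5, seed = 42)
  v0 <- simulate_coalescent_dataset(cfg0)
  expect_equal(sum(is_variant_site(v0)), 0)
  expect_equal(n_sites(v0), 10000)
})

test_that("T_div = 0 with equal sizes collapses to panmixia (Fst ~ 0)", {
  cfg <- sim_config(n_samples_per_pop = 6, Ne_anc = 5000, Ne_1 = 5000,
                    Ne_2 = 5000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 1000, n_loci = 300, seed = 7)
  vt <- simulate_coalescent_dataset(cfg)
  w <- windowed_dxy_fst(vt, sim_popmap(vt), "pop1", "pop2", window = 1e6)
  fst <- genome_stat(w, "fst")$value
  expect_lt(abs(fst), 0.05)
})

test_that("panmictic mean pi is within 3 SE of 4*Ne*mu over 500 loci", {
  cfg <- sim_config(n_samples_per_pop = 5, Ne_anc = 5000, Ne_1 = 5000,
                    Ne_2 = 5000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 1000, n_loci = 500, seed = 11)
  vt <- simulate_coalescent_dataset(cfg)
  pm <- sim_popmap(vt)
  pm$population <- "all"
  w <- windowed_pi(vt, pm, "all", window = 1000)   # one window per locus
  per_locus <- w$pi
  expect_equal(length(per_locus), 500)
  se <- sd(per_locus) / sqrt(length(per_locus))
  expect_lt(abs(mean(per_locus) - 4 * 5000 * 1e-7), 3 * se)
})

test_that("expected Fst decreases with migration at fixed T_div", {
  fst_at <- function(m, seed) {
    cfg <- sim_config(n_samples_per_pop = 5, Ne_anc = 5000, Ne_1 = 5000,
                      Ne_2 = 5000, T_div = 2000, m_12 = m, m_21 = m,
                      mu = 1e-7, seq_length = 1000, n_loci = 250, seed = seed)
    vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
    w <- windowed_dxy_fst(vt, sim_popmap(vt), "pop1", "pop2", window = 1e6)
    genome_stat(w, "fst")$value
  }
  f0 <- fst_at(0, 21); f1 <- fst_at(0.001, 22); f2 <- fst_at(0.01, 23)
  expect_gt(f0, f1)
  expect_gt(f1, f2)
})

test_that("folded SFS of a panmictic population matches the neutral shape", {
  # many short loci keep sites nearly independent, so the chi-square GOF
  # is valid (long loci share genealogies and over-disperse the counts)
  cfg <- sim_config(n_samples_per_pop = 5, Ne_anc = 5000, Ne_1 = 5000,
                    Ne_2 = 5000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 100, n_loci = 6000, seed = 11)
  vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
  gm <- to_genotype_matrix(vt)
  ac <- colSums(gm)
  an <- 2 * nrow(gm)
  mac <- pmin(ac, an - ac)
  obs <- tabulate(mac, nbins = an / 2)
  exp_p <- vapply(seq_len(an / 2), function(i)
    if (i < an / 2) 1 / i + 1 / (an - i) else 1 / i, 0)
  exp_p <- exp_p / sum(exp_p)
  p <- suppressWarnings(stats::chisq.test(obs, p = exp_p))$p.value
  expect_gt(p, 0.01)
})

test_that("mean Tajima's D over 500 neutral loci lies within 3 SE of 0", {
  cfg <- sim_config(n_samples_per_pop = 5, Ne_anc = 5000, Ne_1 = 5000,
                    Ne_2 = 5000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 1000, n_loci = 500, seed = 13)
  vt <- simulate_coalescent_dataset(cfg)
  pm <- sim_popmap(vt)
  pm$population <- "all"
  w <- windowed_theta_tajd(vt, pm, "all", window = 1000)
  D <- w$tajima_d[!is.na(w$tajima_d)]
  expect_gt(length(D), 400)
  expect_lt(abs(mean(D)), 3 * sd(D) / sqrt(length(D)))
})

test_that("artifact overlay: determinism, aberrant AB, missingness, clean pass-through", {
  cfg <- sim_config(n_samples_per_pop = 4, seq_length = 3000, n_loci = 10,
                    seed = 5)
  vt <- simulate_coalescent_dataset(cfg)

  a1 <- apply_sequencing_artifacts(vt, artifact_config(seed = 8))
  a2 <- apply_sequencing_artifacts(vt, artifact_config(seed = 8))
  expect_identical(a1$gt, a2$gt)
  expect_identical(a1$dp, a2$dp)
  expect_identical(a1$ad_alt, a2$ad_alt)

  # every het AD ratio outside the band when the aberrant fraction is 1
  ab <- apply_sequencing_artifacts(vt, artifact_config(aberrant_ab_fraction = 1,
                                                       seed = 9))
  het <- which(ab$gt == 1L & is_variant_site(ab))
  frac <- ab$ad_alt[het] / ab$dp[het]
  frac <- frac[ab$dp[het] > 0]
  expect_true(all(frac < 0.25 | frac > 0.75))

  miss <- apply_sequencing_artifacts(vt, artifact_config(genotype_missing_rate = 0.3,
                                                         seed = 10))
  expect_gt(mean(is.na(miss$gt)), 0.25)
  expect_lt(mean(is.na(miss$gt)), 0.35)
  expect_identical(attr(miss, "truth_gt"), vt$gt)

  expect_error(apply_sequencing_artifacts(miss, artifact_config()), "missing")
})

test_that("environment simulation: exact cline, null correlation, collinear pair", {
  # zero noise, nonzero slope: |Spearman rho| with latitude is exactly 1
  e0 <- simulate_environment(sprintf("s%d", 1:30),
                             env_config(n_env_vars = 1, slopes = 2,
                                        noise_sd = 0, seed = 3))
  expect_equal(abs(cor(e0$env$env1, e0$coords$lat, method = "spearman")), 1)

  # zero slope: |rho| < 0.3 at n = 60
  en <- simulate_environment(sprintf("s%d", 1:60),
                             env_config(n_env_vars = 1, slopes = 0,
                                        noise_sd = 1, seed = 4))
  expect_lt(abs(cor(en$env$env1, en$coords$lat, method = "spearman")), 0.3)

  # two variables sharing a slope with small noise: collinearity filter
  # removes exactly one
  e2 <- simulate_environment(sprintf("s%d", 1:40),
                             env_config(n_env_vars = 2, slopes = c(1, 1),
                                        noise_sd = 0.5, seed = 5))
  expect_gt(abs(cor(e2$env$env1, e2$env$env2, method = "spearman")), 0.7)
  expect_length(collinearity_filter(e2$env, 0.7), 1)
})
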