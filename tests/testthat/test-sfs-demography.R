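test_that("SFS projection places counts per the hypergeometric rules", {
  pm <- make_popmap(sprintf("s%02d", 1:8))
  # full coverage, projection = full size: counts land directly
  gt <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),   # counts (1, 0)
              c(1L, 1L, 1L, 0L, 2L, 2L, 0L, 0L),   # (3, 4): total 7 of 16 stays unfolded
              matrix(0L, 3, 8))
  vt <- make_table(gt, alt = c("T", "T", NA, NA, NA))
  sfs <- build_folded_joint_sfs(vt, pm, c("A", "B"), projection = c(8, 8))
  expect_equal(sfs$counts[2, 1], 1)    # cell (1, 0)
  expect_equal(sfs$counts[4, 5], 1)    # cell (3, 4): total 7 <= 8, unfolded
  expect_equal(sfs$counts[1, 1], 3)    # monomorphic rows
  expect_equal(sfs$n_sites, 5)

  # folding: derived counts (7, 6) of (8, 8) -> total 13 > 8 -> cell (1, 2)
  gt2 <- rbind(c(2L, 2L, 2L, 1L, 0L, 0L, 0L, 0L))
  gt2[1, 5:8] <- c(2L, 2L, 1L, 1L)
  vt2 <- make_table(gt2)
  sfs2 <- build_folded_joint_sfs(vt2, pm, c("A", "B"), projection = c(8, 8))
  expect_equal(sfs2$counts[2, 3], 1)

  # at projection (4, 4): derived (3, 4) totals 7 > 4 -> folds to (1, 0)
  pm4 <- make_popmap(sprintf("s%02d", 1:4))
  gt4 <- rbind(c(2L, 1L, 2L, 2L))
  vt4 <- make_table(gt4)
  sfs4 <- build_folded_joint_sfs(vt4, pm4, c("A", "B"), projection = c(4, 4))
  expect_equal(sfs4$counts[2, 1], 1)

  # sites with fewer alleles than the projection are excluded and counted
  gt3 <- rbind(c(1L, NA, 0L, 0L, 0L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  vt3 <- make_table(gt3)
  sfs3 <- build_folded_joint_sfs(vt3, pm, c("A", "B"), projection = c(8, 8))
  expect_equal(sfs3$n_excluded, 1)
  expect_error(build_folded_joint_sfs(vt3, pm, c("A", "B"),
                                      projection = c(10, 8)), "projection")
})

test_that("downsampling projection equals exhaustive subsample enumeration", {
  pm <- make_popmap(sprintf("s%02d", 1:6), 3)
  set.seed(110)
  gt <- matrix(sample(c(0:2, NA), 25 * 6, TRUE, prob = c(0.4, 0.25, 0.25, 0.1)),
               25, 6)
  vs <- rowSums(gt > 0, na.rm = TRUE) > 0
  vt <- make_table(gt, alt = ifelse(vs, "T", NA))
  n1 <- 4; n2 <- 4
  sfs <- build_folded_joint_sfs(vt, pm, c("A", "B"), projection = c(n1, n2))
  # oracle: enumerate all allele subsets of size n per population
  S <- matrix(0, n1 + 1, n2 + 1)
  excl <- 0
  for (i in 1:25) {
    a <- dosage_to_alleles(gt[i, 1:3]); a <- a[!is.na(a)]
    b <- dosage_to_alleles(gt[i, 4:6]); b <- b[!is.na(b)]
    if (length(a) < n1 || length(b) < n2) { excl <- excl + 1; next }
    if (!vs[i]) { S[1, 1] <- S[1, 1] + 1; next }
    ca <- utils::combn(length(a), n1)
    cb <- utils::combn(length(b), n2)
    wa <- tabulate(colSums(matrix(a[ca], n1)) + 1, n1 + 1) / ncol(ca)
    wb <- tabulate(colSums(matrix(b[cb], n2)) + 1, n2 + 1) / ncol(cb)
    S <- S + outer(wa, wb)
  }
  # fold the oracle with the same canonical rule
  F <- twodeme:::.fold_joint(S)
  expect_equal(sfs$counts, F, tolerance = 1e-12)
  expect_equal(sfs$n_excluded, excl)
})

test_that("composite likelihood, AIC and dAIC arithmetic are exact", {
  O <- matrix(0, 2, 2); O[1, 1] <- 90; O[2, 1] <- 10
  p <- matrix(0, 2, 2); p[1, 1] <- 0.9; p[2, 1] <- 0.1
  expect_equal(composite_log10_likelihood(O, p),
               10 * log10(0.1) + 90 * log10(0.9), tolerance = 1e-12)
  expect_equal(composite_log10_likelihood(O, p), -14.1182, tolerance = 1e-4)

  # Gibbs: the observed frequencies maximise L over the simplex
  base <- composite_log10_likelihood(O, O / sum(O))
  for (eps in c(0.02, 0.1)) {
    q <- O / sum(O)
    q[1, 1] <- q[1, 1] - eps; q[2, 1] <- q[2, 1] + eps
    expect_lt(composite_log10_likelihood(O, q), base)
  }

  # a zero-probability cell with observations is floored with a warning
  p0 <- p; p0[2, 1] <- 0
  expect_warning(l0 <- composite_log10_likelihood(O, p0), "floored")
  expect_true(is.finite(l0))

  expect_error(composite_log10_likelihood(matrix(-1, 1, 1), matrix(1, 1, 1)),
               "negative")

  expect_equal(aic(6, -23431), 12 + 2 * 23431 / 0.4342944819, tolerance = 1e-6)
  expect_error(aic(0, -10), "k must be")
  expect_equal(delta_aic(c(108365, 107928, 107914)), c(451, 14, 0))
  expect_equal(delta_aic(42), 0)
  expect_error(delta_aic(numeric(0)), "empty")
})

test_that("expected SFS: neutral shape, panmictic collapse, migration limit", {
  # single-population folded marginal follows 1/i + 1/(2n - i)
  m1 <- demographic_model("single", Ne_anc = 5000, mu = 1e-7)
  P <- expected_sfs(m1, 6, 6, n_sims = 1e5, seed = 21)
  poly <- P; poly[1, 1] <- 0
  # fold cells back onto total minor count 1..6
  tot <- outer(0:6, 0:6, "+")
  marg <- vapply(1:6, function(i) sum(poly[tot == i]), 0)
  exp_p <- vapply(1:6, function(i) if (i < 6) 1 / i + 1 / (12 - i) else 1 / 6, 0)
  chi <- sum((marg / sum(marg) - exp_p / sum(exp_p))^2 / (exp_p / sum(exp_p)))
  expect_lt(chi, 0.01)

  # Tdiv = 0 equal sizes: joint SFS statistically identical to single
  m2 <- demographic_model("split_migration", Ne_anc = 5000, Ne_1 = 5000,
                          Ne_2 = 5000, T_div = 0, m_12 = 0.01, m_21 = 0.01,
                          mu = 1e-7)
  P2 <- expected_sfs(m2, 6, 6, n_sims = 1e5, seed = 22)
  expect_lt(max(abs(P2 - P)), 0.0002)

  # strong migration approaches the panmictic pattern; weak keeps more
  # reciprocally-private mass (off-diagonal corners)
  corner_mass <- function(m) {
    mod <- demographic_model("split_migration", Ne_anc = 5000, Ne_1 = 5000,
                             Ne_2 = 5000, T_div = 4000, m_12 = m, m_21 = m,
                             mu = 1e-7)
    P <- expected_sfs(mod, 6, 6, n_sims = 4e4, seed = 23)
    sum(P[1, -1]) + sum(P[-1, 1])   # variants private to one deme
  }
  pan <- sum(P[1, -1]) + sum(P[-1, 1])
  expect_gt(abs(corner_mass(1e-5) - pan), abs(corner_mass(0.05) - pan))

  expect_warning(expected_sfs(m1, 4, 4, n_sims = 500, seed = 1), "noisy")
})

test_that("model fitting recovers a single-population size and is deterministic", {
  cfg <- sim_config(n_samples_per_pop = 6, Ne_anc = 2000, Ne_1 = 2000,
                    Ne_2 = 2000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 1000, n_loci = 400, seed = 130)
  vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
  sfs <- build_folded_joint_sfs(vt, sim_popmap(vt), c("pop1", "pop2"),
                                projection = c(8, 8))
  f <- fit_model(sfs, "single", mu = 1e-7, n_cycles = 8, n_sims = 5000,
                 seed = 9)
  expect_equal(f$model$Ne_anc, 2000, tolerance = 0.25)
  expect_equal(f$model$T_div, 0)
  expect_equal(f$k, 1)
  expect_equal(f$AIC, aic(1, f$MaxEstLhood))
  f2 <- fit_model(sfs, "single", mu = 1e-7, n_cycles = 8, n_sims = 5000,
                  seed = 9)
  expect_identical(f$model$Ne_anc, f2$model$Ne_anc)
  expect_identical(f$MaxEstLhood, f2$MaxEstLhood)
})

test_that("likelihood at the truth beats x4 parameter perturbations", {
  cfg <- sim_config(n_samples_per_pop = 6, Ne_anc = 3000, Ne_1 = 3000,
                    Ne_2 = 3000, T_div = 0, m_12 = 0, m_21 = 0, mu = 1e-7,
                    seq_length = 1000, n_loci = 500, seed = 131)
  vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
  sfs <- build_folded_joint_sfs(vt, sim_popmap(vt), c("pop1", "pop2"),
                                projection = c(8, 8))
  ll_of <- function(ne) composite_log10_likelihood(
    sfs, expected_sfs(demographic_model("single", Ne_anc = ne, mu = 1e-7),
                      8, 8, n_sims = 3e4, seed = 44))
  expect_gt(ll_of(3000), ll_of(12000))
  expect_gt(ll_of(3000), ll_of(750))
})
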