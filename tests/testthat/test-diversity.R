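test_that("per-site pi arithmetic matches hand counts", {
  # genotypes 0/0 and 1/1: alleles {0,0,1,1}, 4 differing pairs of 6
  vt <- make_table(rbind(c(0L, 2L)))
  pm <- data.frame(sample = vt$samples, population = "p")
  w <- windowed_pi(vt, pm, "p", window = 100)
  expect_equal(w$pi, 4 / 6)

  # all invariant sites: pi exactly 0, not NA
  inv <- make_table(matrix(0L, 5, 2), alt = rep(NA, 5))
  wi <- windowed_pi(inv, pm, "p", window = 100)
  expect_identical(wi$pi, 0)
  expect_equal(wi$n_comp, 5 * 6)

  # empty window data -> NA, never 0
  miss <- make_table(matrix(NA_integer_, 2, 2))
  wm <- windowed_pi(miss, pm, "p", window = 100)
  expect_true(is.na(wm$pi))
})

test_that("windowed pi and dxy equal brute-force pairwise counting", {
  set.seed(52)
  pm <- make_popmap(sprintf("s%02d", 1:8))
  for (rep in 1:8) {
    ns <- 120
    gt <- matrix(sample(c(0:2, NA), ns * 8, TRUE,
                        prob = c(0.5, 0.2, 0.2, 0.1)), ns, 8)
    vs <- rowSums(gt > 0, na.rm = TRUE) > 0
    vt <- make_table(gt, alt = ifelse(vs, "T", NA),
                     pos = sort(sample(1:5000, ns)))
    w <- windowed_pi(vt, pm, "A", window = 1000)
    # brute force within population A
    ga <- gt[, 1:4, drop = FALSE]
    widx <- (vt$sites$pos - 1) %/% 1000
    for (uw in unique(widx)) {
      rows <- which(widx == uw)
      dc <- sapply(rows, function(i) oracle_pi_site(dosage_to_alleles(ga[i, ])))
      d <- sum(dc[1, ], na.rm = TRUE); cmp <- sum(dc[2, ], na.rm = TRUE)
      got <- w$pi[w$start == uw * 1000 + 1]
      if (cmp == 0) expect_true(is.na(got)) else
        expect_equal(got, d / cmp, tolerance = 1e-12)
    }
    # dxy brute force: between-population allele pairs
    wd <- windowed_dxy_fst(vt, pm, "A", "B", window = 1e6)
    num <- den <- 0
    for (i in seq_len(ns)) {
      a <- dosage_to_alleles(gt[i, 1:4]); a <- a[!is.na(a)]
      b <- dosage_to_alleles(gt[i, 5:8]); b <- b[!is.na(b)]
      if (!length(a) || !length(b)) next
      num <- num + sum(outer(a, b, "!="))
      den <- den + length(a) * length(b)
    }
    expect_equal(wd$dxy, num / den, tolerance = 1e-12)
  }
})

test_that("theta and Tajima's D match the direct 1989 formulas", {
  # a_4 = 1 + 1/2 + 1/3
  expect_equal(twodeme:::.harmonic(3), 1 + 1/2 + 1/3)

  # k constant = 4 alleles, S = 3 segregating of 100 comparable sites
  gt <- matrix(0L, 100, 2)
  gt[1:3, 1] <- 1L
  vt <- make_table(gt, alt = c(rep("T", 3), rep(NA, 97)))
  pm <- data.frame(sample = vt$samples, population = "p")
  w <- windowed_theta_tajd(vt, pm, "p", window = 1000)
  expect_equal(w$theta, 3 / (1 + 1/2 + 1/3) / 100, tolerance = 1e-12)
  expect_equal(w$S, 3)

  # independent implementation of the D constants (non-missing data)
  oracle_tajd <- function(S, pi_abs, n) {
    a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi_abs - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  }
  set.seed(61)
  for (rep in 1:20) {
    np <- sample(3:8, 1)
    ns <- 50
    gt <- matrix(sample(0:2, ns * np, TRUE, prob = c(0.6, 0.25, 0.15)), ns, np)
    seg <- apply(gt, 1, function(g) any(g > 0) && any(g < 2))
    vt <- make_table(gt, alt = ifelse(rowSums(gt) > 0, "T", NA))
    pm <- data.frame(sample = vt$samples, population = "p")
    w <- windowed_theta_tajd(vt, pm, "p", window = 1000)
    if (sum(seg) == 0) { expect_true(is.na(w$tajima_d)); next }
    pi_abs <- sum(sapply(which(seg), function(i) {
      o <- oracle_pi_site(dosage_to_alleles(gt[i, ])); o["diff"] / o["comp"]
    }))
    expect_equal(w$tajima_d, oracle_tajd(sum(seg), pi_abs, 2 * np),
                 tolerance = 1e-9)
  }
})

test_that("dxy and Hudson Fst behave at the fixation extremes", {
  pm <- make_popmap(sprintf("s%02d", 1:6), 3)
  # A fixed ref, B fixed alt at 4 variant sites of 10 total
  gt <- rbind(matrix(rep(c(0L, 0L, 0L, 2L, 2L, 2L), 4), 4, byrow = TRUE),
              matrix(0L, 6, 6))
  vt <- make_table(gt, alt = c(rep("T", 4), rep(NA, 6)))
  w <- windowed_dxy_fst(vt, pm, "A", "B", window = 100)
  expect_equal(w$dxy, 4 / 10)
  expect_equal(w$fst, 1)

  # identical allele frequencies in both: Fst ~ 0 (ratio of sums; the
  # unbiased within-pop heterozygosity leaves a small negative O(1/k) bias)
  pm2 <- make_popmap(sprintf("s%02d", 1:40), 20)
  g2 <- matrix(rep(c(rep(0L, 8), rep(1L, 6), rep(2L, 6)), 2 * 30), 30,
               byrow = TRUE)
  vt2 <- make_table(g2)
  w2 <- windowed_dxy_fst(vt2, pm2, "A", "B", window = 1e6)
  expect_lt(abs(w2$fst), 0.05)
})

test_that("Fst under high migration is below Fst under low migration", {
  fst_of <- function(m, seed) {
    cfg <- sim_config(n_samples_per_pop = 5, Ne_anc = 5000, Ne_1 = 5000,
                      Ne_2 = 5000, T_div = 2000, m_12 = m, m_21 = m,
                      mu = 1e-7, seq_length = 1000, n_loci = 200, seed = seed)
    vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
    w <- windowed_dxy_fst(vt, sim_popmap(vt), "pop1", "pop2", window = 1e6)
    genome_stat(w, "fst")$value
  }
  expect_lt(fst_of(0.02, 41), fst_of(2e-5, 42))  # Ne m ~ 100 vs ~ 0.1
})

test_that("weighted window pi equals one-pass genome-wide pi", {
  cfg <- sim_config(n_samples_per_pop = 4, seq_length = 50000, n_loci = 4,
                    seed = 55)
  vt <- simulate_coalescent_dataset(cfg)
  pm <- sim_popmap(vt)
  w <- windowed_pi(vt, pm, "pop1", window = 10000)
  one <- windowed_pi(vt, pm, "pop1", window = 1e9)
  expect_equal(genome_stat(w, "pi")$value,
               sum(one$pi * one$n_comp) / sum(one$n_comp), tolerance = 1e-12)
})

test_that("heterozygosity and F_IS are computed per spec", {
  # 13 het of 100 non-missing variant calls -> Het 0.13
  g <- matrix(0L, 4, 100)
  g[1, 1:13] <- 1L
  g[2, ] <- sample(0:2, 100, TRUE)    # give sites some frequency spread
  gm <- make_gm(g)
  hf <- sample_het_fis(gm)
  expect_equal(hf$het[1], 0.13)

  # fully homozygous sample: Het 0, F_IS 1
  g2 <- rbind(rep(0L, 40), sample(0:2, 40, TRUE), sample(0:2, 40, TRUE))
  g2[1, 1:20] <- 2L
  hf2 <- sample_het_fis(make_gm(g2))
  expect_equal(hf2$het[1], 0)
  expect_equal(hf2$f_is[1], 1)

  # zero non-missing calls -> NA
  g3 <- rbind(rep(NA_integer_, 10), rep(1L, 10), rep(0L, 10))
  hf3 <- sample_het_fis(make_gm(g3))
  expect_true(is.na(hf3$het[1]))

  # Hardy-Weinberg panmictic simulation: cohort F_IS within 3 SE of 0
  cfg <- sim_config(n_samples_per_pop = 15, Ne_anc = 5000, T_div = 0,
                    m_12 = 0, m_21 = 0, mu = 1e-7, seq_length = 2000,
                    n_loci = 150, seed = 62)
  vt <- simulate_coalescent_dataset(cfg, materialize_invariant = FALSE)
  hf4 <- sample_het_fis(to_genotype_matrix(vt))
  se <- sd(hf4$f_is) / sqrt(nrow(hf4))
  expect_lt(abs(attr(hf4, "f_is_cohort")), 3 * se)
})
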