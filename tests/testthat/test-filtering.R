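# an independent brute-force reimplementation of the cascade, written
# against the rule list rather than sharing code with filter_variants()
oracle_filter <- function(vt, cfg = filter_config()) {
  keep <- rep(TRUE, n_sites(vt))
  gt <- vt$gt
  vs <- !is.na(vt$sites$alt)
  # qual (variant records)
  for (i in seq_len(n_sites(vt)))
    if (vs[i] && !is.na(vt$sites$qual[i]) && vt$sites$qual[i] < cfg$min_qual)
      keep[i] <- FALSE
  # allele balance masks het genotypes
  for (i in which(keep & vs)) for (j in seq_along(vt$samples)) {
    if (!is.na(gt[i, j]) && gt[i, j] == 1L) {
      ok <- !is.null(vt$ad_alt) && !is.na(vt$ad_alt[i, j]) &&
        !is.na(vt$dp[i, j]) && vt$dp[i, j] > 0 &&
        vt$ad_alt[i, j] / vt$dp[i, j] >= cfg$ab_low &&
        vt$ad_alt[i, j] / vt$dp[i, j] <= cfg$ab_high
      if (!ok) gt[i, j] <- NA
    }
  }
  # all-het sites
  for (i in which(keep & vs)) {
    g <- gt[i, !is.na(gt[i, ])]
    if (length(g) > 0 && all(g == 1L)) keep[i] <- FALSE
  }
  # depth bounds (all sites), thresholds from the table entering this step
  if (!is.null(vt$dp)) {
    mu <- colMeans(vt$dp[keep, , drop = FALSE], na.rm = TRUE)
    sdp <- sqrt(colMeans(sweep(vt$dp[keep, , drop = FALSE], 2, mu)^2,
                         na.rm = TRUE))
    for (i in which(keep)) for (j in seq_along(vt$samples)) {
      d <- vt$dp[i, j]
      if (!is.na(gt[i, j]) && !is.na(d) &&
          (d < cfg$min_dp || d > mu[j] + cfg$dp_sd_mult * sdp[j]))
        gt[i, j] <- NA
    }
  }
  # missingness
  for (i in which(keep))
    if (mean(is.na(gt[i, ])) > cfg$max_site_missing) keep[i] <- FALSE
  list(keep = keep, gt = gt[keep, , drop = FALSE])
}

test_that("depth thresholds use the population-SD convention", {
  dp <- cbind(rep(20L, 3), c(10L, 20L, 30L), c(15L, 15L, 15L))
  vt <- make_table(matrix(0L, 3, 3), dp = dp)
  th <- compute_depth_thresholds(vt)
  expect_equal(unname(th[1]), 20)                       # SD 0 -> bound = mean
  expect_equal(unname(th[2]), 20 + 3 * 8.16496580927726, tolerance = 1e-10)
  expect_equal(unname(th[2]), 44.495, tolerance = 1e-3) # {10,20,30}: 44.495
  expect_equal(unname(th[3]), 15)

  one <- make_table(matrix(0L, 1, 1), dp = matrix(7L, 1, 1))
  expect_equal(as.vector(compute_depth_thresholds(one)), 7)

  no_dp <- make_table(matrix(0L, 2, 2))
  expect_error(compute_depth_thresholds(no_dp), "no DP")
})

test_that("individual cascade rules fire as specified", {
  # het with AD (2, 8): alt fraction 0.2 < 0.25 -> genotype masked
  gt <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L))
  dp <- matrix(10L, 3, 2)
  ad <- rbind(c(2L, 0L), c(5L, 5L), c(0L, 5L))
  vt <- make_table(gt, dp = dp, ad_alt = ad, qual = 50)
  out <- filter_variants(vt, filter_config(max_site_missing = 1))
  expect_true(is.na(out$table$gt[1, 1]))
  expect_equal(out$report$rules$allele_balance$genotypes_masked, 1L)

  # all-het site removed; qual < 20 removed
  gt2 <- rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L))
  vt2 <- make_table(gt2, alt = c("T", "T", NA), qual = c(50, 10, NA),
                    dp = matrix(10L, 3, 2),
                    ad_alt = rbind(c(5L, 5L), c(0L, 5L), c(NA, NA)))
  out2 <- filter_variants(vt2, filter_config(max_site_missing = 1))
  expect_equal(out2$report$rules$qual$sites_removed, 1L)      # the qual-10 row
  expect_equal(out2$report$rules$all_het$sites_removed, 1L)
  expect_equal(n_sites(out2$table), 1)                        # invariant row

  # 40 samples, 5 missing -> 12.5% > 10% -> removed
  g <- matrix(0L, 2, 40)
  g[1, 1:5] <- NA
  vt3 <- make_table(g, alt = c(NA, NA))
  out3 <- filter_variants(vt3, filter_config())
  expect_equal(out3$report$rules$missingness$sites_removed, 1L)
  expect_equal(n_sites(out3$table), 1)
})

test_that("site-mode allele balance removes whole sites", {
  gt <- rbind(c(1L, 0L), c(0L, 1L))
  dp <- matrix(10L, 2, 2)
  ad <- rbind(c(1L, 0L), c(0L, 5L))
  vt <- make_table(gt, dp = dp, ad_alt = ad, qual = 50)
  out <- filter_variants(vt, filter_config(ab_site_mode = TRUE,
                                           max_site_missing = 1))
  expect_equal(out$report$rules$allele_balance$sites_removed, 1L)
  expect_equal(n_sites(out$table), 1)
})

test_that("random toy tables match the brute-force oracle", {
  set.seed(404)
  for (rep in 1:10) {
    ns <- 40; np <- 8
    gt <- matrix(sample(c(0:2, NA), ns * np, TRUE,
                        prob = c(0.55, 0.2, 0.15, 0.1)), ns, np)
    vs <- runif(ns) < 0.7
    dp <- matrix(rpois(ns * np, 15), ns, np)
    ad <- matrix(NA_integer_, ns, np)
    het <- which(gt == 1L & vs)
    ad[het] <- rbinom(length(het), dp[het], runif(length(het), 0.1, 0.9))
    hom <- which(gt == 2L & vs)
    ad[hom] <- dp[hom]
    vt <- make_table(gt, alt = ifelse(vs, "T", NA),
                     qual = sample(c(NA, 10, 30, 60), ns, TRUE),
                     dp = dp, ad_alt = ad)
    got <- filter_variants(vt)
    want <- oracle_filter(vt)
    expect_equal(n_sites(got$table), sum(want$keep))
    expect_identical(unname(got$table$gt), unname(want$gt))
  }
})

test_that("filtering is idempotent and monotone in thresholds", {
  cfg <- sim_config(n_samples_per_pop = 5, seq_length = 2000, n_loci = 10,
                    seed = 77)
  vt <- simulate_coalescent_dataset(cfg)
  art <- apply_sequencing_artifacts(vt, artifact_config(
    genotype_missing_rate = 0.05, aberrant_ab_fraction = 0.1,
    low_qual_fraction = 0.1, seed = 78))
  f1 <- filter_variants(art)
  f2 <- filter_variants(f1$table)
  expect_equal(n_sites(f2$table), n_sites(f1$table))
  expect_identical(f2$table$gt, f1$table$gt)

  loose <- filter_variants(art, filter_config(min_qual = 10, ab_low = 0.1,
                                              ab_high = 0.9, min_dp = 1,
                                              dp_sd_mult = 6,
                                              max_site_missing = 0.5))
  expect_gte(n_sites(loose$table), n_sites(f1$table))
})

test_that("the artifact-free configuration passes the cascade untouched", {
  cfg <- sim_config(n_samples_per_pop = 6, seq_length = 2000, n_loci = 10,
                    seed = 91)
  vt <- simulate_coalescent_dataset(cfg)
  clean <- apply_sequencing_artifacts(vt, artifact_config(
    depth_dispersion = Inf, ab_noise = FALSE, seed = 92))
  out <- filter_variants(clean)
  expect_equal(out$report$n_retained, out$report$n_input)
  expect_equal(sum(is.na(out$table$gt)), 0)
})
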