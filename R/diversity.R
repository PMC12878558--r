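#' Missing-data-aware windowed diversity and divergence
#'
#' All statistics use counted denominators over non-missing alleles, in the
#' all-sites tradition: at a site where the focal population has k genotyped
#' alleles and a alt copies, the number of comparable allele pairs is
#' k(k-1)/2 and the number of differing pairs a(k-a); invariant sites
#' contribute comparisons with zero differences. Windows are
#' `[(w-1)*window+1, w*window]` per contig (1-based inclusive). Windows with
#' no comparable data yield `NA`, never 0.
#'
#' @param table a filtered all-sites `variant_table`
#' @param popmap data.frame with columns `sample`, `population`
#' @param population focal population label
#' @param window window width in bp (default 100,000)
#' @return data.frame, one row per window: `chrom`, `start`, `end`, `pi`,
#'   `n_comp` (allele-pair comparisons), `n_sites` (sites with >= 2 alleles),
#'   `n_variant` (segregating sites among genotyped alleles)
#' @export
windowed_pi <- function(table, popmap, population, window = 100000) {
  cols <- .pop_cols(table, popmap, population)
  ac <- .allele_counts(table, cols)
  w <- .site_windows(table, window)
  has <- ac$an >= 2
  diffs <- ac$ac * (ac$an - ac$ac)
  comps <- ac$an * (ac$an - 1) / 2
  agg <- .window_aggregate(w, cbind(diff = ifelse(has, diffs, 0),
                                    comp = ifelse(has, comps, 0),
                                    n_sites = as.numeric(has),
                                    n_variant = as.numeric(has & diffs > 0)))
  agg$pi <- ifelse(agg$comp > 0, agg$diff / agg$comp, NA_real_)
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$end,
             pi = agg$pi, n_comp = agg$comp, n_sites = agg$n_sites,
             n_variant = agg$n_variant, stringsAsFactors = FALSE)
}

#' Windowed Watterson's theta and Tajima's D
#'
#' Theta per window is `sum over segregating sites of 1/a_k` divided by the
#' count of sites with data, with `a_k = sum_{j<k} 1/j` evaluated at each
#' site's non-missing allele count k. Tajima's D uses the 1989 variance
#' constants evaluated at the harmonic mean of per-site allele counts over
#' the window's segregating sites; D is `NA` when S = 0.
#'
#' @inheritParams windowed_pi
#' @return data.frame per window: `chrom`, `start`, `end`, `theta`, `tajima_d`,
#'   `S` (segregating sites), `n_sites`, `pi_abs` (summed per-site pi, the
#'   mean pairwise difference count entering D)
#' @export
windowed_theta_tajd <- function(table, popmap, population, window = 100000) {
  cols <- .pop_cols(table, popmap, population)
  ac <- .allele_counts(table, cols)
  w <- .site_windows(table, window)
  has <- ac$an >= 2
  seg <- has & ac$ac > 0 & ac$ac < ac$an
  inv_a <- ifelse(seg, 1 / .harmonic(pmax(ac$an - 1, 1)), 0)
  pi_site <- ifelse(has & ac$an >= 2,
                    ac$ac * (ac$an - ac$ac) / (ac$an * (ac$an - 1) / 2), 0)
  agg <- .window_aggregate(w, cbind(
    inv_a = inv_a, n_sites = as.numeric(has), S = as.numeric(seg),
    pi_abs = pi_site, inv_k = ifelse(seg, 1 / ac$an, 0)))
  theta <- ifelse(agg$n_sites > 0, agg$inv_a / agg$n_sites, NA_real_)
  n_harm <- ifelse(agg$S > 0, agg$S / agg$inv_k, NA_real_)
  D <- mapply(tajima_d, S = agg$S, pi_abs = agg$pi_abs, n = n_harm)
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$end,
             theta = theta, tajima_d = D, S = agg$S, n_sites = agg$n_sites,
             pi_abs = agg$pi_abs, stringsAsFactors = FALSE)
}

#' Tajima's D from summary quantities
#'
#' Direct evaluation of the 1989 constants a1, a2, b1, b2, c1, c2, e1, e2 at
#' (possibly non-integer) sample size `n`.
#'
#' @param S number of segregating sites
#' @param pi_abs mean pairwise difference count (summed per-site pi)
#' @param n sample size in alleles (harmonic mean under missing data)
#' @return Tajima's D, or `NA` when `S` = 0 or `n` < 2
#' @export
tajima_d <- function(S, pi_abs, n) {
  if (is.na(S) || is.na(n) || S <= 0 || n < 2) return(NA_real_)
  a1 <- .harmonic(n - 1)
  a2 <- .harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_abs - S / a1) / denom
}

# harmonic numbers; accept non-integer upper limits by linear interpolation
# between floor and ceiling (exact at integers)
.harmonic <- function(x) {
  f <- function(k) vapply(k, function(m) if (m < 1) 0 else sum(1 / seq_len(m)), 0)
  lo <- floor(x); hi <- ceiling(x)
  w <- x - lo
  (1 - w) * f(lo) + w * f(hi)
}
.harmonic2 <- function(x) {
  f <- function(k) vapply(k, function(m) if (m < 1) 0 else sum(1 / seq_len(m)^2), 0)
  lo <- floor(x); hi <- ceiling(x)
  w <- x - lo
  (1 - w) * f(lo) + w * f(hi)
}

#' Windowed absolute divergence and Hudson's Fst between two populations
#'
#' Dxy is the ratio-of-sums of between-population allele-pair differences
#' over between-population pair counts (all sites). Fst is Hudson's
#' estimator aggregated as a ratio of sums over the window's variant sites:
#' `1 - sum(Hw) / sum(Hb)` with per-site within heterozygosity
#' `Hw = (h1 + h2)/2`, `h_i = a_i(k_i - a_i) / (k_i(k_i-1)/2)`, and between
#' heterozygosity `Hb = (a1(k2-a2) + a2(k1-a1)) / (k1 k2)`.
#'
#' @inheritParams windowed_pi
#' @param popA,popB the two population labels
#' @return data.frame per window: `chrom`, `start`, `end`, `dxy`, `fst`,
#'   `n_comp_between`, `n_sites`, `hw_sum`, `hb_sum`
#' @export
windowed_dxy_fst <- function(table, popmap, popA, popB, window = 100000) {
  ca <- .pop_cols(table, popmap, popA)
  cb <- .pop_cols(table, popmap, popB)
  A <- .allele_counts(table, ca)
  B <- .allele_counts(table, cb)
  w <- .site_windows(table, window)
  has <- A$an >= 1 & B$an >= 1
  diff_b <- A$ac * (B$an - B$ac) + B$ac * (A$an - A$ac)
  comp_b <- A$an * B$an
  # Hudson per-site components (need >= 2 alleles per pop)
  ok2 <- A$an >= 2 & B$an >= 2
  h1 <- ifelse(ok2, A$ac * (A$an - A$ac) / (A$an * (A$an - 1) / 2), 0)
  h2 <- ifelse(ok2, B$ac * (B$an - B$ac) / (B$an * (B$an - 1) / 2), 0)
  hb <- ifelse(ok2, diff_b / comp_b, 0)
  poly <- ok2 & (A$ac + B$ac > 0) & (A$ac + B$ac < A$an + B$an)
  agg <- .window_aggregate(w, cbind(
    diff_b = ifelse(has, diff_b, 0), comp_b = ifelse(has, comp_b, 0),
    hw = ifelse(poly, (h1 + h2) / 2, 0), hb = ifelse(poly, hb, 0),
    n_sites = as.numeric(has)))
  dxy <- ifelse(agg$comp_b > 0, agg$diff_b / agg$comp_b, NA_real_)
  fst <- ifelse(agg$hb > 0, 1 - agg$hw / agg$hb, NA_real_)
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$end,
             dxy = dxy, fst = fst, n_comp_between = agg$comp_b,
             n_sites = agg$n_sites, hw_sum = agg$hw, hb_sum = agg$hb,
             stringsAsFactors = FALSE)
}

#' Genome-wide summary with across-window standard errors
#'
#' Collapses windowed statistics to a single genome-wide value (ratio of
#' summed numerators/denominators, so it equals a one-pass computation) and
#' reports SE = SD across windows / sqrt(number of windows with data).
#'
#' @param wdf a data.frame from one of the `windowed_*` functions
#' @param stat column name to summarise (`"pi"`, `"theta"`, `"tajima_d"`,
#'   `"dxy"` or `"fst"`)
#' @return list with `value`, `se`, `n_windows`
#' @export
genome_stat <- function(wdf, stat) {
  x <- wdf[[stat]]
  ok <- !is.na(x)
  value <- switch(stat,
    pi = sum(wdf$pi * wdf$n_comp, na.rm = TRUE) / sum(wdf$n_comp[ok]),
    dxy = sum(wdf$dxy * wdf$n_comp_between, na.rm = TRUE) /
      sum(wdf$n_comp_between[ok]),
    fst = 1 - sum(wdf$hw_sum[ok]) / sum(wdf$hb_sum[ok]),
    theta = sum(wdf$theta * wdf$n_sites, na.rm = TRUE) / sum(wdf$n_sites[ok]),
    mean(x[ok]))
  list(value = value, se = stats::sd(x[ok]) / sqrt(sum(ok)),
       n_windows = sum(ok))
}

#' Per-sample heterozygosity and inbreeding coefficient
#'
#' Observed heterozygosity is the fraction of heterozygous calls among a
#' sample's non-missing variant-site calls. F_IS per sample is
#' `1 - O_het / E_het`, where `E_het` sums the bias-corrected expected
#' heterozygosity `2 p q * k/(k-1)` (p from the full cohort's non-missing
#' alleles at each of the sample's genotyped sites). The cohort F_IS is the
#' mean over samples.
#'
#' @param matrix a `genotype_matrix` (variant sites only)
#' @return data.frame per sample: `sample`, `het`, `f_is`, `n_called`; the
#'   cohort mean F_IS is attached as attribute `f_is_cohort`
#' @export
sample_het_fis <- function(matrix) {
  g <- unclass(matrix)
  n <- nrow(g)
  an <- 2 * colSums(!is.na(g))             # per-site allele number (cohort)
  ac <- colSums(g, na.rm = TRUE)
  p <- ifelse(an > 0, ac / an, NA_real_)
  ehet_site <- ifelse(an > 1, 2 * p * (1 - p) * an / (an - 1), NA_real_)
  res <- data.frame(sample = rownames(g), het = NA_real_, f_is = NA_real_,
                    n_called = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- !is.na(g[i, ]) & !is.na(ehet_site)
    nc <- sum(ok)
    res$n_called[i] <- nc
    if (nc == 0) next
    o_het <- sum(g[i, ok] == 1L)
    res$het[i] <- o_het / nc
    e_het <- sum(ehet_site[ok])
    res$f_is[i] <- if (e_het > 0) 1 - o_het / e_het else NA_real_
  }
  attr(res, "f_is_cohort") <- mean(res$f_is, na.rm = TRUE)
  res
}

# --- internal window machinery ------------------------------------------

.site_windows <- function(table, window) {
  idx <- (table$sites$pos - 1L) %/% as.integer(window)
  key <- paste(table$sites$chrom, idx, sep = "\r")
  list(key = key, chrom = table$sites$chrom, idx = idx, window = window)
}

.window_aggregate <- function(w, cols) {
  dt <- data.table::as.data.table(cols)
  dt[, `:=`(chrom = w$chrom, idx = w$idx)]
  agg <- dt[, lapply(.SD, sum), by = .(chrom, idx)]
  data.table::setorder(agg, chrom, idx)
  out <- as.data.frame(agg)
  out$start <- out$idx * w$window + 1
  out$end <- (out$idx + 1) * w$window
  out
}
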