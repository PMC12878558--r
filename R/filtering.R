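#' Filter cascade configuration
#'
#' Defaults reproduce the study-style cascade: site QUAL >= 20 (variant
#' records), heterozygous allele balance inside [0.25, 0.75], removal of
#' variant sites heterozygous in every genotyped sample, per-genotype depth
#' inside [3, sample mean + 3 SD] at all sites, and finally at most 10%
#' missing genotypes per site.
#'
#' @param min_qual minimum site QUAL for variant records
#' @param ab_low,ab_high allowed alt-fraction band for heterozygous calls
#' @param min_dp minimum per-genotype read depth
#' @param dp_sd_mult multiplier on the per-sample depth SD for the upper bound
#' @param max_site_missing maximum fraction of missing genotypes per site
#' @param drop_all_het drop variant sites whose every non-missing call is het
#' @param ab_site_mode if `TRUE`, an out-of-band het removes the whole site
#'   instead of masking the genotype
#' @param qual_invariant if `TRUE`, apply the QUAL rule to invariant records
#'   too (off by default: invariant records often lack meaningful QUAL)
#' @return list of class `filter_config`
#' @export
filter_config <- function(min_qual = 20, ab_low = 0.25, ab_high = 0.75,
                          min_dp = 3, dp_sd_mult = 3, max_site_missing = 0.10,
                          drop_all_het = TRUE, ab_site_mode = FALSE,
                          qual_invariant = FALSE) {
  if (!(ab_low >= 0 && ab_low < ab_high && ab_high <= 1))
    stop("need 0 <= ab_low < ab_high <= 1")
  if (max_site_missing < 0 || max_site_missing > 1)
    stop("max_site_missing must lie in [0, 1]")
  structure(list(min_qual = min_qual, ab_low = ab_low, ab_high = ab_high,
                 min_dp = min_dp, dp_sd_mult = dp_sd_mult,
                 max_site_missing = max_site_missing,
                 drop_all_het = drop_all_het, ab_site_mode = ab_site_mode,
                 qual_invariant = qual_invariant),
            class = "filter_config")
}

#' Per-sample upper depth thresholds
#'
#' Upper bound = sample mean DP + `dp_sd_mult` * sample SD of DP, computed
#' over all sites (variant and invariant) with a recorded depth. The SD is
#' the population SD (divisor n), matching the genome-wide moment
#' convention of per-sample depth summaries.
#'
#' @param table a `variant_table` with a DP matrix
#' @param dp_sd_mult SD multiplier (default 3)
#' @return named numeric vector of upper bounds, one per sample, with the
#'   per-sample means and SDs attached as attributes
#' @export
compute_depth_thresholds <- function(table, dp_sd_mult = 3) {
  if (is.null(table$dp)) stop("table has no DP matrix")
  n_ok <- colSums(!is.na(table$dp))
  if (any(n_ok == 0))
    stop("no DP values for sample(s): ",
         paste(table$samples[n_ok == 0], collapse = ", "))
  mu <- colMeans(table$dp, na.rm = TRUE)
  sd_pop <- sqrt(colMeans(sweep(table$dp, 2, mu)^2, na.rm = TRUE))
  structure(setNames(mu + dp_sd_mult * sd_pop, table$samples),
            mean = mu, sd = sd_pop)
}

#' Apply the filter cascade to an all-sites table
#'
#' Rules run in this order: (1) variant-site QUAL below `min_qual` removes
#' the site; (2) heterozygous calls with alt-read fraction outside
#' [`ab_low`, `ab_high`] are masked (or remove the site in `ab_site_mode`);
#' a het call without AD counts as failing; (3) variant sites whose every
#' remaining call is heterozygous are removed; (4) genotypes with DP below
#' `min_dp` or above the per-sample bound are masked at all sites;
#' (5) sites with more than `max_site_missing` missing genotypes are removed.
#'
#' The per-sample depth thresholds are estimated once, from the table as it
#' enters the depth rule, and attached to the returned table (attribute
#' `dp_thresholds`); re-filtering a filtered table reuses them, so the
#' cascade is idempotent (thresholds are genome-wide sample properties, not
#' quantities to re-estimate on a filtered subset).
#'
#' @param table a `variant_table`
#' @param cfg a [filter_config()]
#' @param thresholds optional named per-sample upper depth bounds (as from
#'   [compute_depth_thresholds()]), overriding estimation
#' @return list with `table` (filtered) and `report` (class `filter_report`:
#'   ordered per-rule site/genotype counts, thresholds, site totals)
#' @export
filter_variants <- function(table, cfg = filter_config(), thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- attr(table, "dp_thresholds")
  stopifnot(inherits(table, "variant_table"))
  if (!inherits(cfg, "filter_config")) stop("cfg must be a filter_config")
  n0 <- n_sites(table)
  rules <- list()

  # (1) QUAL
  vs <- is_variant_site(table)
  qual_fail <- !is.na(table$sites$qual) & table$sites$qual < cfg$min_qual &
    (vs | cfg$qual_invariant)
  rules$qual <- list(sites_removed = sum(qual_fail), genotypes_masked = 0L)
  if (any(qual_fail)) table <- subset_sites(table, !qual_fail)

  # (2) allele balance on het calls at variant sites
  vs <- is_variant_site(table)
  ab_mask <- 0L; ab_sites <- 0L
  if (any(vs)) {
    het <- !is.na(table$gt) & table$gt == 1L & vs
    if (is.null(table$ad_alt) || is.null(table$dp)) {
      fail <- het  # no AD recorded: every het fails (conservative)
      if (any(het)) message("AD/DP absent: all ", sum(het),
                            " het calls fail the allele-balance rule")
    } else {
      frac <- table$ad_alt / table$dp
      fail <- het & (is.na(frac) | frac < cfg$ab_low | frac > cfg$ab_high)
    }
    if (cfg$ab_site_mode) {
      bad_sites <- rowSums(fail, na.rm = TRUE) > 0L
      ab_sites <- sum(bad_sites)
      if (ab_sites) table <- subset_sites(table, !bad_sites)
    } else {
      ab_mask <- sum(fail, na.rm = TRUE)
      # only the call is voided; DP stays (depth thresholds are genome-wide
      # observed-depth summaries, independent of call masking)
      table$gt[fail] <- NA_integer_
    }
  }
  rules$allele_balance <- list(sites_removed = ab_sites, genotypes_masked = ab_mask)

  # (3) all-heterozygous variant sites
  all_het_removed <- 0L
  if (cfg$drop_all_het) {
    vs <- is_variant_site(table)
    n_called <- rowSums(!is.na(table$gt))
    n_het <- rowSums(table$gt == 1L, na.rm = TRUE)
    bad <- vs & n_called > 0L & n_het == n_called
    all_het_removed <- sum(bad)
    if (any(bad)) table <- subset_sites(table, !bad)
  }
  rules$all_het <- list(sites_removed = all_het_removed, genotypes_masked = 0L)

  # (4) depth masking at all sites
  dp_mask <- 0L
  if (!is.null(table$dp)) {
    if (is.null(thresholds))
      thresholds <- compute_depth_thresholds(table, cfg$dp_sd_mult)
    upper <- matrix(thresholds, nrow = n_sites(table),
                    ncol = length(table$samples), byrow = TRUE)
    fail <- !is.na(table$dp) & (table$dp < cfg$min_dp | table$dp > upper)
    fail <- fail & !is.na(table$gt)
    dp_mask <- sum(fail)
    table$gt[fail] <- NA_integer_
  }
  rules$depth <- list(sites_removed = 0L, genotypes_masked = dp_mask)

  # (5) site missingness
  miss_frac <- rowMeans(is.na(table$gt))
  bad <- miss_frac > cfg$max_site_missing
  rules$missingness <- list(sites_removed = sum(bad), genotypes_masked = 0L)
  if (any(bad)) table <- subset_sites(table, !bad)

  report <- structure(list(rules = rules, thresholds = thresholds,
                           n_input = n0, n_retained = n_sites(table),
                           config = cfg),
                      class = "filter_report")
  if (!is.null(thresholds)) attr(table, "dp_thresholds") <- thresholds
  list(table = table, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in, %d retained (%d removed)\n",
              x$n_input, x$n_retained, x$n_input - x$n_retained))
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  %-14s sites removed %7d   genotypes masked %9d\n",
                nm, r$sites_removed, r$genotypes_masked))
  }
  invisible(x)
}

#' Serialise a filter report to JSON
#' @param report a `filter_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(report, path) {
  out <- list(n_input = report$n_input, n_retained = report$n_retained,
              rules = report$rules,
              thresholds = if (!is.null(report$thresholds))
                as.list(unclass(report$thresholds)[seq_along(report$thresholds)]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
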