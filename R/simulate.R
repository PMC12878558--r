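#' Configuration for the two-deme coalescent simulator
#'
#' Defaults follow the demographic scales of the fitted models for the focal
#' species pair: ancestral and daughter diploid effective sizes in the
#' 10^3-10^4 range, divergence a few hundred generations ago, backward
#' migration probabilities within the soft bounds 1e-4..0.1, and a
#' basidiomycete-style mutation rate of 1e-8..1e-7 per site per generation.
#'
#' @param n_samples_per_pop diploid individuals per deme
#' @param Ne_anc,Ne_1,Ne_2 diploid effective population sizes (ancestral,
#'   deme 1, deme 2)
#' @param T_div divergence time in generations (0 collapses to panmixia)
#' @param m_12,m_21 per-generation backward migration probabilities
#'   (lineage in deme 1 traces to deme 2 at rate `m_12`, and vice versa)
#' @param mu mutation rate per site per generation
#' @param seq_length bp per locus
#' @param n_loci number of independent loci (one synthetic contig each)
#' @param seed RNG seed (integer)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_samples_per_pop = 15, Ne_anc = 5000, Ne_1 = 5000,
                       Ne_2 = 5000, T_div = 500, m_12 = 0.01, m_21 = 0.01,
                       mu = 1e-7, seq_length = 10000, n_loci = 20,
                       seed = 1L) {
  cfg <- list(n_samples_per_pop = n_samples_per_pop, Ne_anc = Ne_anc,
              Ne_1 = Ne_1, Ne_2 = Ne_2, T_div = T_div, m_12 = m_12,
              m_21 = m_21, mu = mu, seq_length = seq_length,
              n_loci = n_loci, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples_per_pop < 1) stop("n_samples_per_pop must be positive")
    if (any(c(Ne_anc, Ne_1, Ne_2) <= 0)) stop("effective sizes must be positive")
    if (m_12 < 0 || m_12 >= 1 || m_21 < 0 || m_21 >= 1)
      stop("migration probabilities must lie in [0, 1)")
    if (T_div < 0) stop("T_div must be >= 0")
    if (mu < 0) stop("mu must be >= 0")
    if (seq_length < 1) stop("seq_length must be positive")
    if (n_loci < 1) stop("n_loci must be positive (zero loci is a configuration error)")
  })
  invisible(cfg)
}

#' Simulate an all-sites dataset under a two-deme isolation-with-migration
#' history
#'
#' Draws independent structured-coalescent genealogies per locus (exponential
#' waiting times; pairwise coalescence at rate k(k-1)/(4 Ne) per generation
#' within a deme, backward migration at rate k m; single ancestral deme older
#' than `T_div`), places infinite-sites mutations as a Poisson process of
#' rate `branch_length * mu * seq_length` at uniform distinct positions, and
#' pairs haplotypes within each deme into diploid genotypes. Haplotypes are
#' exchangeable within a deme, so consecutive pairing realises random pairing.
#'
#' @param config a [sim_config()]
#' @param materialize_invariant if `TRUE` (default) invariant sites appear as
#'   explicit rows (dosage 0), as in an all-sites VCF; if `FALSE` only
#'   variant rows are materialised while `contig_lengths` still records the
#'   full simulated span (sufficient for SFS building on clean data)
#' @return a [variant_table()]; samples are named `P1_01.., P2_01..`; an
#'   attribute `popmap` holds the sample-to-deme map
#' @export
simulate_coalescent_dataset <- function(config, materialize_invariant = TRUE) {
  .validate_sim_config(config)
  set.seed(config$seed)
  n_ind <- config$n_samples_per_pop
  n_hap <- 2L * n_ind                       # haploid sample size per deme
  samples <- c(sprintf("P1_%02d", seq_len(n_ind)),
               sprintf("P2_%02d", seq_len(n_ind)))
  hap_pop <- rep(1:2, each = n_hap)         # deme of haplotype 1..2*n_hap

  per_locus <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    sim <- .coal_sim_locus(n_hap, n_hap, config$Ne_1, config$Ne_2,
                           config$Ne_anc, config$T_div, config$m_12,
                           config$m_21, config$mu, config$seq_length)
    pos <- sim$pos
    o <- order(pos)
    pos <- pos[o]
    # dosage: individual i of deme d owns haplotypes (2i-1, 2i) of that deme
    ns <- length(pos)
    gt <- matrix(0L, nrow = ns, ncol = 2L * n_ind)
    if (ns > 0) {
      for (s in seq_len(ns)) {
        carriers <- sim$carriers[[o[s]]]   # haplotype ids 1..2*n_hap
        ind <- (carriers + 1L) %/% 2L      # 1..n_hap within pooled numbering
        # haplotypes 1..n_hap are deme 1 -> individuals 1..n_ind;
        # haplotypes n_hap+1..2 n_hap are deme 2 -> individuals n_ind+1..2 n_ind
        tb <- tabulate(ind, nbins = 2L * n_ind)
        gt[s, ] <- as.integer(tb)
      }
    }
    per_locus[[l]] <- list(pos = pos, gt = gt)
  }

  chrom_names <- sprintf("contig_%03d", seq_len(config$n_loci))
  contig_lengths <- setNames(rep(as.numeric(config$seq_length), config$n_loci),
                             chrom_names)
  if (materialize_invariant) {
    sl <- config$seq_length
    chrom <- rep(chrom_names, each = sl)
    pos <- rep.int(seq_len(sl), config$n_loci)
    alt <- rep(NA_character_, length(pos))
    gt <- matrix(0L, nrow = length(pos), ncol = 2L * n_ind)
    for (l in seq_len(config$n_loci)) {
      pl <- per_locus[[l]]
      if (length(pl$pos)) {
        rows <- (l - 1L) * sl + pl$pos
        alt[rows] <- "T"
        gt[rows, ] <- pl$gt
      }
    }
  } else {
    chrom <- rep(chrom_names, vapply(per_locus, function(p) length(p$pos), 1L))
    pos <- unlist(lapply(per_locus, `[[`, "pos"), use.names = FALSE)
    if (is.null(pos)) pos <- integer(0)
    alt <- rep("T", length(pos))
    gt <- do.call(rbind, lapply(per_locus, `[[`, "gt"))
    if (is.null(gt)) gt <- matrix(0L, 0, 2L * n_ind)
  }
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep("A", length(pos)), alt = alt,
                      qual = rep(99, length(pos)), stringsAsFactors = FALSE)
  vt <- variant_table(sites, gt, samples, contig_lengths = contig_lengths)
  attr(vt, "popmap") <- data.frame(
    sample = samples, population = paste0("pop", rep(1:2, each = n_ind)),
    stringsAsFactors = FALSE)
  vt
}

#' Default popmap of a simulated dataset
#' @param table a `variant_table` from [simulate_coalescent_dataset()]
#' @return data.frame with columns `sample`, `population`
#' @export
sim_popmap <- function(table) {
  pm <- attr(table, "popmap")
  if (is.null(pm)) stop("table carries no popmap attribute")
  pm
}

#' Configuration for sequencing-artifact injection
#'
#' Emulates the data features the filter cascade is designed to remove:
#' negative-binomial per-genotype depth around a per-sample mean, binomial
#' allele balance on heterozygous calls with an optional aberrant fraction
#' forced outside the 0.25-0.75 band, site QUAL drawn around a high mode
#' with a low-quality fraction, and uniform genotype missingness.
#'
#' @param mean_depth per-sample mean read depth (recycled over samples)
#' @param depth_dispersion negative-binomial size parameter (larger = tighter)
#' @param qual_mean,qual_sd Gaussian site QUAL parameters
#' @param low_qual_fraction fraction of variant sites assigned QUAL below 20
#' @param aberrant_ab_fraction fraction of het calls forced outside [0.25, 0.75]
#' @param genotype_missing_rate probability a genotype is dropped
#' @param ab_noise if `TRUE` (default) het allele depths are binomial(DP, 0.5),
#'   so a small fraction naturally falls outside the allele-balance band; set
#'   `FALSE` for the idealised artifact-free dataset (AD exactly balanced)
#'   under which the filter cascade provably removes nothing
#' @param seed RNG seed
#' @return list of class `artifact_config`
#' @export
artifact_config <- function(mean_depth = 20, depth_dispersion = 10,
                            qual_mean = 60, qual_sd = 10,
                            low_qual_fraction = 0, aberrant_ab_fraction = 0,
                            genotype_missing_rate = 0, ab_noise = TRUE,
                            seed = 1L) {
  rates <- c(low_qual_fraction, aberrant_ab_fraction, genotype_missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(mean_depth < 0)) stop("depth must be >= 0")
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 low_qual_fraction = low_qual_fraction,
                 aberrant_ab_fraction = aberrant_ab_fraction,
                 genotype_missing_rate = genotype_missing_rate,
                 ab_noise = ab_noise, seed = as.integer(seed)),
            class = "artifact_config")
}

#' Overlay sequencing artifacts on a clean simulated table
#'
#' Adds DP (negative binomial around the sample mean), AD for variant-site
#' calls (binomial(DP, 0.5) allele balance for hets unless forced aberrant),
#' site QUAL, and genotype missingness. The clean truth dosages are kept in
#' attribute `truth_gt` for recovery tests.
#'
#' @param truth a `variant_table` with complete (non-missing) genotypes
#' @param config an [artifact_config()]
#' @return a `variant_table` with `dp`, `ad_alt` and perturbed `gt`/`qual`
#' @export
apply_sequencing_artifacts <- function(truth, config) {
  stopifnot(inherits(truth, "variant_table"), inherits(config, "artifact_config"))
  if (anyNA(truth$gt)) stop("truth table must not contain missing genotypes")
  set.seed(config$seed)
  ns <- n_sites(truth); np <- length(truth$samples)
  mean_depth <- rep_len(config$mean_depth, np)

  dp <- matrix(0L, ns, np)
  for (j in seq_len(np)) {
    # infinite dispersion = noise-free constant depth (the "clean" setting
    # under which the filter cascade must retain everything)
    dp[, j] <- if (is.infinite(config$depth_dispersion))
      rep(as.integer(round(mean_depth[j])), ns)
    else as.integer(rnbinom(ns, size = config$depth_dispersion,
                            mu = mean_depth[j]))
  }
  gt <- truth$gt
  ad <- matrix(NA_integer_, ns, np)
  vs <- is_variant_site(truth)
  # allele-supporting depths at variant sites
  if (any(vs)) {
    vidx <- which(vs)
    gv <- gt[vidx, , drop = FALSE]
    dv <- dp[vidx, , drop = FALSE]
    adv <- matrix(0L, length(vidx), np)
    adv[gv == 2L] <- dv[gv == 2L]
    het <- which(gv == 1L)
    if (length(het)) {
      adh <- if (config$ab_noise) rbinom(length(het), dv[het], 0.5)
             else as.integer(round(dv[het] / 2))
      if (config$aberrant_ab_fraction > 0) {
        force <- runif(length(het)) < config$aberrant_ab_fraction
        # push forced calls outside [0.25, 0.75]: keep < 25% or > 75% of DP
        lo <- runif(sum(force)) < 0.5
        dph <- dv[het][force]
        adh[force] <- ifelse(lo, pmax(0L, floor(dph * 0.25) - 1L),
                             pmin(dph, ceiling(dph * 0.75) + 1L))
        # degenerate small depths can land on the boundary; nudge to extremes
        frac <- ifelse(dph > 0, adh[force] / dph, 0)
        bad <- frac >= 0.25 & frac <= 0.75
        adh[force][bad] <- ifelse(lo[bad], 0L, dph[bad])
      }
      adv[het] <- as.integer(adh)
    }
    ad[vidx, ] <- adv
  }
  qual <- truth$sites$qual
  qv <- rnorm(sum(vs), config$qual_mean, config$qual_sd)
  if (config$low_qual_fraction > 0) {
    low <- runif(sum(vs)) < config$low_qual_fraction
    qv[low] <- runif(sum(low), 0, 19.9)
  }
  qual[vs] <- pmax(0, round(qv, 1))

  if (config$genotype_missing_rate > 0) {
    drop <- matrix(runif(ns * np) < config$genotype_missing_rate, ns, np)
    gt[drop] <- NA_integer_
    dp[drop] <- NA_integer_
    ad[drop] <- NA_integer_
  }
  sites <- truth$sites
  sites$qual <- qual
  out <- variant_table(sites, gt, truth$samples, dp = dp, ad_alt = ad,
                       contig_lengths = truth$contig_lengths)
  attr(out, "truth_gt") <- truth$gt
  attr(out, "popmap") <- attr(truth, "popmap")
  out
}

#' Configuration for coordinates and environment simulation
#'
#' Coordinates are spread uniformly over the configured ranges (default:
#' roughly the European latitudinal span of the study system). Each
#' environment variable is `slope * latitude + Gaussian noise`, emulating
#' bioclimatic predictors that track the latitudinal gradient. Optional
#' adaptive loci receive allele-frequency clines along latitude.
#'
#' @param lat_range,lon_range coordinate ranges in decimal degrees
#' @param n_env_vars number of environment variables
#' @param slopes per-variable slope against latitude (recycled)
#' @param noise_sd Gaussian noise SD added to each variable (recycled)
#' @param n_adaptive_loci loci to receive an allele-frequency cline
#' @param effect_size allele-frequency range of the cline across the
#'   latitudinal span (1 = frequency sweeps 0 to 1)
#' @param adaptive_var index of the variable whose gradient drives the cline
#' @param seed RNG seed
#' @return list of class `env_config`
#' @export
env_config <- function(lat_range = c(42, 68), lon_range = c(5, 30),
                       n_env_vars = 4, slopes = c(1, -0.8, 0.5, 0.2),
                       noise_sd = 1, n_adaptive_loci = 0, effect_size = 0.8,
                       adaptive_var = 1, seed = 1L) {
  if (n_env_vars < 1) stop("n_env_vars must be >= 1")
  if (any(noise_sd < 0)) stop("noise SD must be >= 0")
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 n_env_vars = n_env_vars, slopes = slopes,
                 noise_sd = noise_sd, n_adaptive_loci = n_adaptive_loci,
                 effect_size = effect_size, adaptive_var = adaptive_var,
                 seed = as.integer(seed)),
            class = "env_config")
}

#' Simulate coordinates, environment variables and optional adaptive loci
#'
#' @param samples character vector of sample ids, or a `genotype_matrix`
#'   (required when `n_adaptive_loci > 0`, so clines can be planted)
#' @param config an [env_config()]
#' @return list with `coords` (data.frame sample/lat/lon), `env` (data.frame,
#'   one column per variable `env1..`), and when a matrix was supplied,
#'   `matrix` (dosages with planted clines) and `adaptive_idx`
#' @export
simulate_environment <- function(samples, config) {
  stopifnot(inherits(config, "env_config"))
  geno <- NULL
  if (inherits(samples, "genotype_matrix") || is.matrix(samples)) {
    geno <- samples
    samples <- rownames(geno)
  }
  if (!length(samples)) stop("sample list must be non-empty")
  set.seed(config$seed)
  n <- length(samples)
  lat <- runif(n, config$lat_range[1], config$lat_range[2])
  lon <- runif(n, config$lon_range[1], config$lon_range[2])
  slopes <- rep_len(config$slopes, config$n_env_vars)
  noise <- rep_len(config$noise_sd, config$n_env_vars)
  env <- sapply(seq_len(config$n_env_vars), function(v)
    slopes[v] * lat + rnorm(n, 0, noise[v]))
  env <- as.data.frame(env)
  names(env) <- paste0("env", seq_len(config$n_env_vars))
  rownames(env) <- samples
  out <- list(coords = data.frame(sample = samples, lat = lat, lon = lon,
                                  stringsAsFactors = FALSE),
              env = env)
  if (config$n_adaptive_loci > 0) {
    if (is.null(geno))
      stop("a genotype matrix is required to plant adaptive loci")
    if (config$n_adaptive_loci > ncol(geno))
      stop("n_adaptive_loci exceeds the number of variant loci")
    idx <- sort(sample.int(ncol(geno), config$n_adaptive_loci))
    lat_scaled <- (lat - mean(config$lat_range)) / diff(config$lat_range)
    p <- pmin(0.98, pmax(0.02, 0.5 + config$effect_size * lat_scaled))
    for (j in idx) geno[, j] <- rbinom(n, 2L, p)
    storage.mode(geno) <- "integer"
    out$matrix <- geno
    out$adaptive_idx <- idx
  }
  out
}
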