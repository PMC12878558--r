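#' Runs-of-homozygosity parameters
#'
#' Defaults follow the study rule set: a run must contain at least 100 SNPs,
#' span at least 100 kb and keep a density of at least one SNP per 50 kb
#' (span / SNP count <= 50,000). By default no heterozygote is tolerated
#' inside a run; missing genotypes are skipped without breaking a run.
#'
#' @param min_snps minimum SNP count per run
#' @param min_length_bp minimum run span in bp
#' @param max_bp_per_snp density bound (span / SNPs)
#' @param max_het_in_run heterozygous calls tolerated inside a run
#' @return list of class `roh_params`
#' @export
roh_params <- function(min_snps = 100, min_length_bp = 100000,
                       max_bp_per_snp = 50000, max_het_in_run = 0) {
  if (any(c(min_snps, min_length_bp, max_bp_per_snp) <= 0) ||
      max_het_in_run < 0)
    stop("ROH parameters must be positive (max_het_in_run >= 0)")
  structure(list(min_snps = min_snps, min_length_bp = min_length_bp,
                 max_bp_per_snp = max_bp_per_snp,
                 max_het_in_run = max_het_in_run), class = "roh_params")
}

#' Detect runs of homozygosity in one sample's genotypes
#'
#' Scans variant sites sorted by position within a contig for maximal runs
#' of consecutive homozygous genotypes containing at most `max_het_in_run`
#' heterozygotes (missing calls are skipped), then keeps runs meeting the
#' SNP-count, span and density requirements. Overlapping qualifying runs
#' (possible when heterozygotes are tolerated) are merged, so reported
#' intervals are sorted and non-overlapping.
#'
#' @param genotypes integer dosage vector (0/1/2, `NA` missing) for one sample
#' @param positions 1-based positions, strictly increasing
#' @param params a [roh_params()]
#' @return data.frame: `start`, `end`, `n_snps` (one row per ROH)
#' @export
detect_roh <- function(genotypes, positions, params = roh_params()) {
  stopifnot(length(genotypes) == length(positions))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing (sort within contig first)")
  keep <- !is.na(genotypes)
  g <- genotypes[keep]; pos <- positions[keep]
  n <- length(g)
  empty <- data.frame(start = numeric(0), end = numeric(0), n_snps = integer(0))
  if (n == 0) return(empty)
  is_het <- g == 1L
  H <- params$max_het_in_run
  # two-pointer: rightmost end for each start with <= H hets
  r <- 0L; hets <- 0L
  right <- integer(n)
  for (l in seq_len(n)) {
    if (r < l) { r <- l - 1L; hets <- 0L }
    while (r < n && hets + (if (r < n) is_het[r + 1L] else 0L) <= H) {
      r <- r + 1L
      hets <- hets + is_het[r]
    }
    right[l] <- r
    hets <- hets - is_het[l]
  }
  # for each start, the furthest end whose window qualifies on SNP count,
  # span and density (the rules are not monotone in the end, so every
  # admissible end is checked, vectorised per start)
  cand <- matrix(numeric(0), 0, 3)
  for (l in seq_len(n)) {
    r0 <- l + as.integer(params$min_snps) - 1L
    if (r0 > right[l]) next
    rs <- r0:right[l]
    span <- pos[rs] - pos[l] + 1
    nsnp <- rs - l + 1L
    ok <- span >= params$min_length_bp & span / nsnp <= params$max_bp_per_snp
    if (!any(ok)) next
    rbest <- rs[max(which(ok))]
    cand <- rbind(cand, c(l, rbest, 0))
  }
  if (!nrow(cand)) return(empty)
  # drop windows contained in an earlier (smaller start) window
  keep_w <- cand[, 2] > c(-Inf, cummax(cand[, 2]))[seq_len(nrow(cand))]
  cand <- cand[keep_w, , drop = FALSE]
  iv <- cbind(pos[cand[, 1]], pos[cand[, 2]], cand[, 2] - cand[, 1] + 1)
  out <- data.frame(start = iv[, 1], end = iv[, 2], n_snps = as.integer(iv[, 3]))
  out <- out[order(out$start), , drop = FALSE]
  # merge overlaps
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    last <- nrow(merged)
    if (out$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], out$end[i])
      merged$n_snps[last] <- sum(pos >= merged$start[last] & pos <= merged$end[last])
    } else merged <- rbind(merged, out[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' ROH-based inbreeding coefficient
#'
#' @param intervals data.frame from [detect_roh()] (possibly concatenated
#'   over contigs)
#' @param genome_size total genome length in bp (default 33 Mb, the focal
#'   reference assembly size)
#' @return total ROH span divided by genome size
#' @export
froh <- function(intervals, genome_size = 33e6) {
  if (!nrow(intervals)) return(0)
  sum(intervals$end - intervals$start + 1) / genome_size
}

#' ROH and F_ROH for every sample of a table
#'
#' @param table a filtered `variant_table`
#' @param params a [roh_params()]
#' @param genome_size genome length in bp for F_ROH
#' @return list with `intervals` (data.frame sample/chrom/start/end/n_snps)
#'   and `froh` (named vector per sample)
#' @export
roh_all_samples <- function(table, params = roh_params(), genome_size = 33e6) {
  vs <- which(is_variant_site(table))
  ivs <- list()
  fr <- setNames(numeric(length(table$samples)), table$samples)
  for (s in seq_along(table$samples)) {
    per_sample <- list()
    for (ctg in unique(table$sites$chrom[vs])) {
      i <- vs[table$sites$chrom[vs] == ctg]
      r <- detect_roh(table$gt[i, s], table$sites$pos[i], params)
      if (nrow(r)) per_sample[[ctg]] <- cbind(chrom = ctg, r)
    }
    if (length(per_sample)) {
      d <- do.call(rbind, per_sample)
      d <- cbind(sample = table$samples[s], d)
      ivs[[s]] <- d
      fr[s] <- froh(d, genome_size)
    }
  }
  intervals <- if (length(ivs)) do.call(rbind, ivs) else
    data.frame(sample = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_snps = integer(0))
  rownames(intervals) <- NULL
  list(intervals = intervals, froh = fr)
}
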