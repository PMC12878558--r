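# Small hand-buildable fixtures used across test files.

# a variant_table from a dosage matrix (sites x samples); invariant sites
# are rows of NA alt via `alt`
make_table <- function(gt, pos = seq_len(nrow(gt)), chrom = "c1",
                       alt = NULL, qual = 99, dp = NULL, ad_alt = NULL,
                       contig_lengths = NULL) {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  samples <- sprintf("s%02d", seq_len(ncol(gt)))
  if (is.null(alt)) alt <- rep("T", ns)
  sites <- data.frame(chrom = rep_len(chrom, ns), pos = pos,
                      ref = rep("A", ns), alt = alt,
                      qual = rep_len(qual, ns), stringsAsFactors = FALSE)
  variant_table(sites, gt, samples, dp = dp, ad_alt = ad_alt,
                contig_lengths = contig_lengths)
}

make_popmap <- function(samples, split = length(samples) %/% 2) {
  data.frame(sample = samples,
             population = rep(c("A", "B"), c(split, length(samples) - split)),
             stringsAsFactors = FALSE)
}

# genotype_matrix from a plain matrix (samples x sites)
make_gm <- function(m, pos = seq_len(ncol(m)), chrom = "c1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  structure(m, chrom = rep_len(chrom, ncol(m)), pos = pos,
            class = c("genotype_matrix", class(m)))
}

# brute-force per-site pairwise difference counts for pi/dxy oracles
oracle_pi_site <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  if (length(a) < 2) return(c(diff = NA, comp = NA))
  pairs <- utils::combn(length(a), 2)
  c(diff = sum(a[pairs[1, ]] != a[pairs[2, ]]), comp = ncol(pairs))
}

# expand dosages (one site, one population) into alleles
dosage_to_alleles <- function(g) {
  out <- c()
  for (x in g) {
    if (is.na(x)) out <- c(out, NA, NA)
    else out <- c(out, c(0, 0, 0)[0], if (x == 0) c(0, 0) else if (x == 1) c(0, 1) else c(1, 1))
  }
  out
}
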