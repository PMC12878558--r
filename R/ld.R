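#' Linkage-disequilibrium decay curve
#'
#' Genotype r-squared (squared Pearson correlation of dosage vectors,
#' pairwise-complete) for all variant-site pairs on the same contig within
#' `max_dist` bp, summarised as mean r^2 per distance bin. Pairs involving a
#' zero-variance dosage vector are skipped and counted.
#'
#' @param matrix a `genotype_matrix`
#' @param max_dist maximum pair distance in bp (default 10,000)
#' @param bin reporting bin width in bp (default 5,000)
#' @return data.frame: `bin_start`, `bin_mid`, `mean_r2`, `n_pairs`, with
#'   attribute `n_skipped` (zero-variance pairs)
#' @export
ld_decay <- function(matrix, max_dist = 10000, bin = 5000) {
  g <- unclass(matrix)
  chrom <- attr(matrix, "chrom"); pos <- attr(matrix, "pos")
  if (ncol(g) < 2) stop("need >= 2 variant sites")
  d_all <- numeric(0); r2_all <- numeric(0); skipped <- 0L
  for (ctg in unique(chrom)) {
    j <- which(chrom == ctg)
    if (length(j) < 2) next
    pj <- pos[j]
    for (a in seq_len(length(j) - 1)) {
      b <- which(pj > pj[a] & pj - pj[a] <= max_dist)
      b <- b[b > a]
      for (k in b) {
        r <- suppressWarnings(cor(g[, j[a]], g[, j[k]],
                                  use = "pairwise.complete.obs"))
        if (is.na(r)) { skipped <- skipped + 1L; next }
        d_all <- c(d_all, pj[k] - pj[a])
        r2_all <- c(r2_all, r^2)
      }
    }
  }
  if (!length(d_all)) {
    out <- data.frame(bin_start = numeric(0), bin_mid = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0))
    attr(out, "n_skipped") <- skipped
    return(out)
  }
  bins <- (d_all - 1) %/% bin
  agg <- tapply(r2_all, bins, mean)
  cnt <- tapply(r2_all, bins, length)
  b0 <- as.numeric(names(agg)) * bin
  out <- data.frame(bin_start = b0 + 1, bin_mid = b0 + bin / 2,
                    mean_r2 = as.numeric(agg), n_pairs = as.integer(cnt))
  attr(out, "n_skipped") <- skipped
  out
}

#' Sliding-window LD pruning
#'
#' Within each window of `window` SNPs (advanced by `step` SNPs), any pair of
#' still-retained SNPs with genotype r^2 above `r2_max` loses its later
#' member (the first-encountered SNP is kept). Removal is global and
#' permanent, mirroring the standard 50/5/0.2 pruning recipe.
#'
#' @param matrix a `genotype_matrix` (sites ordered by position)
#' @param window window size in SNPs
#' @param step window shift in SNPs
#' @param r2_max maximum tolerated r^2
#' @return integer vector of retained column indices
#' @export
ld_prune <- function(matrix, window = 50, step = 5, r2_max = 0.2) {
  g <- unclass(matrix)
  p <- ncol(g)
  keep <- rep(TRUE, p)
  if (p < 2) return(seq_len(p))
  starts <- seq(1L, max(1L, p - 1L), by = step)
  for (s in starts) {
    e <- min(p, s + window - 1L)
    idx <- which(keep[s:e]) + s - 1L
    if (length(idx) < 2) next
    for (a in seq_len(length(idx) - 1)) {
      ia <- idx[a]
      if (!keep[ia]) next
      for (b in (a + 1):length(idx)) {
        ib <- idx[b]
        if (!keep[ib]) next
        r <- suppressWarnings(cor(g[, ia], g[, ib],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) keep[ib] <- FALSE
      }
    }
    if (e == p) break
  }
  which(keep)
}
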