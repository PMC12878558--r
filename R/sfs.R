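#' Folded joint site-frequency spectrum with hypergeometric projection
#'
#' Each site's observed alt-allele counts are projected down to haploid
#' sample sizes (n1, n2) by the hypergeometric expectation: a site with a
#' alt copies among k non-missing alleles contributes mass
#' `dhyper(i, a, k - a, n1)` to row i (and analogously for columns). Sites
#' with fewer genotyped alleles than the projection in either population are
#' excluded and counted. Cells are folded by the global minor allele: mass
#' at (i, j) with i + j > (n1 + n2)/2 is added to (n1 - i, n2 - j); on the
#' fold diagonal the canonical cell (smaller row index) receives the mass.
#' The (0, 0) cell accumulates invariant sites (and projections landing on
#' zero copies).
#'
#' @param table an all-sites `variant_table` (filtered). If the table was
#'   simulated without materialised invariant rows, the monomorphic count is
#'   inferred from `contig_lengths` (valid when no sites were removed).
#' @param popmap data.frame `sample`/`population`
#' @param pops character(2): the two population labels (row, column)
#' @param projection integer(2): haploid sizes (n1, n2); default the largest
#'   full-coverage projection, i.e. 2 x sample count per population
#' @return list of class `joint_sfs`: `counts` ((n1+1) x (n2+1), folded,
#'   upper fold zero), `n1`, `n2`, `n_sites` (usable total incl. monomorphic),
#'   `n_excluded`
#' @export
build_folded_joint_sfs <- function(table, popmap, pops, projection = NULL) {
  c1 <- .pop_cols(table, popmap, pops[1])
  c2 <- .pop_cols(table, popmap, pops[2])
  if (is.null(projection)) projection <- c(2L * length(c1), 2L * length(c2))
  n1 <- projection[1]; n2 <- projection[2]
  if (n1 > 2 * length(c1) || n2 > 2 * length(c2))
    stop("projection exceeds 2 x samples in a population")
  A <- .allele_counts(table, c1)
  B <- .allele_counts(table, c2)
  vs <- is_variant_site(table)
  usable <- A$an >= n1 & B$an >= n2
  if (!any(usable)) stop("projection larger than every site's genotyped sample")
  S <- matrix(0, n1 + 1, n2 + 1)
  vidx <- which(vs & usable)
  if (length(vidx)) {
    # sites sharing an allele-count configuration share projection weights
    key <- paste(A$ac[vidx], A$an[vidx], B$ac[vidx], B$an[vidx])
    tab <- table(key)
    cfgs <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    storage.mode(cfgs) <- "numeric"
    for (r in seq_len(nrow(cfgs))) {
      w1 <- stats::dhyper(0:n1, cfgs[r, 1], cfgs[r, 2] - cfgs[r, 1], n1)
      w2 <- stats::dhyper(0:n2, cfgs[r, 3], cfgs[r, 4] - cfgs[r, 3], n2)
      S <- S + as.numeric(tab[r]) * outer(w1, w2)
    }
  }
  # monomorphic rows (materialised or implied by contig lengths)
  n_inv_rows <- sum(!vs & usable)
  implied <- sum(table$contig_lengths) - n_sites(table)
  if (implied > 0 && sum(!vs) == 0) n_inv_rows <- n_inv_rows + implied
  S[1, 1] <- S[1, 1] + n_inv_rows
  folded <- .fold_joint(S)
  structure(list(counts = folded, n1 = n1, n2 = n2,
                 n_sites = sum(folded), n_excluded = sum(!usable)),
            class = "joint_sfs")
}

# fold an (n1+1) x (n2+1) spectrum by total minor-allele count
.fold_joint <- function(S) {
  n1 <- nrow(S) - 1L; n2 <- ncol(S) - 1L
  tot <- n1 + n2
  F <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    m <- S[i + 1, j + 1]
    if (m == 0) next
    ii <- n1 - i; jj <- n2 - j
    keep_here <- (i + j < tot / 2) ||
      (i + j == tot / 2 && (i < ii || (i == ii && j <= jj)))
    if (keep_here) F[i + 1, j + 1] <- F[i + 1, j + 1] + m
    else F[ii + 1, jj + 1] <- F[ii + 1, jj + 1] + m
  }
  F
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("joint_sfs: projection (%d, %d), %s usable sites (%s excluded)\n",
              x$n1, x$n2, format(x$n_sites, big.mark = ","),
              format(x$n_excluded, big.mark = ",")))
  cat(sprintf("  monomorphic cell: %s; polymorphic mass: %s\n",
              format(x$counts[1, 1], big.mark = ","),
              format(round(sum(x$counts) - x$counts[1, 1], 1), big.mark = ",")))
  invisible(x)
}

#' Write a joint SFS as a 2D TSV
#' @param sfs a `joint_sfs`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sfs_tsv <- function(sfs, path) {
  m <- as.data.frame(sfs$counts)
  names(m) <- paste0("d2_", 0:sfs$n2)
  out <- cbind(data.frame(d1 = paste0("d1_", 0:sfs$n1)), m)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
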