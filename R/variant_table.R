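#' All-sites variant table
#'
#' The central container of the pipeline: one row per genomic site (variant
#' *and* invariant/monomorphic), plus per-genotype matrices. Genotypes are
#' stored as alt-allele dosage (0, 1, 2) with `NA` for missing; invariant
#' sites have `alt = NA` and dosage 0 wherever genotyped.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (`NA` for invariant sites), `qual` (may be `NA`).
#' @param gt integer matrix, sites x samples, alt-allele dosage in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of sample ids (column names of `gt`).
#' @param dp optional integer matrix of per-genotype read depth.
#' @param ad_alt optional integer matrix of alt-supporting read depth
#'   (`NA` where undefined, e.g. invariant sites).
#' @param contig_lengths named numeric vector giving the full length of each
#'   contig (needed for windowed statistics and total-site bookkeeping);
#'   defaults to the max position seen per contig.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, samples, dp = NULL, ad_alt = NULL,
                          contig_lengths = NULL) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(gt),
            length(samples) == ncol(gt))
  req <- c("chrom", "pos", "ref", "alt", "qual")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites lacks columns: ", paste(miss, collapse = ", "))
  sites <- as.data.frame(sites)[, req]
  sites$chrom <- as.character(sites$chrom)
  sites$alt <- as.character(sites$alt)
  sites$alt[!is.na(sites$alt) & sites$alt == "."] <- NA_character_
  # positions strictly increasing within contig
  ord_ok <- all(tapply(sites$pos, sites$chrom,
                       function(p) all(diff(p) > 0) || length(p) < 2))
  if (!isTRUE(ord_ok)) stop("positions must be strictly increasing within contig")
  storage.mode(gt) <- "integer"
  bad <- gt[!is.na(gt)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  colnames(gt) <- samples
  if (!is.null(dp)) { storage.mode(dp) <- "integer"; colnames(dp) <- samples }
  if (!is.null(ad_alt)) { storage.mode(ad_alt) <- "integer"; colnames(ad_alt) <- samples }
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(sites$pos, sites$chrom, max)
    contig_lengths <- setNames(as.numeric(contig_lengths), names(contig_lengths))
  }
  structure(list(sites = sites, gt = gt, dp = dp, ad_alt = ad_alt,
                 samples = samples, contig_lengths = contig_lengths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  nv <- sum(is_variant_site(x))
  cat(sprintf("variant_table: %d sites (%d variant, %d invariant), %d samples, %d contig(s)\n",
              nrow(x$sites), nv, nrow(x$sites) - nv, length(x$samples),
              length(x$contig_lengths)))
  cat(sprintf("  total contig length: %s bp; DP %s, AD %s\n",
              format(sum(x$contig_lengths), big.mark = ","),
              if (is.null(x$dp)) "absent" else "present",
              if (is.null(x$ad_alt)) "absent" else "present"))
  invisible(x)
}

#' Number of sites in a variant table
#' @param x a `variant_table`
#' @return integer site count
#' @export
n_sites <- function(x) nrow(x$sites)

#' Logical mask of variant (bi-allelic polymorphic record) sites
#' @param x a `variant_table`
#' @return logical vector along sites
#' @export
is_variant_site <- function(x) !is.na(x$sites$alt)

#' Subset a variant table by site index
#' @param x a `variant_table`
#' @param idx integer or logical site index
#' @return a `variant_table` with the selected sites
#' @export
subset_sites <- function(x, idx) {
  variant_table(x$sites[idx, , drop = FALSE],
                x$gt[idx, , drop = FALSE], x$samples,
                dp = if (!is.null(x$dp)) x$dp[idx, , drop = FALSE],
                ad_alt = if (!is.null(x$ad_alt)) x$ad_alt[idx, , drop = FALSE],
                contig_lengths = x$contig_lengths)
}

#' Extract the genotype (dosage) matrix of variant sites
#'
#' Samples x variant-site matrix of alt-allele dosage; invariant sites are
#' dropped. Column metadata (`chrom`, `pos`) is attached as attributes.
#'
#' @param table a `variant_table` (normally after filtering)
#' @return integer matrix samples x variant sites with attributes `chrom`,
#'   `pos`, class `genotype_matrix`
#' @export
to_genotype_matrix <- function(table) {
  keep <- which(is_variant_site(table))
  m <- t(table$gt[keep, , drop = FALSE])
  rownames(m) <- table$samples
  structure(m, chrom = table$sites$chrom[keep], pos = table$sites$pos[keep],
            class = c("genotype_matrix", class(m)))
}

# internal: per-site alt allele count and non-missing allele count for a
# sample subset (columns). Returns list(ac, an) of numeric vectors.
.allele_counts <- function(table, cols) {
  g <- table$gt[, cols, drop = FALSE]
  an <- 2L * rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  list(ac = as.numeric(ac), an = as.numeric(an))
}

# internal: resolve a popmap (data.frame sample/population) to column indices
.pop_cols <- function(table, popmap, population) {
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  ids <- popmap$sample[popmap$population == population]
  if (!length(ids)) stop("population not present in popmap: ", population)
  cols <- match(ids, table$samples)
  if (anyNA(cols)) stop("popmap samples absent from table: ",
                        paste(ids[is.na(cols)], collapse = ", "))
  cols
}
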