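#' Principal component analysis of a genotype matrix
#'
#' Sites with more than `max_missing` missing genotypes are dropped,
#' remaining missing dosages are replaced by the site mean, columns are
#' centred (not scaled) and the sample covariance is eigendecomposed. Axis
#' signs are fixed by making each axis's largest-magnitude SNP loading
#' positive, so results are deterministic.
#'
#' @param matrix a `genotype_matrix`
#' @param max_missing maximum per-site missing fraction (default 0.01)
#' @param n_axes number of axes to return
#' @return list of class `pca_result`: `scores` (samples x axes),
#'   `loadings`, `eigenvalues`, `explained` (proportions), `n_sites_used`,
#'   `degenerate` flag
#' @export
pca_genotypes <- function(matrix, max_missing = 0.01, n_axes = 10) {
  g <- unclass(matrix)
  if (nrow(g) < 2) stop("need >= 2 samples")
  miss <- colMeans(is.na(g))
  keep <- miss <= max_missing
  if (!any(keep)) stop("no sites left after the missingness filter")
  g <- g[, keep, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  x <- sweep(g, 2, colMeans(g))
  sv <- svd(x)
  eig <- sv$d^2 / (nrow(g) - 1)
  tot <- sum(eig)
  degenerate <- tot < .Machine$double.eps * nrow(g)
  n_axes <- min(n_axes, length(eig))
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  for (a in seq_len(n_axes)) {
    s <- sign(loadings[which.max(abs(loadings[, a])), a])
    if (s < 0) { loadings[, a] <- -loadings[, a]; scores[, a] <- -scores[, a] }
  }
  rownames(scores) <- rownames(g)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_axes))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eig[seq_len(n_axes)],
                 explained = if (degenerate) rep(0, n_axes) else
                   eig[seq_len(n_axes)] / tot,
                 n_sites_used = sum(keep), degenerate = degenerate),
            class = "pca_result")
}

#' Identity-by-state distance matrix
#'
#' Per pair, the mean over mutually non-missing variant sites of 0 for
#' identical dosage, 0.5 for a one-step dosage difference and 1 for opposite
#' homozygotes (equivalently `|g_i - g_j| / 2`). Pairs with no shared sites
#' are `NA`.
#'
#' @param matrix a `genotype_matrix`
#' @return symmetric numeric matrix (zero diagonal) of 1-IBS distances
#' @export
ibs_distance <- function(matrix) {
  g <- unclass(matrix)
  n <- nrow(g)
  D <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- abs(g[i, ] - g[j, ]) / 2
    D[i, j] <- D[j, i] <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }
  D
}

#' Allele-sharing distance over all sites
#'
#' The neighbour-joining input distance: computed like [ibs_distance()] but
#' over all sites, invariant included (invariant sites contribute zero
#' difference, shrinking distances toward the genome-wide scale). For
#' bi-allelic diploid data this equals the IUPAC-ambiguity sequence
#' p-distance under the 0.5-heterozygote convention.
#'
#' @param table an all-sites `variant_table`
#' @return symmetric distance matrix
#' @export
allele_sharing_distance <- function(table) {
  m <- t(table$gt)
  rownames(m) <- table$samples
  ibs_distance(m)
}

#' Great-circle (haversine) distance matrix
#'
#' @param coords data.frame with columns `sample`, `lat`, `lon` in decimal
#'   degrees
#' @param radius_km Earth radius (default 6371 km)
#' @return symmetric matrix of distances in km
#' @export
haversine_matrix <- function(coords, radius_km = 6371) {
  stopifnot(all(c("sample", "lat", "lon") %in% names(coords)))
  if (any(abs(coords$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(coords$lon) > 180)) stop("longitude outside [-180, 180]")
  lat <- coords$lat * pi / 180
  lon <- coords$lon * pi / 180
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(coords$sample, coords$sample))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    D[i, j] <- D[j, i] <- 2 * radius_km * asin(pmin(1, sqrt(a)))
  }
  D
}

#' Multiple regression on distance matrices
#'
#' Ordinary least squares of the vectorised lower triangle of `response` on
#' that of `predictor`; significance by jointly permuting rows and columns
#' of the response matrix and recomputing R^2 (Mantel-style):
#' p = (number of permuted R^2 >= observed + 1) / (n_perm + 1).
#'
#' @param response,predictor symmetric distance matrices over the same
#'   samples (matching dimnames if present)
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed
#' @return list of class `mrm_result`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n_perm`
#' @export
mrm <- function(response, predictor, n_perm = 999, seed = 1L) {
  if (!all(dim(response) == dim(predictor)))
    stop("matrix dimensions differ")
  if (!is.null(rownames(response)) && !is.null(rownames(predictor)) &&
      !identical(rownames(response), rownames(predictor)))
    stop("sample ids of the two matrices do not match")
  lt <- lower.tri(response)
  y <- response[lt]; x <- predictor[lt]
  ok <- complete.cases(x, y)
  fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  ssr <- sum(fit$residuals^2)
  sst <- sum((y[ok] - mean(y[ok]))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  set.seed(seed)
  n <- nrow(response)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pi_ <- sample.int(n)
    yp <- response[pi_, pi_][lt]
    okp <- complete.cases(x, yp)
    fb <- stats::lm.fit(cbind(1, x[okp]), yp[okp])
    sstp <- sum((yp[okp] - mean(yp[okp]))^2)
    r2p <- if (sstp > 0) 1 - sum(fb$residuals^2) / sstp else 0
    if (r2p >= r2) count <- count + 1L
  }
  structure(list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
                 r_squared = r2, p_value = (count + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mrm_result")
}

#' Neighbour-joining tree
#'
#' Canonical Saitou-Nei agglomeration on a distance matrix: at each step the
#' pair minimising Q(i,j) = (n-2) d(i,j) - r_i - r_j is joined (ties broken
#' by the lowest pair of indices), branch lengths follow the standard
#' formulas, and negative branch lengths are clamped to zero with the
#' negative amount transferred to the sister branch.
#'
#' @param dist symmetric distance matrix with >= 3 samples
#' @return an `ape::phylo` tree (unrooted)
#' @export
nj_tree <- function(dist) {
  n <- nrow(dist)
  if (n < 3) stop("need >= 3 samples")
  labs <- rownames(dist)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  D <- dist
  nodes <- as.list(labs)          # newick fragment per active node
  active <- seq_len(n)
  while (length(active) > 3) {
    k <- length(active)
    Dk <- D[active, active]
    r <- rowSums(Dk)
    Q <- (k - 2) * Dk - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index tie-break: row-major scan of the upper triangle
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dk[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    ai <- active[i]; aj <- active[j]
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[ai]], bi,
                       nodes[[aj]], bj)
    dnew <- (Dk[i, ] + Dk[j, ] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    m <- nrow(D)
    D[m, active] <- D[active, m] <- dnew
    D[m, m] <- 0
    nodes[[m]] <- newnode
    active <- c(active[-c(i, j)], m)
  }
  # resolve the final three nodes on a central vertex
  a <- active[1]; b <- active[2]; c <- active[3]
  la <- (D[a, b] + D[a, c] - D[b, c]) / 2
  lb <- (D[a, b] + D[b, c] - D[a, c]) / 2
  lc <- (D[a, c] + D[b, c] - D[a, b]) / 2
  for (v in c("la", "lb", "lc")) assign(v, max(0, get(v)))
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[a]], la, nodes[[b]], lb, nodes[[c]], lc)
  ape::read.tree(text = nwk)
}
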