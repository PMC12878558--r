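#' Greedy collinearity filter on environment variables
#'
#' While any pair of variables exceeds the Spearman |rho| threshold, the
#' member of the worst (largest |rho|) pair with the larger mean absolute
#' correlation to all other variables is dropped (ties broken by column
#' order), mirroring the caret-style findCorrelation recipe. Constant
#' variables (undefined Spearman) are dropped first with a warning.
#'
#' @param env data.frame or matrix of environment variables (samples x vars)
#' @param threshold Spearman |rho| above which a pair is collinear
#' @return character vector of retained variable names
#' @export
collinearity_filter <- function(env, threshold = 0.7) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) return(names(env))
  if (nrow(env) < 3) stop("need >= 3 samples")
  const <- vapply(env, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), TRUE)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(names(env)[const], collapse = ", "))
    env <- env[, !const, drop = FALSE]
  }
  keep <- names(env)
  repeat {
    if (length(keep) < 2) break
    rho <- abs(cor(env[, keep, drop = FALSE], method = "spearman",
                   use = "pairwise.complete.obs"))
    diag(rho) <- 0
    if (max(rho, na.rm = TRUE) <= threshold) break
    worst <- which(rho == max(rho, na.rm = TRUE), arr.ind = TRUE)
    worst <- worst[order(worst[, 1], worst[, 2]), , drop = FALSE][1, ]
    mean_abs <- (rowSums(rho) - 0) / (length(keep) - 1)
    a <- worst[1]; b <- worst[2]
    drop_i <- if (mean_abs[a] >= mean_abs[b]) a else b
    keep <- keep[-drop_i]
  }
  keep
}

#' Redundancy analysis of genotypes on environment
#'
#' Missing dosages are mean-imputed (as in the PCA), genotype columns are
#' centred, environment variables standardised to zero mean and unit
#' variance, genotypes are regressed on the environment and the fitted
#' values eigendecomposed: constrained axis scores for samples, per-SNP
#' loadings, and the share of total genotype variance explained per axis.
#'
#' @param matrix a `genotype_matrix`
#' @param env data.frame of environment variables (rows follow `matrix`)
#' @param n_axes constrained axes to return (at most `ncol(env)`)
#' @return list of class `rda_result`: `scores` (samples x axes),
#'   `loadings` (SNPs x axes), `explained` (share of total genotype
#'   variance), `explained_constrained` (share within the constrained
#'   space), `total_constrained` (share of variance constrained overall),
#'   plus the centred response and design kept for permutation tests
#' @export
rda_fit <- function(matrix, env, n_axes = 2) {
  g <- unclass(matrix)
  env <- as.data.frame(env)
  if (nrow(env) != nrow(g)) stop("env rows must match samples")
  if (ncol(env) >= nrow(g)) stop("n_env >= n_samples: model unidentifiable")
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  Y <- sweep(g, 2, colMeans(g))
  X <- scale(as.matrix(env))
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, Y)
  sv <- svd(fitted, nu = min(n_axes, ncol(env)), nv = min(n_axes, ncol(env)))
  n_axes <- min(n_axes, ncol(env), sum(sv$d > 1e-12))
  d <- sv$d[seq_len(n_axes)]
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*% diag(d, n_axes)
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  tot_var <- sum(Y^2)
  eig <- sv$d^2
  rownames(scores) <- rownames(g)
  colnames(scores) <- colnames(loadings) <- paste0("RDA", seq_len(n_axes))
  rownames(loadings) <- colnames(g)
  structure(list(scores = scores, loadings = loadings,
                 explained = eig[seq_len(n_axes)] / tot_var,
                 explained_constrained = eig[seq_len(n_axes)] / sum(eig),
                 total_constrained = sum(eig) / tot_var,
                 Y = Y, X = X, env_names = names(env)),
            class = "rda_result")
}

#' Outlier loci from RDA loadings
#'
#' Per axis, SNPs whose loading deviates from the axis mean by more than
#' `sd_mult` standard deviations are flagged; the union over the requested
#' axes is returned. A degenerate axis (zero loading SD) yields no outliers.
#'
#' @param result an `rda_result`
#' @param axes axes to scan (default 1:2)
#' @param sd_mult the z-score threshold (default 3)
#' @return data.frame: `snp` (column name or index), `axis`, `loading`, `z`
#' @export
rda_outliers <- function(result, axes = 1:2, sd_mult = 3) {
  axes <- axes[axes <= ncol(result$loadings)]
  out <- list()
  for (a in axes) {
    l <- result$loadings[, a]
    s <- stats::sd(l)
    if (!is.finite(s) || s == 0) next
    z <- (l - mean(l)) / s
    hit <- which(abs(z) > sd_mult)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        snp = if (!is.null(names(l))) names(l)[hit] else hit,
        idx = hit, axis = a, loading = l[hit], z = z[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp = character(0), idx = integer(0), axis = integer(0),
                      loading = numeric(0), z = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marginal permutation test for one environment variable
#'
#' Statistic: the constrained sum of squares attributable to the focal
#' variable given all others (full-model constrained SS minus the SS of the
#' model without it). Null distribution: the focal variable's values are
#' permuted over samples and the models refitted.
#' p = (count of permuted statistics >= observed + 1) / (n_perm + 1).
#'
#' @param matrix a `genotype_matrix`
#' @param env data.frame of environment variables
#' @param variable name (or index) of the focal variable
#' @param n_perm permutations (default 100)
#' @param seed RNG seed
#' @return list: `statistic` (partial constrained SS), `p_value`, `n_perm`
#' @export
marginal_permutation_test <- function(matrix, env, variable, n_perm = 100,
                                      seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  env <- as.data.frame(env)
  if (is.numeric(variable)) variable <- names(env)[variable]
  if (!variable %in% names(env)) stop("no such variable: ", variable)
  g <- unclass(matrix)
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  Y <- sweep(g, 2, colMeans(g))
  X <- scale(as.matrix(env))
  others <- setdiff(colnames(X), variable)
  ss_con <- function(Xm) sum(qr.fitted(qr(Xm), Y)^2)
  ss_reduced <- if (length(others)) ss_con(X[, others, drop = FALSE]) else 0
  stat <- ss_con(X) - ss_reduced
  set.seed(seed)
  n <- nrow(X)
  count <- 0L
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, variable] <- X[sample.int(n), variable]
    sp <- ss_con(Xp) - ss_reduced
    if (sp >= stat) count <- count + 1L
  }
  list(statistic = stat, p_value = (count + 1) / (n_perm + 1), n_perm = n_perm)
}
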