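#' Ancestry estimation by masked-cross-validation NMF
#'
#' Genotypes are expressed as alt-allele frequencies (dosage / 2) and
#' factorised as `Q %*% G`, with each sample's ancestry vector `Q[i, ]` on
#' the K-simplex and ancestral allele frequencies `G` in [0, 1], by
#' alternating projected least squares (missing and held-out entries are
#' EM-imputed with the current fit, which solves the masked least-squares
#' problem exactly at convergence). A random `mask_fraction` of observed
#' entries is held out per run; the masked binary cross-entropy
#' `-mean(y log yhat + (1-y) log(1-yhat))` (predictions clipped to
#' [1e-6, 1 - 1e-6]) scores the run, and the best of `n_runs` restarts is
#' kept.
#'
#' @param matrix a `genotype_matrix` (variant sites only)
#' @param K number of ancestral populations (>= 1)
#' @param mask_fraction fraction of entries held out for cross-entropy
#' @param n_runs random restarts
#' @param seed RNG seed
#' @param max_iter,tol ALS iteration cap and relative RSS change tolerance
#' @return list of class `admixture_result`: `K`, `Q` (samples x K, rows sum
#'   to 1), `G` (K x sites), `cross_entropy` (best run), `ce_runs` (per run),
#'   `iterations`
#' @export
admixture_nmf <- function(matrix, K, mask_fraction = 0.05, n_runs = 10,
                          seed = 1L, max_iter = 500, tol = 1e-6) {
  g <- unclass(matrix)
  n <- nrow(g); p <- ncol(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  Y <- g / 2
  obs <- which(!is.na(Y))
  set.seed(seed)
  best <- NULL
  ce_runs <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    mask <- sample(obs, max(1L, round(mask_fraction * length(obs))))
    fit <- .nmf_fit(Y, K, mask, max_iter, tol)
    yhat <- pmin(1 - 1e-6, pmax(1e-6, (fit$Q %*% fit$G)[mask]))
    y <- Y[mask]
    ce_runs[run] <- -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
    if (is.null(best) || ce_runs[run] < best$cross_entropy) {
      best <- list(K = K, Q = fit$Q, G = fit$G,
                   cross_entropy = ce_runs[run], iterations = fit$iter)
    }
  }
  best$ce_runs <- ce_runs
  rownames(best$Q) <- rownames(g)
  structure(best, class = "admixture_result")
}

.nmf_fit <- function(Y, K, mask, max_iter, tol) {
  n <- nrow(Y); p <- ncol(Y)
  unk <- is.na(Y)
  Yw <- Y
  Yw[unk] <- mean(Y, na.rm = TRUE)
  Yw[mask] <- mean(Y, na.rm = TRUE)
  hidden <- unk
  hidden[mask] <- TRUE
  if (K == 1) {
    # closed form: Q = 1, G = column means over visible entries
    Yv <- Y
    Yv[hidden] <- NA
    G <- matrix(colMeans(Yv, na.rm = TRUE), 1, p)
    G[is.na(G)] <- mean(Yv, na.rm = TRUE)
    return(list(Q = matrix(1, n, 1), G = pmin(pmax(G, 0), 1), iter = 0L))
  }
  # archetype initialisation: ancestral frequencies start at the (imputed)
  # genotypes of K random samples, which avoids the symmetric local optima
  # random inits fall into when clusters are strongly separated
  Q <- matrix(stats::rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  Yi <- Yw
  G <- Yi[sample.int(n, K), , drop = FALSE] * 0.9 + 0.05
  G <- G + matrix(runif(K * p, -0.02, 0.02), K, p)
  G <- pmin(pmax(G, 0), 1)
  rss_old <- Inf
  for (it in seq_len(max_iter)) {
    # EM step: impute hidden entries with the current fit
    fitted <- Q %*% G
    Yw[hidden] <- fitted[hidden]
    # Q update: exact simplex-constrained least squares per sample
    # (Euclidean projection of the unconstrained solution is wrong when
    # G is ill-conditioned, e.g. an all-zero archetype)
    GtG <- tcrossprod(G)
    GY <- G %*% t(Yw)
    Q <- t(.simplex_ls_batch(GtG, GY))
    # G update: least squares, clipped to [0, 1]
    QtQ <- crossprod(Q)
    G <- solve(QtQ + diag(1e-10, K), crossprod(Q, Yw))
    G <- pmin(pmax(G, 0), 1)
    res <- (Yw - Q %*% G)[!hidden]
    rss <- sum(res^2)
    if (is.finite(rss_old) && abs(rss_old - rss) < tol * max(rss_old, 1e-12))
      break
    rss_old <- rss
  }
  list(Q = Q, G = G, iter = it)
}

# Euclidean projection onto the probability simplex (Held et al. scheme)
.proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# exact min_q q'Aq/2 - b'q  s.t. q >= 0, sum(q) = 1, for every column of B
# simultaneously, by active-set enumeration (K <= ~6 keeps the 2^K - 1
# subsets trivial; each subset costs one linear solve for all columns).
# A = G G', B = G Y' for the least-squares rows. Euclidean projection of
# the unconstrained solution is NOT equivalent when A is ill-conditioned
# (e.g. an all-zero archetype), hence the exact solve.
.simplex_ls_batch <- function(A, B) {
  K <- nrow(A); n <- ncol(B)
  bestQ <- matrix(0, K, n)
  bestObj <- rep(Inf, n)
  for (mask in seq_len(2^K - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    m <- length(S)
    # KKT: [A_SS 1; 1' 0] [q; lambda] = [b_S; 1]
    M <- rbind(cbind(A[S, S, drop = FALSE] + diag(1e-12, m), rep(1, m)),
               c(rep(1, m), 0))
    sol <- tryCatch(solve(M, rbind(B[S, , drop = FALSE], rep(1, n))),
                    error = function(e) NULL)
    if (is.null(sol)) next
    Qs <- sol[seq_len(m), , drop = FALSE]
    feas <- colSums(Qs < -1e-9) == 0
    if (!any(feas)) next
    Qf <- matrix(0, K, n)
    Qf[S, ] <- pmax(Qs, 0)
    Qf <- sweep(Qf, 2, colSums(Qf), "/")
    obj <- 0.5 * colSums(Qf * (A %*% Qf)) - colSums(B * Qf)
    upd <- feas & (obj < bestObj - 1e-12)
    if (any(upd)) {
      bestQ[, upd] <- Qf[, upd]
      bestObj[upd] <- obj[upd]
    }
  }
  bestQ
}

#' Choose K by masked cross-entropy
#'
#' Runs [admixture_nmf()] for each K and returns the K minimising the mean
#' cross-entropy over restarts (the entropy criterion for the number of
#' ancestral populations).
#'
#' @param matrix a `genotype_matrix`
#' @param K_range candidate K values (default 1:4)
#' @param ... passed to [admixture_nmf()]
#' @return list of class `k_selection`: `K` (chosen), `cross_entropy` (mean
#'   per K), `results` (full fits per K)
#' @export
select_k <- function(matrix, K_range = 1:4, ...) {
  results <- lapply(K_range, function(k) admixture_nmf(matrix, k, ...))
  ce <- vapply(results, function(r) mean(r$ce_runs), 0)
  structure(list(K = K_range[which.min(ce)],
                 cross_entropy = setNames(ce, K_range), results = results),
            class = "k_selection")
}
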