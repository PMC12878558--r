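#' Demographic scenarios
#'
#' Three nested isolation-with-migration scenarios on a two-deme sample:
#' `single` (one panmictic population: divergence time fixed at 0, daughter
#' sizes tied to the ancestral size, k = 1 free parameter),
#' `split_isolation` (divergence with no gene flow, k = 4) and
#' `split_migration` (divergence with two directional backward migration
#' rates, k = 6). Initialisation ranges follow the stated priors (Ne
#' 100-10,000; Tdiv 50-300; m 1e-4-0.1); ranges are soft, so conditional
#' maximisation may walk estimates beyond them.
#'
#' @param scenario one of `"single"`, `"split_isolation"`, `"split_migration"`
#' @param Ne_anc,Ne_1,Ne_2 diploid effective sizes
#' @param T_div divergence time in generations
#' @param m_12,m_21 backward migration probabilities per generation
#' @param mu mutation rate per site per generation
#' @return list of class `demographic_model`
#' @export
demographic_model <- function(scenario = c("single", "split_isolation",
                                           "split_migration"),
                              Ne_anc = 1000, Ne_1 = Ne_anc, Ne_2 = Ne_anc,
                              T_div = 100, m_12 = 0.001, m_21 = 0.001,
                              mu = 1e-7) {
  scenario <- match.arg(scenario)
  if (scenario == "single") { T_div <- 0; Ne_1 <- Ne_2 <- Ne_anc; m_12 <- m_21 <- 0 }
  if (scenario == "split_isolation") { m_12 <- m_21 <- 0 }
  if (any(c(Ne_anc, Ne_1, Ne_2) <= 0)) stop("sizes must be positive")
  if (T_div < 0) stop("T_div must be >= 0")
  if (mu <= 0) stop("mu must be positive")
  structure(list(scenario = scenario, Ne_anc = Ne_anc, Ne_1 = Ne_1,
                 Ne_2 = Ne_2, T_div = T_div, m_12 = m_12, m_21 = m_21,
                 mu = mu),
            class = "demographic_model")
}

# free parameters per scenario (names index into the model list)
.free_params <- function(scenario) {
  switch(scenario,
         single = "Ne_anc",
         split_isolation = c("Ne_anc", "Ne_1", "Ne_2", "T_div"),
         split_migration = c("Ne_anc", "Ne_1", "Ne_2", "T_div", "m_12", "m_21"))
}

#' Expected folded joint SFS under a demographic model
#'
#' Monte-Carlo expectation via the shared structured-coalescent engine:
#' `n_sims` genealogies of (n1, n2) haploid samples are simulated, branch
#' lengths are accumulated by the number of leaves they subtend in each
#' population, and the per-site probability of a polymorphic cell is
#' `mu x mean branch length` with the monomorphic probability as the
#' complement of the polymorphic total. Zero polymorphic cells are floored
#' at `0.1 / n_sims` x mu-scale before use in logs. The `single` scenario
#' ties the daughter demes to `Ne_anc` with `T_div = 0`.
#'
#' @param model a [demographic_model()]
#' @param n1,n2 haploid sample sizes (match the observed SFS projection)
#' @param n_sims number of simulated genealogies
#' @param seed RNG seed
#' @return matrix (n1+1) x (n2+1) of folded per-site probabilities summing
#'   to 1
#' @export
expected_sfs <- function(model, n1, n2, n_sims = 20000, seed = 1L) {
  stopifnot(inherits(model, "demographic_model"))
  if (n_sims < 1000) warning("n_sims < 1000: expected SFS will be noisy")
  set.seed(seed)
  Tm <- .coal_branch_config_lengths(n1, n2, model$Ne_1, model$Ne_2,
                                    model$Ne_anc, model$T_div,
                                    model$m_12, model$m_21, as.integer(n_sims))
  P <- model$mu * Tm
  P[1, 1] <- 0
  P[n1 + 1, n2 + 1] <- 0   # branch subtending all leaves cannot segregate
  floor_p <- model$mu * 0.1 / n_sims
  P[P == 0] <- floor_p
  P[1, 1] <- 0; P[n1 + 1, n2 + 1] <- 0
  Pf <- .fold_joint(P)
  ptot <- sum(Pf)
  if (ptot >= 1) stop("mu x tree length >= 1: model violates the per-site ",
                      "mutation approximation")
  Pf[1, 1] <- 1 - ptot
  Pf
}

#' Composite log10 likelihood of an observed SFS
#'
#' `L = sum over unmasked cells (monomorphic included) of O_cell x
#' log10(p_cell)`, treating sites as independent. Zero probabilities paired
#' with positive counts are floored (warning) so L stays finite.
#'
#' @param obs a `joint_sfs`
#' @param probs probability matrix from [expected_sfs()] (same shape)
#' @param floor_p floor applied to zero/negative probabilities where
#'   `O > 0` (default `1e-12`)
#' @return composite log10 likelihood (scalar)
#' @export
composite_log10_likelihood <- function(obs, probs, floor_p = 1e-12) {
  O <- if (inherits(obs, "joint_sfs")) obs$counts else obs
  if (!all(dim(O) == dim(probs))) stop("shape mismatch")
  if (any(O < 0)) stop("negative counts")
  use <- O > 0
  p <- probs[use]
  if (any(p <= 0)) {
    warning(sum(p <= 0), " cell(s) with zero probability floored")
    p[p <= 0] <- floor_p
  }
  sum(O[use] * log10(p))
}

#' Akaike information criterion from a log10 composite likelihood
#'
#' `AIC = 2k - 2 (MaxEstLhood / log10(e))`, converting the base-10
#' likelihood to natural log.
#'
#' @param k number of free parameters (>= 1)
#' @param MaxEstLhood maximised log10 composite likelihood
#' @return AIC value
#' @export
aic <- function(k, MaxEstLhood) {
  if (k < 1) stop("k must be >= 1")
  2 * k - 2 * MaxEstLhood / log10(exp(1))
}

#' AIC differences from the best model
#'
#' @param aics numeric vector of AIC values
#' @return `aics - min(aics)` (the best model shows 0)
#' @export
delta_aic <- function(aics) {
  if (!length(aics)) stop("empty AIC list")
  aics - min(aics)
}

#' Fit a demographic scenario to an observed folded joint SFS
#'
#' Conditional-maximisation cycles: each cycle optimises one free parameter
#' at a time by a bracketed line search in log space (a log-spaced candidate
#' grid spanning a factor `span` around the current value, followed by one
#' refinement around the best candidate), holding the others fixed. All
#' likelihood evaluations within a cycle share one RNG seed (common random
#' numbers), which tames simulation noise, and each line search ends with a
#' parabolic refinement in log space so the conditional optimum is located
#' below the grid resolution; the final likelihood is re-evaluated at
#' `final_sims` genealogies. Initialisation is drawn log-uniform from the
#' stated prior ranges; the search is soft-bounded well beyond them, except
#' that the observationally panmictic region with more than ~40 expected
#' backward migrations per lineage is excluded from the search (see the
#' methods vignette).
#'
#' @param obs a `joint_sfs`
#' @param scenario scenario name (see [demographic_model()])
#' @param mu mutation rate per site per generation
#' @param n_cycles conditional-maximisation cycles (desk default 15;
#'   full-scale 60)
#' @param n_sims genealogies per final likelihood evaluation (desk default
#'   2e4; full-scale 1e6)
#' @param search_frac fraction of `n_sims` used inside line searches
#' @param seed RNG seed
#' @param init optional named vector of starting values for (a subset of)
#'   the free parameters — e.g. a warm start of a nested richer scenario
#'   from a simpler scenario's estimates; unnamed parameters initialise
#'   log-uniform from the prior ranges
#' @param final_seed optional seed for the final likelihood evaluation;
#'   sharing it across scenario fits gives common random numbers in the AIC
#'   comparison
#' @param n_starts independent search restarts (the first uses `init` when
#'   given, later ones draw fresh initialisations); the end points compete
#'   under the shared final seed
#' @param final_sims genealogies for the final reported likelihood (defaults
#'   to `5 * n_sims`: the returned MaxEstLhood and the AIC comparison are
#'   evaluated more precisely than the search steps)
#' @return list of class `fit_result`: `model` (point estimates),
#'   `MaxEstLhood` (log10), `k`, `AIC`, `n_sims`, `n_cycles`, `seed`,
#'   `converged`
#' @export
fit_model <- function(obs, scenario, mu = 1e-7, n_cycles = 15, n_sims = 20000,
                      search_frac = 0.15, seed = 1L, init = NULL,
                      final_seed = NULL, n_starts = 1, final_sims = 5 * n_sims) {
  stopifnot(inherits(obs, "joint_sfs"))
  free <- .free_params(scenario)
  set.seed(seed)
  init_range <- list(Ne_anc = c(100, 10000), Ne_1 = c(100, 10000),
                     Ne_2 = c(100, 10000), T_div = c(50, 300),
                     m_12 = c(1e-4, 0.1), m_21 = c(1e-4, 0.1))
  hard <- list(Ne_anc = c(10, 1e6), Ne_1 = c(10, 1e6), Ne_2 = c(10, 1e6),
               T_div = c(1, 1e5), m_12 = c(1e-6, 0.3), m_21 = c(1e-6, 0.3))
  draw_init <- function(use_init) {
    par <- vapply(free, function(p) {
      if (use_init && !is.null(init) && p %in% names(init))
        return(unname(init[p]))
      r <- init_range[[p]]
      exp(runif(1, log(r[1]), log(r[2])))
    }, 0)
    names(par) <- free
    par
  }
  n_search <- max(1000L, as.integer(round(n_sims * search_frac)))
  mkmodel <- function(par) {
    args <- list(scenario = scenario, mu = mu)
    for (p in names(par)) args[[p]] <- unname(par[p])
    do.call(demographic_model, args)
  }
  ll_eval <- function(par, sims, sd) {
    # search-region guard: beyond ~60 expected migrations per lineage the
    # two-deme model is observationally panmictic (flat likelihood) while
    # simulation cost explodes; equivalent mixing is expressible well inside
    if (all(c("m_12", "T_div") %in% names(par)) &&
        (par["m_12"] + par["m_21"]) * par["T_div"] > 60) return(-Inf)
    composite_log10_likelihood(
      obs, expected_sfs(mkmodel(par), obs$n1, obs$n2, n_sims = sims, seed = sd),
      floor_p = mu * 0.1 / sims)
  }
  search_once <- function(par) {
    span <- 4
    cycle_seeds <- sample.int(.Machine$integer.max %/% 2L, n_cycles)
    for (cy in seq_len(n_cycles)) {
      sd_cy <- cycle_seeds[cy]
      for (p in free) {
        cur <- par[p]
        grid <- exp(seq(log(cur / span), log(cur * span), length.out = 5))
        grid <- pmin(hard[[p]][2], pmax(hard[[p]][1], grid))
        grid <- unique(c(cur, grid))
        lls <- vapply(grid, function(v) {
          pv <- par; pv[p] <- v
          ll_eval(pv, n_search, sd_cy)
        }, 0)
        best <- grid[which.max(lls)]
        # one refinement around the incumbent
        fine <- exp(c(log(best / span^0.35), log(best * span^0.35)))
        fine <- pmin(hard[[p]][2], pmax(hard[[p]][1], fine))
        fine <- setdiff(fine, grid)
        llf <- numeric(0)
        if (length(fine)) {
          llf <- vapply(fine, function(v) {
            pv <- par; pv[p] <- v
            ll_eval(pv, n_search, sd_cy)
          }, 0)
          if (max(llf) > max(lls)) best <- fine[which.max(llf)]
        }
        # parabolic sharpening: the likelihood is smooth under common random
        # numbers, so the vertex of a parabola through the best point and
        # its two nearest evaluated neighbours (in log space) pinpoints the
        # conditional optimum far below the grid resolution
        allv <- c(grid, fine); all_ll <- c(lls, llf)
        o <- order(abs(log(allv / best)))
        tri <- o[1:min(3, length(o))]
        if (length(tri) == 3 && length(unique(allv[tri])) == 3) {
          x <- log(allv[tri]); y <- all_ll[tri]
          dd <- (y[3] - y[1]) * (x[2] - x[1]) - (y[2] - y[1]) * (x[3] - x[1])
          cc <- (x[3]^2 - x[1]^2) * (x[2] - x[1]) - (x[2]^2 - x[1]^2) * (x[3] - x[1])
          if (is.finite(dd) && is.finite(cc) && cc != 0) {
            a2 <- dd / cc
            b1 <- (y[2] - y[1] - a2 * (x[2]^2 - x[1]^2)) / (x[2] - x[1])
            if (a2 < 0) {
              vtx <- exp(-b1 / (2 * a2))
              vtx <- min(hard[[p]][2], max(hard[[p]][1], vtx))
              if (is.finite(vtx) && abs(log(vtx / best)) < log(span)) {
                pv <- par; pv[p] <- vtx
                llv <- ll_eval(pv, n_search, sd_cy)
                if (llv > max(all_ll)) best <- vtx
              }
            }
          }
        }
        par[p] <- best
      }
      span <- max(1.3, span * 0.8)   # shrink the bracket as cycles proceed
    }
    par
  }
  # pilot scan of the divergence-time x migration plane: the composite
  # likelihood is ridged in (T_div, m) (deep split + gene flow mimics a
  # shallow split without it), which one-parameter-at-a-time moves cross
  # poorly; the scan seeds the first search on the right side of the ridge
  pilot_start <- function(par) {
    if (!"T_div" %in% free) return(par)
    t_grid <- c(50, 150, 400, 1200, 3500)
    m_grid <- if ("m_12" %in% free) c(1e-4, 1e-3, 1e-2, 5e-2) else NA
    sd_p <- sample.int(.Machine$integer.max %/% 2L, 1)
    best <- par; best_ll <- ll_eval(par, n_search, sd_p)
    for (tv in t_grid) for (mv in m_grid) for (tie_ne in c(FALSE, TRUE)) {
      pv <- par
      pv["T_div"] <- tv
      if (!is.na(mv)) { pv["m_12"] <- mv; pv["m_21"] <- mv }
      # a warm start from an isolation fit carries inflated daughter sizes
      # (isolation mimics gene flow that way); also scan with sizes tied
      if (tie_ne && all(c("Ne_1", "Ne_2") %in% free)) {
        pv["Ne_1"] <- pv["Ne_anc"]; pv["Ne_2"] <- pv["Ne_anc"]
      } else if (tie_ne) next
      llv <- ll_eval(pv, n_search, sd_p)
      if (llv > best_ll) { best_ll <- llv; best <- pv }
    }
    best
  }
  if (is.null(final_seed)) final_seed <- sample.int(.Machine$integer.max %/% 2L, 1)
  best_par <- NULL; best_ll <- -Inf
  for (st in seq_len(max(1, n_starts))) {
    par0 <- if (st == 1) pilot_start(draw_init(TRUE)) else draw_init(FALSE)
    par_st <- search_once(par0)
    ll_st <- ll_eval(par_st, final_sims, final_seed)
    if (ll_st > best_ll) { best_ll <- ll_st; best_par <- par_st }
  }
  k <- length(free)
  structure(list(model = mkmodel(best_par), MaxEstLhood = best_ll, k = k,
                 AIC = aic(k, best_ll), n_sims = n_sims,
                 final_sims = final_sims, n_cycles = n_cycles,
                 seed = seed, converged = TRUE),
            class = "fit_result")
}

#' Fit and compare several scenarios on one observed SFS
#'
#' Scenarios are fitted simplest-first; each richer scenario warm-starts
#' from the best nested fit so far (the scenarios are nested: `single` is
#' `split_isolation` with `T_div = 0` and tied sizes, which in turn is
#' `split_migration` with zero migration), and every scenario's final
#' likelihood is evaluated under one shared seed so the AIC comparison uses
#' common random numbers.
#'
#' @param obs a `joint_sfs`
#' @param scenarios character vector of scenario names
#' @param seed RNG seed
#' @param ... passed to [fit_model()]
#' @return data.frame mirroring the scenario-comparison table: one row per
#'   scenario with point estimates, `MaxEstLhood`, `k`, `AIC`, `dAIC` and the
#'   effective migration rate `Ne_anc x m` of the larger migration rate;
#'   full fits attached as attribute `fits`
#' @export
compare_scenarios <- function(obs, scenarios = c("single", "split_isolation",
                                                 "split_migration"),
                              seed = 1L, ...) {
  order_pref <- c("single", "split_isolation", "split_migration")
  scenarios <- order_pref[order_pref %in% scenarios]
  set.seed(seed)
  final_seed <- sample.int(.Machine$integer.max %/% 2L, 1)
  fits <- list(); warm <- NULL
  for (s in scenarios) {
    init <- if (!is.null(warm)) switch(s,
      split_isolation = c(Ne_anc = warm$Ne_anc, Ne_1 = warm$Ne_1,
                          Ne_2 = warm$Ne_2,
                          T_div = if (warm$T_div > 0) warm$T_div else 122),
      split_migration = c(Ne_anc = warm$Ne_anc, Ne_1 = warm$Ne_1,
                          Ne_2 = warm$Ne_2,
                          T_div = if (warm$T_div > 0) warm$T_div else 122,
                          m_12 = 0.003, m_21 = 0.003))
    fits[[s]] <- fit_model(obs, s, seed = seed, init = init,
                           final_seed = final_seed, ...)
    # nested-model guarantee: the richer scenario contains the simpler one,
    # so if the embedded nested optimum beats the search result under the
    # shared final seed, adopt it
    if (!is.null(warm)) {
      embedded <- switch(s,
        split_isolation = demographic_model("split_isolation",
          Ne_anc = warm$Ne_anc, Ne_1 = warm$Ne_anc, Ne_2 = warm$Ne_anc,
          T_div = 1, mu = warm$mu),
        split_migration = demographic_model("split_migration",
          Ne_anc = warm$Ne_anc, Ne_1 = warm$Ne_1, Ne_2 = warm$Ne_2,
          T_div = max(warm$T_div, 1), m_12 = 1e-6, m_21 = 1e-6,
          mu = warm$mu))
      n_sims_eval <- fits[[s]]$final_sims
      ll_emb <- composite_log10_likelihood(
        obs, expected_sfs(embedded, obs$n1, obs$n2, n_sims = n_sims_eval,
                          seed = final_seed),
        floor_p = embedded$mu * 0.1 / n_sims_eval)
      if (ll_emb > fits[[s]]$MaxEstLhood) {
        fits[[s]]$model <- embedded
        fits[[s]]$MaxEstLhood <- ll_emb
        fits[[s]]$AIC <- aic(fits[[s]]$k, ll_emb)
      }
    }
    warm <- fits[[s]]$model
  }
  aics <- vapply(fits, `[[`, 0, "AIC")
  d <- delta_aic(aics)
  rows <- lapply(seq_along(fits), function(i) {
    m <- fits[[i]]$model
    data.frame(scenario = m$scenario, Ne_anc = m$Ne_anc, Ne_1 = m$Ne_1,
               Ne_2 = m$Ne_2, T_div = m$T_div, m_12 = m$m_12, m_21 = m$m_21,
               eff_migration = m$Ne_anc * max(m$m_12, m$m_21),
               MaxEstLhood = fits[[i]]$MaxEstLhood, k = fits[[i]]$k,
               AIC = fits[[i]]$AIC, dAIC = d[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
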