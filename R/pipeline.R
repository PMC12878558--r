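#' Run the staged analysis pipeline
#'
#' Executes simulate -> filter -> diversity -> structure -> demography ->
#' gea on a configuration, writing per-stage TSV/JSON outputs plus a log
#' with package version, seed and site counts at every filter step. Stages
#' toggle independently; each stage that is enabled must find its inputs
#' (an input VCF or a simulation block, a popmap, an environment table) or
#' the run aborts before any work.
#'
#' @param config configuration list or path to a JSON file. Recognised
#'   blocks: `stages` (character vector), `simulation` (fields of
#'   [sim_config()], optionally `artifacts` = fields of [artifact_config()]
#'   and `environment` = fields of [env_config()]), `input` (`vcf`,
#'   `popmap`, `env`, `coords`), `filter` (fields of [filter_config()]),
#'   `diversity` (`window`, `pops`), `structure` (`k_range`, `n_perm`),
#'   `demography` (`scenarios`, `mu`, `n_cycles`, `n_sims`, `projection`),
#'   `gea` (`threshold`, `sd_mult`, `n_perm`).
#' @param out_dir output directory (created if absent)
#' @param seed master RNG seed; stage seeds derive from it deterministically
#' @return invisibly, a list of in-memory stage results
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages_all <- c("simulate", "filter", "diversity", "structure",
                  "demography", "gea")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  cat(sprintf("twodeme %s | seed %d | %s\n",
              as.character(utils::packageVersion("twodeme")), seed,
              format(Sys.time())), file = logf)
  log("stages: %s", paste(stages, collapse = ", "))
  seeds <- setNames(seed + seq_along(stages_all) * 1000L, stages_all)
  res <- list()

  # --- inputs / simulation -------------------------------------------
  needs_table <- length(intersect(stages, c("filter", "diversity",
                                            "demography"))) > 0 ||
    "structure" %in% stages || "gea" %in% stages
  if ("simulate" %in% stages) {
    sim_fields <- as.list(config$simulation %||% list())
    sim_fields <- sim_fields[intersect(names(sim_fields),
                                       names(formals(sim_config)))]
    sc <- do.call(sim_config, modifyList(list(seed = seeds[["simulate"]]),
                                         sim_fields))
    table <- simulate_coalescent_dataset(sc)
    popmap <- sim_popmap(table)
    if (!is.null(config$simulation$artifacts)) {
      art_fields <- as.list(config$simulation$artifacts)
      art_fields <- art_fields[intersect(names(art_fields),
                                         names(formals(artifact_config)))]
      ac <- do.call(artifact_config,
                    modifyList(list(seed = seeds[["simulate"]] + 1L),
                               art_fields))
      table <- apply_sequencing_artifacts(table, ac)
    }
    ec_fields <- as.list(config$simulation$environment %||% list())
    ec_fields <- ec_fields[intersect(names(ec_fields),
                                     names(formals(env_config)))]
    ec <- do.call(env_config, modifyList(list(seed = seeds[["simulate"]] + 2L),
                                         ec_fields))
    envres <- simulate_environment(table$samples, ec)
    write_allsites_vcf(table, file.path(out_dir, "simulated.vcf"))
    write_tsv(cbind(popmap, envres$coords[match(popmap$sample,
                                                envres$coords$sample),
                                          c("lat", "lon")]),
              file.path(out_dir, "samples.tsv"))
    write_tsv(cbind(sample = rownames(envres$env), envres$env),
              file.path(out_dir, "environment.tsv"))
    res$simulate <- list(table = table, popmap = popmap, env = envres$env,
                         coords = envres$coords)
    log("simulate: %d sites, %d samples", n_sites(table), length(table$samples))
  } else if (needs_table) {
    inp <- config$input
    if (is.null(inp$vcf) || is.null(inp$popmap))
      stop("enabled stages need input$vcf and input$popmap (or the simulate stage)")
    table <- read_allsites_vcf(inp$vcf)
    popmap <- read_popmap(inp$popmap)
    envres <- NULL
    if (!is.null(inp$env)) {
      e <- as.data.frame(data.table::fread(inp$env))
      rn <- e$sample %||% rownames(e)
      env <- e[, setdiff(names(e), "sample"), drop = FALSE]
      rownames(env) <- rn
      envres <- list(env = env)
    }
    if (!is.null(inp$coords)) {
      envres$coords <- as.data.frame(data.table::fread(inp$coords))
    }
    res$input <- list(table = table, popmap = popmap)
    log("input: %d sites, %d samples", n_sites(table), length(table$samples))
  }
  if ("gea" %in% stages && (is.null(envres) || is.null(envres$env)))
    stop("gea stage needs an environment table (input$env or the simulate stage)")
  if ("structure" %in% stages &&
      !is.null(config$structure$mrm) && is.null(envres$coords))
    stop("structure MRM needs coordinates")

  # --- filter ---------------------------------------------------------
  if ("filter" %in% stages) {
    fc <- do.call(filter_config,
                  as.list(config$filter %||% list())[
                    intersect(names(config$filter %||% list()),
                              names(formals(filter_config)))])
    fr <- filter_variants(table, fc)
    table <- fr$table
    write_filter_report(fr$report, file.path(out_dir, "filter_report.json"))
    res$filter <- fr$report
    for (nm in names(fr$report$rules))
      log("filter/%s: removed %d sites, masked %d genotypes", nm,
          fr$report$rules[[nm]]$sites_removed,
          fr$report$rules[[nm]]$genotypes_masked)
    log("filter: %d -> %d sites", fr$report$n_input, fr$report$n_retained)
  }
  pops <- config$diversity$pops %||% unique(popmap$population)

  # --- diversity ------------------------------------------------------
  if ("diversity" %in% stages) {
    window <- config$diversity$window %||% 100000
    div <- list()
    for (p in pops) {
      wp <- windowed_pi(table, popmap, p, window)
      wt <- windowed_theta_tajd(table, popmap, p, window)
      div[[p]] <- merge(wp, wt, by = c("chrom", "start", "end"))
      write_tsv(div[[p]], file.path(out_dir, sprintf("diversity_%s.tsv", p)))
    }
    if (length(pops) >= 2) {
      dx <- windowed_dxy_fst(table, popmap, pops[1], pops[2], window)
      write_tsv(dx, file.path(out_dir, "divergence.tsv"))
      div$between <- dx
    }
    gm <- to_genotype_matrix(table)
    hf <- sample_het_fis(gm)
    write_tsv(hf, file.path(out_dir, "het_fis.tsv"))
    roh <- roh_all_samples(table, genome_size = sum(table$contig_lengths))
    write_tsv(roh$intervals, file.path(out_dir, "roh.tsv"))
    write_tsv(data.frame(sample = names(roh$froh), froh = roh$froh),
              file.path(out_dir, "froh.tsv"))
    if (sum(is_variant_site(table)) >= 2) {
      ld <- ld_decay(gm)
      write_tsv(ld, file.path(out_dir, "ld_decay.tsv"))
      div$ld <- ld
    }
    res$diversity <- c(div, list(het_fis = hf, roh = roh))
    log("diversity: %d windows (%s)", nrow(div[[pops[1]]]), pops[1])
  }

  # --- structure ------------------------------------------------------
  if ("structure" %in% stages) {
    gm <- to_genotype_matrix(table)
    pr <- ld_prune(gm)
    gmp <- gm[, pr, drop = FALSE]
    attr(gmp, "chrom") <- attr(gm, "chrom")[pr]
    attr(gmp, "pos") <- attr(gm, "pos")[pr]
    class(gmp) <- class(gm)
    pca <- pca_genotypes(gmp, max_missing = config$structure$max_missing %||% 0.01)
    write_tsv(cbind(sample = rownames(pca$scores), as.data.frame(pca$scores)),
              file.path(out_dir, "pca_scores.tsv"))
    ks <- select_k(gmp, K_range = config$structure$k_range %||% 1:4,
                   n_runs = config$structure$n_runs %||% 5,
                   seed = seeds[["structure"]])
    k_range <- config$structure$k_range %||% 1:4
    bestq <- ks$results[[which(k_range == ks$K)[1]]]$Q
    write_tsv(cbind(sample = rownames(bestq), as.data.frame(bestq)),
              file.path(out_dir, "ancestry_Q.tsv"))
    tr <- nj_tree(allele_sharing_distance(table))
    ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
    st <- list(pca = pca, k_selection = ks, tree = tr, pruned = pr)
    if (!is.null(envres$coords)) {
      ibs <- ibs_distance(gm)
      geo <- haversine_matrix(envres$coords[match(rownames(gm),
                                                  envres$coords$sample), ])
      st$mrm <- mrm(ibs, geo, n_perm = config$structure$n_perm %||% 999,
                    seed = seeds[["structure"]] + 1L)
      write_tsv(data.frame(ibs = ibs[lower.tri(ibs)], km = geo[lower.tri(geo)]),
                file.path(out_dir, "ibs_vs_km.tsv"))
      jsonlite::write_json(unclass(st$mrm), file.path(out_dir, "mrm.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    res$structure <- st
    log("structure: %d pruned SNPs, chosen K = %d", length(pr), ks$K)
  }

  # --- demography -----------------------------------------------------
  if ("demography" %in% stages) {
    if (length(pops) < 2) stop("demography needs two populations")
    proj <- config$demography$projection
    sfs <- build_folded_joint_sfs(table, popmap, pops[1:2],
                                  projection = proj)
    write_sfs_tsv(sfs, file.path(out_dir, "joint_sfs.tsv"))
    cmp <- compare_scenarios(
      sfs, scenarios = config$demography$scenarios %||%
        c("single", "split_isolation", "split_migration"),
      mu = config$demography$mu %||% 1e-7,
      n_cycles = config$demography$n_cycles %||% 15,
      n_sims = config$demography$n_sims %||% 20000,
      seed = seeds[["demography"]])
    write_tsv(cmp, file.path(out_dir, "demography_comparison.tsv"))
    for (i in seq_len(nrow(cmp)))
      jsonlite::write_json(
        c(attr(cmp, "fits")[[i]]$model,
          list(MaxEstLhood = cmp$MaxEstLhood[i], AIC = cmp$AIC[i],
               dAIC = cmp$dAIC[i], k = cmp$k[i])),
        file.path(out_dir, sprintf("fit_%s.json", cmp$scenario[i])),
        auto_unbox = TRUE, digits = NA)
    res$demography <- cmp
    log("demography: best scenario %s", cmp$scenario[which.min(cmp$AIC)])
  }

  # --- gea ------------------------------------------------------------
  if ("gea" %in% stages) {
    gm <- to_genotype_matrix(table)
    env <- envres$env[match(rownames(gm), rownames(envres$env)), , drop = FALSE]
    keepv <- collinearity_filter(env, config$gea$threshold %||% 0.7)
    rda <- rda_fit(gm, env[, keepv, drop = FALSE])
    outl <- rda_outliers(rda, sd_mult = config$gea$sd_mult %||% 3)
    write_tsv(outl, file.path(out_dir, "rda_outliers.tsv"))
    write_tsv(cbind(sample = rownames(rda$scores), as.data.frame(rda$scores)),
              file.path(out_dir, "rda_scores.tsv"))
    pvals <- vapply(keepv, function(v)
      marginal_permutation_test(gm, env[, keepv, drop = FALSE], v,
                                n_perm = config$gea$n_perm %||% 100,
                                seed = seeds[["gea"]])$p_value, 0)
    write_tsv(data.frame(variable = keepv, p_value = pvals),
              file.path(out_dir, "gea_pvalues.tsv"))
    res$gea <- list(retained_vars = keepv, rda = rda, outliers = outl,
                    p_values = pvals)
    log("gea: %d/%d variables retained, %d outlier SNPs", length(keepv),
        ncol(env), length(unique(outl$idx)))
  }
  log("done")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
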