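#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' Either `scenario` (a [scenario()] or a list of its arguments) or the
#' three per-kingdom input paths must be supplied.
#'
#' @param scenario A [scenario()] or argument list for one, or `NULL`.
#' @param prok_paths,euk_paths Named lists with `table`, `tree`, `env`
#'   paths (ignored when `scenario` is given).
#' @param rarefy_depths Per-kingdom depths, `NULL` entries skip rarefaction
#'   (synthetic tables are already even-depth).
#' @param min_prevalence,min_rel_abundance Network-stage ASV filter
#'   (defaults 0.10 / 0.001).
#' @param q_grid Hill orders (default `c(0, 1, 2)`).
#' @param n_null Null iterations for NRI/NTI, betaNTI, RCbray (default 999).
#' @param corr_threshold,alpha Consensus-network thresholds (0.6 / 0.05).
#' @param core_prevalence Bipartite core threshold (default 0.75).
#' @param stage_boundaries Last floccular / last intermediate day.
#' @param signal_variable Environmental variable for optima and the Mantel
#'   correlogram (default `"nitrate"`).
#' @param sparcc_control List of SparCC settings (see
#'   [sparcc_correlations()]).
#' @param n_perm Permutations for ordination tests (default 199).
#' @param stages Analysis stages to run, any of `"diversity"`, `"signal"`,
#'   `"nulls"`, `"networks"`, `"bipartite"`, `"ordination"` (default all).
#'   Rarefaction and input validation always run; `"bipartite"` requires
#'   `"networks"` for module annotation.
#' @param seed Master seed (mandatory; all stage seeds derive from it).
#' @param outdir Output directory for tidy TSVs and the JSON summary, or
#'   `NULL` to return results only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, prok_paths = NULL,
                            euk_paths = NULL,
                            rarefy_depths = list(prokaryote = NULL,
                                                 eukaryote = NULL),
                            min_prevalence = 0.10, min_rel_abundance = 0.001,
                            q_grid = c(0, 1, 2), n_null = 999,
                            corr_threshold = 0.6, alpha = 0.05,
                            core_prevalence = 0.75,
                            stage_boundaries = c(15, 115),
                            signal_variable = "nitrate",
                            sparcc_control = list(n_boot = 999), n_perm = 199,
                            stages = c("diversity", "signal", "nulls",
                                       "networks", "bipartite", "ordination"),
                            seed = 1L, outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(scenario) && (is.null(prok_paths) || is.null(euk_paths)))
    stop("either a scenario or input paths must be given")
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            min_rel_abundance >= 0, min_rel_abundance < 1,
            corr_threshold > 0, corr_threshold < 1,
            alpha > 0, alpha < 1, core_prevalence >= 0, core_prevalence < 1,
            n_null >= 1, n_perm >= 0)
  structure(list(scenario = scenario, prok_paths = prok_paths,
                 euk_paths = euk_paths, rarefy_depths = rarefy_depths,
                 min_prevalence = min_prevalence,
                 min_rel_abundance = min_rel_abundance, q_grid = q_grid,
                 n_null = n_null, corr_threshold = corr_threshold,
                 alpha = alpha, core_prevalence = core_prevalence,
                 stage_boundaries = stage_boundaries,
                 signal_variable = signal_variable,
                 sparcc_control = sparcc_control, n_perm = n_perm,
                 stages = stages, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Pairwise Bray-Curtis dissimilarity matrix of a count table.
bray_matrix <- function(table) {
  as.matrix(vegan::vegdist(table$counts, method = "bray"))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Full within-kingdom network stack: filter, correlate, consensus, modules.
kingdom_network <- function(table, cfg, seed) {
  filt <- filter_prevalence_abundance(table, cfg$min_prevalence,
                                      cfg$min_rel_abundance)
  sp <- spearman_correlations(filt)
  q_rho <- fdr_adjust_matrix(sp$p)
  sc <- do.call(sparcc_correlations,
                c(list(table = filt, seed = derive_seed(seed, 1)),
                  cfg$sparcc_control))
  q_sparcc <- fdr_adjust_matrix(sc$p)
  net <- build_consensus_network(sp$rho, sc$r, q_rho, q_sparcc,
                                 kingdom = table$kingdom,
                                 corr_threshold = cfg$corr_threshold,
                                 alpha = cfg$alpha)
  abund <- colSums(filt$counts) / sum(filt$counts)
  net <- detect_modules(net, abundance = abund, seed = derive_seed(seed, 2))
  list(filtered = filt, network = net,
       dynamics = module_dynamics(net, filt),
       sample_stats = per_sample_network_stats(net, filt,
                                               seed = derive_seed(seed, 3)))
}

kingdom_ordination <- function(table, env, other_hill, cfg, seed) {
  bc <- bray_matrix(table)
  abiotic_pool <- env[, intersect(c("nitrate", "vss", "phosphate", "toc"),
                                  names(env)), drop = FALSE]
  sel <- forward_select_predictors(bc, abiotic_pool, alpha = cfg$alpha,
                                   n_perm = cfg$n_perm,
                                   seed = derive_seed(seed, 1))
  abiotic <- if (length(sel)) abiotic_pool[, sel, drop = FALSE]
             else abiotic_pool
  biotic <- as.data.frame(do.call(cbind, lapply(cfg$q_grid, function(q)
    other_hill$qTD[other_hill$q == q])))
  names(biotic) <- paste0("other_qTD", cfg$q_grid)
  stage_df <- data.frame(stage = factor(env$stage))
  fit <- dbrda(bc, cbind(abiotic, biotic, stage_df), n_perm = cfg$n_perm,
               seed = derive_seed(seed, 2))
  vp <- variance_partition(bc, abiotic, biotic, stage_df)
  list(selected_abiotic = sel, dbrda = fit, varpart = vp)
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis graph on simulated or on-disk inputs:
#' rarefaction, Hill diversity profiles and successive beta series,
#' phylogenetic-signal check, NRI/NTI series, successive-pair null models
#' (betaNTI, RCbray), per-kingdom consensus networks with module dynamics
#' and per-sample properties, the core inter-kingdom bipartite network, and
#' dbRDA variance partitioning. Writes tidy TSVs plus a JSON summary when
#' `cfg$outdir` is set; inputs on disk are never modified.
#'
#' @param cfg A [pipeline_config()].
#' @return List with all stage results and `summary` (the JSON-ready list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed

  ds <- run_stage("inputs", {
    if (!is.null(cfg$scenario)) {
      sc <- if (inherits(cfg$scenario, "scenario")) cfg$scenario
            else do.call(scenario, cfg$scenario)
      simulate_reactor_series(sc)
    } else {
      p <- do.call(load_dataset, c(cfg$prok_paths, kingdom = "prokaryote"))
      e <- do.call(load_dataset, c(cfg$euk_paths, kingdom = "eukaryote"))
      stopifnot(identical(p$env$sample_id, e$env$sample_id))
      list(prok_table = p$table, euk_table = e$table,
           prok_tree = p$tree, euk_tree = e$tree, env = p$env)
    }
  })
  env <- ds$env
  env$stage <- assign_stage(env$day, cfg$stage_boundaries)

  tabs <- run_stage("rarefy", {
    out <- list(prokaryote = ds$prok_table, eukaryote = ds$euk_table)
    for (k in names(out)) {
      depth <- cfg$rarefy_depths[[k]]
      if (!is.null(depth))
        out[[k]] <- rarefy(out[[k]], depth, derive_seed(seed, 10))
    }
    out
  })
  trees <- list(prokaryote = ds$prok_tree, eukaryote = ds$euk_tree)

  on <- function(s) s %in% cfg$stages
  hill <- beta <- signal <- ses <- turnover <- nets <- NULL
  bipartite <- ordin <- NULL

  if (on("diversity")) {
    hill <- run_stage("diversity",
                      lapply(tabs, hill_profile, q_list = cfg$q_grid))
    beta <- run_stage("beta_series",
                      lapply(tabs, successive_beta_series,
                             q_list = cfg$q_grid))
  }

  if (on("signal")) {
    signal <- run_stage("phylo_signal", lapply(names(tabs), function(k) {
      opt <- env_optima(tabs[[k]], env, cfg$signal_variable)
      mantel_correlogram(opt, trees[[k]], n_perm = max(cfg$n_perm, 99),
                         seed = derive_seed(seed, 20))
    }))
    names(signal) <- names(tabs)
  }

  if (on("nulls")) {
    ses <- run_stage("alpha_nulls", lapply(names(tabs), function(k) {
      rbind(ses_alpha_series(tabs[[k]], trees[[k]], "MPD", cfg$n_null,
                             derive_seed(seed, 30)),
            ses_alpha_series(tabs[[k]], trees[[k]], "MNTD", cfg$n_null,
                             derive_seed(seed, 31)))
    }))
    names(ses) <- names(tabs)
    turnover <- run_stage("turnover_nulls", lapply(names(tabs), function(k)
      turnover_series(tabs[[k]], trees[[k]], cfg$n_null,
                      derive_seed(seed, 40))))
    names(turnover) <- names(tabs)
  }

  if (on("networks")) {
    nets <- run_stage("networks", lapply(names(tabs), function(k)
      kingdom_network(tabs[[k]], cfg, derive_seed(seed, 50))))
    names(nets) <- names(tabs)
  }

  if (on("bipartite")) {
    bipartite <- run_stage("bipartite", build_bipartite_core_network(
      tabs$prokaryote, tabs$eukaryote,
      if (on("networks")) nets$prokaryote$network,
      if (on("networks")) nets$eukaryote$network,
      core_prevalence = cfg$core_prevalence,
      corr_threshold = cfg$corr_threshold, alpha = cfg$alpha,
      sparcc_control = cfg$sparcc_control, seed = derive_seed(seed, 60)))
  }

  if (on("ordination")) {
    if (is.null(hill)) stop("ordination stage needs the diversity stage")
    ordin <- run_stage("ordination", list(
      prokaryote = kingdom_ordination(tabs$prokaryote, env, hill$eukaryote,
                                      cfg, derive_seed(seed, 70)),
      eukaryote = kingdom_ordination(tabs$eukaryote, env, hill$prokaryote,
                                     cfg, derive_seed(seed, 71))))
  }

  summary <- pipeline_summary(env, hill, beta, signal, ses, turnover, nets,
                              bipartite, ordin, cfg)
  res <- list(dataset = ds, env = env, tables = tabs, hill = hill,
              beta = beta, signal = signal, ses = ses, turnover = turnover,
              networks = nets, bipartite = bipartite, ordination = ordin,
              summary = summary, config = cfg)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(res, cfg$outdir)
  res
}

stage_means <- function(values, stage) {
  out <- tapply(values, stage, mean)
  as.list(out[c("floccular", "intermediate", "granular")])
}

# Machine-readable run summary: per-stage means, significance-call
# fractions, network sizes, variance fractions, effective parameters.
pipeline_summary <- function(env, hill, beta, signal, ses, turnover, nets,
                             bipartite, ordin, cfg) {
  pair_stage <- env$stage[-1]   # stage of the later sample of each pair
  kingdoms <- c("prokaryote", "eukaryote")
  per_kingdom <- lapply(kingdoms, function(k) {
    out <- list()
    if (!is.null(hill)) {
      out$mean_qTD <- lapply(split(hill[[k]]$qTD, hill[[k]]$q), mean)
      out$mean_beta_dis <- lapply(split(beta[[k]]$beta_dis, beta[[k]]$q),
                                  mean)
    }
    if (!is.null(signal)) {
      out$shortest_class_mantel_r <- signal[[k]]$mantel_r[1]
      out$shortest_class_p <- signal[[k]]$p_corrected[1]
    }
    if (!is.null(ses)) {
      ses_k <- ses[[k]]
      out$nri_stage_mean <- stage_means(
        ses_k$ses[ses_k$statistic == "MPD"], env$stage)
      out$nti_stage_mean <- stage_means(
        ses_k$ses[ses_k$statistic == "MNTD"], env$stage)
      to <- turnover[[k]]
      out$bnti_frac_significant <-
        stage_means(as.numeric(to$bnti_significant), pair_stage)
      out$rc_frac_significant <-
        stage_means(as.numeric(to$rc_significant), pair_stage)
    }
    if (!is.null(nets)) {
      net <- nets[[k]]$network
      out$network <- list(n_nodes = nrow(net$nodes),
                          n_edges = nrow(net$edges),
                          n_modules = length(unique(net$nodes$module)))
    }
    if (!is.null(ordin)) {
      out$varpart <- stats::setNames(as.list(ordin[[k]]$varpart$adj_r2),
                                     ordin[[k]]$varpart$fraction)
      out$selected_abiotic <- ordin[[k]]$selected_abiotic
    }
    out
  })
  names(per_kingdom) <- kingdoms
  out <- list(schema_version = "1.0",
              n_samples = nrow(env),
              stages = as.list(table(env$stage)),
              kingdoms = per_kingdom,
              parameters = cfg[c("min_prevalence", "min_rel_abundance",
                                 "q_grid", "n_null", "corr_threshold",
                                 "alpha", "core_prevalence",
                                 "signal_variable", "n_perm", "seed")])
  if (!is.null(bipartite))
    out$bipartite <- list(
      n_prok_core = sum(bipartite$nodes$kingdom == "prokaryote"),
      n_euk_core = sum(bipartite$nodes$kingdom == "eukaryote"),
      n_edges = nrow(bipartite$edges))
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    if (!is.null(df))
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  for (k in c("prokaryote", "eukaryote")) {
    wt(res$hill[[k]], paste0(k, "_hill.tsv"))
    wt(res$beta[[k]], paste0(k, "_beta_series.tsv"))
    wt(res$signal[[k]], paste0(k, "_mantel_correlogram.tsv"))
    wt(res$ses[[k]], paste0(k, "_ses_alpha.tsv"))
    wt(res$turnover[[k]], paste0(k, "_turnover.tsv"))
    wt(res$networks[[k]]$network$edges, paste0(k, "_network_edges.tsv"))
    wt(res$networks[[k]]$network$nodes, paste0(k, "_network_nodes.tsv"))
    wt(res$networks[[k]]$dynamics, paste0(k, "_module_dynamics.tsv"))
    wt(res$networks[[k]]$sample_stats,
       paste0(k, "_sample_network_stats.tsv"))
    wt(res$ordination[[k]]$varpart, paste0(k, "_varpart.tsv"))
  }
  wt(res$bipartite$edges, "bipartite_edges.tsv")
  wt(res$bipartite$nodes, "bipartite_nodes.tsv")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
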