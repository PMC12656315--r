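#' Default pipeline configuration
#'
#' @param seed master seed for every stochastic stage.
#' @return nested list consumable by [run_pipeline()]; saveable as YAML.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(seed = seed,
       synth = list(enabled = TRUE),
       aggregates = list(max_diameter = 5, force_origin = FALSE),
       sqi = list(by_season = TRUE, scoring = "linear", eigen_min = 1,
                  loading_window = 0.1, corr_redundancy = 0.5),
       community = list(depth = "min", n_perm = 999),
       network = list(r_threshold = 0.7, p_threshold = 0.05,
                      method = "spearman", min_prevalence = 4,
                      pool_treatments = TRUE),
       anova = list(indicator = "pH", alpha = 0.05),
       plspm = list(tol = 1e-7, max_iter = 300, prune = 0.5))
}

# stable FNV-1a hash of the serialised config (no binary deps)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates synth -> aggregates -> sqi -> community -> network ->
#' anova -> plspm under one seed; writes every stage artifact under
#' `outdir` plus a run manifest. Deterministic: re-running with the same
#' config and seed reproduces every output byte-identically (manifest
#' wall-times aside).
#'
#' @param config nested list as from [default_pipeline_config()], or a
#'   YAML file path.
#' @param outdir run directory (created).
#' @return the manifest list, invisibly; `$results` carries the
#'   in-memory stage outputs.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  seed <- config$seed
  fresh <- !dir.exists(outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  results <- list()
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      # leave no partial artifacts behind a failed run
      if (fresh) unlink(outdir, recursive = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    stages[[name]] <<- list(stage = name,
                            seconds = proc.time()[["elapsed"]] - t0)
    out
  }

  cfg <- synth_config(seed = seed)
  results$synth <- t_stage("synth", function() {
    generate_study(cfg, file.path(outdir, "inputs"))
  })
  exp <- attr(results$synth, "experiment")
  com <- attr(results$synth, "community")

  results$aggregates <- t_stage("aggregates", function() {
    agg <- aggregate_indices_table(exp$sieves,
                                   force_origin = config$aggregates$force_origin)
    write.table(agg, file.path(outdir, "aggregate_indices.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg
  })

  results$sqi <- t_stage("sqi", function() {
    sq <- soil_quality_index(exp$table,
                             by_season = config$sqi$by_season,
                             method = config$sqi$scoring,
                             eigen_min = config$sqi$eigen_min,
                             loading_window = config$sqi$loading_window,
                             corr_redundancy = config$sqi$corr_redundancy)
    write.table(sq$table, file.path(outdir, "sqi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sq
  })

  results$community <- t_stage("community", function() {
    treat <- sub("-R[0-9]+$", "", colnames(com$bacteria))
    out <- lapply(list(bacteria = com$bacteria, fungi = com$fungi),
                  function(ft) {
      rft <- rarefy(ft, depth = config$community$depth, seed = seed)
      ad <- alpha_diversity(rft)
      d <- bray_curtis(rft)
      ord <- pcoa(d)
      list(alpha = ad, dist = d, pcoa = ord,
           permanova = permanova(d, treat, config$community$n_perm, seed),
           anosim = anosim(d, treat, config$community$n_perm, seed))
    })
    out$mantel <- mantel(out$bacteria$dist, out$fungi$dist,
                         config$community$n_perm, seed)
    write.table(rbind(cbind(kingdom = "bacteria", out$bacteria$alpha),
                      cbind(kingdom = "fungi", out$fungi$alpha)),
                file.path(outdir, "alpha_diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(bacteria = list(permanova = out$bacteria$permanova,
                           anosim = out$bacteria$anosim),
           fungi = list(permanova = out$fungi$permanova,
                        anosim = out$fungi$anosim),
           mantel = out$mantel),
      file.path(outdir, "community_tests.json"), auto_unbox = TRUE,
      digits = NA)
    out
  })

  results$network <- t_stage("network", function() {
    combined <- feature_table(
      rbind(unclass(com$bacteria), unclass(com$fungi)),
      kingdom = c(attr(com$bacteria, "kingdom"),
                  attr(com$fungi, "kingdom")))
    corr <- pairwise_correlation(combined,
                                 method = config$network$method,
                                 min_prevalence = config$network$min_prevalence)
    net <- build_network(corr, config$network$r_threshold,
                         config$network$p_threshold)
    if (nrow(net$edges) > 0) {
      net <- detect_modules(net, seed = seed)
      net <- zipi(net)
      net <- assign_roles(net)
    }
    write_network_graphml(net, file.path(outdir, "network.graphml"))
    write.table(net$nodes, file.path(outdir, "node_roles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    topo <- network_topology(net)
    jsonlite::write_json(topo, file.path(outdir, "network_topology.json"),
                         auto_unbox = TRUE, digits = NA)
    list(network = net, topology = topo)
  })

  results$anova <- t_stage("anova", function() {
    ind <- config$anova$indicator
    tab <- exp$table
    an <- two_way_anova(tab[[ind]], tab$treatment, tab$crop_season)
    letters <- do.call(rbind, lapply(season_levels(), function(s) {
      sel <- tab$crop_season == s
      cbind(crop_season = s,
            duncan_mrt(tab[[ind]][sel], tab$treatment[sel],
                       alpha = config$anova$alpha))
    }))
    write.table(an, file.path(outdir, "anova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(letters, file.path(outdir, "duncan_letters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(anova = an, letters = letters)
  })

  results$plspm <- t_stage("plspm", function() {
    sem <- generate_sem_data(cfg)
    fit <- fit_plspm(sem$data, sem$spec, tol = config$plspm$tol,
                     max_iter = config$plspm$max_iter)
    spec2 <- prune_loadings(fit, config$plspm$prune)
    fit2 <- fit_plspm(sem$data, spec2, tol = config$plspm$tol,
                      max_iter = config$plspm$max_iter)
    write.table(fit2$path_coefficients,
                file.path(outdir, "plspm_paths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(gof = fit2$gof, r_squared = fit2$r_squared,
                              communality = fit2$communality),
                         file.path(outdir, "plspm_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit2, truth = sem$truth)
  })

  manifest <- list(config_hash = config_hash(config), seed = seed,
                   version = as.character(packageVersion("soilamend")),
                   stages = unname(stages))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- results
  invisible(manifest)
}
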