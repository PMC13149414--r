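#' Default pipeline configuration
#'
#' Mirrors the shipped `inst/extdata/default_config.yaml`: simulate the
#' default synthetic panel, fit on the EAC land-border graph with the
#' default penalized-complexity hyperpriors, and run the full diagnostics
#' and effect extraction.
#'
#' @param seed RNG seed used for simulation and inference.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(panel = NULL,
       simulate = list(seed = seed),
       graph = "eac", lake_edges = FALSE,
       vif_threshold = 5,
       priors = NULL,
       inference = list(n_iter = 2000L, burnin = 700L, thin = 2L,
                        seed = seed))
}

#' Read a pipeline configuration file
#'
#' YAML with keys `panel` (CSV path or null to simulate), `simulate`
#' (arguments of [simulation_config()]), `graph` (`"eac"` or an edge-list
#' CSV path), `lake_edges`, `vif_threshold`, `priors` (overrides of
#' [default_hyperpriors()]), `inference` (arguments of [fit_control()]).
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Run the full analysis pipeline
#'
#' validate -> standardize -> VIF screen -> fit -> diagnostics -> effect
#' extraction -> export. Every stage failure aborts with the stage name.
#' Writes all tables plus a run manifest into `out`.
#'
#' @param config configuration list (see [read_config()]) or a YAML path.
#' @param out output directory (created if absent).
#' @param seed optional override of the config seeds.
#' @param verbose print stage progress.
#' @return (invisibly) list with panel, model, posterior, diagnostics,
#'   surfaces, vif, and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out = tempfile("run"),
                         seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) {
    config$simulate$seed <- seed
    config$inference$seed <- seed
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline aborted in stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  truth <- NULL
  panel <- stage("ingest", {
    if (!is.null(config$panel)) {
      read_panel_csv(config$panel)
    } else {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- 1L
      sim <- do.call(simulation_config, sim_args)
      res <- simulate_panel(sim)
      truth <<- res$truth
      write_panel_csv(res$panel, file.path(out, "panel.csv"))
      write_truth_csv(res$truth, file.path(out, "truth_synthetic.csv"))
      res$panel
    }
  })
  graph <- stage("graph", {
    if (identical(config$graph, "eac")) {
      build_eac_graph(lake_edges = isTRUE(config$lake_edges))
    } else {
      read_graph_csv(config$graph)
    }
  })
  screened <- stage("covariate_screen", {
    sc <- standardize_covariates(panel)
    vif <- compute_vif(covariate_cells(sc$panel)$X,
                       threshold = config$vif_threshold)
    utils::write.csv(sc$record, file.path(out, "standardization.csv"),
                     row.names = FALSE)
    utils::write.csv(vif, file.path(out, "vif.csv"), row.names = FALSE)
    list(record = sc$record, vif = vif)
  })
  priors <- default_hyperpriors()
  if (!is.null(config$priors)) priors <- utils::modifyList(priors, config$priors)
  model <- stage("model", build_model(panel, graph, priors = priors))
  posterior <- stage("fit", {
    ctrl <- do.call(fit_control, config$inference)
    sample_hyperparameters(model, ctrl)
  })
  stage("summaries", {
    utils::write.csv(fixed_effect_summary(posterior),
                     file.path(out, "fixed_effects.csv"), row.names = FALSE)
    utils::write.csv(hyper_summary(posterior),
                     file.path(out, "hyperparameters.csv"), row.names = FALSE)
  })
  diagnostics <- stage("diagnostics", {
    dg <- model_diagnostics(posterior)
    flat <- data.frame(
      key = c("dic", "p_d", "waic", "p_waic", "lppd", "lcpo", "lcpo_mean",
              "cpo_failures", "predictive_coverage"),
      value = c(dg$dic, dg$p_d, dg$waic, dg$p_waic, dg$lppd, dg$lcpo,
                dg$lcpo_mean, dg$cpo_failures, dg$predictive_coverage))
    utils::write.csv(flat, file.path(out, "diagnostics.csv"), row.names = FALSE)
    perrow <- cbind(as.data.frame(panel)[, c("country_id", "year", "disease")],
                    cpo = dg$cpo, pit = dg$pit, dg$observed_vs_fitted[-1L])
    utils::write.csv(perrow, file.path(out, "cpo_pit_fitted.csv"),
                     row.names = FALSE)
    dg
  })
  surfaces <- stage("extract", {
    comps <- c("lambda", "u", "phi", "v", "rr")
    ss <- lapply(comps, extract_effect, posterior = posterior)
    names(ss) <- comps
    for (cmp in comps) {
      write_effect_csv(ss[[cmp]], file.path(out, paste0("effect_", cmp, ".csv")))
    }
    write_rr_csv(posterior, file.path(out, "relative_risk.csv"))
    ss
  })
  manifest <- list(
    package = "sharedmap",
    version = as.character(utils::packageVersion("sharedmap")),
    r_version = R.version.string,
    seed = list(simulate = config$simulate$seed,
                inference = config$inference$seed),
    config = utils::modifyList(config, list(graph = if (is.character(config$graph))
      config$graph else "custom")),
    timings_sec = lapply(timings, round, 2),
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  say("pipeline finished in ", manifest$total_sec, " s -> ", out)
  invisible(list(panel = panel, truth = truth, model = model,
                 posterior = posterior, diagnostics = diagnostics,
                 surfaces = surfaces, vif = screened$vif,
                 standardization = screened$record, manifest = manifest,
                 out = out))
}
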