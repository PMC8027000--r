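#' Run configuration
#'
#' Validates and normalizes a pipeline configuration, either built in code or
#' read from a YAML file with [read_run_config()]. Exactly one of `input`
#' (paths to a feature table + annotation sidecar) or `simulation` (arguments
#' for [sim_config()]) must be present.
#'
#' @param config named list with optional blocks `input` (`table`,
#'   `annotations`, optional `reference_reactions` paths), `simulation`
#'   ([sim_config()] arguments), `preprocessing` (`max_missing_fraction`,
#'   `k`, `glog_offset`), `ggm` (`q`, `trim`), and scalars `cohort`,
#'   `output_dir`, `seed`.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(config) {
  cfg <- config
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim)
    stop("exactly one of 'input' and 'simulation' must be configured")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$cohort <- if (is.null(cfg$cohort)) "cohort" else as.character(cfg$cohort)
  pp <- cfg$preprocessing
  cfg$preprocessing <- list(
    max_missing_fraction = if (is.null(pp$max_missing_fraction)) 0.5
                           else as.numeric(pp$max_missing_fraction),
    k = if (is.null(pp$k)) 10L else as.integer(pp$k),
    glog_offset = pp$glog_offset)
  gg <- cfg$ggm
  cfg$ggm <- list(q = if (is.null(gg$q)) 0.1 else as.numeric(gg$q),
                  trim = if (is.null(gg$trim)) 0.9 else as.numeric(gg$trim))
  if (cfg$preprocessing$max_missing_fraction < 0 ||
      cfg$preprocessing$max_missing_fraction >= 1)
    stop("preprocessing$max_missing_fraction must lie in [0, 1)")
  if (cfg$ggm$q <= 0 || cfg$ggm$q >= 1) stop("ggm$q must lie in (0, 1)")
  if (has_sim) {
    sim_args <- cfg$simulation
    sim_args$seed <- if (is.null(sim_args$seed)) cfg$seed else sim_args$seed
    cfg$simulation <- do.call(sim_config, sim_args)
  }
  if (has_input && is.null(cfg$input$table))
    stop("input block requires a 'table' path")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Split a feature table into strata
#'
#' Returns the per-label sub-tables plus the pooled table, re-running the
#' missingness filter downstream per stratum (different strata legitimately
#' retain different molecule sets, e.g. a chemical detectable in only one
#' occupational group).
#'
#' @param table a [feature_table()].
#' @param groups named character vector (or factor) mapping every sample id
#'   to a stratum label.
#' @return Named list of `feature_table`s: one per label plus `"pooled"`.
#' @export
stratify <- function(table, groups) {
  stopifnot(inherits(table, "feature_table"))
  ids <- rownames(table$intensities)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) && length(groups) == length(ids))
    names(groups) <- ids
  unlabeled <- setdiff(ids, names(groups))
  if (length(unlabeled))
    stop("unlabeled sample(s): ", paste(unlabeled, collapse = ", "))
  labels <- unique(groups[ids])
  out <- lapply(labels, function(l)
    subset_table(table, samples = ids[groups[ids] == l]))
  names(out) <- labels
  out$pooled <- table
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end run from a [run_config()]: simulate or load
#' the annotated feature table, preprocess it, fit the Gaussian graphical
#' model, build the typed network, export GraphML/SIF/edge tables, score the
#' overlay against a reference reaction set (if configured) and against the
#' synthetic ground truth (if simulated), and write a run manifest. Re-running
#' with the same configuration reproduces identical artifacts.
#'
#' @param config a `run_config` (or plain list passed through
#'   [run_config()]).
#' @param output_dir overrides `config$output_dir`; `NULL` keeps results in
#'   memory only.
#' @return Invisibly, a list with `table`, `preprocessed`, `report`, `fit`,
#'   `network`, `overlay` (or NULL), `recovery` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config, output_dir = config$output_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_cohort(config$simulation))
    table <- sim$table
    truth <- sim$model
  } else {
    table <- stage("load", {
      ann <- config$input$annotations
      if (is.null(ann)) read_feature_table(config$input$table)
      else read_feature_table(config$input$table, ann)
    })
  }
  prep <- stage("preprocess",
                preprocess(table,
                           max_missing_fraction =
                             config$preprocessing$max_missing_fraction,
                           k = config$preprocessing$k,
                           glog_offset = config$preprocessing$glog_offset))
  fit <- stage("ggm", fit_ggm(prep$table, q = config$ggm$q,
                              trim = config$ggm$trim))
  network <- stage("network",
                   build_network(fit, cohort = config$cohort))
  overlay <- NULL
  if (!is.null(config$input$reference_reactions)) {
    ref <- stage("overlay",
                 read_reference_reactions(config$input$reference_reactions))
    overlay <- stage("overlay", overlay_reference(network, ref))
  }
  recovery <- if (!is.null(truth))
    stage("evaluate", evaluate_recovery(network, truth))
  manifest <- list(
    cohort = config$cohort,
    seed = config$seed,
    n_samples = nrow(prep$table$intensities),
    n_molecules = ncol(prep$table$intensities),
    removed_molecules = nrow(prep$report$removed_molecules),
    imputed_cells = prep$report$imputed_cell_count,
    shrinkage_lambda = fit$shrinkage_lambda,
    null_kappa = fit$null_kappa,
    fdr_threshold = fit$fdr_threshold,
    pvalue_cutoff = fit$pvalue_cutoff,
    n_edges = fit$n_edges,
    package_version = as.character(utils::packageVersion("exposonet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  result <- list(table = table, preprocessed = prep$table,
                 report = prep$report, fit = fit, network = network,
                 overlay = overlay, recovery = recovery, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(output_dir, f)
    write_preprocess_report(prep$report, fp("preprocess_report.txt"))
    write_ggm_matrices(fit, fp("pcor.tsv"), fp("pvalues.tsv"))
    write_edge_table(edge_table(fit, significant_only = TRUE),
                     fp("edges.tsv"))
    write_graphml(network, fp("network.graphml"))
    write_sif(network, fp("network.sif"))
    if (!is.null(overlay)) {
      write_overlay_report(overlay, fp("overlay_report.txt"))
      write_overlay_graphml(network, overlay, fp("overlay.graphml"))
    }
    if (!is.null(recovery))
      writeLines(paste(names(recovery),
                       vapply(recovery, format, "", digits = 15), sep = ": "),
                 fp("recovery.txt"))
    yaml::write_yaml(manifest, fp("manifest.yaml"))
  }
  invisible(result)
}

#' Run the pipeline separately per stratum
#'
#' Mirrors stratified cohort analyses: fits one model per stratum label plus
#' the pooled data, re-applying the missingness filter within each stratum.
#'
#' @param table a [feature_table()] (raw, pre-filtering).
#' @param groups sample-to-label map as in [stratify()].
#' @param ... arguments forwarded to [preprocess()] / [fit_ggm()] via a
#'   common configuration: `max_missing_fraction`, `k`, `q`, `trim`.
#' @param q FDR threshold per stratum, default 0.1.
#' @return Named list (per label + `pooled`) of lists with `fit`, `network`
#'   and `table` (the stratum's preprocessed table).
#' @export
run_stratified <- function(table, groups, q = 0.1, ...) {
  strata <- stratify(table, groups)
  lapply(stats::setNames(names(strata), names(strata)), function(l) {
    prep <- preprocess(strata[[l]], ...)
    fit <- fit_ggm(prep$table, q = q)
    list(fit = fit, network = build_network(fit, cohort = l),
         table = prep$table)
  })
}
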