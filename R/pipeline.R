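#' Build a validated pipeline configuration
#'
#' All tunable parameters of the screen pipeline in one list. Defaults
#' reproduce the screen's analysis settings: an 8-percentage-point change
#' threshold with the strict dual-siRNA rule, 10% relative size tolerance
#' for amplicon matching, average linkage.
#'
#' @param n_ases number of ASEs to simulate (ignored when `catalog_path`
#'   points at data to load).
#' @param cell_lines cell lines to screen; default the five lines of
#'   [rbm10_kd_table()].
#' @param threshold change threshold in psi points (> 0).
#' @param rel_tol amplicon matching tolerance.
#' @param lenient one-siRNA-over-threshold change rule variant.
#' @param linkage `"average"` or `"ward"`.
#' @param seed integer seed controlling every random draw.
#' @param prop_null,discordant_rate,respond_prob,effect_mean,effect_sd
#'   truth-table parameters (see [generate_truth()]).
#' @param baseline_sd,size_jitter_sd,amount_cv noise model (see
#'   [noise_model()]).
#' @param output `"peaks"` or `"traces"` simulation route.
#' @param sirna_days `"shared"` or `"separate"` mock pairing.
#' @param min_height,min_separation,min_total quantification settings.
#' @param catalog_path,peaks_path,samples_path load a screen from TSV files
#'   instead of simulating (all three required together).
#' @param gmt_path optional GMT file for enrichment.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_ases = 96, cell_lines = unique(rbm10_kd_table()$cell_line),
                            threshold = 8, rel_tol = 0.10, lenient = FALSE,
                            linkage = c("average", "ward"), seed = 1L,
                            prop_null = 0.6, discordant_rate = 0.05,
                            respond_prob = 0.6, effect_mean = 20, effect_sd = 5,
                            baseline_sd = 8, size_jitter_sd = 0.02,
                            amount_cv = 0.05, output = c("peaks", "traces"),
                            sirna_days = c("shared", "separate"),
                            min_height = 50, min_separation = 0.5, min_total = 0,
                            catalog_path = NULL, peaks_path = NULL,
                            samples_path = NULL, gmt_path = NULL,
                            out_dir = tempfile("psiscreen_run_")) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  if (rel_tol <= 0 || rel_tol >= 0.5)
    stop("rel_tol must lie in (0, 0.5)", call. = FALSE)
  loading <- !is.null(catalog_path) || !is.null(peaks_path) || !is.null(samples_path)
  if (loading && (is.null(catalog_path) || is.null(peaks_path) || is.null(samples_path)))
    stop("catalog_path, peaks_path and samples_path must be given together",
         call. = FALSE)
  if (loading) {
    for (p in c(catalog_path, peaks_path, samples_path))
      if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path))
    stop("input not found: ", gmt_path, call. = FALSE)
  structure(list(
    n_ases = n_ases, cell_lines = cell_lines, threshold = threshold,
    rel_tol = rel_tol, lenient = isTRUE(lenient), linkage = match.arg(linkage),
    seed = as.integer(seed), prop_null = prop_null,
    discordant_rate = discordant_rate, respond_prob = respond_prob,
    effect_mean = effect_mean, effect_sd = effect_sd,
    baseline_sd = baseline_sd, size_jitter_sd = size_jitter_sd,
    amount_cv = amount_cv, output = match.arg(output),
    sirna_days = match.arg(sirna_days), min_height = min_height,
    min_separation = min_separation, min_total = min_total,
    catalog_path = catalog_path, peaks_path = peaks_path,
    samples_path = samples_path, gmt_path = gmt_path, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full splicing-screen pipeline
#'
#' Simulates (or loads) a screen, quantifies psi for every sample x ASE,
#' computes same-day delta-psi, applies the dual-siRNA change rule,
#' summarizes the screen, clusters the changed profiles, optionally tests
#' gene-set over-representation, and writes every result table to
#' `config$out_dir`. Re-running with an identical config reproduces
#' identical output files.
#'
#' Output files: `catalog.tsv`, `samples.tsv`, `psi.tsv`, `delta_psi.tsv`,
#' `calls.tsv`, `summary.tsv`, `matrix.tsv`, `clusters.tsv`,
#' `enrichment.tsv` (when a GMT is given), `truth.tsv` (when simulated)
#' and `run_log.txt`.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with every intermediate object (`screen`,
#'   `psi`, `delta`, `calls`, `summary`, `consensus`, `matrix`, `tree`,
#'   `clusters`, `enrichment`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage <- "setup"
  on_fail <- function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    stage <- "input"
    simulated <- is.null(config$catalog_path)
    if (simulated) {
      catalog <- generate_ase_catalog(config$n_ases)
      truth <- generate_truth(
        catalog, config$cell_lines, prop_null = config$prop_null,
        effect_dist = list(mean_abs = config$effect_mean, sd = config$effect_sd),
        kd_table = rbm10_kd_table(), discordant_rate = config$discordant_rate,
        respond_prob = config$respond_prob)
      screen <- simulate_screen(
        catalog, truth,
        noise = noise_model(config$baseline_sd, config$size_jitter_sd,
                            config$amount_cv),
        output = config$output, sirna_days = config$sirna_days)
    } else {
      catalog <- validate_catalog(read_screen_table(config$catalog_path, "catalog"))
      screen <- list(catalog = catalog,
                     samples = read_screen_table(config$samples_path, "samples"),
                     peaks = read_screen_table(config$peaks_path, "peaks"))
      truth <- NULL
    }

    stage <- "quantify"
    psi <- quantify_screen(screen, min_height = config$min_height,
                           min_separation = config$min_separation,
                           rel_tol = config$rel_tol, min_total = config$min_total)
    stage <- "delta_psi"
    delta <- compute_delta_psi(psi)
    stage <- "call"
    calls <- call_changes(delta, threshold = config$threshold,
                          lenient = config$lenient)
    stage <- "summarize"
    summ <- summarize_screen(calls, n_ases = nrow(catalog))
    consensus <- if (length(unique(calls$cell_line)) >= 2L)
      consensus_distribution(calls) else NULL

    stage <- "cluster"
    mat <- build_dpsi_matrix(delta, calls, catalog = catalog)
    tree <- NULL
    clusters <- NULL
    if (nrow(mat) >= 2L) {
      tree <- hierarchical_cluster(mat, linkage = config$linkage)
      clusters <- cut_k(tree, k = min(2L, nrow(mat)))
    }

    stage <- "enrich"
    enrichment <- NULL
    if (!is.null(config$gmt_path)) {
      changed_genes <- unique(catalog$gene[catalog$ase_id %in%
                                             calls$ase_id[calls$changed]])
      enrichment <- test_overrepresentation(changed_genes,
                                            unique(catalog$gene),
                                            read_gmt(config$gmt_path))
    }

    stage <- "write"
    out <- config$out_dir
    write_screen_table(catalog, file.path(out, "catalog.tsv"), "catalog")
    write_screen_table(screen$samples, file.path(out, "samples.tsv"), "samples")
    write_screen_table(psi, file.path(out, "psi.tsv"), "psi")
    write_screen_table(delta, file.path(out, "delta_psi.tsv"), "delta_psi")
    write_screen_table(calls, file.path(out, "calls.tsv"), "calls")
    if (!is.null(truth))
      write_screen_table(truth$effects, file.path(out, "truth.tsv"), "truth")
    write_summary_tsv(summ, consensus, file.path(out, "summary.tsv"))
    if (nrow(mat) >= 1L) {
      utils::write.table(data.frame(row = rownames(mat), mat, check.names = FALSE),
                         file.path(out, "matrix.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    }
    if (!is.null(tree)) {
      utils::write.table(
        data.frame(row = names(clusters), cluster = as.integer(clusters),
                   leaf_position = order(tree$rows$order)[seq_along(clusters)]),
        file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    if (!is.null(enrichment))
      write_screen_table(enrichment, file.path(out, "enrichment.tsv"), "enrichment")
    write_run_log(config, summ, file.path(out, "run_log.txt"))

    invisible(list(screen = screen, psi = psi, delta = delta, calls = calls,
                   summary = summ, consensus = consensus, matrix = mat,
                   tree = tree, clusters = clusters, enrichment = enrichment,
                   out_dir = out))
  }, error = on_fail)
}

# internal: key/value summary table
write_summary_tsv <- function(summ, consensus, path) {
  kv <- list(
    n_ases = summ$n_ases,
    n_changed_any = summ$n_changed_any,
    pct_changed_any = summ$pct_changed_any,
    pct_changed_any_printed = summ$formatted$changed_any,
    n_inclusion_events = summ$direction_counts[["inclusion"]],
    n_exclusion_events = summ$direction_counts[["exclusion"]],
    pct_inclusion_events = summ$pct_inclusion_events
  )
  for (cl in names(summ$per_cell_line))
    kv[[paste0("changed_", cl)]] <- summ$per_cell_line[[cl]]
  for (k in names(summ$multiplicity))
    kv[[paste0("multiplicity_k", k)]] <- summ$multiplicity[[k]]
  utils::write.table(
    data.frame(key = names(kv), value = vapply(kv, as.character, character(1))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: deterministic run log (no timestamps, so identical configs give
# byte-identical outputs)
write_run_log <- function(config, summ, path) {
  param_keys <- setdiff(names(unclass(config)), "out_dir")
  lines <- c(
    sprintf("psiscreen %s", as.character(utils::packageVersion("psiscreen"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    "parameters:",
    vapply(param_keys, function(k) {
      v <- config[[k]]
      sprintf("  %s: %s", k, if (is.null(v)) "NULL" else paste(v, collapse = ","))
    }, character(1)),
    sprintf("result: %d/%d ASEs changed", summ$n_changed_any, summ$n_ases)
  )
  writeLines(lines, path)
  invisible(path)
}
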