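#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Input is either raw focal
#' records plus a sampling-effort table (`input = "records"`) or a
#' directory of precomputed symmetric dyadic matrices, one CSV per layer
#' (`input = "matrices"`; layer label = file name without extension).
#'
#' @param input `"records"` or `"matrices"`.
#' @param records path to the focal-record CSV (records mode).
#' @param effort path to the sampling-effort CSV (records mode).
#' @param matrices_dir directory of dyadic-matrix CSVs (matrices mode).
#' @param period_id optional period selector for multi-period files.
#' @param exclude ids to exclude; indices are recalculated on the reduced
#'   universe.
#' @param omega interlayer coupling weight.
#' @param couple_all couple individuals between all layers regardless of
#'   presence.
#' @param overlap_method pairwise overlap method
#'   (`weighted_min`/`binary_jaccard`).
#' @param global_method global overlap method
#'   (`mean_pairwise`/`all_layers_weighted`).
#' @param ward Ward convention, `"d2"` or `"d1"`.
#' @param normalization centrality normalization, `"max"` or `"sum"`.
#' @param sd_type rate SD convention, `"sample"` or `"population"`.
#' @param seed integer seed echoed into the report (the analysis itself is
#'   deterministic; the seed drives only simulation).
#' @param out output directory.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = c("records", "matrices"),
                            records = NULL, effort = NULL,
                            matrices_dir = NULL, period_id = NULL,
                            exclude = character(),
                            omega = 1, couple_all = FALSE,
                            overlap_method = c("weighted_min",
                                               "binary_jaccard"),
                            global_method = c("mean_pairwise",
                                              "all_layers_weighted"),
                            ward = c("d2", "d1"),
                            normalization = c("max", "sum"),
                            sd_type = c("sample", "population"),
                            seed = 1, out = "socmux_out") {
  input <- match.arg(input)
  overlap_method <- match.arg(overlap_method)
  global_method <- match.arg(global_method)
  ward <- match.arg(ward)
  normalization <- match.arg(normalization)
  sd_type <- match.arg(sd_type)
  if (input == "records") {
    if (is.null(records) || is.null(effort))
      stop("records mode needs 'records' and 'effort' paths", call. = FALSE)
  } else if (is.null(matrices_dir)) {
    stop("matrices mode needs 'matrices_dir'", call. = FALSE)
  }
  if (!is.finite(omega) || omega <= 0)
    stop("omega must be positive", call. = FALSE)
  structure(list(input = input, records = records, effort = effort,
                 matrices_dir = matrices_dir, period_id = period_id,
                 exclude = as.character(exclude), omega = omega,
                 couple_all = isTRUE(couple_all),
                 overlap_method = overlap_method,
                 global_method = global_method, ward = ward,
                 normalization = normalization, sd_type = sd_type,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror the arguments of [pipeline_config()]; `overrides` (e.g.
#' from CLI flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Simulate a focal-sampling data set to disk
#'
#' Writes `records.csv` and `effort.csv` for a synthetic observation
#' period (see [synth_config()]).
#'
#' @param out output directory (created if needed).
#' @param seed RNG seed.
#' @param config optional full [synth_config()]; when given, `seed` is
#'   ignored in its favour.
#' @return invisible list with the two paths.
#' @export
stage_simulate <- function(out, seed = 1, config = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- config %||% synth_config(seed = seed)
  sim <- simulate_focal_records(cfg)
  rp <- file.path(out, "records.csv")
  ep <- file.path(out, "effort.csv")
  write_focal_records(sim$records, rp)
  write_sampling_effort(sim$effort, ep, cfg$period_id)
  log_stage("simulate", nrow(sim$records), " records for ",
            cfg$n_individuals, " individuals written to ", out)
  invisible(list(records = rp, effort = ep))
}

# Load dyadic indices according to the config; returns list of
# dyadic_index plus (records mode) descriptive summaries.
load_indices <- function(config) {
  if (config$input == "records") {
    records <- read_focal_records(config$records)
    if (!is.null(config$period_id))
      records <- records[records$period_id == config$period_id, , drop = FALSE]
    effort <- read_sampling_effort(config$effort, config$period_id)
    universe <- names(effort)
    keep <- setdiff(universe, config$exclude)
    types <- names(.type_behaviors)
    totals <- lapply(types, function(ty) dyadic_totals(records, ty, universe))
    names(totals) <- types
    if (length(config$exclude))
      totals <- lapply(totals, restrict_universe, keep = keep)
    nonzero <- vapply(totals, function(t) upper_sum(t$matrix) > 0, logical(1))
    if (!all(nonzero))
      log_stage("indices", "dropping zero-total layer(s): ",
                paste(types[!nonzero], collapse = ", "))
    totals <- totals[nonzero]
    rates <- lapply(totals, dyadic_rates, effort = effort[keep],
                    sd_type = config$sd_type)
    list(indices = lapply(totals, dyadic_index), rates = rates,
         records = records)
  } else {
    files <- sort(list.files(config$matrices_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files))
      stop("no CSV matrices in ", config$matrices_dir, call. = FALSE)
    labels <- sub("\\.csv$", "", basename(files))
    totals <- lapply(seq_along(files), function(i)
      as_dyadic_totals(read_dyadic_matrix(files[i]), labels[i]))
    names(totals) <- labels
    if (length(config$exclude)) {
      keep <- setdiff(totals[[1]]$universe, config$exclude)
      totals <- lapply(totals, restrict_universe, keep = keep)
    }
    list(indices = lapply(totals, dyadic_index), rates = NULL,
         records = NULL)
  }
}

#' Compute and write dyadic indices
#'
#' @param config a `pipeline_config`.
#' @return invisible list of `dyadic_index` objects.
#' @export
stage_indices <- function(config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  loaded <- load_indices(config)
  for (ix in loaded$indices)
    write_dyadic_matrix(ix, file.path(config$out,
                                      paste0("index_", ix$type, ".csv")))
  log_stage("indices", length(loaded$indices), " index layer(s) written")
  invisible(loaded)
}

#' Build the multiplex and export its edge list
#'
#' @param indices list of `dyadic_index` objects (e.g. from
#'   [stage_indices()]).
#' @param config a `pipeline_config`.
#' @return the `multiplex` object, invisibly.
#' @export
stage_build <- function(indices, config) {
  net <- build_multiplex(indices, omega = config$omega,
                         couple_all = config$couple_all)
  export_edge_list(net, file.path(config$out, "multiplex"))
  log_stage("build", n_layers(net), " layers, ",
            intra_layer_edges(net), " intra-layer edges")
  invisible(net)
}

#' Centrality, versatility and overlap analysis
#'
#' Writes `centrality.tsv` (per-layer eigenvector centrality plus
#' versatility) and `overlap.tsv`.
#'
#' @param net a `multiplex`.
#' @param config a `pipeline_config`.
#' @return invisible list with the centrality report and overlap tables.
#' @export
stage_analyze <- function(net, config) {
  rep <- centrality_report(net, config$normalization)
  utils::write.table(rep, file.path(config$out, "centrality.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ov <- NULL; gl <- NULL
  if (n_layers(net) >= 2) {
    ov <- overlap_table(net, config$overlap_method)
    gl <- global_edge_overlap(net, config$global_method,
                              config$overlap_method)
    utils::write.table(ov, file.path(config$out, "overlap.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  log_stage("analyze", "centrality/versatility for ",
            length(net$universe), " individuals")
  invisible(list(centrality = rep, overlap = ov, global_overlap = gl))
}

#' Structural reducibility stage
#'
#' Writes `jsd.tsv` (layer distance matrix) and `entropy_curve.tsv`
#' (relative entropy per aggregation step).
#'
#' @param net a `multiplex` with at least 2 layers.
#' @param config a `pipeline_config`.
#' @return the `reducibility` object, invisibly.
#' @export
stage_reduce <- function(net, config) {
  if (n_layers(net) < 2)
    stop("reduce: need >= 2 layers", call. = FALSE)
  red <- reduce_multiplex(net, config$ward)
  utils::write.table(as.data.frame(red$jsd),
                     file.path(config$out, "jsd.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(data.frame(step = seq_along(red$q) - 1, q = red$q),
                     file.path(config$out, "entropy_curve.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("reduce", "best step ", red$best_step)
  invisible(red)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Composes the stages: load observations (or matrices), compute dyadic
#' indices, build the multiplex, analyze centrality/versatility/overlap,
#' run the reducibility analysis, and write a human-readable summary with
#' a full provenance block (config echo, seed, config hash, package
#' version). Running the staged functions by hand with the same config
#' produces byte-identical artifacts.
#'
#' @param config a `pipeline_config` (or path to a YAML config file).
#' @return an `analysis_report` list with every computed component,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  loaded <- stage_indices(config)
  net <- stage_build(loaded$indices, config)
  ana <- stage_analyze(net, config)
  red <- if (n_layers(net) >= 2) stage_reduce(net, config) else NULL
  report <- list(config = config, rates = loaded$rates, network = net,
                 centrality = ana$centrality, overlap = ana$overlap,
                 global_overlap = ana$global_overlap, reducibility = red)
  class(report) <- "analysis_report"
  write_summary(report, file.path(config$out, "summary.txt"))
  log_stage("report", "summary written to ",
            file.path(config$out, "summary.txt"))
  invisible(report)
}

write_summary <- function(report, path) {
  cfg <- report$config
  net <- report$network
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# socmux analysis summary")
  w("package_version: %s", as.character(utils::packageVersion("socmux")))
  w("seed: %d", cfg$seed)
  w("config_hash: %s", config_hash(cfg))
  w("config:")
  for (nm in names(unclass(cfg))) {
    v <- cfg[[nm]]
    w("  %s: %s", nm, if (is.null(v) || !length(v)) "~"
      else paste(v, collapse = ","))
  }
  w("")
  w("individuals: %d (%s)", length(net$universe),
    paste(net$universe, collapse = ", "))
  w("layers: %d (%s)", n_layers(net), paste(names(net$layers),
                                            collapse = ", "))
  w("intra_layer_edges: %d", intra_layer_edges(net))
  if (!is.null(report$rates)) {
    w("")
    w("descriptive rates (per dyadic hour, mean +/- sd over all dyads):")
    for (ty in names(report$rates)) {
      r <- report$rates[[ty]]
      w("  %s: %d/%d dyads observed (%.1f%%), mean %.2f +/- %.2f",
        ty, r$n_observed, r$n_possible, r$percent_observed,
        round_half_up(r$mean, 2), round_half_up(r$sd, 2))
    }
  }
  if (!is.null(report$global_overlap)) {
    w("")
    w("global edge overlap (%s/%s): %.4f (%.2f%%)", cfg$global_method,
      cfg$overlap_method, report$global_overlap$fraction,
      round_half_up(report$global_overlap$percent, 2))
  }
  top <- attr(report$centrality, "most_central")
  w("")
  w("most central per layer (ties within 1e-9 all listed):")
  for (nm in names(top)) w("  %s: %s", nm, paste(top[[nm]], collapse = ", "))
  if (!is.null(report$reducibility)) {
    red <- report$reducibility
    w("")
    w("reducibility: best step %d of %d; q = %s", red$best_step,
      length(red$q) - 1, paste(sprintf("%.6f", red$q), collapse = ", "))
    for (m in red$merges)
      w("  merge %d: {%s} + {%s} at %.6f", m$step,
        paste(m$pair[[1]], collapse = ","),
        paste(m$pair[[2]], collapse = ","), m$height)
  }
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(readLines(file.path(x$config$out, "summary.txt")), sep = "\n")
  invisible(x)
}
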