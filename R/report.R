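write_manifest <- function(dir, command, config, inputs, seed = NULL) {
  digests <- vapply(inputs, function(p)
    unname(tools::md5sum(normalizePath(p))), "")
  manifest <- list(command = command,
                   tool = "dmsparis",
                   version = as.character(utils::packageVersion("dmsparis")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   config = unclass(config),
                   inputs = as.list(digests),
                   input_paths = as.list(vapply(inputs, normalizePath, "")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop("no manifest.json in '", dir, "': not a pipeline output directory")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

config_from_manifest <- function(manifest) {
  do.call(analysis_config, manifest$config[names(manifest$config) %in%
                                           names(formals(analysis_config))])
}

load_model_files <- function(ct_path, catalog_path = NULL) {
  model <- parse_ct(ct_path)
  if (!is.null(catalog_path)) model <- load_catalog(model, read_catalog(catalog_path))
  model
}

#' Run the DMS comparison pipeline end to end
#'
#' Reads the model (CT + catalog TSV) and a per-position count table,
#' classifies positions, compares to the model, scores hairpin disruption,
#' and writes `calls.tsv`, `hairpins.tsv`, `summary.json` and a
#' `manifest.json` (config snapshot + input digests) into `out_dir`.
#' Deterministic given identical inputs and config.
#'
#' @param ct_path CT file of the reference model.
#' @param catalog_path Catalog TSV (hairpin/pseudoknot ids), or `NULL`.
#' @param counts_path DMS counts TSV.
#' @param out_dir Output directory, created if needed.
#' @param config An [analysis_config()].
#' @return Invisibly, a list with `model`, `calls`, `delta`, `disruptions`,
#'   `summary`, and `out_dir`.
#' @export
run_dms <- function(ct_path, catalog_path, counts_path, out_dir,
                    config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_model_files(ct_path, catalog_path)
  profile <- read_dms_counts(counts_path, model$transcript_id, nchar(model$sequence))
  calls <- classify_positions(profile, model, config)
  delta <- compare_to_model(calls, model)
  disruptions <- disruption_table(model, calls, config)
  summary <- summarize_dms(calls, delta, disruptions, config)
  write_calls_tsv(calls, delta, model, file.path(out_dir, "calls.tsv"))
  write_tsv_with_header(disruptions, file.path(out_dir, "hairpins.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "dms", config,
                 inputs = c(ct_path, catalog_path, counts_path))
  invisible(list(model = model, calls = calls, delta = delta,
                 disruptions = disruptions, summary = summary,
                 out_dir = out_dir))
}

#' Run the PARIS pipeline end to end
#'
#' Filters and deduplicates duplex reads, compresses them into supported
#' groups, classifies each group against the model, reports pseudoknot
#' status, and writes `groups.tsv`, `pk_status.tsv`, `summary.json` and
#' `manifest.json` into `out_dir`. An empty read table produces empty
#' outputs with a warning rather than an error.
#'
#' @param ct_path,catalog_path Model files as in [run_dms()].
#' @param reads_path PARIS reads TSV.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @return Invisibly, a list with `model`, `groups`, `pk_status`, `summary`
#'   (or `NULL` when no groups survive), and `out_dir`.
#' @export
run_paris <- function(ct_path, catalog_path, reads_path, out_dir,
                      config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_model_files(ct_path, catalog_path)
  reads <- read_paris_reads(reads_path)
  kept <- dedup_by_barcode(filter_reads(reads, nchar(model$sequence), config))
  groups <- classify_groups(compress_duplexes(kept, config), model, config)
  pk_status <- pseudoknot_status(groups, model)
  summary <- if (nrow(groups) > 0) summarize_paris(groups, pk_status, model)
             else { warning("no duplex groups survive filtering"); NULL }
  write_tsv_with_header(groups, file.path(out_dir, "groups.tsv"))
  write_tsv_with_header(pk_status, file.path(out_dir, "pk_status.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_manifest(out_dir, "paris", config,
                 inputs = c(ct_path, catalog_path, reads_path))
  invisible(list(model = model, groups = groups, pk_status = pk_status,
                 summary = summary, out_dir = out_dir))
}

#' Overlay annotations on a prior pipeline run
#'
#' Reads the prior run's manifest (error if absent), reconstructs its
#' configuration and inputs, and intersects an annotation table with the
#' structural-change calls, writing `overlay_calls.tsv` and
#' `overlay_tallies.json` into the run directory.
#'
#' @param run_dir Output directory of a prior [run_dms()] or [run_paris()].
#' @param annotations_path Annotation TSV (see [read_annotations()]).
#' @param mode `"dms"` or `"paris"`; must match the prior run.
#' @return Invisibly, a list with `calls` and `tallies`.
#' @export
run_overlay <- function(run_dir, annotations_path, mode = c("dms", "paris")) {
  mode <- match.arg(mode)
  manifest <- read_manifest(run_dir)
  if (!identical(manifest$command, mode))
    stop("prior run in '", run_dir, "' was '", manifest$command,
         "', not '", mode, "'")
  config <- config_from_manifest(manifest)
  paths <- unlist(manifest$input_paths)
  if (mode == "dms") {
    res <- run_dms(paths[1], if (length(paths) == 3) paths[2] else NULL,
                   paths[length(paths)], out_dir = run_dir, config = config)
    ann <- read_annotations(annotations_path, nchar(res$model$sequence))
    calls <- overlay_dms(ann, res$model, res$disruptions, res$delta, config)
  } else {
    res <- run_paris(paths[1], if (length(paths) == 3) paths[2] else NULL,
                     paths[length(paths)], out_dir = run_dir, config = config)
    ann <- read_annotations(annotations_path, nchar(res$model$sequence))
    calls <- overlay_paris(ann, res$groups, config)
  }
  tallies <- tally_overlays(calls)
  write_tsv_with_header(calls, file.path(run_dir, "overlay_calls.tsv"))
  jsonlite::write_json(
    list(n_annotations = nrow(calls),
         tallies = tallies),
    file.path(run_dir, "overlay_tallies.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, tallies = tallies))
}
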