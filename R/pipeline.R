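#' Pipeline configuration
#'
#' Resolved settings for a full screening run. Usually built from a YAML
#' file via [read_pipeline_config()]; every field can also be set directly.
#'
#' @param query Path to the pharmacophore query JSON.
#' @param library Path to the screening library SDF.
#' @param scores Path to the docking score CSV.
#' @param rules List of [threshold_rule()] objects (non-empty).
#' @param mode Matcher mode, `"superpose"` or `"in_place"`.
#' @param cutoff Matcher RMSD cutoff (Angstrom).
#' @param out_dir Output directory for the JSON report.
#' @param seed Integer seed echoed into the report.
#' @param log_level `"info"` (stage messages) or `"quiet"`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(query, library, scores, rules,
                            mode = "superpose", cutoff = 1.0,
                            out_dir = NULL, seed = 1L,
                            log_level = "info") {
  if (inherits(rules, "threshold_rule")) rules <- list(rules)
  if (!length(rules)) stop_config("threshold rules must be non-empty")
  structure(list(query = query, library = library, scores = scores,
                 rules = rules, mode = mode, cutoff = cutoff,
                 out_dir = out_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

stop_config <- function(...)
  stop(structure(class = c("dualphore_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))

#' Read a pipeline configuration from YAML
#'
#' Expected keys: `query`, `library`, `scores`, `rules` (list of
#' `target`/`cutoff`/`strict`), and optionally `mode`, `cutoff`, `out_dir`,
#' `seed`, `log_level`.
#'
#' @param path YAML file path.
#' @param overrides Named list of fields overriding the file (CLI flags).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  rules <- lapply(y$rules, function(r)
    threshold_rule(r$target, r$cutoff,
                   strict = if (is.null(r$strict)) TRUE else r$strict))
  pipeline_config(query = y$query, library = y$library, scores = y$scores,
                  rules = rules,
                  mode = if (is.null(y$mode)) "superpose" else y$mode,
                  cutoff = if (is.null(y$cutoff)) 1.0 else y$cutoff,
                  out_dir = y$out_dir,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  log_level = if (is.null(y$log_level)) "info"
                              else y$log_level)
}

#' Run the full dual-target screen
#'
#' Pharmacophore screen of the library, then the dual docking-energy
#' threshold cascade, then a reproducible JSON report: stage counts,
#' survivor ids, the ranked final candidates, a settings echo and the seed.
#' The stage counts are funnel-monotone by construction (library >=
#' pharmacophore hits >= each survivor set >= intersection). An empty final
#' intersection is a valid result, not an error.
#'
#' @param config A [pipeline_config()].
#' @return The report (list), invisibly; written as `report.json` under
#'   `out_dir` when that is set.
#' @export
run_full_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("query", "library", "scores"))
    if (!file.exists(config[[f]]))
      stop_config("missing input file for '", f, "': ", config[[f]])
  say <- function(...) if (config$log_level != "quiet")
    message(sprintf(...))

  t0 <- Sys.time()
  query <- read_query_json(config$query)
  mols <- read_sdf(config$library)
  scores <- read_score_table(config$scores)
  say("[dualphore] library: %d molecules, query '%s' (%d features)",
      length(mols), query$name, length(query$features))

  hits <- screen_library(query, mols, mode = config$mode,
                         rmsd_cutoff = config$cutoff)
  ids <- hit_ids(hits)
  say("[dualphore] pharmacophore stage: %d hits (%d match failures)",
      length(ids), length(attr(hits, "failures")))

  casc <- run_cascade(ids, scores, config$rules)
  say("[dualphore] cascade: %d final candidates",
      nrow(casc$final_ranked))

  rmsds <- stats::setNames(vapply(hits, `[[`, 0, "rmsd"), ids)
  report <- list(
    schema_version = "1.0",
    settings = list(
      query = config$query, library = config$library,
      scores = config$scores, mode = config$mode, cutoff = config$cutoff,
      rules = lapply(config$rules, function(r)
        list(target = r$target_id, cutoff = r$cutoff,
             strict = r$strict))),
    seed = config$seed,
    stage_counts = c(list(library = length(mols),
                          pharmacophore = length(ids)),
                     lapply(casc$stage_survivors[-1L], length)),
    survivors = casc$stage_survivors,
    match_rmsd = as.list(rmsds),
    match_failures = attr(hits, "failures"),
    final_ranked = lapply(seq_len(nrow(casc$final_ranked)), function(i)
      list(compound_id = casc$final_ranked$compound_id[i],
           score = casc$final_ranked$score[i])))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("[dualphore] report written to %s",
        file.path(config$out_dir, "report.json"))
  }
  say("[dualphore] done in %.2f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(report)
}
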