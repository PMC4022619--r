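# End-to-end orchestration: config resolution, the simulate/sweep/importance/
# habitat stages, and a run manifest. One config drives all stages; data go
# to files, log messages to standard error via message().

pipeline_defaults <- function() {
  list(
    distances = c(3000, 5000, 10000, 13000, 16000),
    tail_prob = 0.05,
    include_self = TRUE,
    mode = "max_product",
    buffer_radii = c(1000, 2000),
    importance_scenario = "E",
    base_min_area = 700,
    out_dir = "aguadas-output",
    seed = 1L
  )
}

#' Resolve a pipeline configuration
#'
#' Reads a YAML or JSON config file (or takes a named list), merges it over
#' the package defaults, and validates it. The config must provide either
#' input paths (`waterholes`, optionally `boundary` and `reserve`) or a
#' `synthetic` block of [synthetic_config()] fields — not neither.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param overrides named list of values overriding config keys (CLI flags).
#' @return resolved config list of class `pipeline_config`.
#' @export
resolve_config <- function(config = list(), overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  if (is.null(cfg$waterholes) && is.null(cfg$synthetic))
    abort_config("config needs either input paths ('waterholes') or a 'synthetic' block")
  if (any(cfg$distances <= 0)) abort_config("distances must be positive")
  if (any(cfg$buffer_radii <= 0)) abort_config("buffer radii must be positive")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_scenarios <- function(cfg) {
  if (is.null(cfg$scenario_thresholds)) return(default_scenarios(cfg$base_min_area))
  th <- as.numeric(cfg$scenario_thresholds)
  labels <- if (!is.null(cfg$scenario_labels)) cfg$scenario_labels else LETTERS[seq_along(th)]
  out <- data.frame(label = labels, removal_threshold = th,
                    base_min_area = cfg$base_min_area, stringsAsFactors = FALSE)
  class(out) <- c("drought_scenarios", "data.frame")
  out
}

config_synthetic <- function(cfg) {
  syn <- cfg$synthetic
  if (isTRUE(syn)) syn <- list()
  if (!is.null(syn$extent)) syn$extent <- as.numeric(syn$extent)
  syn$seed <- cfg$seed
  do.call(synthetic_config, syn)
}

#' Load pipeline inputs
#'
#' Generates the synthetic landscape or reads the configured waterhole and
#' boundary files, tagging reserve membership when a reserve is available.
#'
#' @param cfg a resolved [resolve_config()] list.
#' @return list with `waterholes` and `area` (possibly `NULL` when no
#'   boundary was configured).
#' @export
pipeline_load <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    land <- generate_landscape(config_synthetic(cfg))
    return(land[c("waterholes", "area")])
  }
  if (!file.exists(cfg$waterholes))
    abort_config(sprintf("waterhole input not found: %s", cfg$waterholes))
  tab <- read_waterholes(cfg$waterholes)
  area <- NULL
  if (!is.null(cfg$boundary)) {
    area <- read_study_area(cfg$boundary, cfg$reserve)
    if (!is.null(area$reserve)) tab <- tag_reserve_membership(tab, area)
  }
  list(waterholes = tab, area = area)
}

out_path <- function(cfg, ...) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(cfg$out_dir, ...)
}

#' Simulate and write a synthetic landscape
#'
#' @param config config path or list (see [resolve_config()]); must contain a
#'   `synthetic` block.
#' @param overrides named list of config overrides.
#' @return invisibly, the generated landscape with the written file paths.
#' @export
pipeline_simulate <- function(config = list(), overrides = list()) {
  cfg <- resolve_config(config, overrides)
  if (is.null(cfg$synthetic)) abort_config("simulate requires a 'synthetic' config block")
  land <- generate_landscape(config_synthetic(cfg))
  paths <- c(
    waterholes_csv = out_path(cfg, "waterholes.csv"),
    waterholes_geojson = out_path(cfg, "waterholes.geojson"),
    boundary_geojson = out_path(cfg, "boundary.geojson"),
    reserve_geojson = out_path(cfg, "reserve.geojson")
  )
  write_table(land$waterholes, paths[["waterholes_csv"]])
  write_waterholes_geojson(land$waterholes, paths[["waterholes_geojson"]])
  write_polygon_geojson(land$area$boundary, paths[["boundary_geojson"]],
                        list(role = "boundary"))
  write_polygon_geojson(land$area$reserve, paths[["reserve_geojson"]],
                        list(role = "reserve"))
  message(sprintf("simulate: %d waterholes written under %s (seed %d)",
                  nrow(land$waterholes), cfg$out_dir, cfg$seed))
  invisible(c(land, list(paths = paths, config = cfg)))
}

#' Run the scenario x distance sweep stage
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the sweep data.frame (also written to `sweep.csv`).
#' @export
pipeline_sweep <- function(config = list(), overrides = list()) {
  cfg <- resolve_config(config, overrides)
  inputs <- pipeline_load(cfg)
  sweep <- run_sweep(inputs$waterholes, config_scenarios(cfg), cfg$distances,
                     tail_prob = cfg$tail_prob, include_self = cfg$include_self,
                     mode = cfg$mode)
  write_table(sweep, out_path(cfg, "sweep.csv"))
  message(sprintf("sweep: %d records written to %s", nrow(sweep),
                  out_path(cfg, "sweep.csv")))
  invisible(sweep)
}

#' Run the node-importance stage
#'
#' Computes patch-removal dPC at every configured distance on the network of
#' the configured importance scenario, aggregates across distances, and
#' writes CSV plus GeoJSON node exports.
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the aggregated importance data.frame.
#' @export
pipeline_importance <- function(config = list(), overrides = list()) {
  cfg <- resolve_config(config, overrides)
  inputs <- pipeline_load(cfg)
  scen <- config_scenarios(cfg)
  srow <- scen[scen$label == cfg$importance_scenario, ]
  if (!nrow(srow)) abort_config(sprintf("unknown importance scenario '%s'",
                                        cfg$importance_scenario))
  sub <- apply_scenario(inputs$waterholes, srow)
  if (!nrow(sub)) abort_config("importance scenario removes every waterhole")
  complete <- build_complete_network(sub)
  results <- lapply(cfg$distances, function(d) {
    node_importance(prune_by_distance(complete, d),
                    calibrate_kernel(d, cfg$tail_prob),
                    mode = cfg$mode, include_self = cfg$include_self)
  })
  agg <- aggregate_importance(results)
  if (!is.null(sub$in_reserve)) agg$in_reserve <- sub$in_reserve[match(agg$id, sub$id)]
  write_table(agg, out_path(cfg, "importance.csv"))
  node_tab <- sub
  net <- resource_network(node_tab, data.frame(from = character(0),
                                               to = character(0),
                                               length = numeric(0)))
  net$nodes$total_dPC <- agg$total_dPC[match(net$nodes$id, agg$id)]
  write_network_geojson(net, out_path(cfg, "importance.geojson"))
  message(sprintf("importance: %d nodes ranked (scenario %s) -> %s",
                  nrow(agg), cfg$importance_scenario,
                  out_path(cfg, "importance.csv")))
  invisible(agg)
}

#' Run the habitat-buffer stage
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the habitat sweep data.frame.
#' @export
pipeline_habitat <- function(config = list(), overrides = list()) {
  cfg <- resolve_config(config, overrides)
  inputs <- pipeline_load(cfg)
  if (is.null(inputs$area))
    abort_config("habitat stage needs a study boundary (or synthetic inputs)")
  hab <- habitat_sweep(inputs$waterholes, config_scenarios(cfg),
                       radii = cfg$buffer_radii, area = inputs$area)
  write_table(hab, out_path(cfg, "habitat.csv"))
  for (key in names(attr(hab, "summaries"))) {
    write_habitat_geojson(attr(hab, "summaries")[[key]],
                          out_path(cfg, sprintf("habitat_%s.geojson", key)))
  }
  message(sprintf("habitat: %d summaries written under %s", nrow(hab), cfg$out_dir))
  invisible(hab)
}

#' Run all stages and write a manifest
#'
#' Runs sweep, importance and habitat on the configured inputs and writes a
#' single JSON manifest holding the resolved configuration, its hash, the
#' seed, the package version, and every computed record. Deterministic for
#' fixed inputs and seed.
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
pipeline_report <- function(config = list(), overrides = list()) {
  cfg <- resolve_config(config, overrides)
  cfg_plain <- unclass(cfg)
  # hash the analysis-relevant config; the output location does not affect results
  cfg_json <- jsonlite::toJSON(cfg_plain[setdiff(names(cfg_plain), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  sweep <- pipeline_sweep(cfg)
  importance <- pipeline_importance(cfg)
  habitat <- pipeline_habitat(cfg)
  attr(habitat, "summaries") <- NULL
  manifest <- list(
    package = "aguadas",
    version = as.character(utils::packageVersion("aguadas")),
    seed = cfg$seed,
    config_hash = cfg_hash,
    config = cfg_plain,
    sweep = sweep,
    importance = importance,
    habitat = as.data.frame(habitat)
  )
  path <- out_path(cfg, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  message(sprintf("report: manifest with %d sweep records -> %s",
                  nrow(sweep), path))
  invisible(manifest)
}
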