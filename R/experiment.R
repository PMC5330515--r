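# Experiment configuration (YAML), orchestration and provenance.

.config_schema <- list(
  name = "character", protocol = "list", variant = "character",
  geometry = "list", analysis = "list", seed = "integer",
  numerics = "list", out_dir = "character"
)

#' Build / validate an experiment configuration
#'
#' Known top-level keys: `name`, `protocol` (with `kind` in `ead2d`,
#' `trigger3d`, `af3d` plus kind-specific overrides), `variant` (registry
#' name), `geometry` (idealized-LA parameters), `analysis`, `numerics`
#' (`dt`, `D`), `seed`, `out_dir`. Unknown keys are rejected.
#'
#' @param ... configuration entries, or a single named list.
#' @return A validated `experiment_config` with a provenance hash.
#' @export
experiment_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$protocol) || is.null(cfg$protocol$kind))
    stop("configuration requires protocol$kind")
  cfg$protocol$kind <- match.arg(cfg$protocol$kind,
                                 c("ead2d", "trigger3d", "af3d"))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$name)) cfg$name <- cfg$protocol$kind
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname experiment_config
#' @param path YAML file to read.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  experiment_config(yaml::read_yaml(path))
}

#' Run a configured experiment
#'
#' Dispatches on `protocol$kind`, executes simulate -> analyze -> summarize,
#' and (if `out_dir` is set) writes a manifest (config hash, seed, runtime),
#' probe CSVs, a summary JSON, and — for surface protocols — a VTK export of
#' the geometry with its region/ACh fields.
#'
#' @param config an [experiment_config()] (or path to a YAML file).
#' @return List with `config`, `result` (protocol-specific), `summary`,
#'   and `manifest`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  set.seed(config$seed)
  num <- config$numerics
  dt <- num$dt %||% 0.02
  D <- num$D %||% default_diffusion()
  kind <- config$protocol$kind
  pr <- config$protocol
  pr$kind <- NULL

  geom <- NULL; layout <- NULL
  if (kind %in% c("trigger3d", "af3d")) {
    gpar <- config$geometry %||% list()
    geom <- do.call(generate_idealized_la,
                    c(gpar[setdiff(names(gpar), c("ach", "n_nerves_per_gp"))],
                      list(seed = config$seed)))
    layout <- generate_gp_octopus(
      geom, n_nerves_per_gp = gpar$n_nerves_per_gp %||% 8,
      ach = gpar$ach %||% 0.05, seed = config$seed)
  }
  result <- switch(kind,
    ead2d = do.call(run_2d_ead_protocol, c(pr, list(dt = dt, D = D))),
    trigger3d = do.call(run_3d_trigger_protocol,
                        c(list(geom = geom, layout = layout, dt = dt, D = D),
                          pr)),
    af3d = do.call(induce_af,
                   c(list(geom = geom, layout = layout, dt = dt, D = D,
                          seed = config$seed), pr)))
  summary <- switch(kind,
    ead2d = list(diastolic_end_pacing = result$diastolic_end_pacing,
                 ead_first_beat = result$ead_first_beat,
                 ead_later_beats = result$ead_later_beats),
    trigger3d = list(spontaneous_pv_count = result$spontaneous$count,
                     spontaneous_pv_nodes = length(result$spontaneous$nodes)),
    af3d = list(induced = result$induced))
  manifest <- list(name = config$name, kind = kind, hash = config$hash,
                   seed = config$seed,
                   runtime_s = as.numeric(Sys.time() - t_start, units = "secs"),
                   package_version = as.character(utils::packageVersion("atriagp")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(c(summary, list(config_hash = config$hash)),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (kind == "ead2d")
      write.csv(result$trace, file.path(config$out_dir, "probe_trace.csv"),
                row.names = FALSE)
    if (!is.null(geom))
      write_vtk(geom, file.path(config$out_dir, "geometry.vtk"),
                point_data = list(region = as.integer(geom$region),
                                  ach = layout$ach))
  }
  list(config = config, result = result, summary = summary,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
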