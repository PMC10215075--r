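#' Default pipeline configuration
#'
#' The standard model conditions: 200 nm fibril diameter, 1000 nm length,
#' staggered platelet lattice relaxed by 6e6 perturbation moves (32% mineral
#' volume fraction), collagen lattice, `delta_t` = 2e-10 s,
#' `D0` = 2.66e-9 m^2/s, 1000 trajectories and the seven reference quotes at
#' multiples of 134 nm.
#'
#' @return nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    geometry = list(
      fixture = NULL,
      envelope_radius = 100, envelope_length = 1000,
      d_period = 67, a_W = 13.19, a_T = 2.35, a_L = NULL,
      stagger_offset = 0.5, boundary = "clip",
      width = c(5, 90, 41.80, (90 - 5) / 6),
      thickness = c(2, 5, 3.55, (5 - 2) / 6),
      length = c(50, 170, 94.51, (170 - 50) / 6),
      collagen = TRUE, collagen_spacing = 1.6, collagen_radius = 0.615,
      n_moves = 6e6, max_translation = 1, max_rotation = pi / 180,
      max_inclination = 20 * pi / 180,
      seed = 1),
    walk = list(
      delta_t = 2e-10, D0 = 2.66e-9, n_trajectories = 1000,
      max_steps = 5e7, record_stride = 1, master_seed = 1,
      stop_L = NULL, max_rejections = 1e4),
    analysis = list(
      quotes = 134 * (1:7), msd_lags_max = 128, level = 0.95),
    output = list(save_trajectories = TRUE, save_geometry = TRUE))
}

required_config_keys <- list(
  geometry = c("seed"),
  walk = c("n_trajectories", "master_seed"),
  analysis = c("quotes"))

#' Read and validate a pipeline configuration file
#'
#' YAML file mirroring [default_run_config()]. The seeds, ensemble size and
#' quotes must be stated explicitly; every other key falls back to the
#' default model conditions. A missing required key raises an error naming
#' the key.
#'
#' @param path YAML configuration file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
validate_run_config <- function(config) {
  for (section in names(required_config_keys)) {
    if (is.null(config[[section]]))
      stopf("missing config key: %s", section)
    for (key in required_config_keys[[section]]) {
      if (is.null(config[[section]][[key]]))
        stopf("missing config key: %s$%s", section, key)
    }
  }
  defaults <- default_run_config()
  for (section in names(defaults)) {
    user <- if (is.null(config[[section]])) list() else config[[section]]
    merged <- defaults[[section]]
    for (key in names(user)) merged[[key]] <- user[[key]]
    config[[section]] <- merged
  }
  config
}

pipeline_geometry <- function(gcfg) {
  if (!is.null(gcfg$fixture) && !identical(gcfg$fixture, "lattice")) {
    return(make_fixture(gcfg$fixture, envelope_radius = gcfg$envelope_radius,
                        envelope_length = gcfg$envelope_length,
                        seed = gcfg$seed))
  }
  g <- build_lattice(
    spec = lattice_spec(a_W = gcfg$a_W, a_T = gcfg$a_T, a_L = gcfg$a_L,
                        d_period = gcfg$d_period,
                        stagger_offset = gcfg$stagger_offset),
    dim_ranges = platelet_dim_ranges(width = gcfg$width,
                                     thickness = gcfg$thickness,
                                     length = gcfg$length),
    envelope_radius = gcfg$envelope_radius,
    envelope_length = gcfg$envelope_length,
    seed = gcfg$seed, boundary = gcfg$boundary,
    collagen = isTRUE(gcfg$collagen),
    collagen_spacing = gcfg$collagen_spacing,
    collagen_radius = gcfg$collagen_radius)
  perturb(g, n_moves = gcfg$n_moves, max_translation = gcfg$max_translation,
          max_rotation = gcfg$max_rotation,
          max_inclination = gcfg$max_inclination, seed = gcfg$seed + 500009)
}

#' Run the full build-simulate-analyze pipeline
#'
#' Builds (or loads a fixture) geometry, simulates the walker ensemble,
#' computes the per-quote sub-trajectory statistics, and writes geometry,
#' trajectories, result CSVs and a run manifest into `out_dir`. The manifest
#' (JSON) snapshots the configuration and output hashes so a run can be
#' reproduced bit-identically.
#'
#' @param config configuration list or path to a YAML file (see
#'   [read_run_config()]).
#' @param out_dir output directory, created if needed.
#' @param progress print per-trajectory progress.
#' @return The run manifest, invisibly; class `run_manifest`.
#' @export
run_pipeline <- function(config, out_dir, progress = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "mcfrw",
                   version = as.character(utils::packageVersion("mcfrw")),
                   config = config, stages = list(), outputs = list(),
                   complete = FALSE)
  stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  manifest$stages$geometry_start <- stamp()
  geom <- pipeline_geometry(config$geometry)
  if (isTRUE(config$output$save_geometry)) {
    gpath <- file.path(out_dir, "geometry.txt")
    write_mcf_geometry(geom, gpath)
    manifest$outputs$geometry <- gpath
  }
  manifest$stages$geometry_done <- stamp()

  wcfg <- config$walk
  wc <- walk_config(delta_t = wcfg$delta_t, D0 = wcfg$D0,
                    n_trajectories = wcfg$n_trajectories,
                    max_steps = wcfg$max_steps,
                    record_stride = wcfg$record_stride,
                    master_seed = wcfg$master_seed, stop_L = wcfg$stop_L,
                    max_rejections = wcfg$max_rejections)
  traj_dir <- if (isTRUE(config$output$save_trajectories))
    file.path(out_dir, "trajectories") else NULL

  env <- new.env()
  env$per <- list()
  acfg <- config$analysis
  ens <- simulate_ensemble(
    geom, wc, keep_positions = FALSE, out_dir = traj_dir, progress = progress,
    callback = function(traj, i) {
      env$per[[length(env$per) + 1]] <- quote_stats_one_trajectory(
        traj, i, acfg$quotes, NULL, acfg$msd_lags_max)
      NULL
    })
  manifest$stages$simulate_done <- stamp()

  per_traj <- if (length(env$per)) do.call(rbind, env$per) else
    data.frame(trajectory = integer(0), quote_L_nm = numeric(0),
               n_points = integer(0), tortuosity = numeric(0),
               beta0 = numeric(0), beta1 = numeric(0), r2 = numeric(0),
               D_m2_per_s = numeric(0))
  report <- summarize_quotes(per_traj, acfg$quotes, acfg$level)
  spath <- file.path(out_dir, "quote_summary.csv")
  write_quote_report(report, spath)
  manifest$outputs$summary <- spath
  manifest$outputs$per_trajectory <- file.path(out_dir,
                                               "quote_summary_per_trajectory.csv")
  if (!is.null(traj_dir)) manifest$outputs$trajectories <- traj_dir
  manifest$stages$analyze_done <- stamp()

  manifest$failed_trajectories <- ens$failed
  manifest$complete <- TRUE
  files <- unlist(manifest$outputs)
  files <- files[file.exists(files) & !dir.exists(files)]
  manifest$hashes <- as.list(tools::md5sum(files))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("mcfrw run manifest (version %s, complete: %s)\n", x$version,
              x$complete))
  cat("  outputs:\n")
  for (nm in names(x$outputs)) cat(sprintf("    %s: %s\n", nm, x$outputs[[nm]]))
  if (length(x$failed_trajectories))
    cat(sprintf("  failed trajectories: %d\n", length(x$failed_trajectories)))
  invisible(x)
}
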