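#' Per-coordinate step standard deviation
#'
#' For a Brownian particle with bulk diffusivity `D0`, each coordinate of a
#' step over `delta_t` is Gaussian with standard deviation
#' `sigma = sqrt(2 * D0 * delta_t)`. With the defaults
#' (`D0 = 2.66e-9` m^2/s, `delta_t = 2e-10` s) this is 1.03 nm, just below
#' the 1.23 nm tropocollagen diameter: a warning is raised if sigma reaches
#' that size, because larger steps could jump the thinnest obstacles.
#'
#' @param D0 bulk diffusion coefficient, m^2/s.
#' @param delta_t time step, s.
#' @return sigma in meters.
#' @export
step_sigma <- function(D0 = 2.66e-9, delta_t = 2e-10) {
  if (D0 < 0) stopf("D0 must be >= 0")
  if (delta_t <= 0) stopf("delta_t must be > 0")
  sigma <- sqrt(2 * D0 * delta_t)
  if (sigma * 1e9 >= 1.23)
    warning("step sigma ", signif(sigma * 1e9, 3),
            " nm is not smaller than the 1.23 nm collagen diameter; ",
            "steps may jump the thinnest obstacles", call. = FALSE)
  sigma
}

#' Random-walk configuration
#'
#' @param delta_t time step in seconds.
#' @param D0 bulk water diffusivity, m^2/s.
#' @param n_trajectories ensemble size.
#' @param max_steps per-trajectory safety cap; walkers still in flight are
#'   truncated and flagged.
#' @param record_stride record every k-th position (the start and the final
#'   position are always recorded).
#' @param master_seed integer; trajectory i uses seed `master_seed + i`.
#' @param stop_L termination plane in nm; `NULL` means the upper extremity of
#'   the envelope.
#' @param max_rejections consecutive rejected proposals tolerated in a single
#'   time step before a trapped-walker error.
#' @param collision collision rule; only `"resample"` (stay at the current
#'   location and redraw the step) is implemented.
#' @return object of class `walk_config` (includes derived `sigma`, meters).
#' @export
walk_config <- function(delta_t = 2e-10, D0 = 2.66e-9, n_trajectories = 1000,
                        max_steps = 5e7, record_stride = 1L, master_seed = 1L,
                        stop_L = NULL, max_rejections = 1e4,
                        collision = "resample") {
  if (n_trajectories < 1) stopf("n_trajectories must be >= 1")
  if (max_steps < 1) stopf("max_steps must be >= 1")
  if (record_stride < 1) stopf("record_stride must be >= 1")
  if (!identical(collision, "resample"))
    stopf("only the stay-and-resample collision rule is implemented")
  sigma <- step_sigma(D0, delta_t)
  structure(list(delta_t = delta_t, D0 = D0, sigma = sigma,
                 n_trajectories = as.integer(n_trajectories),
                 max_steps = max_steps, record_stride = as.integer(record_stride),
                 master_seed = master_seed, stop_L = stop_L,
                 max_rejections = max_rejections, collision = collision),
            class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat("Random-walk configuration\n")
  cat(sprintf("  delta_t: %g s, D0: %g m^2/s, sigma: %.4g nm/coordinate\n",
              x$delta_t, x$D0, x$sigma * 1e9))
  cat(sprintf("  trajectories: %d, max steps: %g, record stride: %d\n",
              x$n_trajectories, x$max_steps, x$record_stride))
  if (!is.null(x$stop_L)) cat(sprintf("  stop plane: L = %g nm\n", x$stop_L))
  invisible(x)
}

#' Propose an unconstrained Gaussian step
#'
#' Three independent N(0, sigma) displacement draws per step (one per
#' coordinate W, T, L), returned in nm. Uses the current R RNG stream.
#'
#' @param n number of proposals.
#' @param sigma per-coordinate standard deviation in meters.
#' @return n x 3 matrix of displacements in nm.
#' @export
propose_step <- function(n = 1, sigma) {
  if (sigma < 0) stopf("sigma must be >= 0")
  matrix(rnorm(3 * n, 0, sigma * 1e9), ncol = 3,
         dimnames = list(NULL, c("W", "T", "L")))
}

#' Advance a walker by one time step
#'
#' Repeatedly proposes Gaussian steps until the whole segment from the
#' current position to the proposal is unobstructed, then returns the new
#' position. Exactly one time step elapses regardless of how many proposals
#' were rejected; the rejection count is returned. More than
#' `config$max_rejections` consecutive rejections raises a trapped-walker
#' error identifying the position.
#'
#' @param position length-3 un-blocked position (nm).
#' @param geometry an `mcf_geometry`.
#' @param config a [walk_config()].
#' @param seed integer seed for the proposal stream.
#' @return list with `position` (nm) and `n_rejections`.
#' @export
advance <- function(position, geometry, config = walk_config(), seed = 1L) {
  stopifnot(inherits(geometry, "mcf_geometry"))
  res <- cpp_advance(as_geom_list(geometry), as.numeric(position),
                     config$sigma * 1e9, seed, config$max_rejections)
  names(res$position) <- c("W", "T", "L")
  res
}

new_trajectory <- function(positions, delta_t, seed, n_steps, n_rejections,
                           termination, record_stride = 1L) {
  colnames(positions) <- c("W", "T", "L")
  structure(list(positions = positions, delta_t = delta_t, seed = seed,
                 n_steps = n_steps, n_rejections = n_rejections,
                 termination = termination, record_stride = record_stride),
            class = "mcf_trajectory")
}

#' Simulate one obstructed random-walk trajectory
#'
#' The start position is sampled uniformly on the un-blocked disc at L = 0
#' (for unbounded fixture geometries the walker starts at the origin). Steps
#' follow [advance()] until the walker first reaches `stop_L` (default: the
#' upper extremity of the envelope) or `max_steps` elapses, in which case the
#' trajectory is flagged as truncated.
#'
#' @param geometry an `mcf_geometry`.
#' @param config a [walk_config()].
#' @param seed integer seed for this trajectory.
#' @param start optional fixed start position (mainly for tests).
#' @return An `mcf_trajectory`: positions in nm at uniform `delta_t` spacing.
#' @export
simulate_trajectory <- function(geometry, config = walk_config(), seed = 1L,
                                start = NULL) {
  stopifnot(inherits(geometry, "mcf_geometry"))
  stop_L <- if (is.null(config$stop_L)) geometry$envelope$length else config$stop_L
  res <- cpp_simulate(as_geom_list(geometry), config$sigma * 1e9, stop_L,
                      config$max_steps, config$max_rejections, seed,
                      config$record_stride,
                      if (is.null(start)) NULL else as.numeric(start))
  if (identical(res$termination, "max_steps"))
    warning("trajectory truncated at max_steps = ", config$max_steps,
            " before reaching L = ", stop_L, call. = FALSE)
  new_trajectory(res$positions, config$delta_t, seed, res$n_steps,
                 res$n_rejections, res$termination, config$record_stride)
}

#' @export
print.mcf_trajectory <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("Random-walk trajectory: %d recorded positions, %g steps (%s)\n",
              n, x$n_steps, x$termination))
  cat(sprintf("  elapsed time: %.4g s, rejections: %g, seed: %g\n",
              x$n_steps * x$delta_t, x$n_rejections, x$seed))
  cat(sprintf("  final position: (%.2f, %.2f, %.2f) nm\n",
              x$positions[n, 1], x$positions[n, 2], x$positions[n, 3]))
  invisible(x)
}

#' Simulate an ensemble of trajectories
#'
#' Runs `config$n_trajectories` independent walkers with per-trajectory seeds
#' `master_seed + i`. Per-trajectory errors (e.g. trapped walkers) are
#' collected, not propagated, so one pathological walker cannot abort the
#' ensemble. With `out_dir` each completed trajectory is also persisted as
#' CSV, making long runs resumable by inspection.
#'
#' @param geometry an `mcf_geometry`.
#' @param config a [walk_config()].
#' @param callback optional `function(trajectory, index)` invoked per
#'   trajectory; when `keep_positions = FALSE` its return value is stored in
#'   place of the full trajectory (memory-lean streaming analysis).
#' @param keep_positions keep full trajectories in the returned list.
#' @param out_dir optional directory for per-trajectory CSV files.
#' @param progress print one line per completed trajectory.
#' @return An `mcf_ensemble`: list with `trajectories`, `failed` (indices and
#'   messages), and the `config`.
#' @export
simulate_ensemble <- function(geometry, config = walk_config(),
                              callback = NULL, keep_positions = TRUE,
                              out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(geometry, "mcf_geometry"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  n <- config$n_trajectories
  trajectories <- vector("list", n)
  failed <- list()
  for (i in seq_len(n)) {
    seed_i <- config$master_seed + i
    traj <- tryCatch(
      withCallingHandlers(
        simulate_trajectory(geometry, config, seed = seed_i),
        warning = function(w) {
          if (grepl("truncated", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(traj, "error")) {
      failed[[length(failed) + 1]] <- list(index = i, seed = seed_i,
                                           message = conditionMessage(traj))
      if (progress) message(sprintf("trajectory %d/%d FAILED: %s", i, n,
                                    conditionMessage(traj)))
      next
    }
    if (!is.null(out_dir))
      write_trajectory_csv(traj, file.path(out_dir, sprintf("traj_%05d.csv", i)))
    res_i <- traj
    if (!is.null(callback)) {
      cb <- callback(traj, i)
      if (!keep_positions) res_i <- cb
    }
    trajectories[[i]] <- res_i
    if (progress)
      message(sprintf("trajectory %d/%d: %g steps (%s)", i, n, traj$n_steps,
                      traj$termination))
  }
  structure(list(trajectories = trajectories, failed = failed, config = config),
            class = "mcf_ensemble")
}

#' @export
print.mcf_ensemble <- function(x, ...) {
  ok <- !vapply(x$trajectories, is.null, logical(1))
  cat(sprintf("Random-walk ensemble: %d trajectories (%d failed)\n",
              length(x$trajectories), length(x$failed)))
  tr <- x$trajectories[ok]
  if (length(tr) > 0 && inherits(tr[[1]], "mcf_trajectory")) {
    steps <- vapply(tr, function(t) t$n_steps, numeric(1))
    cat(sprintf("  steps: median %g, max %g\n", stats::median(steps), max(steps)))
    reached <- vapply(tr, function(t) identical(t$termination, "reached"),
                      logical(1))
    cat(sprintf("  reached the stop plane: %d\n", sum(reached)))
  }
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns `step`, `t_s`, `W_nm`, `T_nm`, `L_nm`; trajectory attributes are
#' carried in commented header lines.
#'
#' @param trajectory an `mcf_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mcf_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# delta_t_s: %.17g", trajectory$delta_t),
    sprintf("# seed: %.17g", trajectory$seed),
    sprintf("# n_steps: %.17g", trajectory$n_steps),
    sprintf("# n_rejections: %.17g", trajectory$n_rejections),
    sprintf("# record_stride: %d", trajectory$record_stride),
    sprintf("# termination: %s", trajectory$termination),
    "step,t_s,W_nm,T_nm,L_nm"), con)
  n <- nrow(trajectory$positions)
  step <- seq(0, trajectory$n_steps, by = trajectory$record_stride)
  if (step[length(step)] != trajectory$n_steps &&
      identical(trajectory$termination, "reached"))
    step <- c(step, trajectory$n_steps)
  step <- step[seq_len(n)]
  writeLines(sprintf("%d,%.10g,%.8f,%.8f,%.8f", step,
                     step * trajectory$delta_t,
                     trajectory$positions[, 1], trajectory$positions[, 2],
                     trajectory$positions[, 3]), con)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' @param path input file.
#' @return An `mcf_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key, as = as.numeric) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1]
    if (is.na(ln)) stopf("trajectory file is missing header '%s'", key)
    as(trimws(sub(paste0("^# ", key, ":"), "", ln)))
  }
  d <- read.csv(path, comment.char = "#")
  new_trajectory(as.matrix(d[, c("W_nm", "T_nm", "L_nm")]),
                 delta_t = get("delta_t_s"), seed = get("seed"),
                 n_steps = get("n_steps"), n_rejections = get("n_rejections"),
                 termination = get("termination", as = identity),
                 record_stride = as.integer(get("record_stride")))
}

#' Export a trajectory as XYZ for molecular viewers
#'
#' @param trajectory an `mcf_trajectory`.
#' @param path output file.
#' @param element atom label used for every position.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path, element = "O") {
  stopifnot(inherits(trajectory, "mcf_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(trajectory$positions)
  writeLines(c(as.character(n), "mcfrw water-particle trajectory [nm]"), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", element, trajectory$positions[, 1],
                     trajectory$positions[, 2], trajectory$positions[, 3]), con)
  invisible(path)
}
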