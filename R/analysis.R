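#' Time-averaged mean squared displacement
#'
#' For each lag n the MSD is the average squared 3D displacement over all
#' N - n overlapping position pairs of the single trajectory:
#' `MSD(n tau) = 1/(N-n) * sum_j |r((j+n) tau) - r(j tau)|^2`.
#'
#' By default every lag 1..N-1 is evaluated for short trajectories; for long
#' trajectories an evenly spaced subset of `max_lags` lags is evaluated (each
#' value is still the exact overlapping-pair average at that lag), which is
#' what a straight-line fit of the curve needs.
#'
#' @param trajectory an `mcf_trajectory` (N >= 2 positions).
#' @param lags integer lags in 1..N-1, or `NULL` for the default set.
#' @param max_lags cap on the size of the default lag set.
#' @return object of class `msd_curve`: `lags`, `time` (s), `msd` (nm^2).
#' @export
msd_time_average <- function(trajectory, lags = NULL, max_lags = 2000) {
  stopifnot(inherits(trajectory, "mcf_trajectory"))
  N <- nrow(trajectory$positions)
  if (N < 2) stopf("trajectory must have at least 2 positions")
  if (is.null(lags)) {
    lags <- if (N - 1 <= max_lags) seq_len(N - 1) else
      unique(round(seq(1, N - 1, length.out = max_lags)))
  }
  lags <- as.integer(lags)
  if (any(lags < 1 | lags >= N)) stopf("lags must lie in 1..N-1 (N = %d)", N)
  dt_eff <- trajectory$delta_t * trajectory$record_stride
  msd <- as.numeric(cpp_msd_at_lags(trajectory$positions, lags))
  structure(list(lags = lags, time = lags * dt_eff, msd = msd,
                 delta_t = dt_eff, n_positions = N),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags (1..%d of N = %d), delta_t %g s\n",
              length(x$lags), max(x$lags), x$n_positions, x$delta_t))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$time, x$msd, type = "l", xlab = "lag time [s]",
       ylab = expression(MSD ~ group("[", nm^2, "]")), ...)
  invisible(x)
}

#' Least-squares line fit of an MSD curve
#'
#' Ordinary least squares of `msd` against lag time over a lag window. The
#' default window is lags 1 to floor(N/10): restricting the fit to short lags
#' keeps the poorly averaged long-lag tail of the time-averaged MSD out of
#' the slope estimate.
#'
#' @param curve an `msd_curve`.
#' @param window `c(min_lag, max_lag)`, or `NULL` for the default window.
#' @return object of class `msd_fit`: `beta0` (nm^2), `beta1` (nm^2/s),
#'   `r_squared`, `window`, `n_lags`.
#' @export
fit_msd <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.null(window))
    window <- c(1, max(2, floor(curve$n_positions / 10)))
  if (length(window) != 2 || window[1] > window[2])
    stopf("window must be c(min_lag, max_lag) with min <= max")
  keep <- curve$lags >= window[1] & curve$lags <= window[2]
  t <- curve$time[keep]
  y <- curve$msd[keep]
  if (length(unique(t)) < 2)
    stopf("degenerate fit window: fewer than 2 distinct lags in %d..%d",
          window[1], window[2])
  tm <- mean(t)
  ym <- mean(y)
  beta1 <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  beta0 <- ym - beta1 * tm
  ss_res <- sum((y - beta0 - beta1 * t)^2)
  ss_tot <- sum((y - ym)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(beta0 = beta0, beta1 = beta1, r_squared = r2,
                 window = window, n_lags = length(t)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD linear fit over lags %d..%d (%d points)\n",
              x$window[1], x$window[2], x$n_lags))
  cat(sprintf("  beta0 = %.4g nm^2, beta1 = %.4g nm^2/s, R^2 = %.4f\n",
              x$beta0, x$beta1, x$r_squared))
  cat(sprintf("  D = beta1/6 = %.4g m^2/s\n", diffusion_coefficient(x)))
  invisible(x)
}

#' Diffusion coefficient from an MSD fit
#'
#' Einstein relation in d_S = 3 dimensions: `D = beta1 / (2 d_S)` = one sixth
#' of the MSD-versus-time slope, converted from nm^2/s to m^2/s.
#'
#' @param fit an `msd_fit`.
#' @return D in m^2/s.
#' @export
diffusion_coefficient <- function(fit) {
  stopifnot(inherits(fit, "msd_fit"))
  fit$beta1 / 6 * 1e-18
}

#' Trajectory tortuosity
#'
#' Ratio of the effective path length (sum of consecutive 3D segment
#' lengths) to the Euclidean distance between the first and last point.
#' Always >= 1 by the triangle inequality; coincident endpoints make the
#' ratio undefined and raise an error.
#'
#' @param trajectory an `mcf_trajectory`.
#' @return dimensionless tortuosity.
#' @export
tortuosity <- function(trajectory) {
  stopifnot(inherits(trajectory, "mcf_trajectory"))
  pos <- trajectory$positions
  N <- nrow(pos)
  if (N < 2) stopf("trajectory must have at least 2 positions")
  disp <- sqrt(sum((pos[N, ] - pos[1, ])^2))
  if (disp < 1e-12)
    stopf("undefined tortuosity: start and end positions coincide")
  cpp_path_length(pos) / disp
}

#' First-passage sub-trajectory at a reference quote
#'
#' Returns the prefix of the trajectory up to and including the first
#' recorded position with L >= `quote_L` (the first passage of the reference
#' plane), or `NULL` if the trajectory never reaches it.
#'
#' @param trajectory an `mcf_trajectory`.
#' @param quote_L reference plane coordinate in nm, > 0.
#' @return An `mcf_trajectory` prefix, or `NULL`.
#' @export
extract_subtrajectory <- function(trajectory, quote_L) {
  stopifnot(inherits(trajectory, "mcf_trajectory"))
  if (quote_L <= 0) stopf("quote_L must be > 0")
  L <- trajectory$positions[, 3]
  idx <- which(L >= quote_L)
  if (length(idx) == 0) return(NULL)
  i <- idx[1]
  out <- trajectory
  out$positions <- trajectory$positions[seq_len(i), , drop = FALSE]
  out$n_steps <- (i - 1) * trajectory$record_stride
  out$termination <- "quote"
  out
}

#' Student-t confidence interval for a mean
#'
#' `mean(x) +/- t_{(1+level)/2, n-1} * sd(x) / sqrt(n)`.
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return length-2 vector `c(lower, upper)` with attributes `mean` and `level`.
#' @export
confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stopf("confidence interval requires at least 2 values")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  m <- mean(values)
  half <- qt((1 + level) / 2, n - 1) * sd(values) / sqrt(n)
  structure(c(lower = m - half, upper = m + half), mean = m, level = level)
}

#' Order of magnitude
#'
#' The power of ten below `x`: `10^floor(log10(x))`.
#'
#' @param x positive number.
#' @return power of ten.
#' @export
order_of_magnitude <- function(x) {
  if (any(x <= 0)) stopf("order_of_magnitude requires x > 0")
  10^floor(log10(x))
}

# per-trajectory statistics of one sub-trajectory: tortuosity + MSD-fit D
subtrajectory_stats <- function(sub, fit_window = NULL, msd_lags_max = 128) {
  N <- nrow(sub$positions)
  wmax <- if (is.null(fit_window)) max(2, floor(N / 10)) else fit_window[2]
  wmin <- if (is.null(fit_window)) 1 else fit_window[1]
  wmax <- min(wmax, N - 1)
  lags <- unique(round(seq(wmin, wmax, length.out = min(msd_lags_max,
                                                        wmax - wmin + 1))))
  curve <- msd_time_average(sub, lags = lags)
  fit <- fit_msd(curve, window = c(wmin, wmax))
  list(n_positions = N, tortuosity = tortuosity(sub), beta0 = fit$beta0,
       beta1 = fit$beta1, r_squared = fit$r_squared,
       D = diffusion_coefficient(fit))
}

quote_stats_one_trajectory <- function(traj, index, quotes, fit_window = NULL,
                                       msd_lags_max = 128) {
  rows <- lapply(quotes, function(q) {
    sub <- extract_subtrajectory(traj, q)
    if (is.null(sub) || nrow(sub$positions) < 3) return(NULL)
    s <- subtrajectory_stats(sub, fit_window, msd_lags_max)
    data.frame(trajectory = index, quote_L_nm = q, n_points = s$n_positions,
               tortuosity = s$tortuosity, beta0 = s$beta0, beta1 = s$beta1,
               r2 = s$r_squared, D_m2_per_s = s$D)
  })
  do.call(rbind, rows)
}

summarize_quotes <- function(per_traj, quotes, level = 0.95) {
  rows <- lapply(quotes, function(q) {
    d <- per_traj[per_traj$quote_L_nm == q, , drop = FALSE]
    ns <- nrow(d)
    if (ns == 0) {
      return(data.frame(quote_L_nm = q, n_subtraj = 0L, mean_tortuosity = NA,
                        tort_ci_lo = NA, tort_ci_hi = NA, mean_D = NA,
                        D_ci_lo = NA, D_ci_hi = NA))
    }
    tci <- if (ns >= 2) confidence_interval(d$tortuosity, level) else c(NA, NA)
    dci <- if (ns >= 2) confidence_interval(d$D_m2_per_s, level) else c(NA, NA)
    data.frame(quote_L_nm = q, n_subtraj = ns,
               mean_tortuosity = mean(d$tortuosity),
               tort_ci_lo = tci[[1]], tort_ci_hi = tci[[2]],
               mean_D = mean(d$D_m2_per_s),
               D_ci_lo = dci[[1]], D_ci_hi = dci[[2]])
  })
  out <- do.call(rbind, rows)
  structure(out, per_trajectory = per_traj, class = c("quote_report",
                                                      class(out)))
}

#' Reference-quote sweep over a trajectory ensemble
#'
#' For each reference plane ("quote") along L, extracts the first-passage
#' sub-trajectory of every trajectory that reaches it, computes per
#' sub-trajectory the tortuosity and the MSD-fit diffusion coefficient, and
#' aggregates ensemble means with Student-t 95% confidence intervals.
#'
#' @param ensemble an `mcf_ensemble` whose elements are `mcf_trajectory`
#'   objects.
#' @param quotes reference quotes in nm, sorted ascending; the default is the
#'   seven multiples of the 134 nm axial building block.
#' @param fit_window MSD fit lag window, `NULL` for the per-sub-trajectory
#'   default (lags 1..N/10).
#' @param msd_lags_max lags evaluated per MSD fit.
#' @param level confidence level.
#' @return A `quote_report` data frame (one row per quote) carrying the
#'   per-trajectory table as attribute `"per_trajectory"`.
#' @export
quote_sweep <- function(ensemble, quotes = 134 * (1:7), fit_window = NULL,
                        msd_lags_max = 128, level = 0.95) {
  stopifnot(inherits(ensemble, "mcf_ensemble"))
  if (is.unsorted(quotes, strictly = TRUE))
    stopf("quotes must be sorted in strictly ascending order")
  per <- list()
  for (i in seq_along(ensemble$trajectories)) {
    traj <- ensemble$trajectories[[i]]
    if (is.null(traj) || !inherits(traj, "mcf_trajectory")) next
    per[[length(per) + 1]] <- quote_stats_one_trajectory(traj, i, quotes,
                                                         fit_window,
                                                         msd_lags_max)
  }
  per_traj <- if (length(per)) do.call(rbind, per) else
    data.frame(trajectory = integer(0), quote_L_nm = numeric(0),
               n_points = integer(0), tortuosity = numeric(0),
               beta0 = numeric(0), beta1 = numeric(0), r2 = numeric(0),
               D_m2_per_s = numeric(0))
  summarize_quotes(per_traj, quotes, level)
}

#' Simulate an ensemble and collect quote statistics without storing
#' trajectories
#'
#' Memory-lean driver for production-size runs: each trajectory is simulated,
#' reduced to its per-quote statistics and discarded. Equivalent to
#' [simulate_ensemble()] followed by [quote_sweep()].
#'
#' @inheritParams simulate_ensemble
#' @inheritParams quote_sweep
#' @return A `quote_report` (see [quote_sweep()]); failed trajectory indices
#'   are carried in attribute `"failed"`.
#' @export
simulate_quote_stats <- function(geometry, config = walk_config(),
                                 quotes = 134 * (1:7), fit_window = NULL,
                                 msd_lags_max = 128, level = 0.95,
                                 progress = FALSE) {
  env <- new.env()
  env$per <- list()
  ens <- simulate_ensemble(
    geometry, config, keep_positions = FALSE, progress = progress,
    callback = function(traj, i) {
      env$per[[length(env$per) + 1]] <- quote_stats_one_trajectory(
        traj, i, quotes, fit_window, msd_lags_max)
      NULL
    })
  per_traj <- if (length(env$per)) do.call(rbind, env$per) else
    data.frame(trajectory = integer(0), quote_L_nm = numeric(0),
               n_points = integer(0), tortuosity = numeric(0),
               beta0 = numeric(0), beta1 = numeric(0), r2 = numeric(0),
               D_m2_per_s = numeric(0))
  out <- summarize_quotes(per_traj, quotes, level)
  attr(out, "failed") <- ens$failed
  out
}

#' @export
print.quote_report <- function(x, ...) {
  cat("Per-quote sub-trajectory statistics\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot mean tortuosity and diffusivity along the fibril axis
#'
#' @param x a `quote_report`.
#' @param ... ignored.
#' @export
plot.quote_report <- function(x, ...) {
  old <- par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(par(old))
  ok <- x$n_subtraj > 0
  plot(x$quote_L_nm[ok], x$mean_tortuosity[ok], type = "b", pch = 19,
       xlab = "reference quote L [nm]", ylab = "mean tortuosity")
  arrows(x$quote_L_nm[ok], x$tort_ci_lo[ok], x$quote_L_nm[ok],
         x$tort_ci_hi[ok], angle = 90, code = 3, length = 0.03)
  plot(x$quote_L_nm[ok], x$mean_D[ok], type = "b", pch = 19,
       xlab = "reference quote L [nm]",
       ylab = expression(bar(D) ~ group("[", m^2 %.% s^-1, "]")))
  arrows(x$quote_L_nm[ok], x$D_ci_lo[ok], x$quote_L_nm[ok], x$D_ci_hi[ok],
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Write quote-sweep results as CSV
#'
#' Writes the per-quote summary and, alongside it, the per-trajectory table
#' (`<stem>_per_trajectory.csv`).
#'
#' @param report a `quote_report`.
#' @param path summary CSV path.
#' @return `path`, invisibly.
#' @export
write_quote_report <- function(report, path) {
  stopifnot(inherits(report, "quote_report"))
  write.csv(as.data.frame(report), path, row.names = FALSE)
  per <- attr(report, "per_trajectory")
  if (!is.null(per)) {
    stem <- sub("\\.csv$", "", path)
    write.csv(per, paste0(stem, "_per_trajectory.csv"), row.names = FALSE)
  }
  invisible(path)
}
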