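test_that("step sigma follows the Einstein step relation", {
  expect_equal(step_sigma(2.66e-9, 2e-10), 1.031504e-9, tolerance = 1e-6)
  expect_equal(suppressWarnings(step_sigma(0.5, 1)), 1)
  expect_equal(step_sigma(0, 1e-10), 0)
  expect_error(step_sigma(-1, 1e-10), "D0 must be")
  expect_error(step_sigma(2.66e-9, 0), "delta_t must be")
  # steps at least as large as the thinnest obstacle trigger the warning
  expect_warning(step_sigma(2.66e-9, 4e-10), "collagen diameter")
})

test_that("proposed steps are isotropic Gaussian displacements", {
  expect_equal(propose_step(5, 0), matrix(0, 5, 3), ignore_attr = TRUE)
  set.seed(12)
  s <- propose_step(3e5, step_sigma())
  sig_nm <- step_sigma() * 1e9
  for (k in 1:3) {
    expect_lt(abs(mean(s[, k])), 3 * sig_nm / sqrt(nrow(s)))
    expect_lt(abs(sd(s[, k]) / sig_nm - 1), 0.01)
  }
  set.seed(7); a <- propose_step(10, 1e-9)
  set.seed(7); b <- propose_step(10, 1e-9)
  expect_identical(a, b)
})

test_that("free walk reproduces the raw Gaussian stream and Brownian moments", {
  em <- make_fixture("empty")
  cfg <- walk_config(max_steps = 500, stop_L = Inf)
  tr <- suppressWarnings(simulate_trajectory(em, cfg, seed = 42))
  # with no obstacles, every proposal is accepted: the trajectory is the
  # cumulative sum of the generator's normal stream
  z <- matrix(mcfrw:::cpp_rw_normals(3 * 500, 42), ncol = 3, byrow = TRUE)
  expect_equal(tr$positions[-1, ], apply(z * cfg$sigma * 1e9, 2, cumsum),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$n_rejections, 0)

  # per-coordinate displacement variance matches 2 D0 t within 3 SE
  n_traj <- 400; n_steps <- 400
  ends <- matrix(0, n_traj, 3)
  for (i in seq_len(n_traj)) {
    t2 <- suppressWarnings(simulate_trajectory(
      em, walk_config(max_steps = n_steps, stop_L = Inf), seed = 1000 + i))
    ends[i, ] <- t2$positions[n_steps + 1, ]
  }
  v_true <- (step_sigma() * 1e9)^2 * n_steps
  for (k in 1:3) {
    v <- var(ends[, k])
    expect_lt(abs(v / v_true - 1), 3 * sqrt(2 / (n_traj - 1)))
  }
})

test_that("trajectories are deterministic and conserve the time step", {
  g <- small_lattice()
  cfg <- walk_config(stop_L = 100, max_steps = 2e5)
  t1 <- simulate_trajectory(g, cfg, seed = 5)
  t2 <- simulate_trajectory(g, cfg, seed = 5)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$termination, "reached")
  expect_equal(nrow(t1$positions), t1$n_steps + 1)
  expect_gte(t1$positions[nrow(t1$positions), 3], 100)

  # no recorded position is blocked (final point may sit above the open top)
  pos <- t1$positions[-nrow(t1$positions), ]
  expect_false(any(point_is_blocked(g, pos)))

  # a zero-length fibril terminates at the start plane
  t0 <- simulate_trajectory(g, walk_config(stop_L = 0, max_steps = 10),
                            seed = 5)
  expect_identical(nrow(t0$positions), 1L)
  expect_identical(t0$termination, "reached")
})

test_that("advance resolves collisions by stay-and-resample", {
  g <- small_lattice()
  # walkers pressed against obstacles reject some proposals but always land
  # on un-blocked positions one time step later
  start <- c(0.8, 0.8, 150)
  while (oracle_point_blocked(g, start)) start <- start + c(0.05, 0.03, 0.07)
  rejections <- 0
  for (s in 1:50) {
    res <- advance(start, g, walk_config(), seed = 2000 + s)
    expect_false(point_is_blocked(g, res$position))
    expect_false(segment_is_blocked(g, start, res$position))
    rejections <- rejections + res$n_rejections
  }
  expect_gt(rejections, 0)  # collagen at 1.6 nm spacing forces rejections

  # a cavity smaller than sigma traps the walker
  sealed <- make_fixture("sealed_box")
  expect_error(advance(c(0, 0, 500), sealed, walk_config(), seed = 1),
               "trapped walker")
})

test_that("ensembles are reproducible and isolate failures", {
  g <- small_lattice()
  cfg <- walk_config(n_trajectories = 3, stop_L = 60, max_steps = 1e5,
                     master_seed = 77)
  e1 <- simulate_ensemble(g, cfg)
  e2 <- simulate_ensemble(g, cfg)
  expect_length(e1$trajectories, 3)
  expect_identical(lapply(e1$trajectories, `[[`, "positions"),
                   lapply(e2$trajectories, `[[`, "positions"))
  cfg1 <- walk_config(n_trajectories = 1, stop_L = 60, max_steps = 1e5)
  expect_length(simulate_ensemble(g, cfg1)$trajectories, 1)

  # a start plane with no free space fails that trajectory, not the ensemble
  blocked_start <- make_fixture("single_box")
  blocked_start$platelets$centers[1, ] <- c(0, 0, 0)
  blocked_start$platelets$halfdims[1, ] <- c(150, 150, 2)
  eb <- simulate_ensemble(blocked_start,
                          walk_config(n_trajectories = 2, max_steps = 10))
  expect_length(eb$failed, 2)
  expect_match(eb$failed[[1]]$message, "start position")
})

test_that("obstruction lowers the estimated diffusivity at matched seeds", {
  em <- make_fixture("empty")
  g <- small_lattice()
  n <- 15
  D_free <- D_obs <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- walk_config(max_steps = 3000, stop_L = Inf)
    tf <- suppressWarnings(simulate_trajectory(em, cfg, seed = 500 + i))
    to <- suppressWarnings(simulate_trajectory(g, cfg, seed = 500 + i))
    D_free[i] <- diffusion_coefficient(fit_msd(msd_time_average(tf)))
    D_obs[i] <- diffusion_coefficient(fit_msd(msd_time_average(to)))
  }
  expect_lt(mean(D_obs), mean(D_free))
})

test_that("record stride subsamples positions but keeps endpoints", {
  em <- make_fixture("empty")
  cfg <- walk_config(max_steps = 1000, stop_L = Inf, record_stride = 10L)
  tr <- suppressWarnings(simulate_trajectory(em, cfg, seed = 8))
  expect_equal(nrow(tr$positions), 101)
  full <- suppressWarnings(simulate_trajectory(
    em, walk_config(max_steps = 1000, stop_L = Inf), seed = 8))
  expect_equal(tr$positions[2, ], full$positions[11, ], ignore_attr = TRUE)
})

test_that("trajectory CSV and XYZ exports round-trip", {
  g <- small_lattice()
  tr <- simulate_trajectory(g, walk_config(stop_L = 40, max_steps = 1e5),
                            seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  tr2 <- read_trajectory_csv(csv)
  expect_equal(tr2$positions, tr$positions, tolerance = 1e-7)
  expect_equal(tr2$delta_t, tr$delta_t)
  expect_equal(tr2$n_steps, tr$n_steps)
  expect_identical(tr2$termination, tr$termination)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, xyz)
  expect_equal(as.integer(readLines(xyz, n = 1)), nrow(tr$positions))
})
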