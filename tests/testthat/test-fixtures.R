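test_that("fixture kinds build and unknown kinds error", {
  for (kind in c("empty", "single_box", "slab_array", "regular_lattice",
                 "sealed_box")) {
    g <- make_fixture(kind, envelope_radius = 40, envelope_length = 300,
                      seed = 2)
    expect_s3_class(g, "mcf_geometry")
  }
  expect_error(make_fixture("banana"), "arg")
})

test_that("ballistic trajectories have closed-form MSD and unit tortuosity", {
  tr <- ballistic_trajectory(4, c(1, 0, 0))
  expect_equal(msd_time_average(tr, lags = 2)$msd, 4)
  expect_equal(oracle_msd(tr, 1:3), c(1, 4, 9))
  expect_equal(tortuosity(tr), 1)
  expect_equal(tortuosity(ballistic_trajectory(7, c(0.3, -1, 2))), 1)
  still <- ballistic_trajectory(3, c(0, 0, 0))
  expect_error(tortuosity(still), "undefined tortuosity")
  expect_error(ballistic_trajectory(1, c(1, 0, 0)), "n must be >= 2")
})

test_that("msd oracle handles boundary cases", {
  two <- manual_trajectory(rbind(c(0, 0, 0), c(1, 2, 2)))
  expect_equal(oracle_msd(two, 1), 9)  # single pair: |(1,2,2)|^2
  const <- manual_trajectory(matrix(1, 6, 3))
  expect_equal(oracle_msd(const, 1:5), rep(0, 5))
})

test_that("point oracle agrees with the indexed query on fixtures", {
  sb <- make_fixture("single_box")
  expect_true(oracle_point_blocked(sb, c(0, 0, 500)))
  expect_false(oracle_point_blocked(sb, c(50, 0, 500)))
  em <- make_fixture("empty")
  expect_false(oracle_point_blocked(em, c(1e5, 0, -1e5)))
  set.seed(81)
  pts <- cbind(runif(300, -110, 110), runif(300, -110, 110),
               runif(300, -50, 1050))
  fast <- point_is_blocked(sb, pts)
  slow <- vapply(seq_len(300), function(i) oracle_point_blocked(sb, pts[i, ]),
                 logical(1))
  expect_identical(fast, slow)
})

test_that("segment oracle detects crossings through thin walls", {
  sl <- make_fixture("slab_array")
  # crossing the first wall (L = 100) away from its aperture
  p0 <- c(-20, 0, 95)
  p1 <- c(-20, 0, 105)
  expect_true(oracle_segment_blocked(sl, p0, p1))
  expect_true(segment_is_blocked(sl, p0, p1))
  # passing through the aperture slot (W near +50) is free
  a0 <- c(50, 0, 95)
  a1 <- c(50, 0, 105)
  expect_false(oracle_segment_blocked(sl, a0, a1))
  expect_false(segment_is_blocked(sl, a0, a1))
})

test_that("slab array obstructs transport by construction", {
  sl <- make_fixture("slab_array")
  torts <- Ds <- numeric(30)
  cfg <- walk_config(max_steps = 2e4, stop_L = Inf)
  for (i in seq_len(30)) {
    tr <- suppressWarnings(simulate_trajectory(sl, cfg, seed = 700 + i))
    torts[i] <- tortuosity(tr)
    Ds[i] <- diffusion_coefficient(fit_msd(msd_time_average(tr, lags = 1:2000)))
  }
  expect_gt(mean(torts), 1.05)
  expect_lt(mean(Ds), 2.66e-9)
})

test_that("sealed box is closed from the inside", {
  sealed <- make_fixture("sealed_box")
  ctr <- c(0, 0, 500)
  expect_false(point_is_blocked(sealed, ctr))
  # every wall direction is blocked within one step length
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    expect_true(segment_is_blocked(sealed, ctr, ctr + 1.5 * d))
  }
})
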