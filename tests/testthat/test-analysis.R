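test_that("time-averaged MSD matches hand cases and the double-loop oracle", {
  # constant path
  const <- manual_trajectory(matrix(2, 5, 3))
  expect_equal(msd_time_average(const)$msd, rep(0, 4))

  # collinear path, lag 2: pairs (0->2) and (1->3), both displacement 2
  lin <- manual_trajectory(cbind(0:3, 0, 0))
  expect_equal(msd_time_average(lin, lags = 2)$msd, 4)

  # random trajectories vs the independent O(N^2) oracle
  set.seed(55)
  for (rep in 1:5) {
    tr <- random_walk_trajectory(50)
    lags <- 1:49
    fast <- msd_time_average(tr, lags = lags)$msd
    slow <- oracle_msd(tr, lags)
    expect_lt(max(abs(fast - slow) / pmax(slow, 1e-300)), 1e-9)
  }
  expect_error(msd_time_average(lin, lags = 4), "lags must lie")
  expect_error(msd_time_average(manual_trajectory(matrix(0, 1, 3))),
               "at least 2 positions")
})

test_that("MSD line fit recovers exact lines and flags degenerate windows", {
  tr <- manual_trajectory(matrix(0, 11, 3))
  curve <- msd_time_average(tr)
  curve$msd <- 5 + 3 * curve$time
  fit <- fit_msd(curve, window = c(1, 10))
  expect_equal(fit$beta0, 5, tolerance = 1e-6)
  expect_equal(fit$beta1, 3, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_error(fit_msd(curve, window = c(3, 3)), "degenerate fit window")
})

test_that("diffusion coefficient is one sixth of the slope in SI units", {
  fit <- structure(list(beta0 = 0, beta1 = 6, r_squared = 1,
                        window = c(1, 10), n_lags = 10), class = "msd_fit")
  expect_equal(diffusion_coefficient(fit), 1e-18)
  fit$beta1 <- 0
  expect_equal(diffusion_coefficient(fit), 0)
})

test_that("free-walk ensembles recover the configured diffusivity", {
  # Einstein relation on the analysis side alone: synthetic Gaussian walks
  # with per-step sigma chosen for D0, fitted via Eqs. MSD -> slope/6
  set.seed(99)
  sigma_nm <- step_sigma() * 1e9
  D <- replicate(60, {
    tr <- random_walk_trajectory(2000, sigma_nm = sigma_nm)
    diffusion_coefficient(fit_msd(msd_time_average(tr, lags = 1:200)))
  })
  expect_lt(abs(mean(D) - 2.66e-9), 3 * sd(D) / sqrt(length(D)))
})

test_that("tortuosity is the path-to-distance ratio and at least 1", {
  straight <- manual_trajectory(cbind(0, 0, 0:2))
  expect_equal(tortuosity(straight), 1)
  corner <- manual_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(tortuosity(corner), 2 / sqrt(2), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:10) expect_gte(tortuosity(random_walk_trajectory(100)), 1)
  loop <- manual_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_error(tortuosity(loop), "undefined tortuosity")
})

test_that("tortuosity of free walks grows with path length", {
  set.seed(21)
  short_t <- replicate(25, tortuosity(random_walk_trajectory(500)))
  long_t <- replicate(25, tortuosity(random_walk_trajectory(4000)))
  expect_gt(mean(long_t), mean(short_t))
})

test_that("sub-trajectory extraction stops at the first passage", {
  tr <- manual_trajectory(cbind(0, 0, c(0, 50, 140, 100, 200)))
  sub <- extract_subtrajectory(tr, 134)
  expect_equal(nrow(sub$positions), 3)
  expect_equal(unname(sub$positions[3, 3]), 140)
  expect_null(extract_subtrajectory(tr, 300))
  full <- extract_subtrajectory(tr, 200)
  expect_equal(nrow(full$positions), 5)
  expect_error(extract_subtrajectory(tr, 0), "quote_L must be > 0")
})

test_that("confidence intervals follow the Student-t construction", {
  ci <- confidence_interval(c(2, 2, 2))
  expect_equal(unname(ci), c(2, 2), ignore_attr = TRUE)
  ci2 <- confidence_interval(c(1, 2, 3), 0.95)
  expect_equal(unname(ci2), c(-0.48414, 4.48414), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname((ci2[1] + ci2[2]) / 2), 2, tolerance = 1e-12)
  expect_error(confidence_interval(1), "at least 2")
})

test_that("confidence intervals cover the true mean at the nominal rate", {
  set.seed(404)
  hits <- replicate(500, {
    ci <- confidence_interval(rnorm(10, 3, 2), 0.95)
    ci[1] <= 3 && 3 <= ci[2]
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("order of magnitude is the power of ten below", {
  expect_equal(order_of_magnitude(4.12e-10), 1e-10)
  expect_equal(order_of_magnitude(1.0), 1)
  expect_equal(order_of_magnitude(9.99e-10), 1e-10)
  expect_error(order_of_magnitude(0), "x > 0")
})

test_that("quote sweep aggregates sub-trajectory statistics", {
  # tortuosity-1 and tortuosity-3 paths reaching the quote -> mean 2
  zig <- rbind(c(0, 0, 0), c(3, 0, 1), c(0, 0, 2), c(3, 0, 3), c(0, 0, 4),
               c(3, 0, 5))
  zig_t <- manual_trajectory(zig)
  straight <- manual_trajectory(cbind(0, 0, seq(0, 5, by = 1)))
  ens <- structure(list(trajectories = list(straight, zig_t), failed = list(),
                        config = walk_config(n_trajectories = 2)),
                   class = "mcf_ensemble")
  rep5 <- quote_sweep(ens, quotes = 5)
  expect_equal(rep5$n_subtraj, 2L)
  t_zig <- tortuosity(zig_t)
  expect_equal(rep5$mean_tortuosity, (1 + t_zig) / 2, tolerance = 1e-12)

  # identical diffusivities give a zero-width CI
  ens2 <- structure(list(trajectories = list(straight, straight),
                         failed = list(),
                         config = walk_config(n_trajectories = 2)),
                    class = "mcf_ensemble")
  rep2 <- quote_sweep(ens2, quotes = 5)
  expect_equal(rep2$D_ci_lo, rep2$D_ci_hi)

  # unreached quotes are flagged, not averaged
  rep9 <- quote_sweep(ens, quotes = c(5, 9))
  expect_equal(rep9$n_subtraj, c(2L, 0L))
  expect_true(is.na(rep9$mean_tortuosity[2]))
  expect_error(quote_sweep(ens, quotes = c(9, 5)), "sorted")
})

test_that("streaming quote statistics match the stored-ensemble path", {
  g <- small_lattice()
  cfg <- walk_config(n_trajectories = 4, stop_L = 120, max_steps = 3e5,
                     master_seed = 202)
  ens <- simulate_ensemble(g, cfg)
  a <- quote_sweep(ens, quotes = c(40, 80, 120))
  b <- simulate_quote_stats(g, cfg, quotes = c(40, 80, 120))
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12,
               ignore_attr = TRUE)
})
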