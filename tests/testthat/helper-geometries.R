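# Shared fixtures for the suite. Heavy objects are built once per test run
# and memoized here; every seed is fixed.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small staggered lattice (with collagen) cheap enough for R-side oracles
small_lattice <- function() {
  memo("small_lattice", {
    g <- build_lattice(envelope_radius = 40, envelope_length = 300,
                       seed = 5, mineral_fraction = NULL)
    perturb(g, n_moves = 2e5, seed = 6)
  })
}

# the default model geometry (full envelope, 6e6 perturbation moves)
default_geometry <- function() {
  memo("default_geometry", build_mcf_geometry(seed = 1))
}

# deterministic trajectory from an explicit position matrix
manual_trajectory <- function(positions, delta_t = 2e-10) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  colnames(positions) <- c("W", "T", "L")
  structure(list(positions = positions, delta_t = delta_t, seed = NA_real_,
                 n_steps = nrow(positions) - 1, n_rejections = 0,
                 termination = "fixture", record_stride = 1L),
            class = "mcf_trajectory")
}

# free Gaussian walk positions (analysis-side fixture, independent of the
# compiled walker)
random_walk_trajectory <- function(n, sigma_nm = 1, delta_t = 2e-10) {
  steps <- matrix(rnorm(3 * (n - 1), 0, sigma_nm), ncol = 3)
  manual_trajectory(rbind(c(0, 0, 0), apply(steps, 2, cumsum)),
                    delta_t = delta_t)
}
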