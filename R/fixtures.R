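#' Synthetic test geometries
#'
#' Deterministic geometries with analytically known properties, used to
#' validate the walker and the analysis chain without external data:
#'
#' * `empty`: no obstacles, unbounded envelope; the walker is a free
#'   Brownian particle starting at the origin (closed-form MSD).
#' * `single_box`: one axis-aligned platelet of known volume inside the
#'   standard envelope (closed-form volume fraction).
#' * `slab_array`: thin transverse walls spanning the cross-section, each
#'   pierced by one off-centre slot aperture on alternating sides; any
#'   crossing path must detour, so ensemble tortuosity is > 1 and the
#'   effective diffusivity is below the bulk value by construction.
#' * `regular_lattice`: the unperturbed staggered platelet lattice with the
#'   default parameters.
#' * `sealed_box`: a closed cavity smaller than the step size, for
#'   trapped-walker error tests.
#'
#' @param kind fixture name (see above).
#' @param envelope_radius,envelope_length envelope in nm (bounded fixtures).
#' @param seed seed for `regular_lattice` dimension sampling.
#' @param ... passed to [build_lattice()] for `regular_lattice`.
#' @return An `mcf_geometry`.
#' @export
make_fixture <- function(kind = c("empty", "single_box", "slab_array",
                                  "regular_lattice", "sealed_box"),
                         envelope_radius = 100, envelope_length = 1000,
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  box <- function(center, dims) {
    list(centers = matrix(center, 1, 3,
                          dimnames = list(NULL, c("W", "T", "L"))),
         halfdims = matrix(dims / 2, 1, 3),
         rot = identity_rot(1), inclination = 0)
  }
  stack_boxes <- function(boxes) {
    list(centers = do.call(rbind, lapply(boxes, `[[`, "centers")),
         halfdims = do.call(rbind, lapply(boxes, `[[`, "halfdims")),
         rot = identity_rot(length(boxes)),
         inclination = numeric(length(boxes)))
  }
  env_b <- list(bounded = TRUE, radius = envelope_radius,
                length = envelope_length)
  switch(kind,
    empty = {
      p <- empty_platelets()
      new_mcf_geometry(p$centers, p$halfdims, p$rot, p$inclination,
                       envelope = list(bounded = FALSE,
                                       radius = envelope_radius,
                                       length = envelope_length),
                       collagen = no_collagen(),
                       meta = list(fixture = "empty"))
    },
    single_box = {
      b <- box(c(0, 0, envelope_length / 2), c(10, 10, 10))
      new_mcf_geometry(b$centers, b$halfdims, b$rot, b$inclination,
                       envelope = env_b, collagen = no_collagen(),
                       meta = list(fixture = "single_box",
                                   box_volume = 10^3))
    },
    slab_array = {
      R <- envelope_radius
      wall_L <- seq(100, envelope_length - 100, by = 100)
      aperture_halfwidth <- 10
      boxes <- list()
      for (i in seq_along(wall_L)) {
        side <- if (i %% 2 == 1) 1 else -1
        a_lo <- side * 50 - aperture_halfwidth
        a_hi <- side * 50 + aperture_halfwidth
        # wall = full cross-section minus a vertical slot [a_lo, a_hi] in W
        boxes[[length(boxes) + 1]] <-
          box(c((a_lo + (-R - 10)) / 2, 0, wall_L[i]),
              c(a_lo - (-R - 10), 2 * R + 20, 2))
        boxes[[length(boxes) + 1]] <-
          box(c((a_hi + (R + 10)) / 2, 0, wall_L[i]),
              c((R + 10) - a_hi, 2 * R + 20, 2))
      }
      s <- stack_boxes(boxes)
      new_mcf_geometry(s$centers, s$halfdims, s$rot, s$inclination,
                       envelope = env_b, collagen = no_collagen(),
                       meta = list(fixture = "slab_array", wall_L = wall_L))
    },
    regular_lattice = {
      build_lattice(envelope_radius = envelope_radius,
                    envelope_length = envelope_length, seed = seed, ...)
    },
    sealed_box = {
      # cavity much smaller than the 1.03 nm step sigma at the envelope
      # centre, 1 nm thick walls: the step-acceptance probability
      # ~(cavity/sigma)^3 is far below the trapped-walker threshold
      cavity <- 0.01
      wall <- 1
      ctr <- c(0, 0, envelope_length / 2)
      out <- cavity + wall
      boxes <- list(
        box(ctr + c(-(cavity + wall / 2), 0, 0), c(wall, 2 * out, 2 * out)),
        box(ctr + c(cavity + wall / 2, 0, 0), c(wall, 2 * out, 2 * out)),
        box(ctr + c(0, -(cavity + wall / 2), 0), c(2 * cavity, wall, 2 * out)),
        box(ctr + c(0, cavity + wall / 2, 0), c(2 * cavity, wall, 2 * out)),
        box(ctr + c(0, 0, -(cavity + wall / 2)), c(2 * cavity, 2 * cavity, wall)),
        box(ctr + c(0, 0, cavity + wall / 2), c(2 * cavity, 2 * cavity, wall)))
      s <- stack_boxes(boxes)
      new_mcf_geometry(s$centers, s$halfdims, s$rot, s$inclination,
                       envelope = env_b, collagen = no_collagen(),
                       meta = list(fixture = "sealed_box", center = ctr,
                                   cavity_halfwidth = cavity))
    })
}

#' Deterministic straight-line trajectory
#'
#' Positions `j * step`, j = 0..n-1. Known closed forms: MSD at lag k is
#' `k^2 * |step|^2` and the tortuosity is exactly 1.
#'
#' @param n number of positions (>= 2).
#' @param step length-3 displacement per time step, nm.
#' @param delta_t time step, s.
#' @return An `mcf_trajectory`.
#' @export
ballistic_trajectory <- function(n, step, delta_t = 2e-10) {
  if (n < 2) stopf("n must be >= 2")
  pos <- outer(seq_len(n) - 1, as.numeric(step))
  new_trajectory(pos, delta_t = delta_t, seed = NA_real_, n_steps = n - 1,
                 n_rejections = 0, termination = "fixture")
}

#' Literal double-loop MSD oracle
#'
#' Independent O(N^2) implementation of the time-averaged MSD used only to
#' cross-check [msd_time_average()]; shares no code with the production path.
#'
#' @param trajectory an `mcf_trajectory`.
#' @param lags integer lags in 1..N-1.
#' @return numeric vector of MSD values, nm^2.
#' @export
oracle_msd <- function(trajectory, lags) {
  pos <- trajectory$positions
  N <- nrow(pos)
  vapply(lags, function(n) {
    if (n < 1 || n >= N) stopf("lag %d out of range", n)
    total <- 0
    for (j in seq(0, N - 1 - n)) {
      d <- pos[j + n + 1, ] - pos[j + 1, ]
      total <- total + sum(d * d)
    }
    total / (N - n)
  }, numeric(1))
}

#' Index-free point occupancy oracle
#'
#' Scans every platelet (inverse-rotating the point into the platelet
#' frame), every collagen cylinder (enumerating the hexagonal lattice
#' directly) and the envelope, without any spatial index. Used only to
#' cross-check [point_is_blocked()].
#'
#' @param geometry an `mcf_geometry`.
#' @param point length-3 position (nm).
#' @return logical.
#' @export
oracle_point_blocked <- function(geometry, point) {
  point <- as.numeric(point)
  env <- geometry$envelope
  if (isTRUE(env$bounded)) {
    if (point[1]^2 + point[2]^2 > env$radius^2) return(TRUE)
    if (point[3] < 0 || point[3] > env$length) return(TRUE)
  }
  p <- geometry$platelets
  for (i in seq_len(nrow(p$centers))) {
    Rm <- matrix(p$rot[i, ], 3, 3)
    local <- drop(t(Rm) %*% (point - p$centers[i, ]))
    if (all(abs(local) <= p$halfdims[i, ])) return(TRUE)
  }
  lat <- geometry$collagen$lattice
  if (isTRUE(lat$enabled)) {
    s <- lat$spacing
    H <- s * sqrt(3)
    ii <- seq(floor((point[1] - lat$radius) / s) - 1,
              ceiling((point[1] + lat$radius) / s) + 1)
    jj <- seq(floor((point[2] - lat$radius) / H) - 1,
              ceiling((point[2] + lat$radius) / H) + 1)
    for (i in ii) for (j in jj) {
      for (off in list(c(0, 0), c(s / 2, H / 2))) {
        dw <- point[1] - (i * s + off[1])
        dt <- point[2] - (j * H + off[2])
        if (dw^2 + dt^2 <= lat$radius^2) return(TRUE)
      }
    }
  }
  cy <- geometry$collagen$cylinders
  for (m in seq_len(nrow(cy))) {
    if ((point[1] - cy[m, 1])^2 + (point[2] - cy[m, 2])^2 <= cy[m, 3]^2)
      return(TRUE)
  }
  FALSE
}

#' Dense-sampling segment occupancy oracle
#'
#' Declares a segment blocked if any of `n_samples` evenly spaced points
#' along it (endpoints included) is blocked according to
#' [oracle_point_blocked()]. A sampling oracle can miss grazing hits, so the
#' production [segment_is_blocked()] must agree wherever this oracle reports
#' a hit.
#'
#' @param geometry an `mcf_geometry`.
#' @param p0,p1 segment endpoints (nm).
#' @param n_samples sample count along the segment.
#' @return logical.
#' @export
oracle_segment_blocked <- function(geometry, p0, p1, n_samples = 1000) {
  u <- seq(0, 1, length.out = n_samples)
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  for (k in u) {
    if (oracle_point_blocked(geometry, p0 + k * (p1 - p0))) return(TRUE)
  }
  FALSE
}

#' Brute-force platelet overlap oracle
#'
#' O(P^2) pairwise separating-axis test over all platelet pairs, written
#' independently of the compiled overlap test used during perturbation.
#' Pairs are prefiltered by bounding-sphere distance.
#'
#' @param geometry an `mcf_geometry`.
#' @param tol penetration depth (nm) below which touching boxes are not
#'   reported as overlapping.
#' @return two-column matrix of overlapping pair indices (0 rows if none).
#' @export
oracle_platelet_overlaps <- function(geometry, tol = 1e-9) {
  p <- geometry$platelets
  P <- nrow(p$centers)
  if (P < 2) return(matrix(integer(0), 0, 2))
  br <- sqrt(rowSums(p$halfdims^2))
  pairs <- NULL
  sat_separated <- function(i, j) {
    Ri <- matrix(p$rot[i, ], 3, 3)
    Rj <- matrix(p$rot[j, ], 3, 3)
    hi <- p$halfdims[i, ]
    hj <- p$halfdims[j, ]
    d <- p$centers[j, ] - p$centers[i, ]
    axes <- cbind(Ri, Rj)
    for (a in 1:3) for (b in 1:3) {
      cr <- c(Ri[2, a] * Rj[3, b] - Ri[3, a] * Rj[2, b],
              Ri[3, a] * Rj[1, b] - Ri[1, a] * Rj[3, b],
              Ri[1, a] * Rj[2, b] - Ri[2, a] * Rj[1, b])
      nc <- sqrt(sum(cr^2))
      if (nc > 1e-8) axes <- cbind(axes, cr / nc)
    }
    for (k in seq_len(ncol(axes))) {
      ax <- axes[, k]
      ra <- sum(abs(drop(t(Ri) %*% ax)) * hi)
      rb <- sum(abs(drop(t(Rj) %*% ax)) * hj)
      if (abs(sum(d * ax)) >= ra + rb - tol) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(P - 1)) {
    d2 <- rowSums((p$centers[(i + 1):P, , drop = FALSE] -
                   matrix(p$centers[i, ], P - i, 3, byrow = TRUE))^2)
    cand <- which(d2 < (br[i] + br[(i + 1):P])^2) + i
    for (j in cand) {
      if (!sat_separated(i, j)) pairs <- rbind(pairs, c(i, j))
    }
  }
  if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs
}
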