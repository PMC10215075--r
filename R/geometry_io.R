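#' Write a geometry to a structured text file
#'
#' Key/value header (envelope, collagen lattice) followed by one whitespace
#' separated record per platelet (centre, dims, rotation matrix) and one per
#' explicit collagen cylinder. Values are written at full double precision so
#' a round trip is exact.
#'
#' @param geometry an `mcf_geometry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mcf_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "mcf_geometry"))
  p <- geometry$platelets
  P <- nrow(p$centers)
  cy <- geometry$collagen$cylinders
  lat <- geometry$collagen$lattice
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# mcfrw geometry v1",
    paste("bounded:", isTRUE(geometry$envelope$bounded)),
    paste("envelope_radius:", fmt(geometry$envelope$radius)),
    paste("envelope_length:", fmt(geometry$envelope$length)),
    paste("collagen_lattice:", isTRUE(lat$enabled)),
    paste("collagen_spacing:", fmt(lat$spacing)),
    paste("collagen_radius:", fmt(lat$radius)),
    paste("platelets:", P)), con)
  if (P > 0) {
    rec <- cbind(p$centers, 2 * p$halfdims, p$rot)
    writeLines(apply(rec, 1, function(r) paste(fmt(r), collapse = " ")), con)
  }
  writeLines(paste("cylinders:", nrow(cy)), con)
  if (nrow(cy) > 0)
    writeLines(apply(cy, 1, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Read a geometry written by [write_mcf_geometry()]
#'
#' @param path input file.
#' @return An `mcf_geometry`.
#' @export
read_mcf_geometry <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    if (is.na(ln)) stopf("geometry file is missing key '%s'", key)
    trimws(sub(paste0("^", key, ":"), "", ln))
  }
  P <- as.integer(kv("platelets"))
  ip <- grep("^platelets:", lines)[1]
  prec <- if (P > 0) {
    do.call(rbind, lapply(lines[(ip + 1):(ip + P)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  } else matrix(numeric(0), 0, 15)
  ic <- grep("^cylinders:", lines)[1]
  M <- as.integer(sub("^cylinders:", "", lines[ic]))
  cy <- if (M > 0) {
    do.call(rbind, lapply(lines[(ic + 1):(ic + M)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  } else matrix(numeric(0), 0, 3)
  centers <- prec[, 1:3, drop = FALSE]
  colnames(centers) <- c("W", "T", "L")
  halfdims <- prec[, 4:6, drop = FALSE] / 2
  colnames(halfdims) <- c("width", "thickness", "length")
  rot <- prec[, 7:15, drop = FALSE]
  incl <- if (P > 0) acos(pmin(1, abs(rot[, 9]))) else numeric(0)
  new_mcf_geometry(
    centers = centers, halfdims = halfdims, rot = rot, inclination = incl,
    envelope = list(bounded = as.logical(kv("bounded")),
                    radius = as.numeric(kv("envelope_radius")),
                    length = as.numeric(kv("envelope_length"))),
    collagen = list(lattice = list(enabled = as.logical(kv("collagen_lattice")),
                                   spacing = as.numeric(kv("collagen_spacing")),
                                   radius = as.numeric(kv("collagen_radius"))),
                    cylinders = cy),
    meta = list(source = path))
}

#' Export obstacle corner points as an XYZ point cloud
#'
#' Writes the eight corners of every platelet (element `P`) and the centre
#' line sample points of collagen cylinders (element `C`) in XYZ format for
#' molecular viewers.
#'
#' @param geometry an `mcf_geometry`.
#' @param path output file.
#' @param cylinder_stride axial spacing (nm) of collagen marker points.
#' @return `path`, invisibly.
#' @export
write_geometry_xyz <- function(geometry, path, cylinder_stride = 50) {
  stopifnot(inherits(geometry, "mcf_geometry"))
  p <- geometry$platelets
  P <- nrow(p$centers)
  corners <- matrix(numeric(0), 0, 3)
  if (P > 0) {
    signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    corners <- do.call(rbind, lapply(seq_len(P), function(i) {
      Rm <- matrix(p$rot[i, ], 3, 3)
      local <- t(signs) * p$halfdims[i, ]
      t(Rm %*% local + p$centers[i, ])
    }))
  }
  cyl <- collagen_positions(geometry)
  lpts <- seq(0, geometry$envelope$length, by = cylinder_stride)
  cylpts <- if (nrow(cyl) > 0) {
    cbind(rep(cyl[, 1], each = length(lpts)),
          rep(cyl[, 2], each = length(lpts)),
          rep(lpts, times = nrow(cyl)))
  } else matrix(numeric(0), 0, 3)
  n <- nrow(corners) + nrow(cylpts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n), "mcfrw geometry obstacle points [nm]"), con)
  if (nrow(corners) > 0)
    writeLines(sprintf("P %.6f %.6f %.6f", corners[, 1], corners[, 2],
                       corners[, 3]), con)
  if (nrow(cylpts) > 0)
    writeLines(sprintf("C %.6f %.6f %.6f", cylpts[, 1], cylpts[, 2],
                       cylpts[, 3]), con)
  invisible(path)
}
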