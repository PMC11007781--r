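#' Curved-array transducer geometry
#'
#' Builds a convex curved-array transducer in its own local frame. The
#' coordinate convention throughout the package is x lateral (positive to
#' the right), z axial depth (positive downward, into the tissue), with the
#' origin at the apex of the probe surface. Elements lie on a circular arc
#' of the stated radius of curvature whose center sits at (0, -radius);
#' adjacent elements are separated by `pitch` along the arc and element
#' normals point away from the arc center (into the tissue).
#'
#' @param n_elements number of elements (>= 2).
#' @param pitch inter-element arc spacing in mm.
#' @param radius radius of curvature in mm.
#' @param f0 center frequency in Hz.
#' @param bandwidth fractional bandwidth of the pulse (FWHM / f0).
#' @param label probe identifier, usually 1 or 2.
#' @return an object of class `transducer_geometry` with fields
#'   `n_elements`, `element_positions` (n x 2 matrix, mm),
#'   `element_normals` (n x 2 unit vectors), `pitch`, `radius`,
#'   `arc_center`, `f0`, `bandwidth`, `label`.
#' @examples
#' geom <- make_curved_array(64, pitch = 0.508, radius = 49.57, f0 = 3.7e6)
#' @export
make_curved_array <- function(n_elements, pitch, radius, f0 = 3.7e6,
                              bandwidth = 0.6, label = 1L) {
  if (n_elements < 2) stop("n_elements must be >= 2", call. = FALSE)
  if (pitch <= 0 || radius <= 0 || f0 <= 0)
    stop("pitch, radius and f0 must be positive", call. = FALSE)
  dalpha <- pitch / radius                 # arc spacing in radians
  alpha <- (seq_len(n_elements) - (n_elements + 1) / 2) * dalpha
  normals <- cbind(sin(alpha), cos(alpha))
  positions <- cbind(radius * sin(alpha), radius * cos(alpha) - radius)
  structure(list(
    n_elements = as.integer(n_elements),
    element_positions = positions,
    element_normals = normals,
    pitch = pitch,
    radius = radius,
    arc_center = c(0, -radius),
    f0 = f0,
    bandwidth = bandwidth,
    label = as.integer(label)
  ), class = "transducer_geometry")
}

#' @export
print.transducer_geometry <- function(x, ...) {
  cat(sprintf(
    "curved array (probe %d): %d elements, pitch %.3f mm, radius %.2f mm, f0 %.2f MHz\n",
    x$label, x$n_elements, x$pitch, x$radius, x$f0 / 1e6))
  invisible(x)
}

#' In-plane rigid transform
#'
#' A 2-D rigid transform with two translational and one rotational degree
#' of freedom, used to map points from one probe's local frame into the
#' global (probe-1) frame. Rotation is applied first, then translation.
#' The rotation convention is right handed on (x, z): `phi = 90` degrees
#' maps the point (1, 0) to (0, 1).
#'
#' @param tx,tz translation in mm.
#' @param phi rotation in degrees.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, tz = 0, phi = 0) {
  structure(list(tx = tx, tz = tz, phi = phi), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: tx %.4f mm, tz %.4f mm, phi %.4f deg\n",
              x$tx, x$tz, x$phi))
  invisible(x)
}

rotation_matrix <- function(phi_deg) {
  a <- phi_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param T a [rigid_transform()].
#' @param points an n x 2 matrix of (x, z) coordinates in mm (a length-2
#'   vector is treated as one point).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(T, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 2) else as.matrix(points)
  out <- p %*% t(rotation_matrix(T$phi))
  out[, 1] <- out[, 1] + T$tx
  out[, 2] <- out[, 2] + T$tz
  if (single) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transform(A, B)` is the transform that first applies `B`, then
#' `A`.
#' @param A,B [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(A, B) {
  t_new <- apply_transform(A, c(B$tx, B$tz))
  rigid_transform(t_new[1], t_new[2], A$phi + B$phi)
}

#' Invert a rigid transform
#' @param T a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(T) {
  R <- rotation_matrix(-T$phi)
  t_new <- -as.vector(R %*% c(T$tx, T$tz))
  rigid_transform(t_new[1], t_new[2], -T$phi)
}

#' Cartesian reconstruction grid
#'
#' @param x_range,z_range length-2 vectors (mm).
#' @param spacing grid spacing in mm, either a scalar or c(dx, dz).
#' @return an object of class `cartesian_grid` with `x`, `z`, `spacing`.
#' @export
cartesian_grid <- function(x_range, z_range, spacing) {
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(
    x = seq(x_range[1], x_range[2], by = spacing[1]),
    z = seq(z_range[1], z_range[2], by = spacing[2]),
    spacing = spacing
  ), class = "cartesian_grid")
}

#' Node coordinates of a Cartesian grid
#' @param grid a [cartesian_grid()].
#' @return an (nx * nz) x 2 matrix of (x, z), z varying fastest.
#' @export
grid_points <- function(grid) {
  cbind(rep(grid$x, each = length(grid$z)),
        rep(grid$z, times = length(grid$x)))
}

#' Sector (beam-aligned) reconstruction grid of a curved array
#'
#' The preferred grid for displacement tracking with a curved array: beams
#' fan out radially from the arc center through the aperture, so the axial
#' direction of every node is the local ultrasound propagation direction.
#' The default lateral line density is 2 lines per pitch; the default axial
#' spacing is one eighth of the wavelength.
#'
#' @param geom a [make_curved_array()] geometry (the receiving probe).
#' @param depth_range length-2 vector, depth along the beam from the probe
#'   surface in mm.
#' @param c speed of sound in m/s.
#' @param lines_per_pitch lateral line density.
#' @param axial_spacing axial sample spacing in mm; default `lambda / 8`.
#' @return an object of class `sector_grid` with `beam_angles` (degrees),
#'   `depths` (mm), `axial_spacing`, the generating geometry and helpers.
#' @export
sector_grid <- function(geom, depth_range, c = 1540,
                        lines_per_pitch = 2, axial_spacing = NULL) {
  lambda_mm <- c / geom$f0 * 1e3
  if (is.null(axial_spacing)) axial_spacing <- lambda_mm / 8
  dbeta <- geom$pitch / geom$radius / lines_per_pitch      # radians
  half <- (geom$n_elements - 1) / 2 * (geom$pitch / geom$radius)
  beta <- seq(-half, half, by = dbeta)
  depths <- seq(depth_range[1], depth_range[2], by = axial_spacing)
  structure(list(
    beam_angles = beta * 180 / pi,
    depths = depths,
    axial_spacing = axial_spacing,
    lines_per_pitch = lines_per_pitch,
    radius = geom$radius,
    arc_center = geom$arc_center
  ), class = "sector_grid")
}

#' Node coordinates of a sector grid (in the probe's local frame)
#'
#' @param grid a [sector_grid()].
#' @return an (n_depth * n_beam) x 2 matrix of (x, z) in mm, depth varying
#'   fastest (column-major over a depth x beam matrix).
#' @export
sector_points <- function(grid) {
  beta <- grid$beam_angles * pi / 180
  r <- grid$radius + grid$depths              # distance from arc center
  x <- outer(r, sin(beta))
  z <- outer(r, cos(beta)) - grid$radius
  cbind(as.vector(x), as.vector(z))
}

#' Beam (axial) unit direction at each sector-grid node
#' @param grid a [sector_grid()].
#' @return an (n_depth * n_beam) x 2 matrix of unit vectors.
#' @export
sector_beam_directions <- function(grid) {
  beta <- grid$beam_angles * pi / 180
  nd <- length(grid$depths)
  cbind(rep(sin(beta), each = nd), rep(cos(beta), each = nd))
}

#' Map points to fractional sector-grid indices
#'
#' Inverse of [sector_points()]: converts (x, z) in the probe's local frame
#' to fractional (depth index, beam index), 1-based, for interpolation on
#' matrices laid out depth x beam.
#' @param grid a [sector_grid()].
#' @param points n x 2 matrix in mm.
#' @return n x 2 matrix of fractional (i_depth, i_beam).
#' @export
sector_index <- function(grid, points) {
  p <- if (is.null(dim(points))) matrix(points, 1, 2) else as.matrix(points)
  dx <- p[, 1] - 0
  dz <- p[, 2] + grid$radius                  # relative to arc center
  r <- sqrt(dx^2 + dz^2)
  beta <- atan2(dx, dz) * 180 / pi
  depth <- r - grid$radius
  i_depth <- (depth - grid$depths[1]) / grid$axial_spacing + 1
  dbeta <- grid$beam_angles[2] - grid$beam_angles[1]
  i_beam <- (beta - grid$beam_angles[1]) / dbeta + 1
  cbind(i_depth, i_beam)
}

#' Diverging-wave transmit event
#'
#' Computes per-element transmit delays realizing a steered diverging wave.
#' The virtual source is placed behind the array on the line through the
#' probe origin along the steered direction, at a configurable standoff
#' (default: the radius of curvature, so that at zero steering the virtual
#' source coincides with the arc center). Steering angles are measured at
#' the probe origin against the z axis, counterclockwise positive. A Tukey
#' taper is applied as transmit apodization to reduce side lobes.
#'
#' @param geom a [make_curved_array()] geometry.
#' @param steering_angle steering angle in degrees, |angle| <= 90.
#' @param c speed of sound in m/s.
#' @param vs_standoff distance of the virtual source behind the probe
#'   origin in mm; default `geom$radius`.
#' @param tukey_ratio taper ratio of the Tukey apodization window.
#' @return an object of class `transmit_event` with `steering_angle`,
#'   `element_delays` (seconds, minimum 0), `apodization`, `virtual_source`
#'   (mm, probe local frame) and `t_vs0` (seconds from virtual-source
#'   firing to the delay reference, used by the beamformer).
#' @export
transmit_delays <- function(geom, steering_angle, c = 1540,
                            vs_standoff = NULL, tukey_ratio = 0.25) {
  if (abs(steering_angle) > 90)
    stop("|steering_angle| must be <= 90 degrees", call. = FALSE)
  if (is.null(vs_standoff)) vs_standoff <- geom$radius
  a <- steering_angle * pi / 180
  vs <- -vs_standoff * c(sin(a), cos(a))
  d <- sqrt((geom$element_positions[, 1] - vs[1])^2 +
            (geom$element_positions[, 2] - vs[2])^2)
  delays <- (d - min(d)) / c * 1e-3           # mm / (m/s) -> ms; *1e-3 -> s
  structure(list(
    steering_angle = steering_angle,
    element_delays = delays,
    apodization = tukey_window(geom$n_elements, tukey_ratio),
    virtual_source = vs,
    t_vs0 = min(d) / c * 1e-3
  ), class = "transmit_event")
}

#' Tukey (tapered cosine) window
#' @param n window length.
#' @param ratio taper ratio in [0, 1]; 0 is rectangular, 1 is Hann.
#' @return numeric vector of length `n` in [0, 1].
#' @export
tukey_window <- function(n, ratio = 0.25) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- ratio / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / ratio - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / ratio - 2 / ratio + 1)))
  w
}
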