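#' One pass of 2-D block-matching speckle tracking
#'
#' Estimates frame-to-frame displacement at a lattice of sector-grid nodes
#' by normalized cross-correlation of a reference kernel against a search
#' region in the moving frame, with per-axis parabolic sub-sample
#' refinement and smallest-magnitude tie-breaking. Kernel and search sizes
#' are given in mm; the lateral sizes may be a (shallow, deep) pair that is
#' interpolated linearly over the imaged depth range, since the lateral
#' beam spacing of a sector grid grows with depth. Nodes whose kernel or
#' search window leaves the grid are invalid (NA); flat kernels return
#' zero displacement with quality 0.
#'
#' @param ref,mov [beamformed_image] objects of one pairing on the same
#'   sector grid (consecutive frames).
#' @param kernel_mm `c(axial, lateral)` or `c(axial, lateral_shallow,
#'   lateral_deep)` kernel size, mm.
#' @param search_mm search-region size, same convention; the maximum lag
#'   per axis is (search - kernel) / 2, floored at one sample.
#' @param mode `"envelope"` (magnitude, zero-mean correlation) or `"rf"`
#'   (real part, raw correlation).
#' @param i_idx,j_idx node lattice: depth and beam indices into the grid
#'   (defaults: every 4th depth sample, every beam line).
#' @param seed a previous (coarse) `displacement_field` on the same
#'   lattice; its integer-rounded sample displacements seed the search.
#' @param zero_mean override the correlation centering.
#' @return an object of class `displacement_field` with `u_ax`, `u_lat`
#'   (mm, matrices over the node lattice), `u_samp_d`, `u_samp_b`
#'   (samples), `quality`, the lattice (`i_idx`, `j_idx`), `grid`,
#'   `pairing`, `T_tx`, `T_rx`, `frame_pair`.
#' @export
block_match <- function(ref, mov, kernel_mm, search_mm,
                        mode = c("envelope", "rf"),
                        i_idx = NULL, j_idx = NULL, seed = NULL,
                        zero_mean = NULL) {
  mode <- match.arg(mode)
  if (is.null(zero_mean)) zero_mean <- mode == "envelope"
  grid <- ref$grid
  if (!inherits(grid, "sector_grid"))
    stop("block_match expects images on a sector grid", call. = FALSE)
  a <- if (mode == "envelope") Mod(ref$iq) else Re(ref$iq)
  b <- if (mode == "envelope") Mod(mov$iq) else Re(mov$iq)
  nd <- nrow(a); nb <- ncol(a)
  if (is.null(i_idx)) i_idx <- seq(1, nd, by = 4)
  if (is.null(j_idx)) j_idx <- seq(1, nb, by = 1)

  dz <- grid$axial_spacing
  dbeta <- (grid$beam_angles[2] - grid$beam_angles[1]) * pi / 180
  lat_spacing <- (grid$radius + grid$depths) * dbeta   # mm per line, by depth

  lat_at <- function(spec_mm, depth_idx) {
    # lateral size in mm at given depth indices (linear in depth)
    if (length(spec_mm) == 1) return(rep(spec_mm, length(depth_idx)))
    d <- grid$depths[depth_idx]
    dr <- range(grid$depths)
    spec_mm[1] + (spec_mm[2] - spec_mm[1]) *
      (d - dr[1]) / max(dr[2] - dr[1], .Machine$double.eps)
  }
  k_ax <- kernel_mm[1]
  k_lat_spec <- kernel_mm[-1]
  s_ax <- search_mm[1]
  s_lat_spec <- search_mm[-1]

  kh_d_per_depth <- max(1L, round(k_ax / 2 / dz))
  lag_d <- max(1L, floor((s_ax - k_ax) / 2 / dz))
  # lateral sizes per node depth
  node_ij <- expand.grid(i = i_idx, j = j_idx)
  klat_mm <- lat_at(k_lat_spec, node_ij$i)
  kh_b <- pmax(1L, round(klat_mm / 2 / lat_spacing[node_ij$i]))
  slat_mm <- lat_at(s_lat_spec, node_ij$i)
  lag_b <- max(1L, floor(max((slat_mm - klat_mm) / 2 /
                               lat_spacing[node_ij$i])))

  if (is.null(seed)) {
    seed_d <- integer(nrow(node_ij)); seed_b <- integer(nrow(node_ij))
  } else {
    seed_d <- as.integer(round(as.vector(seed$u_samp_d)))
    seed_b <- as.integer(round(as.vector(seed$u_samp_b)))
    seed_d[is.na(seed_d)] <- 0L
    seed_b[is.na(seed_b)] <- 0L
  }

  res <- ncc_match_cpp(a, b, as.integer(node_ij$i - 1L),
                       as.integer(node_ij$j - 1L),
                       as.integer(rep(kh_d_per_depth, nrow(node_ij))),
                       as.integer(kh_b), as.integer(lag_d),
                       as.integer(lag_b), seed_d, seed_b, zero_mean)
  dims <- c(length(i_idx), length(j_idx))
  u_samp_d <- matrix(res[, 1], dims[1], dims[2])
  u_samp_b <- matrix(res[, 2], dims[1], dims[2])
  quality <- matrix(res[, 3], dims[1], dims[2])
  u_int_d <- matrix(res[, 4], dims[1], dims[2])
  u_int_b <- matrix(res[, 5], dims[1], dims[2])
  u_ax <- u_samp_d * dz
  u_lat <- u_samp_b * matrix(lat_spacing[node_ij$i], dims[1], dims[2])
  structure(list(u_ax = u_ax, u_lat = u_lat,
                 u_samp_d = u_samp_d, u_samp_b = u_samp_b,
                 u_int_d = u_int_d, u_int_b = u_int_b,
                 quality = quality, i_idx = i_idx, j_idx = j_idx,
                 grid = grid, pairing = ref$pairing,
                 T_tx = ref$T_tx, T_rx = ref$T_rx,
                 frame_pair = c(ref$frame_index, mov$frame_index),
                 mode = mode),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "displacement field %s (%s pass): %d x %d nodes, median |u_ax| %.4f mm\n",
    paste0("T", x$pairing[1], "R", x$pairing[2]), x$mode,
    length(x$i_idx), length(x$j_idx),
    median(abs(x$u_ax), na.rm = TRUE)))
  invisible(x)
}

#' Median filtering of a displacement field
#'
#' Component-wise 2-D median filter over the node lattice with reflected
#' edges; invalid (NA) nodes are skipped inside the window. The window is
#' given in mm and converted to an odd node count from the lattice
#' spacing.
#'
#' @param field a [block_match()] displacement field.
#' @param size_mm `c(axial, lateral)` window size, mm.
#' @return the filtered `displacement_field`.
#' @export
median_filter_field <- function(field, size_mm = c(0.6, 5.2)) {
  grid <- field$grid
  stride_d <- if (length(field$i_idx) > 1) diff(field$i_idx[1:2]) else 1
  stride_b <- if (length(field$j_idx) > 1) diff(field$j_idx[1:2]) else 1
  dz <- grid$axial_spacing * stride_d
  dbeta <- (grid$beam_angles[2] - grid$beam_angles[1]) * pi / 180
  dlat <- (grid$radius + mean(grid$depths)) * dbeta * stride_b
  hh <- max(0L, as.integer(round(size_mm[1] / 2 / dz)))
  hw <- max(0L, as.integer(round(size_mm[2] / 2 / dlat)))
  for (comp in c("u_ax", "u_lat", "u_samp_d", "u_samp_b"))
    field[[comp]] <- medfilt2_cpp(field[[comp]], hh, hw)
  field
}

#' Parabolic sub-sample peak interpolation
#'
#' Vertex offset of the parabola through three correlation samples at lags
#' -1, 0, +1, clamped to half a sample. Zero (or non-concave) curvature
#' returns 0.
#'
#' @param c_minus,c_0,c_plus correlation values; `c_0` must be the integer
#'   argmax.
#' @return fractional lag offset in [-0.5, 0.5].
#' @export
parabolic_subsample <- function(c_minus, c_0, c_plus) {
  if (c_0 < max(c_minus, c_plus))
    stop("c_0 must be the centered argmax", call. = FALSE)
  den <- c_minus - 2 * c_0 + c_plus
  if (den >= 0) return(0)
  max(-0.5, min(0.5, (c_minus - c_plus) / (2 * den)))
}

#' Coarse-to-fine tracking of one pairing
#'
#' The standard two-pass scheme: coarse displacements on the envelope with
#' a large kernel, median filtering, then fine displacements on the RF
#' (real part) with a small kernel seeded by the coarse estimates, and a
#' final median filter. Defaults follow kernel sizes tied to the wall
#' thickness (coarse covering the full wall, fine about half of it) and a
#' lateral extent matching the lateral resolution.
#'
#' @param ref,mov consecutive [beamformed_image]s on a sector grid.
#' @param i_idx,j_idx node lattice (see [block_match()]).
#' @param coarse_kernel,coarse_search,fine_kernel,fine_search sizes in mm.
#' @param median_size median filter window, mm.
#' @return the fine-pass `displacement_field` (median filtered), with the
#'   coarse field attached as `$coarse`.
#' @export
track_pairing <- function(ref, mov, i_idx = NULL, j_idx = NULL,
                          coarse_kernel = c(2.6, 4.5, 5.9),
                          coarse_search = c(3.0, 4.9, 6.5),
                          fine_kernel = c(0.8, 2.1, 2.7),
                          fine_search = c(1.0, 2.5, 3.2),
                          median_size = c(0.6, 5.2)) {
  coarse <- block_match(ref, mov, coarse_kernel, coarse_search,
                        mode = "envelope", i_idx = i_idx, j_idx = j_idx)
  coarse <- median_filter_field(coarse, median_size)
  fine <- block_match(ref, mov, fine_kernel, fine_search, mode = "rf",
                      i_idx = coarse$i_idx, j_idx = coarse$j_idx,
                      seed = coarse)
  fine <- median_filter_field(fine, median_size)
  fine$coarse <- coarse
  fine
}

#' Beam-to-radial angle at image positions
#'
#' The unsigned angle between the local beam (axial) direction and the
#' outward radial direction of the vessel, in degrees within [0, 180).
#' Positions at the vessel center are undefined (NA).
#'
#' @param points n x 2 positions, mm (probe-1 frame).
#' @param center vessel center, mm.
#' @param beam_dirs n x 2 unit beam directions at the points.
#' @return numeric vector of angles in degrees.
#' @export
compute_theta <- function(points, center, beam_dirs) {
  p <- if (is.null(dim(points))) matrix(points, 1, 2) else as.matrix(points)
  b <- if (is.null(dim(beam_dirs))) matrix(beam_dirs, 1, 2)
       else as.matrix(beam_dirs)
  rx <- p[, 1] - center[1]
  rz <- p[, 2] - center[2]
  rn <- sqrt(rx^2 + rz^2)
  d <- (b[, 1] * rx + b[, 2] * rz) / rn
  theta <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  theta[rn == 0] <- NA_real_
  theta
}

#' Angular compounding mask
#'
#' Cosine weighting of a displacement field by its beam-to-radial angle:
#' `M = cos(2 theta) / 2 + 1/2`, zeroed inside the cut-out band around 90
#' degrees where the radial projection diverges.
#'
#' @param theta angles in degrees (see [compute_theta()]).
#' @param cutout excluded angle band, degrees.
#' @return weights in [0, 1]; NA angles give weight 0.
#' @export
angular_mask <- function(theta, cutout = c(70, 110)) {
  m <- 0.5 * cos(2 * theta * pi / 180) + 0.5
  m[!is.na(theta) & theta >= cutout[1] & theta <= cutout[2]] <- 0
  m[is.na(theta)] <- 0
  m
}

#' Radial projection of axial displacement
#'
#' `u_rad = u_ax / cos(theta)`. Inside the cut-out band the projection
#' diverges and the value is excluded (NA; such nodes carry zero
#' compounding weight and are never evaluated downstream).
#'
#' @param u_ax axial displacement, mm.
#' @param theta beam-to-radial angle, degrees.
#' @param cutout excluded band, degrees.
#' @return radial displacement, mm (positive outward).
#' @export
radial_project <- function(u_ax, theta, cutout = c(70, 110)) {
  out <- u_ax / cos(theta * pi / 180)
  out[is.na(theta) | (theta >= cutout[1] & theta <= cutout[2])] <- NA_real_
  out
}

#' Angular displacement compounding of the four pairings
#'
#' Weighted per-node fusion of the radially projected displacement fields:
#' the two monostatic fields carry their full mask weight, the two
#' trans-probe fields (similar information by reciprocity) carry half,
#' and the active weights are normalized to sum to one at every node so
#' the output remains displacement-valued. Nodes where every weight is
#' zero (or every field invalid) are invalid.
#'
#' @param u_rad_list list of four radial displacement arrays (T1R1, T2R2,
#'   T1R2, T2R1), identical shape, NA where invalid.
#' @param mask_list list of four angular-mask arrays (same shape).
#' @param reciprocity_weights relative contribution of the four fields
#'   before normalization.
#' @return list with `u_rad` (compounded, NA where no contribution),
#'   `weight_sum` (pre-normalization active weight), `n_active`.
#' @export
compound_displacements <- function(u_rad_list, mask_list,
                                   reciprocity_weights = c(1, 1, 0.5, 0.5)) {
  stopifnot(length(u_rad_list) == 4, length(mask_list) == 4)
  dims <- dim(as.array(u_rad_list[[1]]))
  num <- array(0, dims %||% length(u_rad_list[[1]]))
  wsum <- num
  n_act <- num
  for (k in 1:4) {
    u <- u_rad_list[[k]]
    w <- mask_list[[k]] * reciprocity_weights[k]
    ok <- !is.na(u) & w > 0
    num[ok] <- num[ok] + w[ok] * u[ok]
    wsum[ok] <- wsum[ok] + w[ok]
    n_act[ok] <- n_act[ok] + 1
  }
  u <- num / wsum
  u[wsum == 0] <- NA_real_
  list(u_rad = u, weight_sum = wsum, n_active = n_act)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective beam direction of a pairing at given positions
#'
#' For the monostatic pairings the axial direction is the receive beam
#' direction (from the receiving probe's arc center through the point).
#' For the trans-probe pairings a bistatic echo is specular normal to the
#' bisector of the transmit and receive directions, so the mask and the
#' projection use the bisector.
#'
#' @param points n x 2 positions in the probe-1 frame, mm.
#' @param geom_tx,geom_rx probe geometries.
#' @param T_tx,T_rx probe transforms.
#' @return list with `dir` (n x 2 unit vectors), `gamma` (tx/rx
#'   inter-direction angle per point, degrees; 0 for monostatic).
#' @export
pairing_beam_direction <- function(points, geom_tx, geom_rx,
                                   T_tx = rigid_transform(),
                                   T_rx = rigid_transform()) {
  p <- if (is.null(dim(points))) matrix(points, 1, 2) else as.matrix(points)
  ctr_rx <- apply_transform(T_rx, geom_rx$arc_center)
  ctr_tx <- apply_transform(T_tx, geom_tx$arc_center)
  unitize <- function(v) v / sqrt(rowSums(v^2))
  d_rx <- unitize(cbind(p[, 1] - ctr_rx[1], p[, 2] - ctr_rx[2]))
  if (isTRUE(all.equal(ctr_tx, ctr_rx))) {
    return(list(dir = d_rx, gamma = rep(0, nrow(p))))
  }
  d_tx <- unitize(cbind(p[, 1] - ctr_tx[1], p[, 2] - ctr_tx[2]))
  bis <- unitize(d_tx + d_rx)
  cg <- pmin(1, pmax(-1, rowSums(d_tx * d_rx)))
  list(dir = bis, gamma = acos(cg) * 180 / pi)
}

bilinear_na <- function(mat, fi, fj) {
  # NA-propagating bilinear interpolation at fractional 1-based indices
  nr <- nrow(mat); nc <- ncol(mat)
  i0 <- floor(fi); j0 <- floor(fj)
  out <- rep(NA_real_, length(fi))
  ok <- !is.na(fi) & !is.na(fj) & i0 >= 1 & i0 <= nr - 1 & j0 >= 1 &
    j0 <= nc - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]
  wi <- fi[ok] - i0; wj <- fj[ok] - j0
  v00 <- mat[cbind(i0, j0)]
  v10 <- mat[cbind(i0 + 1, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]
  v11 <- mat[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - wi) * (1 - wj) + v10 * wi * (1 - wj) +
    v01 * (1 - wi) * wj + v11 * wi * wj
  out
}

#' Sample a displacement field at arbitrary positions
#'
#' Bilinear interpolation of the tracked axial displacement (and quality)
#' of a field at positions given in the probe-1 frame.
#'
#' @param field a [block_match()] field.
#' @param points n x 2 positions, mm, probe-1 frame.
#' @param T_rx transform of the receiving probe (maps its local frame to
#'   the probe-1 frame); defaults to the identity.
#' @return list with `u_ax` (mm) and `quality` per point (NA outside
#'   coverage).
#' @export
sample_field <- function(field, points, T_rx = rigid_transform()) {
  p_loc <- apply_transform(invert_transform(T_rx), points)
  idx <- sector_index(field$grid, p_loc)
  stride_d <- if (length(field$i_idx) > 1) diff(field$i_idx[1:2]) else 1
  stride_b <- if (length(field$j_idx) > 1) diff(field$j_idx[1:2]) else 1
  fi <- (idx[, 1] - field$i_idx[1]) / stride_d + 1
  fj <- (idx[, 2] - field$j_idx[1]) / stride_b + 1
  list(u_ax = bilinear_na(field$u_ax, fi, fj),
       quality = bilinear_na(field$quality, fi, fj))
}

#' Radial displacement and mask of one pairing at given positions
#'
#' Combines field sampling, the pairing's effective beam direction, the
#' bistatic range conversion for trans-probe fields (tracked axial shifts
#' in a bistatic image correspond to a geometric displacement scaled by
#' cos(gamma/2), where gamma is the angle between the transmit and receive
#' directions), the radial projection, and the angular mask.
#'
#' @param field a tracked `displacement_field`.
#' @param points n x 2 positions (probe-1 frame), mm.
#' @param center vessel center, mm.
#' @param geom_tx,geom_rx,T_tx,T_rx pairing geometry.
#' @param cutout angular cut-out band, degrees.
#' @return list with `u_rad`, `M`, `theta`, `quality` per point.
#' @export
sample_u_rad <- function(field, points, center, geom_tx, geom_rx,
                         T_tx = rigid_transform(), T_rx = rigid_transform(),
                         cutout = c(70, 110)) {
  bd <- pairing_beam_direction(points, geom_tx, geom_rx, T_tx, T_rx)
  theta <- compute_theta(points, center, bd$dir)
  s <- sample_field(field, points, T_rx)
  u_geom <- s$u_ax * cos(bd$gamma / 2 * pi / 180)
  u_rad <- radial_project(u_geom, theta, cutout)
  list(u_rad = u_rad, M = angular_mask(theta, cutout), theta = theta,
       quality = s$quality)
}
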