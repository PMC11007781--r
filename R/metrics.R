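#' Generalized contrast-to-noise ratio
#'
#' Robust contrast between two regions: one minus the overlap of their
#' envelope-amplitude probability densities, estimated by histograms over
#' the pooled amplitude range. Bounded in [0, 1]; invariant to monotone
#' amplitude mappings applied to both regions up to binning.
#'
#' @param envelope matrix (or vector) of envelope-detected amplitudes.
#' @param roi_a,roi_b logical masks (or index vectors) of the two regions.
#' @param n_bins histogram bins over the pooled range.
#' @return scalar gCNR.
#' @export
gcnr <- function(envelope, roi_a, roi_b, n_bins = 256) {
  a <- envelope[roi_a]
  b <- envelope[roi_b]
  if (length(a) == 0 || length(b) == 0)
    stop("empty ROI in gCNR computation", call. = FALSE)
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ha <- tabulate(pmin(n_bins, findInterval(a, brk, rightmost.closed = TRUE)),
                 n_bins) / length(a)
  hb <- tabulate(pmin(n_bins, findInterval(b, brk, rightmost.closed = TRUE)),
                 n_bins) / length(b)
  1 - sum(pmin(ha, hb))
}

#' Wall and lumen masks from a mesh on a Cartesian grid
#'
#' The wall ROI is the annulus between the inner and outer mesh contours;
#' the lumen ROI is the region inside the inner contour, eroded by a
#' disk-shaped structuring element so specular reflections from the wall
#' itself are excluded.
#'
#' @param mesh a [build_wall_mesh()] mesh.
#' @param grid a [cartesian_grid()] (matching an image laid out z by x).
#' @param erosion_radius lumen erosion radius, mm.
#' @return list with logical matrices `wall` and `lumen` (nz x nx).
#' @export
make_rois <- function(mesh, grid, erosion_radius = 0.6) {
  pts <- grid_points(grid)              # (x, z), z fastest
  inner <- mesh$nodes[1, , ]
  outer <- mesh$nodes[mesh$n_layers, , ]
  dims <- c(length(grid$z), length(grid$x))
  in_inner <- pracma::inpolygon(pts[, 1], pts[, 2], inner[, 1], inner[, 2])
  in_outer <- pracma::inpolygon(pts[, 1], pts[, 2], outer[, 1], outer[, 2])
  wall <- matrix(in_outer & !in_inner, dims[1], dims[2])
  lumen <- matrix(in_inner, dims[1], dims[2])
  r_px <- erosion_radius / mean(grid$spacing)
  if (r_px >= 0.5) {
    brush <- EBImage::makeBrush(2 * floor(r_px) + 1, shape = "disc")
    lumen <- EBImage::erode(lumen * 1, brush) > 0.5
  }
  if (!any(lumen))
    stop("erosion emptied the lumen ROI", call. = FALSE)
  list(wall = wall, lumen = lumen)
}

#' Partition wall-mesh nodes into eight 45-degree regions
#'
#' Regions 1 and 5 are centered on the anchor direction (the beam
#' direction of the right transducer through the vessel center) and its
#' opposite; the remaining regions follow clockwise (screen sense, x
#' right, z down).
#'
#' @param mesh a [build_wall_mesh()] mesh (or any object with nodes and
#'   center); alternatively an n x 2 point matrix via `points`.
#' @param anchor unit direction of the right transducer's beam at the
#'   vessel center (probe-1 frame).
#' @param points optional n x 2 matrix overriding the mesh middle layer.
#' @return integer region index (1..8) per node/point.
#' @export
partition_regions <- function(mesh, anchor = c(0, 1), points = NULL) {
  if (is.null(points)) points <- mesh_middle_layer(mesh)
  center <- mesh$center
  v <- cbind(points[, 1] - center[1], points[, 2] - center[2])
  ang0 <- atan2(anchor[1], -anchor[2])
  psi <- atan2(v[, 1], -v[, 2]) - ang0    # clockwise angle from anchor
  psi <- (psi * 180 / pi) %% 360
  as.integer(floor(((psi + 22.5) %% 360) / 45)) + 1L
}

#' Mask of wall nodes outside the excluded lateral sections
#'
#' Strain statistics leave out a small angular section at the left and
#' right wall (perpendicular to the anchor direction), where neither
#' aperture adds sufficient signal.
#'
#' @param mesh a [build_wall_mesh()] mesh.
#' @param width_deg full width of each excluded section, degrees.
#' @param anchor right-transducer beam direction (probe-1 frame).
#' @param points optional n x 2 matrix overriding the mesh middle layer.
#' @return logical vector, TRUE for nodes kept in the analysis.
#' @export
exclude_lateral_sections <- function(mesh, width_deg = 37.5,
                                     anchor = c(0, 1), points = NULL) {
  if (is.null(points)) points <- mesh_middle_layer(mesh)
  if (width_deg <= 0) return(rep(TRUE, nrow(points)))
  center <- mesh$center
  v <- cbind(points[, 1] - center[1], points[, 2] - center[2])
  ang0 <- atan2(anchor[1], -anchor[2])
  psi <- ((atan2(v[, 1], -v[, 2]) - ang0) * 180 / pi) %% 360
  d90 <- pmin(abs(psi - 90), abs(psi - 270))
  d90 > width_deg / 2
}

#' Mean drift error between two meshes
#'
#' Mean Euclidean distance between corresponding middle-layer nodes of the
#' wall mesh at the first and second end-diastolic frames; an ideal
#' tracker returns the wall to its starting position after one full
#' cardiac cycle.
#'
#' @param mesh_bs,mesh_ed meshes at begin systole (first end-diastole) and
#'   second end-diastole.
#' @return mean drift in mm.
#' @export
mean_drift_error <- function(mesh_bs, mesh_ed) {
  a <- mesh_middle_layer(mesh_bs)
  b <- mesh_middle_layer(mesh_ed)
  if (nrow(a) != nrow(b))
    stop("meshes have different node counts", call. = FALSE)
  mean(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

#' Frames of minimal inner radius (end-diastole)
#'
#' Selects the first and last local frames of minimal mean inner-mesh
#' radius, the analogue of reading the end-diastolic frames from an
#' M-mode.
#' @param mesh_seq list of tracked meshes.
#' @return integer vector c(first, last).
#' @export
end_diastole_frames <- function(mesh_seq) {
  r <- vapply(mesh_seq, function(m) {
    inner <- m$nodes[1, , ]
    mean(sqrt((inner[, 1] - m$center[1])^2 + (inner[, 2] - m$center[2])^2))
  }, numeric(1))
  half <- length(r) %/% 2
  c(which.min(r[seq_len(half)]),
    half + which.min(r[(half + 1):length(r)]))
}

#' Elastographic signal-to-noise ratio
#'
#' `20 log10(|mean| / sd)` of the strain values in a region. The absolute
#' mean is used so compressive (negative) strains report positive dB for
#' equally precise estimates.
#'
#' @param strain numeric strain values (NA dropped).
#' @return SNRe in dB; `Inf` (with a warning) for zero variance.
#' @export
snre <- function(strain) {
  s <- strain[!is.na(strain)]
  if (length(s) < 2) stop("need at least 2 strain values", call. = FALSE)
  sdev <- sd(s)
  if (sdev == 0) {
    warning("zero strain variance; SNRe is infinite")
    return(Inf)
  }
  20 * log10(abs(mean(s)) / sdev)
}

#' Paired comparison of a metric between two imaging modes
#'
#' Tests the paired differences for normality (Shapiro-Wilk at 0.05) and
#' applies a paired t-test when normality is not rejected, a paired
#' Wilcoxon signed-rank test otherwise.
#'
#' @param a,b equal-length paired metric values.
#' @param alpha significance level of the normality check.
#' @return list with `test` ("paired t-test", "wilcoxon signed-rank" or
#'   "degenerate"), `statistic`, `p_value`, `normality_p`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need equal-length paired samples, n >= 3", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(test = "degenerate", statistic = 0, p_value = 1,
                normality_p = NA_real_))
  np <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  if (!is.na(np) && np < alpha) {
    w <- wilcox.test(a, b, paired = TRUE, exact = FALSE)
    list(test = "wilcoxon signed-rank", statistic = unname(w$statistic),
         p_value = w$p.value, normality_p = np)
  } else {
    t <- t.test(a, b, paired = TRUE)
    list(test = "paired t-test", statistic = unname(t$statistic),
         p_value = t$p.value, normality_p = np)
  }
}
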