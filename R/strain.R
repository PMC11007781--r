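#' Vessel-wall mesh from an inner-contour segmentation
#'
#' Builds a radial x circumferential node lattice of the wall: the inner
#' (lumen-wall) contour is ordered clockwise starting from the anterior
#' point, and the outer layers are offset along the local outward normal
#' assuming a uniform wall thickness.
#'
#' @param inner_points n x 2 points (mm) on the lumen-wall border, any
#'   order, n >= 8, forming a simple closed contour.
#' @param thickness wall thickness, mm.
#' @param n_layers number of radial layers (inner .. outer).
#' @param center vessel center; default the contour centroid.
#' @return an object of class `wall_mesh`: `nodes` (array n_layers x n x
#'   2), `n_layers`, `n_circ`, `thickness`, `center`,
#'   `middle_layer_index` (NA when `n_layers` is even; see
#'   [mesh_middle_layer()]), `frame_index`.
#' @export
build_wall_mesh <- function(inner_points, thickness = 1.7, n_layers = 5,
                            center = NULL) {
  p <- as.matrix(inner_points)
  if (nrow(p) < 8) stop("need at least 8 inner contour points", call. = FALSE)
  if (thickness <= 0 || n_layers < 2)
    stop("thickness must be positive and n_layers >= 2", call. = FALSE)
  if (is.null(center)) center <- colMeans(p)
  # clockwise ordering (screen sense: x right, z down) from the anterior
  # (topmost) direction
  psi <- atan2(p[, 1] - center[1], -(p[, 2] - center[2])) %% (2 * pi)
  ord <- order(psi)
  p <- p[ord, , drop = FALSE]
  n <- nrow(p)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  tang <- p[nxt, ] - p[prv, ]
  nrm <- cbind(-tang[, 2], tang[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  flip <- rowSums(nrm * (p - matrix(center, n, 2, byrow = TRUE))) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nodes <- array(NA_real_, c(n_layers, n, 2))
  for (l in seq_len(n_layers)) {
    off <- (l - 1) / (n_layers - 1) * thickness
    nodes[l, , ] <- p + off * nrm
  }
  # reject self-intersecting offsets (thickness beyond the local radius of
  # curvature folds the outer contour back on itself)
  outer_seg <- nodes[n_layers, nxt, , drop = FALSE] - nodes[n_layers, , , drop = FALSE]
  inner_seg <- p[nxt, ] - p
  if (any(rowSums(matrix(outer_seg, n, 2) * inner_seg) <= 0))
    stop("outer offset self-intersects: thickness exceeds the local radius ",
         "of curvature", call. = FALSE)
  structure(list(nodes = nodes, n_layers = n_layers, n_circ = n,
                 thickness = thickness, center = center,
                 middle_layer_index = if (n_layers %% 2 == 1)
                   (n_layers + 1) / 2 else NA_integer_,
                 frame_index = 1L),
            class = "wall_mesh")
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat(sprintf("wall mesh: %d radial layers x %d circumferential nodes, thickness %.2f mm\n",
              x$n_layers, x$n_circ, x$thickness))
  invisible(x)
}

#' Middle-layer node positions of a wall mesh
#'
#' The mid-wall layer used for drift-error and strain summaries: the
#' central radial layer for an odd layer count, the midpoint of the two
#' central layers otherwise.
#' @param mesh a [build_wall_mesh()] mesh.
#' @return n x 2 matrix of positions, mm.
#' @export
mesh_middle_layer <- function(mesh) {
  L <- mesh$n_layers
  if (L %% 2 == 1) return(mesh$nodes[(L + 1) / 2, , ])
  (mesh$nodes[L / 2, , ] + mesh$nodes[L / 2 + 1, , ]) / 2
}

#' Track a wall mesh through frame-to-frame displacement fields
#'
#' Eulerian accumulation: the node position at frame k+1 is its position
#' at frame k plus the displacement sampled at that position from the
#' k -> k+1 field. Nodes leaving field coverage are flagged and carried by
#' their last valid displacement.
#'
#' @param mesh0 the reference-frame [build_wall_mesh()] mesh.
#' @param samplers list of displacement samplers, one per frame pair; each
#'   is a function taking an n x 2 position matrix (probe-1 frame, mm) and
#'   returning an n x 2 displacement matrix (mm), NA rows where the field
#'   has no coverage.
#' @return list of `wall_mesh` objects, frames 1 .. length(samplers) + 1;
#'   each carries an `n_flagged` count of coverage drop-outs.
#' @export
track_mesh <- function(mesh0, samplers) {
  meshes <- vector("list", length(samplers) + 1)
  meshes[[1]] <- mesh0
  dims <- dim(mesh0$nodes)
  pts <- matrix(mesh0$nodes, dims[1] * dims[2], 2)
  last_disp <- matrix(0, nrow(pts), 2)
  for (k in seq_along(samplers)) {
    d <- samplers[[k]](pts)
    bad <- is.na(d[, 1]) | is.na(d[, 2])
    d[bad, ] <- last_disp[bad, , drop = FALSE]
    last_disp <- d
    pts <- pts + d
    m <- meshes[[k]]
    m$nodes <- array(pts, dims)
    m$frame_index <- k + 1L
    m$n_flagged <- sum(bad)
    meshes[[k + 1]] <- m
  }
  meshes
}

#' Radial displacement sampler for mesh tracking
#'
#' Builds the per-frame-pair displacement sampler used in bistatic mode:
#' the compounded radial displacement (angular-mask-weighted fusion of the
#' four pairings) applied along the fixed radial direction from the
#' reference vessel center.
#'
#' @param fields list of four tracked `displacement_field`s (T1R1, T2R2,
#'   T1R2, T2R1) for one frame pair.
#' @param center vessel center (reference frame), mm.
#' @param geoms list with `geom1`, `geom2`.
#' @param T2 probe-2 transform used for reconstruction.
#' @param cutout angular cut-out band, degrees.
#' @return a sampler function (points -> displacements) for [track_mesh()].
#' @export
compound_sampler <- function(fields, center, geoms, T2,
                             cutout = c(70, 110)) {
  id <- rigid_transform()
  pairing_defs <- list(list(geoms$geom1, geoms$geom1, id, id),
                       list(geoms$geom2, geoms$geom2, T2, T2),
                       list(geoms$geom1, geoms$geom2, id, T2),
                       list(geoms$geom2, geoms$geom1, T2, id))
  function(points) {
    u_list <- vector("list", 4)
    m_list <- vector("list", 4)
    for (k in 1:4) {
      s <- sample_u_rad(fields[[k]], points, center,
                        pairing_defs[[k]][[1]], pairing_defs[[k]][[2]],
                        pairing_defs[[k]][[3]], pairing_defs[[k]][[4]],
                        cutout)
      u_list[[k]] <- s$u_rad
      m_list[[k]] <- s$M
    }
    cmp <- compound_displacements(u_list, m_list)
    rhat <- cbind(points[, 1] - center[1], points[, 2] - center[2])
    rhat <- rhat / sqrt(rowSums(rhat^2))
    cbind(cmp$u_rad * rhat[, 1], cmp$u_rad * rhat[, 2])
  }
}

#' Single-perspective displacement sampler
#'
#' Comparison mode using only the single-probe pairing: the raw axial and
#' lateral displacement estimates of that field, applied along the beam
#' and lateral directions, without radial projection or compounding.
#'
#' @param field the tracked T1R1 `displacement_field`.
#' @param geom the probe geometry.
#' @param T_rx probe transform (identity for probe 1).
#' @return a sampler function for [track_mesh()].
#' @export
single_perspective_sampler <- function(field, geom, T_rx = rigid_transform()) {
  function(points) {
    ctr <- apply_transform(T_rx, geom$arc_center)
    b <- cbind(points[, 1] - ctr[1], points[, 2] - ctr[2])
    b <- b / sqrt(rowSums(b^2))
    lat <- cbind(b[, 2], -b[, 1])          # in-plane perpendicular
    s <- sample_field(field, points, T_rx)
    p_loc <- apply_transform(invert_transform(T_rx), points)
    idx <- sector_index(field$grid, p_loc)
    stride_d <- if (length(field$i_idx) > 1) diff(field$i_idx[1:2]) else 1
    stride_b <- if (length(field$j_idx) > 1) diff(field$j_idx[1:2]) else 1
    fi <- (idx[, 1] - field$i_idx[1]) / stride_d + 1
    fj <- (idx[, 2] - field$j_idx[1]) / stride_b + 1
    u_lat <- bilinear_na(field$u_lat, fi, fj)
    cbind(s$u_ax * b[, 1] + u_lat * lat[, 1],
          s$u_ax * b[, 2] + u_lat * lat[, 2])
  }
}

#' 2-D least-squares strain estimation on a tracked mesh
#'
#' Node displacements relative to the reference frame are regressed
#' linearly on the local radial/circumferential coordinates over a kernel
#' of mesh nodes (default 5 radial x 5 circumferential); the radial and
#' circumferential normal strains are the fitted displacement gradients.
#' The local directions and the vessel midpoint are fixed from the
#' reference-frame geometry. The kernel shrinks at the inner/outer layer
#' edges; the circumferential direction wraps around the closed contour.
#'
#' @param mesh_seq list of [track_mesh()] meshes (frame 1 = reference by
#'   default).
#' @param reference reference frame index.
#' @param kernel `c(radial, circumferential)` node counts (odd).
#' @return list of `strain_field` objects with `eps_rad`, `eps_circ`
#'   (n_layers x n_circ matrices), `frame_index`, `reference`.
#' @export
least_squares_strain <- function(mesh_seq, reference = 1, kernel = c(5, 5)) {
  ref <- mesh_seq[[reference]]
  L <- ref$n_layers; n <- ref$n_circ
  hr <- (kernel[1] - 1) %/% 2
  hc <- (kernel[2] - 1) %/% 2
  center <- ref$center
  # fixed reference-frame local directions per node
  rhat <- array(NA_real_, c(L, n, 2))
  chat <- array(NA_real_, c(L, n, 2))
  for (l in seq_len(L)) {
    pl <- ref$nodes[l, , ]
    r <- cbind(pl[, 1] - center[1], pl[, 2] - center[2])
    r <- r / sqrt(rowSums(r^2))
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    t <- pl[nxt, ] - pl[prv, ]
    t <- t / sqrt(rowSums(t^2))
    rhat[l, , ] <- r
    chat[l, , ] <- t
  }
  lapply(seq_along(mesh_seq), function(f) {
    cur <- mesh_seq[[f]]
    disp <- cur$nodes - ref$nodes
    eps_r <- matrix(NA_real_, L, n)
    eps_c <- matrix(NA_real_, L, n)
    for (l in seq_len(L)) {
      ll <- max(1, l - hr):min(L, l + hr)
      for (m in seq_len(n)) {
        mm <- ((m - hc):(m + hc) - 1) %% n + 1
        p0 <- ref$nodes[l, m, ]
        r0 <- rhat[l, m, ]; c0 <- chat[l, m, ]
        pk <- matrix(ref$nodes[ll, mm, ], length(ll) * length(mm), 2)
        dk <- matrix(disp[ll, mm, ], length(ll) * length(mm), 2)
        rho <- (pk[, 1] - p0[1]) * r0[1] + (pk[, 2] - p0[2]) * r0[2]
        sig <- (pk[, 1] - p0[1]) * c0[1] + (pk[, 2] - p0[2]) * c0[2]
        dr <- dk[, 1] * r0[1] + dk[, 2] * r0[2]
        dc <- dk[, 1] * c0[1] + dk[, 2] * c0[2]
        X <- cbind(1, rho, sig)
        fit <- tryCatch(qr.coef(qr(X), cbind(dr, dc)),
                        error = function(e) NULL)
        if (is.null(fit) || anyNA(fit)) next
        eps_r[l, m] <- fit[2, 1]
        eps_c[l, m] <- fit[3, 2]
      }
    }
    structure(list(eps_rad = eps_r, eps_circ = eps_c,
                   frame_index = cur$frame_index, reference = reference),
              class = "strain_field")
  })
}
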