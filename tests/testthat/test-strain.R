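circle_points <- function(n, r, center = c(0, 40)) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * sin(a), center[2] - r * cos(a))
}

test_that("wall meshes offset the inner contour by the wall thickness", {
  inner <- circle_points(64, 10)
  mesh <- build_wall_mesh(inner, thickness = 1.7, n_layers = 5)
  outer <- mesh$nodes[5, , ]
  r_out <- sqrt((outer[, 1] - mesh$center[1])^2 +
                (outer[, 2] - mesh$center[2])^2)
  expect_true(all(abs(r_out - 11.7) < 1e-6))
  mid <- mesh_middle_layer(mesh)
  r_mid <- sqrt((mid[, 1] - mesh$center[1])^2 + (mid[, 2] - mesh$center[2])^2)
  expect_true(all(abs(r_mid - 10.85) < 1e-6))

  # two layers: inner and outer only; middle layer is their midpoint
  m2 <- build_wall_mesh(inner, 1.7, n_layers = 2)
  expect_equal(m2$n_layers, 2)
  expect_equal(mesh_middle_layer(m2),
               (m2$nodes[1, , ] + m2$nodes[2, , ]) / 2)

  # ellipse: offset verified against a dense normal-offset oracle
  a <- seq(0, 2 * pi, length.out = 49)[-49]
  ell <- cbind(12 * sin(a), 40 - 8 * cos(a))
  me <- build_wall_mesh(ell, thickness = 1.5, n_layers = 3)
  # dense oracle: distance from each outer node back to the inner contour
  # polyline must equal the thickness
  dense_a <- seq(0, 2 * pi, length.out = 4000)
  dense <- cbind(12 * sin(dense_a), 40 - 8 * cos(dense_a))
  for (k in seq(1, 48, by = 6)) {
    d <- min(sqrt((dense[, 1] - me$nodes[3, k, 1])^2 +
                  (dense[, 2] - me$nodes[3, k, 2])^2))
    expect_equal(d, 1.5, tolerance = 0.02)
  }
  expect_error(build_wall_mesh(inner[1:5, ]), "at least 8")
  # a concave contour whose local curvature radius is below the offset
  # thickness folds the outer contour
  aa <- seq(0, 2 * pi, length.out = 61)[-61]
  rr <- 8 + 2.5 * cos(3 * aa)
  wavy <- cbind(rr * sin(aa), 40 - rr * cos(aa))
  expect_error(build_wall_mesh(wavy, thickness = 6), "self-intersect")
  expect_silent(build_wall_mesh(wavy, thickness = 0.8))
})

test_that("mesh ordering is clockwise from the anterior point", {
  set.seed(3)
  inner <- circle_points(32, 9)[sample(32), ]   # scrambled input
  mesh <- build_wall_mesh(inner, 1.7, 3)
  p <- mesh$nodes[1, , ]
  # first node at the top (anterior), then x increases (clockwise on
  # screen with z pointing down)
  expect_equal(p[1, 2], mesh$center[2] - 9, tolerance = 1e-9)
  expect_gt(p[2, 1], p[1, 1])
})

test_that("mesh tracking accumulates sampled displacements", {
  inner <- circle_points(48, 10)
  mesh <- build_wall_mesh(inner, 1.7, 5)
  zero <- function(p) matrix(0, nrow(p), 2)
  ms <- track_mesh(mesh, list(zero, zero))
  expect_equal(ms[[3]]$nodes, mesh$nodes)

  # uniform outward radial step of 0.1 mm for 5 frames grows radius 0.5 mm
  ctr <- mesh$center
  radial <- function(p) {
    r <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2])
    0.1 * r / sqrt(rowSums(r^2))
  }
  ms5 <- track_mesh(mesh, rep(list(radial), 5))
  r_end <- sqrt((ms5[[6]]$nodes[1, , 1] - ctr[1])^2 +
                (ms5[[6]]$nodes[1, , 2] - ctr[2])^2)
  expect_true(all(abs(r_end - 10.5) < 1e-9))

  # NA coverage: node carried by the last valid displacement and flagged
  once <- function(p) { d <- radial(p); d[1, ] <- NA; d }
  msna <- track_mesh(mesh, list(radial, once))
  expect_equal(msna[[3]]$n_flagged, 1)
  expect_equal(msna[[3]]$nodes[1, 1, ], ms5[[3]]$nodes[1, 1, ])
})

test_that("mesh tracked with analytic fields follows the true trajectories", {
  model <- pulsation_model(10, 1.7, n_frames = 6, excursion = 0.02)
  ctr <- c(0, 40)
  inner <- circle_points(60, 10, ctr)
  mesh <- build_wall_mesh(inner, 1.7, 5, center = ctr)
  truth_disp <- function(k) {            # frame k -> k+1 incompressible map
    ri0 <- 10
    function(p) {
      r <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
      rk <- model$radius_waveform[k]
      rk1 <- model$radius_waveform[k + 1]
      # invert the map to rest radius, then advance one frame
      r0 <- sqrt(pmax(r^2 - rk^2 + ri0^2, 1e-9))
      r_new <- sqrt(r0^2 + rk1^2 - ri0^2)
      u <- r_new - r
      rr <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2]) / r
      cbind(u * rr[, 1], u * rr[, 2])
    }
  }
  ms <- track_mesh(mesh, lapply(1:5, truth_disp))
  for (k in 1:6) {
    mid <- mesh_middle_layer(ms[[k]])
    r_mid <- sqrt((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2)
    want <- sqrt(10.85^2 + model$radius_waveform[k]^2 - 100)
    expect_lt(max(abs(r_mid - want)), 0.05)
  }
  # closed cycle: zero drift with perfect fields
  expect_lt(mean_drift_error(ms[[1]], ms[[6]]), 1e-9)

  # analytic strain oracle at peak dilation (frame 4)
  st <- least_squares_strain(ms, reference = 1)
  # reference strain is identically zero
  expect_lt(max(abs(st[[1]]$eps_circ), na.rm = TRUE), 1e-12)
  rk <- model$radius_waveform[4]
  mid_r0 <- 10.85
  want_ec <- sqrt(mid_r0^2 + rk^2 - 100) / mid_r0 - 1
  mid_l <- 3
  expect_lt(max(abs(st[[4]]$eps_circ[mid_l, ] - want_ec)), 5e-4)
  want_er <- mid_r0 / sqrt(mid_r0^2 + rk^2 - 100) - 1
  expect_lt(max(abs(st[[4]]$eps_rad[mid_l, ] - want_er)), 2e-3)
})

test_that("least-squares strain is exact for affine deformations", {
  ctr <- c(0, 40)
  mesh <- build_wall_mesh(circle_points(50, 10, ctr), 1.7, 5, center = ctr)
  shift <- function(dx, dz) {
    m <- mesh
    m$nodes[, , 1] <- m$nodes[, , 1] + dx
    m$nodes[, , 2] <- m$nodes[, , 2] + dz
    m$frame_index <- 2L
    m
  }
  st <- least_squares_strain(list(mesh, shift(3, -4)))
  expect_lt(max(abs(st[[2]]$eps_rad), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st[[2]]$eps_circ), na.rm = TRUE), 1e-9)

  dil <- mesh
  dil$nodes[, , 1] <- ctr[1] + 1.01 * (mesh$nodes[, , 1] - ctr[1])
  dil$nodes[, , 2] <- ctr[2] + 1.01 * (mesh$nodes[, , 2] - ctr[2])
  std <- least_squares_strain(list(mesh, dil))
  expect_lt(max(abs(std[[2]]$eps_circ - 0.01)), 1e-6)
  expect_lt(max(abs(std[[2]]$eps_rad - 0.01)), 1e-6)

  # general affine map recovered to numerical precision
  A <- matrix(c(1.02, 0.006, -0.004, 0.99), 2, 2)
  aff <- mesh
  rel <- cbind(as.vector(mesh$nodes[, , 1]) - ctr[1],
               as.vector(mesh$nodes[, , 2]) - ctr[2])
  new <- rel %*% t(A)
  aff$nodes[, , 1] <- new[, 1] + ctr[1] + 0.3
  aff$nodes[, , 2] <- new[, 2] + ctr[2] - 0.2
  sta <- least_squares_strain(list(mesh, aff))
  # expected normal strains from the displacement gradient in the local
  # frame of each node
  G <- A - diag(2)
  for (m in seq(1, 50, by = 7)) {
    p <- mesh$nodes[3, m, ]
    r <- (p - ctr) / sqrt(sum((p - ctr)^2))
    nxt <- mesh$nodes[3, m %% 50 + 1, ]
    prv <- mesh$nodes[3, (m - 2) %% 50 + 1, ]
    tv <- nxt - prv; tv <- tv / sqrt(sum(tv^2))
    expect_equal(sta[[2]]$eps_rad[3, m], drop(r %*% G %*% r),
                 tolerance = 1e-9)
    expect_equal(sta[[2]]$eps_circ[3, m], drop(tv %*% G %*% tv),
                 tolerance = 1e-9)
  }
})
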