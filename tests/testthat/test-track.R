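test_that("parabolic sub-sample interpolation is exact on parabolas", {
  expect_equal(parabolic_subsample(0.5, 1.0, 0.5), 0)
  expect_equal(parabolic_subsample(0.4, 1.0, 0.8), 0.25)
  set.seed(4)
  for (rep in 1:20) {
    v <- runif(1, -0.49, 0.49)          # true vertex
    a <- -runif(1, 0.5, 3)              # concavity
    f <- function(x) 1 + a * (x - v)^2
    expect_equal(parabolic_subsample(f(-1), f(0), f(1)), v,
                 tolerance = 1e-12)
  }
  # zero curvature
  expect_equal(parabolic_subsample(1, 1, 1), 0)
  expect_error(parabolic_subsample(1, 0.5, 0.2), "argmax")
})

test_that("block matching recovers known integer and fractional shifts", {
  grid <- toy_sector_grid(220, 40)
  ref <- toy_speckle_image(grid, seed = 6)
  kernel <- c(0.8, 2.4)
  search <- c(1.6, 3.6)

  # self match: zero displacement, quality 1
  f0 <- block_match(ref, ref, kernel, search, mode = "rf",
                    i_idx = seq(30, 190, by = 8), j_idx = seq(6, 34, by = 2))
  expect_equal(max(abs(f0$u_int_d), na.rm = TRUE), 0)
  expect_equal(max(abs(f0$u_int_b), na.rm = TRUE), 0)
  expect_lt(max(abs(f0$u_samp_d), na.rm = TRUE), 0.1)
  expect_true(all(f0$quality[!is.na(f0$u_samp_d)] > 0.999))

  # integer axial shift by 3 samples
  mov <- ref
  mov$iq <- rbind(matrix(0 + 0i, 3, ncol(ref$iq)),
                  ref$iq[1:(nrow(ref$iq) - 3), ])
  mov$frame_index <- 2L
  f3 <- block_match(ref, mov, kernel, search, mode = "envelope",
                    i_idx = seq(40, 180, by = 8), j_idx = seq(6, 34, by = 2))
  inner <- f3$u_int_d[2:(nrow(f3$u_int_d) - 1), ]
  expect_true(all(abs(inner - 3) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(f3$u_samp_d[2:(nrow(f3$u_samp_d) - 1), ] - 3) < 0.1,
                  na.rm = TRUE))
  expect_equal(f3$u_int_d[2, 2] * grid$axial_spacing, 3 * grid$axial_spacing)

  # fractional shift of 0.3 samples, fine RF pass
  movf <- shift_image_axial(ref, 0.3)
  ff <- block_match(ref, movf, kernel, search, mode = "rf",
                    i_idx = seq(40, 180, by = 8), j_idx = seq(6, 34, by = 2))
  errs <- abs(ff$u_samp_d - 0.3)
  expect_gt(mean(errs < 0.1, na.rm = TRUE), 0.95)

  # flat kernel: zero displacement, zero quality
  flat <- ref; flat$iq[] <- 1 + 0i
  fz <- block_match(flat, flat, kernel, search, mode = "rf",
                    i_idx = 100L, j_idx = 20L)
  expect_equal(as.vector(fz$u_samp_d), 0)
  expect_equal(as.vector(fz$quality), 0)
  fz2 <- block_match(flat, flat, kernel, search, mode = "envelope",
                     i_idx = 100L, j_idx = 20L)
  expect_equal(as.vector(fz2$quality), 0)

  # node whose search window exits the grid is invalid
  fe <- block_match(ref, ref, kernel, search, mode = "rf",
                    i_idx = 2L, j_idx = 20L)
  expect_true(is.na(fe$u_samp_d[1, 1]))
})

test_that("median filtering matches a brute-force sliding median", {
  grid <- toy_sector_grid(60, 20)
  ref <- toy_speckle_image(grid, seed = 8)
  f <- block_match(ref, ref, c(0.8, 2.4), c(1.6, 3.6), mode = "rf",
                   i_idx = seq(10, 50, by = 4), j_idx = seq(4, 16))
  set.seed(9)
  f$u_ax <- matrix(rnorm(length(f$u_ax)), nrow(f$u_ax), ncol(f$u_ax))
  f$u_lat <- f$u_ax; f$u_samp_d <- f$u_ax; f$u_samp_b <- f$u_ax
  size_mm <- c(0.5, 2.0)
  out <- median_filter_field(f, size_mm)
  # brute force with reflected edges
  dz <- grid$axial_spacing * 4
  dlat <- (grid$radius + mean(grid$depths)) *
    (grid$beam_angles[2] - grid$beam_angles[1]) * pi / 180
  hh <- round(size_mm[1] / 2 / dz); hw <- round(size_mm[2] / 2 / dlat)
  refl <- function(i, n) { i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n]; i }
  nr <- nrow(f$u_ax); nc <- ncol(f$u_ax)
  brute <- f$u_ax
  for (i in 1:nr) for (j in 1:nc) {
    wi <- refl(i + (-hh:hh), nr); wj <- refl(j + (-hw:hw), nc)
    brute[i, j] <- median(f$u_ax[wi, wj])
  }
  expect_equal(out$u_ax, brute)

  # constant field unchanged; single outlier removed
  f$u_ax[] <- 2.5
  expect_equal(median_filter_field(f, size_mm)$u_ax, f$u_ax)
  f$u_ax[4, 7] <- 50
  expect_equal(median_filter_field(f, size_mm)$u_ax[4, 7], 2.5)
})

test_that("beam-to-radial angles follow the vector-algebra oracle", {
  center <- c(0, 40)
  # node straight below the probe on the vessel axis: collinear
  expect_equal(compute_theta(c(0, 50), center, c(0, 1)), 0)
  # node on the horizontal axis with a vertical beam: 90 degrees
  th <- compute_theta(c(11, 40), center, c(0, 1))
  expect_equal(th, 90)
  expect_equal(angular_mask(th), 0)     # inside the cut-out
  # random geometry against acos of the dot product
  set.seed(15)
  for (rep in 1:20) {
    p <- center + runif(2, -15, 15)
    b <- rnorm(2); b <- b / sqrt(sum(b^2))
    want <- acos(sum(b * (p - center)) / sqrt(sum((p - center)^2))) * 180 / pi
    expect_equal(compute_theta(p, center, b), want, tolerance = 1e-9)
  }
  expect_true(is.na(compute_theta(center, center, c(0, 1))))
})

test_that("angular masks and radial projection implement the cosine law", {
  expect_equal(angular_mask(0), 1)
  expect_equal(angular_mask(45), 0.5)
  expect_equal(angular_mask(80), 0)          # cut-out
  expect_equal(angular_mask(180), 1)
  expect_equal(radial_project(1, 0), 1)
  expect_equal(radial_project(1, 60), 2, tolerance = 1e-12)
  expect_true(is.na(radial_project(1, 89)))  # excluded, never evaluated
  expect_true(is.na(radial_project(1, NA)))
})

test_that("displacement compounding is a normalized convex combination", {
  set.seed(16)
  dims <- c(7, 9)
  u <- lapply(1:4, function(k) matrix(rnorm(63), dims[1], dims[2]))
  th <- lapply(1:4, function(k) matrix(runif(63, 0, 180), dims[1], dims[2]))
  m <- lapply(th, angular_mask)
  out <- compound_displacements(u, m)
  # brute-force elementwise evaluation of the weighted average
  w_rec <- c(1, 1, 0.5, 0.5)
  for (i in 1:dims[1]) for (j in 1:dims[2]) {
    ww <- vapply(1:4, function(k) m[[k]][i, j] * w_rec[k], numeric(1))
    if (sum(ww) == 0) {
      expect_true(is.na(out$u_rad[i, j]))
    } else {
      want <- sum(ww * vapply(1:4, function(k) u[[k]][i, j], numeric(1))) /
        sum(ww)
      expect_equal(out$u_rad[i, j], want, tolerance = 1e-12)
      vals <- vapply(1:4, function(k) u[[k]][i, j], numeric(1))[ww > 0]
      expect_gte(out$u_rad[i, j], min(vals) - 1e-12)
      expect_lte(out$u_rad[i, j], max(vals) + 1e-12)
    }
  }
  # equal fields pass through; single active contribution passes through
  ue <- lapply(1:4, function(k) u[[1]])
  oute <- compound_displacements(ue, m)
  ok <- !is.na(oute$u_rad)
  expect_equal(oute$u_rad[ok], u[[1]][ok], tolerance = 1e-12)
  m_single <- list(matrix(0.8, dims[1], dims[2]),
                   matrix(0, dims[1], dims[2]),
                   matrix(0, dims[1], dims[2]),
                   matrix(0, dims[1], dims[2]))
  expect_equal(compound_displacements(u, m_single)$u_rad, u[[1]],
               tolerance = 1e-12)
})

test_that("compounding uses only radial displacements, never lateral", {
  # structural check: the compounding operation consumes radially
  # projected fields and masks only
  expect_named(formals(compound_displacements),
               c("u_rad_list", "mask_list", "reciprocity_weights"))
  # and the mesh-tracking sampler output is unchanged by lateral estimates
  grid <- toy_sector_grid(120, 30)
  ref <- toy_speckle_image(grid, seed = 30)
  mov <- shift_image_axial(ref, 0.5)
  f <- block_match(ref, mov, c(0.8, 2.4), c(1.6, 3.6), mode = "rf",
                   i_idx = seq(20, 100, by = 4), j_idx = seq(4, 26))
  pts <- apply_transform(rigid_transform(), sector_points(grid))[3000:3010, ]
  s1 <- sample_u_rad(f, pts, center = c(0, 60), test_geom(16), test_geom(16))
  f$u_lat <- f$u_lat + 100
  s2 <- sample_u_rad(f, pts, center = c(0, 60), test_geom(16), test_geom(16))
  expect_identical(s1$u_rad, s2$u_rad)
})

test_that("trans-probe beam directions use the bisector geometry", {
  g1 <- test_geom(16, 1)
  g2 <- test_geom(16, 2)
  T2 <- probe2_transform(c(0, 40), 80, 40)
  p <- matrix(c(0, 40), 1, 2)
  mono <- pairing_beam_direction(p, g1, g1)
  expect_equal(mono$gamma, 0)
  expect_equal(as.vector(mono$dir), c(0, 1), tolerance = 1e-12)
  bi <- pairing_beam_direction(p, g1, g2, rigid_transform(), T2)
  # probe 2 sits up-left of the vessel, so its beam at the center points
  # down-right; the bisector with the vertical probe-1 beam is at +40 deg
  expect_equal(bi$gamma, 80, tolerance = 1e-6)
  want <- c(sin(40 * pi / 180), cos(40 * pi / 180))
  expect_equal(as.vector(bi$dir), want, tolerance = 1e-6)
})
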