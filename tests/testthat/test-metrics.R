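test_that("gCNR separates distributions per the overlap oracle", {
  set.seed(19)
  same <- rnorm(2e5, 5, 1)
  expect_lt(gcnr(same, 1:1e5, 1e5 + 1:1e5), 0.05)
  a <- runif(5e4, 0, 1); b <- runif(5e4, 3, 4)
  expect_equal(gcnr(c(a, b), seq_along(a), length(a) + seq_along(b)), 1)

  # two unit-variance Gaussians, mean gap 3: overlap = 2 Phi(-1.5)
  x <- c(rnorm(1e5, 0, 1), rnorm(1e5, 3, 1))
  g <- gcnr(x, 1:1e5, 1e5 + 1:1e5)
  expect_equal(g, 1 - 2 * pnorm(-1.5), tolerance = 0.02)
  # stability across binning
  expect_equal(gcnr(x, 1:1e5, 1e5 + 1:1e5, 128), g, tolerance = 0.02)
  expect_equal(gcnr(x, 1:1e5, 1e5 + 1:1e5, 512), g, tolerance = 0.02)
  # invariance to a monotone amplitude mapping applied to both regions
  y <- exp(x / 2)
  expect_equal(gcnr(y, 1:1e5, 1e5 + 1:1e5), g, tolerance = 0.02)
  expect_true(gcnr(x, 1:1e5, 1e5 + 1:1e5) >= 0)
  expect_error(gcnr(x, integer(0), 1:10), "empty")
})

test_that("wall and lumen ROIs are disjoint and the lumen is eroded", {
  a <- seq(0, 2 * pi, length.out = 73)[-73]
  inner <- cbind(10 * sin(a), 40 - 10 * cos(a))
  mesh <- build_wall_mesh(inner, 1.7, 5, center = c(0, 40))
  grid <- cartesian_grid(c(-14, 14), c(26, 54), 0.1)
  rois <- make_rois(mesh, grid, erosion_radius = 0.6)
  expect_false(any(rois$wall & rois$lumen))
  pts <- grid_points(grid)
  r <- matrix(sqrt(pts[, 1]^2 + (pts[, 2] - 40)^2), length(grid$z),
              length(grid$x))
  # eroded lumen boundary at 10 - 0.6 mm within one cell
  expect_lt(max(r[rois$lumen]), 9.4 + 0.15)
  expect_gt(max(r[rois$lumen]), 9.4 - 0.15)
  # erosion matches a brute-force distance-map threshold
  brute <- r <= (10 - 0.6)
  agree <- mean(rois$lumen == brute)
  expect_gt(agree, 0.99)
  # wall annulus geometry
  expect_true(all(r[rois$wall] >= 10 - 0.15 & r[rois$wall] <= 11.7 + 0.15))
  expect_error(make_rois(mesh, grid, erosion_radius = 11), "emptied")
})

test_that("regional partition anchors on the right transducer's beam", {
  a <- seq(0, 2 * pi, length.out = 65)[-65]
  inner <- cbind(10 * sin(a), 40 - 10 * cos(a))
  mesh <- build_wall_mesh(inner, 1.7, 5, center = c(0, 40))
  anchor <- c(0, 1)
  # node along the anchor direction (below center): region 1
  expect_equal(partition_regions(mesh, anchor,
                                 points = matrix(c(0, 50), 1, 2)), 1L)
  # node opposite the anchor: region 5
  expect_equal(partition_regions(mesh, anchor,
                                 points = matrix(c(0, 30), 1, 2)), 5L)
  # rotating points clockwise by 45 degrees increments the region index
  p0 <- matrix(c(0, 50), 1, 2)
  for (k in 0:7) {
    ang <- k * 45 * pi / 180
    # clockwise on screen (x right, z down): bottom -> left -> top -> right
    pk <- matrix(c(-10 * sin(ang), 40 + 10 * cos(ang)), 1, 2)
    expect_equal(partition_regions(mesh, anchor, points = pk),
                 as.integer(k %% 8 + 1))
  }
  reg <- partition_regions(mesh, anchor)
  expect_true(all(sort(unique(reg)) == 1:8))
})

test_that("lateral exclusion masks the configured angular width", {
  n <- 360
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  inner <- cbind(10 * sin(a), 40 - 10 * cos(a))
  mesh <- build_wall_mesh(inner, 1.7, 3, center = c(0, 40))
  expect_true(all(exclude_lateral_sections(mesh, 0)))
  expect_false(any(exclude_lateral_sections(mesh, 360)))
  keep41 <- exclude_lateral_sections(mesh, 41)
  # each lateral section spans its full width: 41 of the 360 one-degree
  # nodes fall inside each band
  expect_equal(sum(!keep41), 82)
})

test_that("mean drift error is the mean node distance and a metric", {
  a <- seq(0, 2 * pi, length.out = 33)[-33]
  inner <- cbind(8 * sin(a), 40 - 8 * cos(a))
  m1 <- build_wall_mesh(inner, 1.7, 3, center = c(0, 40))
  expect_equal(mean_drift_error(m1, m1), 0)
  m2 <- m1
  m2$nodes[, , 1] <- m2$nodes[, , 1] + 3
  m2$nodes[, , 2] <- m2$nodes[, , 2] + 4
  expect_equal(mean_drift_error(m1, m2), 5, tolerance = 1e-12)
  # brute force on randomized meshes + metric properties
  set.seed(23)
  rand_mesh <- function() {
    m <- m1
    m$nodes <- m$nodes + array(rnorm(length(m$nodes), 0, 0.5), dim(m$nodes))
    m
  }
  ma <- rand_mesh(); mb <- rand_mesh(); mc <- rand_mesh()
  pa <- mesh_middle_layer(ma); pb <- mesh_middle_layer(mb)
  brute <- mean(sqrt(rowSums((pa - pb)^2)))
  expect_equal(mean_drift_error(ma, mb), brute, tolerance = 1e-12)
  expect_equal(mean_drift_error(ma, mb), mean_drift_error(mb, ma))
  expect_lte(mean_drift_error(ma, mc),
             mean_drift_error(ma, mb) + mean_drift_error(mb, mc))
})

test_that("SNRe implements the decibel ratio of mean to deviation", {
  x <- c(0.01, 0.012, 0.008, 0.011, 0.009)
  expect_equal(snre(x), 20 * log10(mean(x) / sd(x)), tolerance = 1e-12)
  y <- rnorm(50, 0.02, 0.002)
  expect_equal(snre(y), 20 * log10(abs(mean(y)) / sd(y)))
  expect_equal(snre(-y), snre(y))       # compressive strain: same precision
  expect_warning(s <- snre(c(1, 1, 1)), "zero")
  expect_equal(s, Inf)
  expect_error(snre(0.1), "at least 2")
})

test_that("paired comparison chooses the test by normality of differences", {
  set.seed(29)
  a <- rnorm(20, 1, 0.2)
  same <- paired_compare(a, a)
  expect_equal(same$test, "degenerate")
  expect_equal(same$p_value, 1)

  b <- a + 0.5 + rnorm(20, 0, 0.05)
  r <- paired_compare(a, b)
  expect_equal(r$test, "paired t-test")
  expect_lt(r$p_value, 0.05)
  # textbook-formula oracle for the paired t statistic
  d <- a - b
  t_want <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$statistic, t_want, tolerance = 1e-6)
  p_want <- 2 * pt(-abs(t_want), length(d) - 1)
  expect_equal(r$p_value, p_want, tolerance = 1e-6)

  # strongly non-normal differences select the signed-rank test
  skew <- a + c(rep(0.01, 16), 4, 5, 6, 8)
  r2 <- paired_compare(a, skew)
  expect_equal(r2$test, "wilcoxon signed-rank")
  expect_lt(r2$p_value, 0.05)
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
})
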