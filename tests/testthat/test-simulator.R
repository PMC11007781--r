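test_that("phantom generation is reproducible and density-faithful", {
  cf <- phantom_config(wall_density = 0, background_density = 0)
  expect_equal(nrow(make_vessel_phantom(cf, 3)$positions), 0)

  cf2 <- phantom_config()
  p1 <- make_vessel_phantom(cf2, 5)
  p2 <- make_vessel_phantom(cf2, 5)
  expect_identical(p1$positions, p2$positions)
  expect_identical(p1$amplitudes, p2$amplitudes)

  # Poisson bound on the wall count
  r_out <- cf2$inner_radius + cf2$wall_thickness
  A <- pi * (r_out^2 - cf2$inner_radius^2)
  n_wall <- sum(p1$labels == "wall")
  expect_lt(abs(n_wall - cf2$wall_density * A),
            4 * sqrt(cf2$wall_density * A))
  # wall scatterers confined to the annulus
  w <- p1$positions[p1$labels == "wall", ]
  r <- sqrt((w[, 1] - cf2$center[1])^2 + (w[, 2] - cf2$center[2])^2)
  expect_true(all(r >= cf2$inner_radius & r <= r_out))

  expect_error(make_vessel_phantom(phantom_config(center = c(0, 22)), 1),
               "field of view")
})

test_that("incompressible-ring deformation matches the analytic map", {
  cf <- phantom_config()
  ph <- make_vessel_phantom(cf, 8)
  mdl <- pulsation_model(inner_radius_rest = 10,
                         radius_waveform = c(10, 10.2, 10))
  # rest frame: nothing moves
  d0 <- deform_phantom(ph, mdl, 1)
  expect_equal(max(abs(d0$displacement)), 0)
  expect_equal(max(abs(d0$eps_circ), na.rm = TRUE), 0)

  # scatterer placed exactly on the inner boundary moves with it
  ph2 <- ph
  ph2$positions <- rbind(ph$positions, c(cf$center[1], cf$center[2] - 10))
  ph2$amplitudes <- c(ph$amplitudes, 1)
  ph2$labels <- factor(c(as.character(ph$labels), "wall"),
                       levels = levels(ph$labels))
  ph2$rest_radius <- c(ph$rest_radius, 10)
  d1 <- deform_phantom(ph2, mdl, 2)
  n <- nrow(ph2$positions)
  r_new <- sqrt(sum((d1$phantom$positions[n, ] - cf$center)^2))
  expect_equal(r_new, 10.2, tolerance = 1e-12)
  expect_equal(d1$eps_circ[n], 0.02, tolerance = 1e-12)

  # analytic value and finite-difference strain oracle at r = 11.7
  map_r <- function(r) sqrt(r^2 + 10.2^2 - 10^2)
  wall <- which(ph$labels == "wall")
  d2 <- deform_phantom(ph, mdl, 2)
  r0 <- ph$rest_radius[wall]
  r1 <- sqrt((d2$phantom$positions[wall, 1] - cf$center[1])^2 +
             (d2$phantom$positions[wall, 2] - cf$center[2])^2)
  expect_equal(r1, map_r(r0), tolerance = 1e-9)
  expect_equal(map_r(11.7), sqrt(11.7^2 + 10.2^2 - 10^2))
  h <- 1e-5
  fd_rad <- (map_r(r0 + h) - map_r(r0 - h)) / (2 * h) - 1
  expect_equal(d2$eps_rad[wall], fd_rad, tolerance = 1e-6)
  expect_equal(d2$eps_circ[wall], map_r(r0) / r0 - 1, tolerance = 1e-12)
})

test_that("wall annulus area is conserved under incompressible kinematics", {
  mdl <- pulsation_model(10, 1.7, radius_waveform = seq(10, 10.3,
                                                        length.out = 4))
  area <- function(ri, ro) pi * (ro^2 - ri^2)
  a0 <- area(10, 11.7)
  for (k in 2:4) {
    ri <- mdl$radius_waveform[k]
    ro <- sqrt(11.7^2 + ri^2 - 100)
    expect_lt(abs(area(ri, ro) - a0) / a0, 1e-3)
  }
  # wall collapse guard: a boundary particle driven to zero radius
  bad <- pulsation_model(10, 1.7, radius_waveform = c(10, 0))
  ph <- make_vessel_phantom(phantom_config(), 2)
  ph$positions <- rbind(ph$positions, c(0, 30))
  ph$amplitudes <- c(ph$amplitudes, 1)
  ph$labels <- factor(c(as.character(ph$labels), "wall"),
                      levels = levels(ph$labels))
  ph$rest_radius <- c(ph$rest_radius, 10)
  expect_error(deform_phantom(ph, bad, 2), "collapse")
})

test_that("channel simulation is linear and empty scenes are silent", {
  g1 <- test_geom(8)
  ev <- transmit_delays(g1, 0)
  empty <- point_phantom(matrix(0, 0, 2), numeric(0))
  ch0 <- simulate_channel_data(empty, g1, g1, event = ev, fs = 14.8e6)
  expect_equal(max(abs(ch0$samples)), 0)

  pa <- point_phantom(matrix(c(2, 35), 1, 2), 1.3)
  pb <- point_phantom(matrix(c(-3, 42), 1, 2), -0.7)
  pab <- point_phantom(rbind(c(2, 35), c(-3, 42)), c(1.3, -0.7))
  cha <- simulate_channel_data(pa, g1, g1, event = ev, fs = 14.8e6)
  chb <- simulate_channel_data(pb, g1, g1, event = ev, fs = 14.8e6)
  chab <- simulate_channel_data(pab, g1, g1, event = ev, fs = 14.8e6)
  expect_lt(max(abs(chab$samples - cha$samples - chb$samples)), 1e-9)
  expect_error(simulate_channel_data(pa, g1, g1, event = ev, fs = 8e6),
               "Nyquist")
})

test_that("single-scatterer arrival time matches the geometric oracle", {
  g <- test_geom(4)
  ev <- transmit_delays(g, 0, tukey_ratio = 0)   # rectangular transmit
  p <- c(1.5, 33)
  ph <- point_phantom(matrix(p, 1, 2))
  fs <- 14.8e6
  ch <- simulate_channel_data(ph, g, g, event = ev, fs = fs)
  c_mmus <- 1540 * 1e3            # mm per s
  d_tx <- min(ev$element_delays +
              sqrt((g$element_positions[, 1] - p[1])^2 +
                   (g$element_positions[, 2] - p[2])^2) / c_mmus)
  for (j in c(1, 3)) {
    d_rx <- sqrt(sum((g$element_positions[j, ] - p)^2)) / c_mmus
    t_true <- d_tx + d_rx
    env <- Mod(demodulate(ch)$samples[, j])
    t_peak <- ch$t0 + (which.max(env) - 1) / fs
    expect_lt(abs(t_peak - t_true), 1 / fs)
  }
})

test_that("single-element transmit and receive obey acoustic reciprocity", {
  a <- point_probe(c(-5, 0), c(0.3, 1), label = 1L)
  b <- point_probe(c(6, 1), c(-0.2, 1), label = 2L)
  ph <- point_phantom(rbind(c(1, 30), c(-4, 38)), c(1, 0.6))
  ev <- single_element_event()
  ab <- simulate_channel_data(ph, a, b, event = ev, fs = 14.8e6)
  ba <- simulate_channel_data(ph, b, a, event = ev, fs = 14.8e6)
  expect_equal(ab$t0, ba$t0)
  expect_lt(max(abs(ab$samples - ba$samples)), 1e-9)
})

test_that("a simulated cycle closes: periodic phantom, zero true drift", {
  scene <- phantom_config(fov_x = c(-6, 6), fov_z = c(28, 52),
                          center = c(0, 40), inner_radius = 3.5,
                          wall_thickness = 1.2, wall_density = 2,
                          background_density = 0.2)
  acq <- acquisition_config(n_elements = 8, angles = 0,
                            T_probe2 = probe2_transform(c(0, 40), 60, 40))
  mdl <- pulsation_model(3.5, 1.2, n_frames = 4, excursion = 0.02)
  cyc <- simulate_cycle(scene, acq, mdl, seed = 9)
  expect_length(cyc$frames, 4)
  expect_named(cyc$frames[[1]], c("T1R1", "T1R2", "T2R1", "T2R2"))
  # waveform closes, so the last frame's truth equals the first's
  expect_equal(cyc$truth$inner_radius[4], cyc$truth$inner_radius[1])
  expect_lt(max(abs(cyc$truth$displacement[[4]] -
                    cyc$truth$displacement[[1]])), 1e-9)
  expect_equal(max(abs(cyc$truth$displacement[[1]])), 0)
  # determinism of the full record for a fixed seed
  cyc2 <- simulate_cycle(scene, acq, mdl, seed = 9)
  expect_identical(cyc$truth$phantom$positions, cyc2$truth$phantom$positions)
  expect_identical(cyc$frames[[2]]$T1R2[[1]]$samples,
                   cyc2$frames[[2]]$T1R2[[1]]$samples)
})
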