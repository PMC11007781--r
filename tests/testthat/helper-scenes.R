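# Shared small-scale fixtures, built in code. Heavy fixtures are cached in
# this environment so several test files can reuse one computation.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

test_geom <- function(n = 16, label = 1L, f0 = 3.7e6) {
  make_curved_array(n, pitch = 0.508, radius = 49.57, f0 = f0,
                    bandwidth = 0.6, label = label)
}

# single-element "probe" for channel-level reciprocity checks
point_probe <- function(pos, normal, label = 1L, f0 = 3.7e6) {
  structure(list(n_elements = 1L,
                 element_positions = matrix(pos, 1, 2),
                 element_normals = matrix(normal / sqrt(sum(normal^2)), 1, 2),
                 pitch = 0.508, radius = 49.57, arc_center = c(0, -49.57),
                 f0 = f0, bandwidth = 0.6, label = as.integer(label)),
            class = "transducer_geometry")
}

single_element_event <- function() {
  structure(list(steering_angle = 0, element_delays = 0, apodization = 1,
                 virtual_source = c(0, -49.57), t_vs0 = 0),
            class = "transmit_event")
}

# phantom with explicitly placed scatterers (positions n x 2, mm)
point_phantom <- function(positions, amplitudes = rep(1, nrow(positions)),
                          fov_x = c(-20, 20), fov_z = c(20, 60)) {
  cf <- phantom_config(fov_x = fov_x, fov_z = fov_z, wall_density = 0,
                       background_density = 0)
  structure(list(positions = positions, amplitudes = amplitudes,
                 labels = factor(rep("background", nrow(positions)),
                                 levels = c("wall", "lumen", "background",
                                            "spine")),
                 rest_radius = rep(NA_real_, nrow(positions)), config = cf),
            class = "scatterer_phantom")
}

# hand-built channel_data (for demodulation tests)
raw_channels <- function(samples, fs, f0 = 3.7e6, t0 = 0) {
  structure(list(samples = samples, fs = fs, t0 = t0, f0 = f0, c = 1540,
                 bandwidth = 0.6, tx_probe = 1L, rx_probe = 1L,
                 T_tx = rigid_transform(), T_rx = rigid_transform(),
                 event = single_element_event(), frame_index = 1L,
                 baseband = FALSE),
            class = "channel_data")
}

# small sector grid without a full geometry (for synthetic speckle)
toy_sector_grid <- function(n_depth = 160, n_beam = 48, d0 = 30,
                            axial_spacing = 0.052, radius = 49.57,
                            dbeta_deg = 0.294) {
  structure(list(beam_angles = (seq_len(n_beam) - (n_beam + 1) / 2) *
                   dbeta_deg,
                 depths = d0 + (seq_len(n_depth) - 1) * axial_spacing,
                 axial_spacing = axial_spacing, lines_per_pitch = 2,
                 radius = radius, arc_center = c(0, -radius)),
            class = "sector_grid")
}

# band-limited synthetic speckle on a sector grid, with an axial carrier so
# the real part behaves like RF
toy_speckle_image <- function(grid, seed = 1, corr_len = 4,
                              pairing = c(1L, 1L)) {
  set.seed(seed)
  nd <- length(grid$depths); nb <- length(grid$beam_angles)
  x <- matrix(complex(real = rnorm(nd * nb), imaginary = rnorm(nd * nb)),
              nd, nb)
  k <- corr_len
  # separable smoothing by convolution (clamped edges)
  smooth1 <- function(m, kv, along_rows = TRUE) {
    if (!along_rows) return(t(smooth1(t(m), kv)))
    h <- (length(kv) - 1) / 2
    idx <- function(i, n) pmin(pmax(i, 1), n)
    out <- m * 0
    for (o in -h:h) out <- out + kv[o + h + 1] * m[idx(1:nrow(m) + o,
                                                      nrow(m)), , drop = FALSE]
    out
  }
  sm <- smooth1(x, exp(-((-k:k) / (k / 2))^2), TRUE)
  sm <- smooth1(sm, exp(-((-2:2))^2 / 2), FALSE)
  carrier <- exp(2i * pi * grid$depths / (4 * grid$axial_spacing))
  iq <- sm * matrix(carrier, nd, nb)
  structure(list(iq = iq, grid = grid, pairing = pairing,
                 steering_angle = "compounded", frame_index = 1L,
                 T_tx = rigid_transform(), T_rx = rigid_transform()),
            class = "beamformed_image")
}

# subsample (fractional) axial shift of a complex image, FFT-based
shift_image_axial <- function(img, shift_samples) {
  iq <- img$iq
  n <- nrow(iq)
  k <- c(0:floor(n / 2 - 1e-9), -(ceiling(n / 2 - 1e-9):1))
  if (length(k) != n) k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  ramp <- exp(-2i * pi * k * shift_samples / n)
  img$iq <- apply(iq, 2, function(col) fft(fft(col) * ramp,
                                           inverse = TRUE) / n)
  img$frame_index <- img$frame_index + 1L
  img
}

# medium two-probe speckle scene shared by beamform/register tests
recip_scene <- function() {
  cached("recip_scene", {
    scene <- phantom_config(fov_x = c(-14, 14), fov_z = c(28, 52),
                            center = c(0, 40), inner_radius = 6,
                            wall_thickness = 1.7, wall_density = 8,
                            background_density = 1.5)
    acq <- acquisition_config(n_elements = 32, angles = c(-8, 0, 8),
                              T_probe2 = probe2_transform(c(0, 40), 70, 40))
    ph <- make_vessel_phantom(scene, seed = 33)
    g1 <- make_curved_array(32, 0.508, 49.57, 3.7e6, 0.6, 1)
    g2 <- make_curved_array(32, 0.508, 49.57, 3.7e6, 0.6, 2)
    id <- rigid_transform()
    T2 <- acq$T_probe2
    evs <- lapply(acq$angles, function(a) transmit_delays(g1, a))
    sim <- function(tg, rg, Tt, Tr) lapply(evs, function(ev)
      simulate_channel_data(ph, tg, rg, Tt, Tr, ev, fs = acq$fs))
    list(scene = scene, acq = acq, g1 = g1, g2 = g2, T2 = T2,
         ch12 = sim(g1, g2, id, T2), ch21 = sim(g2, g1, T2, id),
         ch11 = sim(g1, g1, id, id), ch22 = sim(g2, g2, T2, T2))
  })
}
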