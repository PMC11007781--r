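#' Default phantom configuration
#'
#' Scene parameters of the standard pulsating-vessel phantom: an echogenic
#' vessel wall ring around an anechoic lumen, embedded in speckle-generating
#' background scatterers, imaged by two curved arrays in one plane. Units
#' are mm and scatterers per mm^2.
#'
#' @param center vessel center (x, z) in the probe-1 frame, mm.
#' @param inner_radius rest inner (lumen) radius, mm.
#' @param wall_thickness rest wall thickness, mm.
#' @param fov_x,fov_z field-of-view ranges populated with scatterers, mm.
#' @param wall_density,background_density,lumen_density scatterers per mm^2.
#' @param wall_amplitude,background_amplitude reflectivity scale (standard
#'   deviation of the scatterer amplitude) per region.
#' @param lumen_amplitude anechoic ceiling for lumen scatterers.
#' @param spine optional high-amplitude curved reflector below the vessel:
#'   a list with `enabled`, `depth_offset` (mm below the vessel center),
#'   `radius`, `half_angle_deg`, `density`, `amplitude`.
#' @return a list of phantom parameters.
#' @export
phantom_config <- function(center = c(0, 40), inner_radius = 10,
                           wall_thickness = 1.7,
                           fov_x = c(-20, 20), fov_z = c(20, 60),
                           wall_density = 10, background_density = 3,
                           lumen_density = 0,
                           wall_amplitude = 3, background_amplitude = 1,
                           lumen_amplitude = 0,
                           spine = list(enabled = FALSE, depth_offset = 16,
                                        radius = 12, half_angle_deg = 40,
                                        density = 12, amplitude = 6)) {
  list(center = center, inner_radius = inner_radius,
       wall_thickness = wall_thickness, fov_x = fov_x, fov_z = fov_z,
       wall_density = wall_density, background_density = background_density,
       lumen_density = lumen_density, wall_amplitude = wall_amplitude,
       background_amplitude = background_amplitude,
       lumen_amplitude = lumen_amplitude, spine = spine)
}

#' Point-scatterer phantom of a vessel cross-section
#'
#' Draws scatterer counts from Poisson distributions at the configured
#' densities: wall scatterers uniform in the annulus, background scatterers
#' uniform in the field of view outside the vessel, and (by default none)
#' anechoic lumen scatterers. Amplitudes are zero-mean Gaussian with the
#' per-region scale. Reproducible for a fixed seed.
#'
#' @param config a [phantom_config()] list.
#' @param seed integer RNG seed.
#' @return an object of class `scatterer_phantom` with `positions` (n x 2,
#'   mm, probe-1 frame), `amplitudes`, `labels` (factor: wall, lumen,
#'   background, spine), `rest_radius` (distance from the vessel center at
#'   rest, NA for non-wall), and the generating `config`.
#' @export
make_vessel_phantom <- function(config = phantom_config(), seed = 1L) {
  cf <- config
  if (cf$inner_radius <= 0 || cf$wall_thickness <= 0)
    stop("vessel radii must be positive", call. = FALSE)
  if (cf$wall_density < 0 || cf$background_density < 0 || cf$lumen_density < 0)
    stop("densities must be non-negative", call. = FALSE)
  r_out <- cf$inner_radius + cf$wall_thickness
  if (cf$center[1] - r_out < cf$fov_x[1] || cf$center[1] + r_out > cf$fov_x[2] ||
      cf$center[2] - r_out < cf$fov_z[1] || cf$center[2] + r_out > cf$fov_z[2])
    stop("vessel exclusion region extends outside the field of view",
         call. = FALSE)
  if (isTRUE(cf$spine$enabled) &&
      cf$spine$depth_offset - cf$spine$radius < r_out)
    stop("spine reflector overlaps the vessel region", call. = FALSE)
  set.seed(seed)

  annulus_ring <- function(n, r0, r1) {
    # uniform by area in the annulus [r0, r1]
    r <- sqrt(runif(n, r0^2, r1^2))
    a <- runif(n, 0, 2 * pi)
    cbind(cf$center[1] + r * sin(a), cf$center[2] - r * cos(a))
  }

  wall_area <- pi * (r_out^2 - cf$inner_radius^2)
  n_wall <- rpois(1, cf$wall_density * wall_area)
  p_wall <- annulus_ring(n_wall, cf$inner_radius, r_out)
  a_wall <- rnorm(n_wall, 0, cf$wall_amplitude)

  lumen_area <- pi * cf$inner_radius^2
  n_lum <- rpois(1, cf$lumen_density * lumen_area)
  p_lum <- annulus_ring(n_lum, 0, cf$inner_radius)
  a_lum <- rep(cf$lumen_amplitude, n_lum)

  fov_area <- diff(cf$fov_x) * diff(cf$fov_z)
  n_bg0 <- rpois(1, cf$background_density * fov_area)
  p_bg <- cbind(runif(n_bg0, cf$fov_x[1], cf$fov_x[2]),
                runif(n_bg0, cf$fov_z[1], cf$fov_z[2]))
  keep <- sqrt((p_bg[, 1] - cf$center[1])^2 +
               (p_bg[, 2] - cf$center[2])^2) > r_out
  p_bg <- p_bg[keep, , drop = FALSE]
  a_bg <- rnorm(nrow(p_bg), 0, cf$background_amplitude)

  p_sp <- matrix(0, 0, 2); a_sp <- numeric(0)
  if (isTRUE(cf$spine$enabled)) {
    sc <- c(cf$center[1], cf$center[2] + cf$spine$depth_offset)
    arc_len <- 2 * cf$spine$half_angle_deg * pi / 180 * cf$spine$radius
    n_sp <- rpois(1, cf$spine$density * arc_len)   # thin arc, per mm
    ang <- runif(n_sp, -1, 1) * cf$spine$half_angle_deg * pi / 180
    rr <- cf$spine$radius + rnorm(n_sp, 0, 0.15)
    p_sp <- cbind(sc[1] + rr * sin(ang), sc[2] - rr * cos(ang))
    a_sp <- rnorm(n_sp, 0, cf$spine$amplitude)
  }

  positions <- rbind(p_wall, p_lum, p_bg, p_sp)
  labels <- factor(c(rep("wall", nrow(p_wall)), rep("lumen", nrow(p_lum)),
                     rep("background", nrow(p_bg)), rep("spine", nrow(p_sp))),
                   levels = c("wall", "lumen", "background", "spine"))
  rest_radius <- rep(NA_real_, nrow(positions))
  if (nrow(p_wall) > 0)
    rest_radius[seq_len(nrow(p_wall))] <-
      sqrt((p_wall[, 1] - cf$center[1])^2 + (p_wall[, 2] - cf$center[2])^2)
  structure(list(positions = positions,
                 amplitudes = c(a_wall, a_lum, a_bg, a_sp),
                 labels = labels, rest_radius = rest_radius, config = cf),
            class = "scatterer_phantom")
}

#' @export
print.scatterer_phantom <- function(x, ...) {
  cat(sprintf("scatterer phantom: %d scatterers (%s)\n", nrow(x$positions),
              paste(sprintf("%s %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Pulsatile vessel-wall kinematics
#'
#' Describes the wall motion over one cardiac cycle through the inner
#' (lumen) radius waveform. Under `incompressible_ring` kinematics a wall
#' particle at rest radius r moves to `sqrt(r^2 + r_i(t)^2 - r_i0^2)`,
#' conserving the annulus area; the analytic circumferential strain at
#' rest radius r is `r'/r - 1` and the radial strain `dr'/dr - 1 = r/r' - 1`.
#' Under `prescribed_strain` the wall dilates uniformly by
#' `r_i(t) / r_i0` (spatially constant circumferential strain).
#'
#' @param inner_radius_rest rest inner radius, mm.
#' @param wall_thickness_rest rest wall thickness, mm.
#' @param radius_waveform inner radius per frame, mm; the default is a
#'   raised-cosine systolic excursion of `excursion` (relative) peaking at
#'   mid cycle and returning to rest at the cycle end.
#' @param n_frames number of frames used to build the default waveform
#'   (frames 1 .. n_frames; frame n_frames equals frame 1).
#' @param excursion relative peak inner-radius excursion of the default
#'   waveform (0.02 = 2 percent).
#' @param kinematics `"incompressible_ring"` or `"prescribed_strain"`.
#' @return an object of class `pulsation_model`.
#' @export
pulsation_model <- function(inner_radius_rest = 10, wall_thickness_rest = 1.7,
                            radius_waveform = NULL, n_frames = 11,
                            excursion = 0.02,
                            kinematics = c("incompressible_ring",
                                           "prescribed_strain")) {
  kinematics <- match.arg(kinematics)
  if (is.null(radius_waveform)) {
    k <- seq(0, n_frames - 1)
    radius_waveform <- inner_radius_rest *
      (1 + excursion * (1 - cos(2 * pi * k / (n_frames - 1))) / 2)
  }
  structure(list(inner_radius_rest = inner_radius_rest,
                 wall_thickness_rest = wall_thickness_rest,
                 radius_waveform = radius_waveform,
                 kinematics = kinematics),
            class = "pulsation_model")
}

#' Deform a phantom to one frame of the pulsation model
#'
#' Wall scatterers move according to the model kinematics; background,
#' spine and lumen scatterers are static. Ground-truth displacement and the
#' analytic strain (relative to the rest frame) are returned per scatterer.
#'
#' @param phantom a [make_vessel_phantom()] phantom at rest.
#' @param model a [pulsation_model()].
#' @param frame 1-based frame index into the radius waveform.
#' @return a list with `phantom` (deformed), `displacement` (n x 2 mm),
#'   `eps_circ`, `eps_rad` (per scatterer, NA for non-wall), and
#'   `inner_radius` at this frame.
#' @export
deform_phantom <- function(phantom, model, frame) {
  if (frame < 1 || frame > length(model$radius_waveform))
    stop("frame outside the radius waveform", call. = FALSE)
  ri0 <- model$inner_radius_rest
  rit <- model$radius_waveform[frame]
  cf <- phantom$config
  n <- nrow(phantom$positions)
  disp <- matrix(0, n, 2)
  eps_c <- rep(NA_real_, n)
  eps_r <- rep(NA_real_, n)
  wall <- which(phantom$labels == "wall")
  out <- phantom
  if (length(wall)) {
    r <- phantom$rest_radius[wall]
    if (model$kinematics == "incompressible_ring") {
      arg <- r^2 + rit^2 - ri0^2
      if (any(arg <= 0))
        stop("wall collapse: inner-radius waveform drives radii through zero",
             call. = FALSE)
      r_new <- sqrt(arg)
      eps_r[wall] <- r / r_new - 1
    } else {
      r_new <- r * rit / ri0
      eps_r[wall] <- rit / ri0 - 1
    }
    eps_c[wall] <- r_new / r - 1
    dx <- phantom$positions[wall, 1] - cf$center[1]
    dz <- phantom$positions[wall, 2] - cf$center[2]
    scale <- r_new / r
    new_pos <- cbind(cf$center[1] + dx * scale, cf$center[2] + dz * scale)
    disp[wall, ] <- new_pos - phantom$positions[wall, , drop = FALSE]
    out$positions[wall, ] <- new_pos
  }
  list(phantom = out, displacement = disp, eps_circ = eps_c,
       eps_rad = eps_r, inner_radius = rit)
}

#' Default acquisition configuration
#'
#' Interleaved dual-probe ultrafast acquisition: each probe transmits a
#' burst of steered diverging waves while both probes receive on every
#' transmit event, yielding the four pairings T1R1, T1R2, T2R1, T2R2 per
#' frame.
#'
#' @param n_elements elements per probe.
#' @param pitch,radius curved-array geometry, mm.
#' @param f0 center frequency, Hz.
#' @param bandwidth fractional pulse bandwidth.
#' @param angles steering angles in degrees.
#' @param fs RF sampling frequency, Hz.
#' @param c speed of sound, m/s.
#' @param prf pulse repetition frequency, Hz.
#' @param T_probe2 a [rigid_transform()] mapping probe-2 coordinates to the
#'   probe-1 frame (the true probe placement). The default places probe 2
#'   at an 80 degree inter-probe angle on the left, aimed at the default
#'   vessel center.
#' @param tukey_ratio transmit apodization taper ratio.
#' @param dir_power exponent of the cosine element directivity.
#' @param noise_snr_db channel signal-to-noise ratio in dB, or NULL for
#'   noiseless data.
#' @return a list of acquisition parameters.
#' @export
acquisition_config <- function(n_elements = 64, pitch = 0.508, radius = 49.57,
                               f0 = 3.7e6, bandwidth = 0.6,
                               angles = seq(-12, 12, length.out = 5),
                               fs = 14.8e6, c = 1540, prf = 4000,
                               T_probe2 = NULL, tukey_ratio = 0.25,
                               dir_power = 1, noise_snr_db = NULL) {
  if (is.null(T_probe2)) T_probe2 <- probe2_transform(c(0, 40), 80, 40)
  list(n_elements = n_elements, pitch = pitch, radius = radius, f0 = f0,
       bandwidth = bandwidth, angles = angles, fs = fs, c = c, prf = prf,
       T_probe2 = T_probe2, tukey_ratio = tukey_ratio, dir_power = dir_power,
       noise_snr_db = noise_snr_db)
}

#' Probe-2 placement aimed at a target
#'
#' Convenience constructor of the true probe-2 transform: probe 2 is
#' rotated by `-inter_angle` about the target point (positive angles put
#' probe 2 to the left of probe 1) with its axis through the target at the
#' given standoff.
#'
#' @param target aim point (x, z) in the probe-1 frame, mm.
#' @param inter_angle inter-probe angle in degrees.
#' @param standoff distance from the probe-2 surface apex to the target, mm.
#' @return a [rigid_transform()].
#' @export
probe2_transform <- function(target = c(0, 40), inter_angle = 80,
                             standoff = 40) {
  phi <- -inter_angle
  R <- rotation_matrix(phi)
  apex <- target + as.vector(R %*% c(0, -standoff))
  rigid_transform(apex[1], apex[2], phi)
}

gauss_pulse_sigma <- function(f0, bandwidth) {
  # Gaussian-modulated sinusoid whose -6 dB (FWHM) spectral width is
  # bandwidth * f0
  sigma_f <- bandwidth * f0 / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

#' Time window covering a phantom for a probe pair
#'
#' Deterministic recording window derived from the field-of-view corners
#' (not the scatterer draw), so phantoms sharing a configuration share the
#' window.
#' @keywords internal
channel_time_window <- function(cf, tx_pos, rx_pos, event, c_mps, sigma_t) {
  corners <- cbind(rep(cf$fov_x, each = 2), rep(cf$fov_z, times = 2))
  d_tx <- range(outer(seq_len(nrow(tx_pos)), seq_len(4), function(i, k)
    event$element_delays[i] * c_mps * 1e3 +
      sqrt((tx_pos[i, 1] - corners[k, 1])^2 + (tx_pos[i, 2] - corners[k, 2])^2)))
  d_rx <- range(outer(seq_len(nrow(rx_pos)), seq_len(4), function(j, k)
    sqrt((rx_pos[j, 1] - corners[k, 1])^2 + (rx_pos[j, 2] - corners[k, 2])^2)))
  t_lo <- (d_tx[1] + d_rx[1]) / c_mps * 1e-3 - 6 * sigma_t
  t_hi <- (d_tx[2] + d_rx[2]) / c_mps * 1e-3 + 6 * sigma_t
  c(max(t_lo, 0), t_hi)
}

#' Simulate channel data for one transmit event and one receiving probe
#'
#' Linear scattering forward model: each recorded sample is the sum over
#' scatterers of reflectivity x element directivity x a Gaussian-modulated
#' pulse evaluated at t - (tau_tx + tau_rx). The transmit arrival time is
#' the first arrival over the transmit aperture under the virtual-source
#' delay model. Optional additive white Gaussian noise at a configured
#' channel SNR.
#'
#' @param phantom a [make_vessel_phantom()] phantom (positions in the
#'   probe-1 frame).
#' @param tx_geom,rx_geom transmitting / receiving [make_curved_array()]
#'   geometries (local frames).
#' @param T_tx,T_rx [rigid_transform()] placing each probe in the probe-1
#'   frame (identity for probe 1).
#' @param event a [transmit_delays()] transmit event for `tx_geom`.
#' @param fs sampling frequency, Hz.
#' @param c speed of sound, m/s.
#' @param noise_snr_db channel SNR in dB or NULL (noiseless).
#' @param frame_index frame label carried along.
#' @return an object of class `channel_data`: `samples` (n_samp x
#'   n_elements, RF), `fs`, `t0`, `f0`, `c`, `tx_probe`, `rx_probe`,
#'   `event`, `frame_index`, `baseband = FALSE`.
#' @export
simulate_channel_data <- function(phantom, tx_geom, rx_geom,
                                  T_tx = rigid_transform(),
                                  T_rx = rigid_transform(),
                                  event, fs, c = 1540,
                                  noise_snr_db = NULL, frame_index = 1L) {
  f0 <- tx_geom$f0
  if (fs <= 2 * f0 * (1 + tx_geom$bandwidth))
    stop("fs violates the RF Nyquist condition for this pulse", call. = FALSE)
  sigma_t <- gauss_pulse_sigma(f0, tx_geom$bandwidth)
  tx_pos <- apply_transform(T_tx, tx_geom$element_positions)
  tx_nrm <- apply_transform(rigid_transform(0, 0, T_tx$phi),
                            tx_geom$element_normals)
  rx_pos <- apply_transform(T_rx, rx_geom$element_positions)
  rx_nrm <- apply_transform(rigid_transform(0, 0, T_rx$phi),
                            rx_geom$element_normals)
  cf <- phantom$config
  tw <- channel_time_window(cf, tx_pos, rx_pos, event, c, sigma_t)
  t0 <- tw[1]
  n_samp <- ceiling((tw[2] - tw[1]) * fs) + 1
  samples <- sim_channels_cpp(
    phantom$positions * 1e-3, phantom$amplitudes,
    tx_pos * 1e-3, tx_nrm, event$element_delays, event$apodization,
    rx_pos * 1e-3, rx_nrm, fs, t0, as.integer(n_samp), c, f0, sigma_t,
    1.0)
  if (!is.null(noise_snr_db)) {
    sig <- sqrt(mean(samples^2))
    if (sig > 0) {
      sd_n <- sig * 10^(-noise_snr_db / 20)
      samples <- samples + matrix(rnorm(length(samples), 0, sd_n),
                                  nrow(samples), ncol(samples))
    }
  }
  structure(list(samples = samples, fs = fs, t0 = t0, f0 = f0, c = c,
                 bandwidth = tx_geom$bandwidth,
                 tx_probe = tx_geom$label, rx_probe = rx_geom$label,
                 T_tx = T_tx, T_rx = T_rx,
                 event = event, frame_index = as.integer(frame_index),
                 baseband = FALSE),
            class = "channel_data")
}

#' Simulate an interleaved dual-probe cardiac cycle
#'
#' Generates channel data for every frame of the pulsation waveform, every
#' steering angle, both transmitting probes and both receiving probes, plus
#' the per-frame ground-truth record (scatterer displacement relative to
#' rest, analytic strain, and the true probe-2 transform).
#'
#' @param scene a [phantom_config()] list.
#' @param acq an [acquisition_config()] list.
#' @param model a [pulsation_model()].
#' @param seed integer seed for the scatterer draw (and noise, if enabled).
#' @return a list with `frames` (per frame: list `T1R1`, `T1R2`, `T2R1`,
#'   `T2R2`, each a list of [simulate_channel_data()] objects per steering
#'   angle), `truth` (per-frame displacement, strain, inner radius;
#'   `T_probe2`; the rest phantom), `geoms`, `events`, `acq`, `model`.
#' @export
simulate_cycle <- function(scene = phantom_config(),
                           acq = acquisition_config(),
                           model = pulsation_model(),
                           seed = 1L) {
  geom1 <- make_curved_array(acq$n_elements, acq$pitch, acq$radius, acq$f0,
                             acq$bandwidth, label = 1L)
  geom2 <- make_curved_array(acq$n_elements, acq$pitch, acq$radius, acq$f0,
                             acq$bandwidth, label = 2L)
  events <- lapply(acq$angles, function(a)
    transmit_delays(geom1, a, acq$c, tukey_ratio = acq$tukey_ratio))
  phantom0 <- make_vessel_phantom(scene, seed)
  id <- rigid_transform()
  T2 <- acq$T_probe2
  n_frames <- length(model$radius_waveform)
  frames <- vector("list", n_frames)
  truth_disp <- vector("list", n_frames)
  truth_eps_c <- vector("list", n_frames)
  truth_eps_r <- vector("list", n_frames)
  inner_radius <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    def <- deform_phantom(phantom0, model, k)
    truth_disp[[k]] <- def$displacement
    truth_eps_c[[k]] <- def$eps_circ
    truth_eps_r[[k]] <- def$eps_rad
    inner_radius[k] <- def$inner_radius
    ph <- def$phantom
    sim_pair <- function(tx_geom, T_tx, rx_geom, T_rx) {
      lapply(events, function(ev)
        simulate_channel_data(ph, tx_geom, rx_geom, T_tx, T_rx, ev,
                              acq$fs, acq$c, acq$noise_snr_db, k))
    }
    frames[[k]] <- list(
      T1R1 = sim_pair(geom1, id, geom1, id),
      T1R2 = sim_pair(geom1, id, geom2, T2),
      T2R1 = sim_pair(geom2, T2, geom1, id),
      T2R2 = sim_pair(geom2, T2, geom2, T2))
  }
  list(frames = frames,
       truth = list(displacement = truth_disp, eps_circ = truth_eps_c,
                    eps_rad = truth_eps_r, inner_radius = inner_radius,
                    T_probe2 = T2, phantom = phantom0),
       geoms = list(geom1 = geom1, geom2 = geom2),
       events = events, acq = acq, model = model, seed = seed)
}
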