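#' Demodulate RF channel data to complex baseband
#'
#' Forms the analytic signal of each channel by the frequency-domain
#' Hilbert transform (negative frequencies zeroed) and mixes it down by
#' the carrier, so the stored samples are complex baseband (IQ). The
#' magnitude of the analytic signal of a pure tone equals its amplitude;
#' after mixing, the phase advances at -f0.
#'
#' @param channels a [simulate_channel_data()] object with RF samples.
#' @param f0 demodulation frequency, Hz; defaults to the pulse center
#'   frequency carried by the data.
#' @return the `channel_data` object with complex `samples` and
#'   `baseband = TRUE`.
#' @export
demodulate <- function(channels, f0 = channels$f0) {
  if (isTRUE(channels$baseband)) return(channels)
  if (channels$fs <= 2 * f0)
    stop("sampling frequency too low for demodulation at f0", call. = FALSE)
  x <- channels$samples
  n <- nrow(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(x) * h
  analytic <- mvfft(X, inverse = TRUE) / n
  t <- channels$t0 + (seq_len(n) - 1) / channels$fs
  channels$samples <- analytic * exp(-2i * pi * f0 * t)
  channels$baseband <- TRUE
  channels$f_demod <- f0
  channels
}

#' Delay-and-sum beamforming of one event onto a grid
#'
#' Reconstructs the complex image of a single transmit event for any
#' transmit/receive probe pairing. Receive element positions are mapped
#' through the (hypothesized or known) rigid transform of the receiving
#' probe; the transmit wavefront is modeled by the virtual source of the
#' event, mapped through the transmitting probe's transform. The output at
#' each node is the carrier-phase-preserving (analytic) signal, so images
#' from different events and pairings compound coherently.
#'
#' @param channels demodulated [channel_data] (see [demodulate()]).
#' @param tx_geom,rx_geom transmit / receive geometries.
#' @param T_tx,T_rx rigid transforms placing the probes in the probe-1
#'   frame. `T_rx` is the registration variable when the receiving probe
#'   is probe 2.
#' @param grid a [cartesian_grid()] or [sector_grid()]; sector grids are
#'   interpreted in the receiving probe's local frame and mapped through
#'   `T_rx`.
#' @param c speed of sound, m/s.
#' @param max_angle acceptance half-angle about the element normal,
#'   degrees.
#' @return an object of class `beamformed_image`: `iq` (complex matrix,
#'   z-or-depth x x-or-beam), `grid`, `pairing` (c(tx, rx)),
#'   `steering_angle`, `frame_index`.
#' @export
das_beamform <- function(channels, tx_geom, rx_geom,
                         T_tx = rigid_transform(), T_rx = rigid_transform(),
                         grid, c = 1540, max_angle = 45) {
  if (!isTRUE(channels$baseband))
    stop("channels must be demodulated before beamforming", call. = FALSE)
  if (inherits(grid, "sector_grid")) {
    nodes <- apply_transform(T_rx, sector_points(grid))
    dims <- c(length(grid$depths), length(grid$beam_angles))
  } else {
    nodes <- grid_points(grid)
    dims <- c(length(grid$z), length(grid$x))
  }
  rx_pos <- apply_transform(T_rx, rx_geom$element_positions)
  rx_nrm <- apply_transform(rigid_transform(0, 0, T_rx$phi),
                            rx_geom$element_normals)
  ev <- channels$event
  vs <- apply_transform(T_tx, ev$virtual_source)
  iq <- das_cpp(channels$samples, rx_pos * 1e-3, rx_nrm, vs * 1e-3,
                ev$t_vs0, nodes * 1e-3, channels$fs, channels$t0, c,
                channels$f_demod, max_angle)
  structure(list(iq = matrix(iq, dims[1], dims[2]), grid = grid,
                 pairing = c(tx_geom$label, rx_geom$label),
                 steering_angle = ev$steering_angle,
                 frame_index = channels$frame_index,
                 T_tx = T_tx, T_rx = T_rx),
            class = "beamformed_image")
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("beamformed image T%sR%s (%s), %d x %d nodes\n",
              x$pairing[1], x$pairing[2],
              if (is.numeric(x$steering_angle))
                sprintf("%g deg", x$steering_angle) else x$steering_angle,
              nrow(x$iq), ncol(x$iq)))
  invisible(x)
}

#' Coherent compounding over steering angles
#'
#' Complex (phase-preserving) sum of images of the same pairing and grid
#' reconstructed from different steered transmits.
#'
#' @param images list of [das_beamform()] images on an identical grid.
#' @return a `beamformed_image` with `steering_angle = "compounded"`.
#' @export
compound_angles <- function(images) {
  ref <- images[[1]]
  for (im in images[-1]) {
    if (!identical(dim(im$iq), dim(ref$iq)) ||
        !identical(im$pairing, ref$pairing))
      stop("compound_angles requires a common grid and pairing",
           call. = FALSE)
  }
  acc <- ref$iq
  for (im in images[-1]) acc <- acc + im$iq
  ref$iq <- acc
  ref$steering_angle <- "compounded"
  ref
}

#' Bistatic coherent compounding of the four probe pairings
#'
#' Fuses the two monostatic and the two trans-probe images into the
#' bistatic image: `I11 + I22 + (I12 + I21) / 2`. The two trans-probe
#' terms carry similar information by acoustic reciprocity, so their
#' relative contribution is averaged before summation.
#'
#' @param I11,I22,I12,I21 angle-compounded [das_beamform()] images of the
#'   pairings T1R1, T2R2, T1R2, T2R1 on a common grid.
#' @return a `beamformed_image` with `pairing = "bistatic"`.
#' @export
bistatic_compound <- function(I11, I22, I12, I21) {
  imgs <- list(I11, I22, I12, I21)
  want <- list(c(1L, 1L), c(2L, 2L), c(1L, 2L), c(2L, 1L))
  for (k in seq_along(imgs)) {
    if (!identical(as.integer(imgs[[k]]$pairing), want[[k]]))
      stop("bistatic_compound: pairing labels inconsistent with I11, I22, ",
           "I12, I21 order", call. = FALSE)
    if (!identical(dim(imgs[[k]]$iq), dim(I11$iq)))
      stop("bistatic_compound requires a common grid", call. = FALSE)
  }
  out <- I11
  out$iq <- I11$iq + I22$iq + 0.5 * (I12$iq + I21$iq)
  out$pairing <- "bistatic"
  out
}

#' Log-compressed envelope for display
#'
#' @param image a [das_beamform()] image.
#' @param dynamic_range display dynamic range in dB.
#' @return matrix of dB values in `[-dynamic_range, 0]`.
#' @export
envelope_log <- function(image, dynamic_range = 50) {
  env <- Mod(image$iq)
  m <- max(env)
  if (m == 0) stop("all-zero image has no displayable envelope",
                   call. = FALSE)
  pmax(20 * log10(env / m), -dynamic_range)
}

#' Beamform and angle-compound one pairing of one frame
#'
#' Convenience wrapper: demodulates the per-angle channel data of one
#' pairing, beamforms each event and compounds them coherently.
#'
#' @param channel_list list of [channel_data] objects (one per steering
#'   angle) of one tx/rx pairing.
#' @param tx_geom,rx_geom probe geometries.
#' @param T_tx,T_rx probe transforms (probe-1 frame).
#' @param grid reconstruction grid.
#' @param c speed of sound, m/s.
#' @param max_angle acceptance half-angle, degrees.
#' @return an angle-compounded `beamformed_image`.
#' @export
beamform_pairing <- function(channel_list, tx_geom, rx_geom,
                             T_tx = rigid_transform(),
                             T_rx = rigid_transform(),
                             grid, c = 1540, max_angle = 45) {
  imgs <- lapply(channel_list, function(ch)
    das_beamform(demodulate(ch), tx_geom, rx_geom, T_tx, T_rx, grid, c,
                 max_angle))
  compound_angles(imgs)
}
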