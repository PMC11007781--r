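#' Negative signal power of an image
#'
#' The objective of coherence-based probe localization: minus the sum of
#' squared envelope amplitudes over the imaged region. Coherent gain in
#' the trans-probe compound is maximal when the hypothesized probe
#' transform matches the true geometry, so the negative power is minimal
#' there.
#'
#' @param image a [beamformed_image] (or a complex/numeric matrix).
#' @return a scalar, `-sum(|A_i|^2)`.
#' @export
negative_signal_power <- function(image) {
  a <- if (inherits(image, "beamformed_image")) image$iq else image
  if (length(a) == 0) stop("empty imaged region", call. = FALSE)
  -sum(Mod(a)^2)
}

#' Registration objective: trans-probe coherence under a hypothesis
#'
#' Beamforms the T1R2 channel data of every steering angle under the
#' hypothesized probe-2 transform, compounds the angles coherently,
#' envelope-detects and returns the negative signal power over the
#' registration region of interest.
#'
#' @param T hypothesized probe-2 [rigid_transform()].
#' @param channels_t1r2 list of T1R2 [channel_data] objects, one per
#'   steering angle (demodulated or RF; RF is demodulated on the fly).
#' @param geom1,geom2 probe geometries.
#' @param grid registration grid (half-wavelength Cartesian grid over the
#'   region of interest).
#' @param c speed of sound, m/s.
#' @param max_angle receive acceptance half-angle, degrees.
#' @param rx_decim receive-element decimation factor (1 = all elements);
#'   a sparser receive aperture trades some coherence sensitivity for
#'   proportionally faster evaluations.
#' @return scalar negative signal power.
#' @export
registration_objective <- function(T, channels_t1r2, geom1, geom2, grid,
                                   c = 1540, max_angle = 45, rx_decim = 1) {
  if (rx_decim > 1) {
    keep <- seq(1, geom2$n_elements, by = rx_decim)
    geom2 <- decimate_geom(geom2, keep)
    channels_t1r2 <- lapply(channels_t1r2, function(ch) {
      ch$samples <- ch$samples[, keep, drop = FALSE]
      ch
    })
  }
  img <- beamform_pairing(channels_t1r2, geom1, geom2,
                          T_tx = rigid_transform(), T_rx = T,
                          grid = grid, c = c, max_angle = max_angle)
  negative_signal_power(img)
}

decimate_geom <- function(geom, keep) {
  geom$element_positions <- geom$element_positions[keep, , drop = FALSE]
  geom$element_normals <- geom$element_normals[keep, , drop = FALSE]
  geom$n_elements <- length(keep)
  geom
}

#' Central-difference numerical gradient over transform parameters
#'
#' Evaluates the objective at plus/minus one step in each of the three
#' degrees of freedom (six evaluations) and forms central differences.
#'
#' @param f objective: a function of a [rigid_transform()].
#' @param T expansion point.
#' @param steps length-3 positive step sizes `c(tx, tz, phi)` in (mm, mm,
#'   degrees).
#' @return length-3 gradient vector.
#' @export
numerical_gradient <- function(f, T, steps) {
  if (any(steps <= 0)) stop("step sizes must be positive", call. = FALSE)
  g <- numeric(3)
  par <- c(T$tx, T$tz, T$phi)
  for (k in 1:3) {
    pp <- par; pp[k] <- pp[k] + steps[k]
    pm <- par; pm[k] <- pm[k] - steps[k]
    g[k] <- (f(rigid_transform(pp[1], pp[2], pp[3])) -
             f(rigid_transform(pm[1], pm[2], pm[3]))) / (2 * steps[k])
  }
  g
}

#' Rotate a probe transform about a fixed point of the image
#'
#' Post-composes `T` with an in-plane rotation about `center` (probe-1
#' frame). Rotations about the imaged vessel are the weakly identified
#' direction of the coherence objective: they leave the vessel position
#' fixed while rotating the probe around it.
#'
#' @param T a [rigid_transform()].
#' @param center fixed point, mm (probe-1 frame).
#' @param dphi rotation, degrees.
#' @return the rotated [rigid_transform()].
#' @export
rotate_about <- function(T, center, dphi) {
  R <- rotation_matrix(dphi)
  t_new <- center - as.vector(R %*% center)
  compose_transform(rigid_transform(t_new[1], t_new[2], dphi), T)
}

#' Envelope-based coarse alignment of the two monostatic images
#'
#' Automates the manual initialization step: the log-envelope of the
#' compounded probe-2 monostatic image (reconstructed in its own frame,
#' independent of the hypothesis) is resampled into the probe-1 frame
#' under candidate translations and correlated with the probe-1 image
#' over the region of interest. A coarse grid search is refined by a
#' finer local search. Only the translation is searched: the dominant
#' image feature (the vessel ring) is nearly rotation symmetric, so the
#' residual rotation error collapses onto the rotation-about-vessel
#' direction handled by [register_probes()]'s coherence scan.
#'
#' @param channels_t1r1,channels_t2r2 per-angle [channel_data] lists of
#'   the two monostatic pairings.
#' @param geom1,geom2 probe geometries.
#' @param T_init initial probe-2 transform.
#' @param roi list(x = range, z = range), mm, the registration region.
#' @param c speed of sound, m/s.
#' @param search_mm half-extent of the coarse translation search.
#' @param coarse_step,fine_step search steps, mm.
#' @param dynamic_range log-compression range for the correlation, dB.
#' @return list with `T` (updated transform), `score` (best normalized
#'   correlation).
#' @export
coarse_align_envelope <- function(channels_t1r1, channels_t2r2,
                                  geom1, geom2, T_init, roi, c = 1540,
                                  search_mm = 7, coarse_step = 1,
                                  fine_step = 0.25,
                                  dynamic_range = 40) {
  lambda_mm <- c / geom1$f0 * 1e3
  grid1 <- cartesian_grid(roi$x, roi$z, lambda_mm / 2)
  img1 <- beamform_pairing(channels_t1r1, geom1, geom1, grid = grid1, c = c)
  e1 <- envelope_log(img1, dynamic_range)
  # probe-2 image on its own grid covering the ROI seen from probe 2
  corners <- cbind(rep(roi$x, each = 2), rep(roi$z, times = 2))
  loc <- apply_transform(invert_transform(T_init), corners)
  pad <- search_mm + 2
  grid2 <- cartesian_grid(range(loc[, 1]) + c(-pad, pad),
                          range(loc[, 2]) + c(-pad, pad), lambda_mm / 2)
  img2 <- beamform_pairing(channels_t2r2, geom2, geom2, grid = grid2, c = c)
  e2 <- envelope_log(img2, dynamic_range)
  pts <- grid_points(grid1)

  score_shift <- function(dtx, dtz) {
    Tc <- rigid_transform(T_init$tx + dtx, T_init$tz + dtz, T_init$phi)
    p_loc <- apply_transform(invert_transform(Tc), pts)
    fi <- (p_loc[, 2] - grid2$z[1]) / grid2$spacing[2] + 1
    fj <- (p_loc[, 1] - grid2$x[1]) / grid2$spacing[1] + 1
    v <- bilinear_na(e2, fi, fj)
    ok <- !is.na(v)
    if (sum(ok) < 100) return(-Inf)
    a <- e1[ok]; b <- v[ok]
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(-Inf)
    sum(a * b) / den
  }
  best <- c(0, 0); best_s <- -Inf
  for (dx in seq(-search_mm, search_mm, by = coarse_step))
    for (dz in seq(-search_mm, search_mm, by = coarse_step)) {
      s <- score_shift(dx, dz)
      if (s > best_s) { best_s <- s; best <- c(dx, dz) }
    }
  for (dx in best[1] + seq(-coarse_step, coarse_step, by = fine_step))
    for (dz in best[2] + seq(-coarse_step, coarse_step, by = fine_step)) {
      s <- score_shift(dx, dz)
      if (s > best_s) { best_s <- s; best <- c(dx, dz) }
    }
  list(T = rigid_transform(T_init$tx + best[1], T_init$tz + best[2],
                           T_init$phi),
       score = best_s)
}

#' Automatic probe localization by gradient descent on trans-probe
#' coherence
#'
#' Minimizes the negative signal power of the compounded trans-probe
#' image over the probe-2 rigid transform, `T <- T - mu grad(P-)`.
#' Optionally, two initialization stages precede the descent: an
#' envelope-correlation alignment of the two monostatic images (the
#' automated analogue of manual initialization; see
#' [coarse_align_envelope()]) and a 1-D scan of the coherence objective
#' along the rotation-about-vessel direction, which the translation
#' alignment cannot resolve. The descent itself uses the numerical
#' gradient (central differences, six evaluations per iteration), takes
#' steps along the negative gradient direction scaled per parameter by
#' the current learning rates `mu`, halves `mu` whenever a step would
#' increase the objective, and grows it by 30% after accepted steps.
#' Convergence is declared when the objective change stays within `tol`
#' (5%) of the total improvement since the start for `patience` (3)
#' consecutive iterations; an objective growing for 10 consecutive
#' proposals flags divergence and the best-seen transform is returned.
#'
#' @param channels_t1r2 list of T1R2 [channel_data] per steering angle.
#' @param geom1,geom2 probe geometries.
#' @param T_init initial [rigid_transform()] (arch read-out / manual
#'   alignment).
#' @param grid registration grid; if NULL, a half-wavelength Cartesian
#'   grid over `roi` is built.
#' @param roi list(x = range, z = range) in mm for the default grid.
#' @param c speed of sound, m/s.
#' @param mu length-3 initial step scale `c(tx mm, tz mm, phi deg)`.
#' @param grad_steps finite-difference steps `c(mm, mm, deg)`; default
#'   quarter wavelength for translations and 0.1 degree for rotation.
#' @param max_iter iteration budget of the descent.
#' @param patience consecutive small changes required for convergence.
#' @param tol relative band of the convergence rule.
#' @param prealign NULL, or a list with `T1R1` and `T2R2` per-angle
#'   channel lists enabling the envelope pre-alignment.
#' @param rotation_scan logical: scan the rotation-about-vessel direction
#'   before the descent.
#' @param scan_center fixed point of the rotation scan (default: ROI
#'   center).
#' @param scan_range,scan_step extent and step of the rotation scan,
#'   degrees.
#' @param rx_decim receive-element decimation for objective evaluations
#'   (see [registration_objective()]).
#' @param verbose print progress.
#' @return an object of class `registration_state`: `T` (best estimate),
#'   `objective_history`, `iteration`, `converged`, `diverged`,
#'   `prealign_score`, `T_history`.
#' @export
register_probes <- function(channels_t1r2, geom1, geom2, T_init,
                            grid = NULL, roi = NULL, c = 1540,
                            mu = c(1, 1, 0.5), grad_steps = NULL,
                            max_iter = 50, patience = 3, tol = 0.05,
                            prealign = NULL, rotation_scan = !is.null(prealign),
                            scan_center = NULL, scan_range = 4,
                            scan_step = 0.5, rx_decim = 1, verbose = FALSE) {
  lambda_mm <- c / geom1$f0 * 1e3
  if (is.null(grad_steps)) grad_steps <- c(lambda_mm / 4, lambda_mm / 4, 0.1)
  if (is.null(roi)) roi <- list(x = c(-16, 16), z = c(24, 56))
  if (is.null(grid)) grid <- cartesian_grid(roi$x, roi$z, lambda_mm / 2)
  if (is.null(scan_center)) scan_center <- c(mean(roi$x), mean(roi$z))
  channels_t1r2 <- lapply(channels_t1r2, demodulate)
  f <- function(T) registration_objective(T, channels_t1r2, geom1, geom2,
                                          grid, c, rx_decim = rx_decim)
  say <- function(...) if (verbose) message(sprintf(...))
  T_cur <- T_init
  pre_score <- NA_real_
  if (!is.null(prealign)) {
    ca <- coarse_align_envelope(prealign$T1R1, prealign$T2R2, geom1, geom2,
                                T_cur, roi, c)
    T_cur <- ca$T
    pre_score <- ca$score
    say("prealign: shift (%.2f, %.2f) mm, score %.3f",
        T_cur$tx - T_init$tx, T_cur$tz - T_init$tz, ca$score)
  }
  if (rotation_scan) {
    dphis <- seq(-scan_range, scan_range, by = scan_step)
    ps <- vapply(dphis, function(d) f(rotate_about(T_cur, scan_center, d)),
                 numeric(1))
    k <- which.min(ps)
    d_best <- dphis[k]
    if (k > 1 && k < length(dphis)) {
      den <- ps[k - 1] - 2 * ps[k] + ps[k + 1]
      if (den > 0)                       # concave-up minimum: refine
        d_best <- d_best + scan_step *
          max(-0.5, min(0.5, (ps[k - 1] - ps[k + 1]) / (2 * den)))
    }
    T_cur <- rotate_about(T_cur, scan_center, d_best)
    say("rotation scan: dphi %.3f deg", d_best)
  }
  p_cur <- f(T_cur)
  history <- p_cur
  T_hist <- list(T_cur)
  best <- list(T = T_cur, p = p_cur)
  mu_cur <- mu
  converged <- FALSE
  still <- 0L
  grow <- 0L
  diverged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- numerical_gradient(f, T_cur, grad_steps)
    gs <- g * mu_cur                       # gradient in scaled parameters
    gn <- sqrt(sum(gs^2))
    if (gn == 0) {
      # degenerate step (zero learning rate or flat objective): no motion
      history <- c(history, p_cur); T_hist <- c(T_hist, list(T_cur))
      next
    }
    step <- -mu_cur * gs / gn              # unit step in scaled space
    T_new <- rigid_transform(T_cur$tx + step[1], T_cur$tz + step[2],
                             T_cur$phi + step[3])
    p_new <- f(T_new)
    if (p_new > p_cur) {
      mu_cur <- mu_cur / 2                 # reject, shrink the step
      grow <- grow + 1L
      if (grow >= 10) {
        # ten consecutive rejected proposals: the step size has collapsed
        # at a stationary point - no descent direction remains
        converged <- TRUE
        break
      }
      history <- c(history, p_cur); T_hist <- c(T_hist, list(T_cur))
      next
    }
    grow <- 0L
    mu_cur <- pmin(mu_cur * 1.3, mu)
    delta <- abs(p_new - p_cur)
    T_cur <- T_new
    p_cur <- p_new
    history <- c(history, p_cur)
    T_hist <- c(T_hist, list(T_cur))
    if (p_cur < best$p) best <- list(T = T_cur, p = p_cur)
    improvement <- abs(history[1] - p_cur)
    if (improvement > 0 && delta < tol * improvement) {
      still <- still + 1L
      if (still >= patience) { converged <- TRUE; break }
    } else still <- 0L
    say("iter %2d: P- = %.6g (tx %.3f, tz %.3f, phi %.3f)",
        iter, p_cur, T_cur$tx, T_cur$tz, T_cur$phi)
  }
  structure(list(T = best$T, objective_history = history,
                 iteration = iter, converged = converged,
                 diverged = diverged, mu = mu, prealign_score = pre_score,
                 T_history = T_hist),
            class = "registration_state")
}

#' @export
print.registration_state <- function(x, ...) {
  cat(sprintf(
    "probe registration: %s after %d iterations, P- %.4g -> %.4g\n",
    if (x$converged) "converged" else if (x$diverged) "diverged (best kept)"
    else "iteration budget reached",
    x$iteration, x$objective_history[1],
    x$objective_history[length(x$objective_history)]))
  print(x$T)
  invisible(x)
}
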