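#' Time offset between the two probes' transmit bursts
#'
#' In interleaved dual-probe acquisition each probe fires its full burst
#' of steered transmits before the other probe starts, so the data of the
#' two probes are separated by `n_transmits / prf`.
#'
#' @param prf pulse repetition frequency, Hz.
#' @param n_transmits transmits per probe per frame.
#' @return offset in seconds.
#' @export
interprobe_time_offset <- function(prf, n_transmits) {
  if (prf <= 0) stop("prf must be positive", call. = FALSE)
  n_transmits / prf
}

#' Full pipeline configuration
#'
#' Bundles the scene, acquisition, pulsation, registration, tracking,
#' strain and metrics settings of an end-to-end run.
#'
#' @param seed integer seed recorded in every artifact.
#' @param scene a [phantom_config()].
#' @param acq an [acquisition_config()].
#' @param model a [pulsation_model()].
#' @param register list: `init_error` c(mm, mm, deg) added to the true
#'   transform to emulate the manual arch-based initialization, `mu`,
#'   `max_iter`, `roi` (list(x=, z=) or NULL for a box around the vessel).
#' @param track list: `i_stride` (node lattice stride in axial samples),
#'   `depth_pad` (mm of sector grid beyond the vessel), kernel/search
#'   overrides (NULL keeps [track_pairing()] defaults).
#' @param strain list: `n_circ` circumferential nodes (NULL: 5 nodes per
#'   2.6 mm at the rest mid-wall radius), `n_layers`, `kernel`.
#' @param metrics list: `dynamic_range`, `n_bins`, `exclusion_deg`,
#'   `anchor` (right-transducer beam direction).
#' @param mode `"bistatic"` or `"single_perspective"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            scene = phantom_config(),
                            acq = acquisition_config(),
                            model = pulsation_model(),
                            register = list(init_error = c(5, 5, 3),
                                            mu = c(1, 1, 0.5),
                                            max_iter = 50, roi = NULL),
                            track = list(i_stride = 4, depth_pad = 4),
                            strain = list(n_circ = NULL, n_layers = 5,
                                          kernel = c(5, 5)),
                            metrics = list(dynamic_range = 50, n_bins = 256,
                                           exclusion_deg = 37.5,
                                           anchor = c(0, 1)),
                            mode = c("bistatic", "single_perspective")) {
  structure(list(seed = as.integer(seed), scene = scene, acq = acq,
                 model = model, register = register, track = track,
                 strain = strain, metrics = metrics,
                 mode = match.arg(mode)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Scalar fields override the defaults of [pipeline_config()] section by
#' section.
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (sec in intersect(names(raw), c("scene", "acq", "model", "register",
                                      "track", "strain", "metrics"))) {
    for (nm in names(raw[[sec]])) {
      v <- raw[[sec]][[nm]]
      # YAML sequences of mixed int/double scalars parse as lists
      if (is.list(v) && all(vapply(v, function(x)
        is.atomic(x) && length(x) == 1, logical(1)))) v <- unlist(v)
      cfg[[sec]][[nm]] <- v
    }
  }
  if (!is.null(raw[["seed"]])) cfg$seed <- as.integer(raw[["seed"]])
  if (!is.null(raw[["mode"]])) cfg$mode <- raw[["mode"]]
  if (!is.null(raw[["acq"]])) {
    a <- cfg$acq
    cfg$acq <- do.call(acquisition_config,
                       a[setdiff(names(a), "T_probe2")])
    if (!is.null(a$T_probe2) && !inherits(a$T_probe2, "rigid_transform"))
      cfg$acq$T_probe2 <- do.call(rigid_transform, as.list(a$T_probe2))
    else if (inherits(a$T_probe2, "rigid_transform"))
      cfg$acq$T_probe2 <- a$T_probe2
  }
  # the pulsation model is a constructed object: rebuild it from its
  # parameters, defaulting the rest geometry to the scene
  m_args <- list(inner_radius_rest = cfg$scene$inner_radius,
                 wall_thickness_rest = cfg$scene$wall_thickness)
  if (!is.null(raw[["model"]]))
    for (nm in names(raw[["model"]])) {
      v <- raw[["model"]][[nm]]
      if (is.list(v)) v <- unlist(v)
      m_args[[nm]] <- v
    }
  cfg$model <- do.call(pulsation_model, m_args)
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

vessel_depth_range <- function(config, T_probe) {
  # depth band (along-beam, probe local) covering the vessel plus padding
  ctr <- config$scene$center
  r_out <- config$scene$inner_radius + config$scene$wall_thickness
  pad <- config$track$depth_pad %||% 4
  loc <- apply_transform(invert_transform(T_probe), ctr)
  d <- sqrt(loc[1]^2 + (loc[2] + config$acq$radius)^2) - config$acq$radius
  c(d - r_out - pad, d + r_out + pad)
}

rest_inner_contour <- function(config, n_circ = NULL) {
  # circular lumen-wall segmentation at rest (the phantom's true border)
  ri <- config$scene$inner_radius
  h <- config$scene$wall_thickness
  if (is.null(n_circ)) {
    spacing <- 2.6 / 4                   # 5 nodes spanning 2.6 mm
    n_circ <- max(16, round(2 * pi * (ri + h / 2) / spacing))
  }
  a <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  cbind(config$scene$center[1] + ri * sin(a),
        config$scene$center[2] - ri * cos(a))
}

pl_require <- function(run, section, stage_needed, producer) {
  if (is.null(run[[section]]))
    stop(sprintf("pipeline stage '%s' requires the '%s' section; run the '%s' stage first",
                 stage_needed, section, producer), call. = FALSE)
}

#' Run the end-to-end dual-aperture pipeline
#'
#' Executes a contiguous prefix of the stages simulate, beamform,
#' register, track, strain, metrics on a shared run container. Each stage
#' reads the previous stage's section and adds its own; a missing upstream
#' section raises an error naming the stage to run. In
#' `single_perspective` mode only the T1R1 signal is used throughout
#' (no trans-probe data, no registration, no radial projection).
#'
#' @param config a [pipeline_config()].
#' @param stages character vector, contiguous prefix of
#'   `c("simulate", "beamform", "register", "track", "strain", "metrics")`.
#' @param run an existing container (environment) from a previous call,
#'   to continue a run; NULL starts fresh.
#' @param out_dir optional directory; sections are saved as .rds plus a
#'   JSON meta record.
#' @param verbose print stage progress.
#' @return the run container (environment) with sections `sim`, `images`,
#'   `register`, `track`, `strain`, `metrics`, plus `config`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "beamform", "register",
                                    "track", "strain", "metrics"),
                         run = NULL, out_dir = NULL, verbose = FALSE) {
  all_stages <- c("simulate", "beamform", "register", "track", "strain",
                  "metrics")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  single <- config$mode == "single_perspective"
  if (is.null(run)) {
    run <- new.env(parent = emptyenv())
    run$config <- config
    run$seed <- config$seed
    run$config_hash <- config_hash(config)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  lambda_mm <- config$acq$c / config$acq$f0 * 1e3
  id <- rigid_transform()

  current_T2 <- function() {
    if (!is.null(run$register)) run$register$T
    else if (!is.null(run$T2_init)) run$T2_init
    else config$acq$T_probe2
  }

  cart_grid_vessel <- function(spacing) {
    ctr <- config$scene$center
    ext <- config$scene$inner_radius + config$scene$wall_thickness + 4
    cartesian_grid(c(ctr[1] - ext, ctr[1] + ext),
                   c(ctr[2] - ext, ctr[2] + ext), spacing)
  }

  beamform_cart <- function(T2) {
    g4 <- cart_grid_vessel(lambda_mm / 4)
    sim <- run$sim
    f1 <- sim$frames[[1]]
    g1 <- sim$geoms$geom1; g2 <- sim$geoms$geom2
    i11 <- beamform_pairing(f1$T1R1, g1, g1, id, id, g4, config$acq$c)
    if (single) return(list(grid = g4, single = i11, bistatic = NULL))
    i22 <- beamform_pairing(f1$T2R2, g2, g2, T2, T2, g4, config$acq$c)
    i12 <- beamform_pairing(f1$T1R2, g1, g2, id, T2, g4, config$acq$c)
    i21 <- beamform_pairing(f1$T2R1, g2, g1, T2, id, g4, config$acq$c)
    list(grid = g4, single = i11,
         bistatic = bistatic_compound(i11, i22, i12, i21),
         pairings = list(T1R1 = i11, T2R2 = i22, T1R2 = i12, T2R1 = i21))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      say("simulate: %d frames", length(config$model$radius_waveform))
      run$sim <- simulate_cycle(config$scene, config$acq, config$model,
                                config$seed)
      # manual initialization of the registration: true placement plus the
      # configured read-out error
      ie <- config$register$init_error %||% c(5, 5, 3)
      Tt <- config$acq$T_probe2
      run$T2_init <- rigid_transform(Tt$tx + ie[1], Tt$tz + ie[2],
                                     Tt$phi + ie[3])
    } else if (stage == "beamform") {
      pl_require(run, "sim", "beamform", "simulate")
      say("beamform: quarter-wavelength vessel images")
      run$images <- beamform_cart(current_T2())
    } else if (stage == "register") {
      if (single) { say("register: skipped (single-perspective mode)"); next }
      pl_require(run, "sim", "register", "simulate")
      say("register: trans-probe coherence optimization")
      roi <- config$register$roi
      if (is.null(roi)) {
        ctr <- config$scene$center
        ext <- config$scene$inner_radius + config$scene$wall_thickness + 5
        roi <- list(x = c(ctr[1] - ext, ctr[1] + ext),
                    z = c(ctr[2] - ext, ctr[2] + ext))
      }
      run$register <- register_probes(
        run$sim$frames[[1]]$T1R2, run$sim$geoms$geom1, run$sim$geoms$geom2,
        T_init = run$T2_init, roi = roi, c = config$acq$c,
        mu = config$register$mu %||% c(1, 1, 0.5),
        max_iter = config$register$max_iter %||% 50,
        prealign = list(T1R1 = run$sim$frames[[1]]$T1R1,
                        T2R2 = run$sim$frames[[1]]$T2R2),
        rotation_scan = TRUE, scan_center = config$scene$center,
        rx_decim = config$register$rx_decim %||% 2,
        verbose = verbose)
      if (!is.null(run$images)) run$images <- beamform_cart(run$register$T)
    } else if (stage == "track") {
      pl_require(run, "sim", "track", "simulate")
      if (!single) pl_require(run, "register", "track", "register")
      T2 <- current_T2()
      sim <- run$sim
      g1 <- sim$geoms$geom1; g2 <- sim$geoms$geom2
      gr1 <- sector_grid(g1, vessel_depth_range(config, id), config$acq$c)
      say("track: sector beamforming %d frames", length(sim$frames))
      istr <- config$track$i_stride %||% 4
      bf_seq <- function(pairing, tx_geom, rx_geom, T_tx, T_rx, grid)
        lapply(sim$frames, function(f)
          beamform_pairing(f[[pairing]], tx_geom, rx_geom, T_tx, T_rx,
                           grid, config$acq$c))
      s11 <- bf_seq("T1R1", g1, g1, id, id, gr1)
      fields <- vector("list", length(sim$frames) - 1)
      if (single) {
        for (k in seq_along(fields))
          fields[[k]] <- list(T1R1 = track_pairing(
            s11[[k]], s11[[k + 1]],
            i_idx = seq(1, length(gr1$depths), by = istr)))
      } else {
        gr2 <- sector_grid(g2, vessel_depth_range(config, T2), config$acq$c)
        s22 <- bf_seq("T2R2", g2, g2, T2, T2, gr2)
        s12 <- bf_seq("T1R2", g1, g2, id, T2, gr2)
        s21 <- bf_seq("T2R1", g2, g1, T2, id, gr1)
        say("track: speckle tracking %d frame pairs", length(fields))
        ii1 <- seq(1, length(gr1$depths), by = istr)
        ii2 <- seq(1, length(gr2$depths), by = istr)
        for (k in seq_along(fields)) {
          fields[[k]] <- list(
            T1R1 = track_pairing(s11[[k]], s11[[k + 1]], i_idx = ii1),
            T2R2 = track_pairing(s22[[k]], s22[[k + 1]], i_idx = ii2),
            T1R2 = track_pairing(s12[[k]], s12[[k + 1]], i_idx = ii2),
            T2R1 = track_pairing(s21[[k]], s21[[k + 1]], i_idx = ii1))
        }
      }
      run$track <- list(fields = fields, T2 = T2)
    } else if (stage == "strain") {
      pl_require(run, "track", "strain", "track")
      say("strain: mesh tracking and least-squares estimation")
      inner <- rest_inner_contour(config, config$strain$n_circ)
      mesh0 <- build_wall_mesh(inner, config$scene$wall_thickness,
                               config$strain$n_layers %||% 5,
                               center = config$scene$center)
      geoms <- run$sim$geoms
      T2 <- run$track$T2
      samplers <- lapply(run$track$fields, function(fl) {
        if (single)
          single_perspective_sampler(fl$T1R1, geoms$geom1, id)
        else
          compound_sampler(list(fl$T1R1, fl$T2R2, fl$T1R2, fl$T2R1),
                           config$scene$center, geoms, T2)
      })
      meshes <- track_mesh(mesh0, samplers)
      strains <- least_squares_strain(meshes, reference = 1,
                                      kernel = config$strain$kernel %||%
                                        c(5, 5))
      run$strain <- list(mesh0 = mesh0, meshes = meshes, strains = strains)
    } else if (stage == "metrics") {
      pl_require(run, "strain", "metrics", "strain")
      pl_require(run, "images", "metrics", "beamform")
      say("metrics: gCNR, drift error, SNRe")
      run$metrics <- metric_report(run)
    }
  }
  if (!is.null(out_dir)) save_run(run, out_dir)
  invisible(run)
}

#' Quality metrics of a pipeline run
#'
#' Computes the vessel-lumen gCNR (global and per 45-degree region), the
#' mean drift error over one cardiac cycle (global and per region), and
#' the circumferential/radial SNRe at peak systole on the middle wall
#' layer (lateral sections excluded), for the run's imaging mode.
#'
#' @param run a [run_pipeline()] container with `images` and `strain`.
#' @return a `metric_report` list.
#' @export
metric_report <- function(run) {
  config <- run$config
  single <- config$mode == "single_perspective"
  anchor <- config$metrics$anchor %||% c(0, 1)
  n_bins <- config$metrics$n_bins %||% 256
  img <- if (single) run$images$single else run$images$bistatic
  mesh0 <- run$strain$mesh0
  rois <- make_rois(mesh0, run$images$grid)
  env <- Mod(img$iq)
  g_all <- gcnr(env, rois$wall, rois$lumen, n_bins)
  # per-region gCNR: pixels partitioned by their angle about the center
  pts <- grid_points(run$images$grid)
  preg <- partition_regions(mesh0, anchor, points = pts)
  preg_m <- matrix(preg, nrow(env), ncol(env))
  g_reg <- vapply(1:8, function(r) {
    wa <- rois$wall & preg_m == r
    lu <- rois$lumen & preg_m == r
    if (!any(wa) || !any(lu)) return(NA_real_)
    gcnr(env, wa, lu, n_bins)
  }, numeric(1))

  meshes <- run$strain$meshes
  ed <- end_diastole_frames(meshes)
  me_all <- mean_drift_error(meshes[[ed[1]]], meshes[[ed[2]]])
  a <- mesh_middle_layer(meshes[[ed[1]]])
  b <- mesh_middle_layer(meshes[[ed[2]]])
  drift <- sqrt(rowSums((a - b)^2))
  nreg <- partition_regions(mesh0, anchor)
  me_reg <- vapply(1:8, function(r) mean(drift[nreg == r]), numeric(1))

  # peak systole: frame of maximal inner radius
  rad <- vapply(meshes, function(m) {
    inner <- m$nodes[1, , ]
    mean(sqrt((inner[, 1] - m$center[1])^2 + (inner[, 2] - m$center[2])^2))
  }, numeric(1))
  peak <- which.max(rad)
  st <- run$strain$strains[[peak]]
  L <- mesh0$n_layers
  mid <- if (L %% 2 == 1) (L + 1) / 2 else L %/% 2
  keep <- exclude_lateral_sections(mesh0,
                                   config$metrics$exclusion_deg %||% 37.5,
                                   anchor)
  ec <- st$eps_circ[mid, keep]
  er <- st$eps_rad[mid, keep]
  structure(list(
    mode = config$mode,
    gcnr = list(global = g_all, regional = g_reg),
    me = list(global = me_all, regional = me_reg,
              end_diastole_frames = ed),
    snre_circ = snre(ec), snre_rad = snre(er),
    peak_frame = peak,
    eps_circ_mid = st$eps_circ[mid, ],
    eps_rad_mid = st$eps_rad[mid, ],
    kept_nodes = keep,
    seed = run$seed, config_hash = run$config_hash),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report (%s):\n", x$mode))
  cat(sprintf("  gCNR (wall vs lumen): %.3f\n", x$gcnr$global))
  cat(sprintf("  mean drift error:     %.3f mm (frames %d -> %d)\n",
              x$me$global, x$me$end_diastole_frames[1],
              x$me$end_diastole_frames[2]))
  cat(sprintf("  SNRe circumferential: %.1f dB\n", x$snre_circ))
  cat(sprintf("  SNRe radial:          %.1f dB\n", x$snre_rad))
  invisible(x)
}

#' Persist a run container to a directory
#'
#' Writes each section as an .rds file plus a `meta.json` record with the
#' seed and configuration hash.
#' @param run a [run_pipeline()] container.
#' @param out_dir target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
save_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sec in intersect(c("sim", "images", "register", "track", "strain",
                          "metrics", "config", "T2_init"), names(run)))
    saveRDS(run[[sec]], file.path(out_dir, paste0(sec, ".rds")))
  jsonlite::write_json(list(seed = run$seed, config_hash = run$config_hash,
                            sections = names(run)),
                       file.path(out_dir, "meta.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Load a persisted run container
#' @param dir directory written by [save_run()].
#' @return a run container environment.
#' @export
load_run <- function(dir) {
  run <- new.env(parent = emptyenv())
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  run$seed <- meta$seed
  run$config_hash <- meta$config_hash
  for (f in list.files(dir, pattern = "[.]rds$", full.names = TRUE))
    run[[sub("[.]rds$", "", basename(f))]] <- readRDS(f)
  run
}
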