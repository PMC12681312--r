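# Session containers and the end-to-end demonstration chain:
# simulate -> recon (corrected / uncorrected) -> metrics. A session is a
# directory of standard formats: NIfTI images, TSV traces/confounds, YAML
# config, JSON reports; complex k-space containers are .rds arrays with JSON
# sidecars.

#' Default session configuration
#'
#' The desk-scale analog of the in-vivo protocol: a 12-fold (3 x 4 CAIPI)
#' accelerated multi-shot 3D-EPI acquisition with two interleaves per kz
#' plane, an embedded 4 x 2 accelerated navigator, 16 receive channels,
#' smooth-drift head motion up to 2 mm / 2 deg and a slow linear field
#' drift.
#'
#' @param seed master seed for all generators.
#' @return nested config list (see the YAML written by [simulate_session()]).
#' @export
default_session_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(shape = c(32L, 30L, 24L), voxel_mm = c(6, 6, 6)),
    n_coils = 16L,
    n_tissues = 3L,
    accel = c(3L, 4L),
    caipi_shift = 1L,
    n_interleaves = 2L,
    tr = 0.039,
    te = 0.021,
    echo_spacing = 0.00047,
    n_volumes = 6L,
    kspace_noise_sd = 0.0,
    nav = list(shape = c(16L, 16L, 16L), accel = c(4L, 2L),
               lines_per_tr = 8L, echo_spacing = 0.00047, te = 0.008,
               acs = c(16L, 12L)),
    motion = list(max_translation_mm = 2, max_rotation_deg = 2,
                  style = "smooth_drift"),
    field = list(max_g0_hz = 2, max_grad_hz_per_mm = 0.005),
    bold = list(band = c(0.01, 0.08), amplitude = 0.08, noise_sd = 0.0,
                n_parcels = 4L)
  )
}

validate_config <- function(config) {
  required <- c("seed", "grid", "n_coils", "accel", "tr", "te",
                "echo_spacing", "n_volumes", "nav", "motion", "field", "bold")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")))
  }
  invisible(config)
}

write_nifti_vol <- function(vol, grid, path, tr = NULL) {
  img <- RNifti::asNifti(vol)
  pd <- grid$voxel_size
  if (!is.null(tr) && length(dim(vol)) == 4) pd <- c(pd, tr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Simulate a complete synthetic session
#'
#' Generates the phantom, coil maps, motion/field trajectories and BOLD-like
#' dynamics, simulates the accelerated multi-shot imaging acquisition (one
#' k-space container per volume, with per-shot encoding states drawn from
#' the trajectories) and the embedded accelerated navigator frames, and
#' writes everything under `dir` with a provenance record.
#'
#' @param config a config list (see [default_session_config()]) or a path to
#'   a YAML file with the same structure.
#' @param dir output session directory (created).
#' @param quiet suppress progress messages.
#' @return the session directory path, invisibly.
#' @export
simulate_session <- function(config = default_session_config(), dir,
                             quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("kspace", "nav", "traces", "recon", "metrics")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  seed <- config$seed
  grid <- grid3d(unlist(config$grid$shape), unlist(config$grid$voxel_mm))
  say("phantom + maps on %s grid", paste(grid$shape, collapse = "x"))
  ph <- make_phantom(phantom_spec(grid, config$n_tissues, seed))
  coils <- make_coil_sensitivities(grid, config$n_coils, seed)

  pattern <- build_caipi_pattern(grid$shape, config$accel[1], config$accel[2],
                                 caipi_shift = config$caipi_shift,
                                 n_interleaves = config$n_interleaves,
                                 echo_spacing = config$echo_spacing,
                                 te = config$te)
  trs_per_volume <- max(pattern$lines$tr_index) + 1
  volume_tr <- trs_per_volume * config$tr

  nav_grid <- grid3d(unlist(config$nav$shape),
                     grid_fov(grid) / unlist(config$nav$shape))
  nav_sched <- build_navigator_schedule(unlist(config$nav$shape),
                                        unlist(config$nav$accel),
                                        config$nav$lines_per_tr,
                                        config$nav$echo_spacing, config$tr,
                                        te = config$nav$te)
  # navigator frames span the whole run
  run_duration <- config$n_volumes * volume_tr
  n_frames <- max(2L, ceiling(run_duration / nav_sched$frame_interval) + 1L)
  motion <- make_motion_trace(n_frames, config$motion$max_translation_mm,
                              config$motion$max_rotation_deg,
                              style = config$motion$style, seed = seed,
                              frame_interval = nav_sched$frame_interval)
  field <- make_field_trace(n_frames, config$field$max_g0_hz,
                            config$field$max_grad_hz_per_mm, seed = seed,
                            frame_interval = nav_sched$frame_interval)

  say("BOLD dynamics: %d volumes at TR %.3g s", config$n_volumes, volume_tr)
  bold <- simulate_bold_series(ph, config$n_volumes, volume_tr,
                               band = unlist(config$bold$band),
                               amplitude = config$bold$amplitude,
                               noise_sd = config$bold$noise_sd,
                               n_parcels = config$bold$n_parcels, seed = seed)

  say("simulating %d accelerated volumes", config$n_volumes)
  for (v in seq_len(config$n_volumes)) {
    state <- states_from_traces(pattern, v, config$tr, motion, field)
    kd <- simulate_kspace(bold$series$data[, , , v] + 0i, coils, state,
                          pattern, grid,
                          noise_sd = config$kspace_noise_sd, seed = seed + v)
    saveRDS(kd, file.path(dir, "kspace", sprintf("volume_%03d.rds", v)))
    jsonlite::write_json(
      list(volume = v, n_channels = config$n_coils,
           n_lines = nrow(pattern$lines), accel = unname(pattern$accel),
           tr = config$tr, te = config$te),
      file.path(dir, "kspace", sprintf("volume_%03d.json", v)),
      auto_unbox = TRUE)
  }

  say("simulating %d navigator frames", n_frames)
  nav_ph <- make_phantom(phantom_spec(nav_grid, config$n_tissues, seed))
  nav_coils <- make_coil_sensitivities(nav_grid, config$n_coils, seed)
  nav <- simulate_navigator_frames(nav_ph$image, nav_grid, nav_coils,
                                   nav_sched, motion, field,
                                   acs_size = unlist(config$nav$acs),
                                   noise_sd = config$kspace_noise_sd,
                                   seed = seed + 1000)
  saveRDS(nav, file.path(dir, "nav", "frames.rds"))

  write_nifti_vol(ph$image, grid, file.path(dir, "phantom.nii.gz"))
  write_nifti_vol(ph$mask + 0, grid, file.path(dir, "mask.nii.gz"))
  write_nifti_vol(bold$parcel_labels, grid, file.path(dir, "parcels.nii.gz"))
  saveRDS(list(coils = coils, nav_coils = nav_coils, grid = grid,
               nav_grid = nav_grid, pattern = pattern, nav_sched = nav_sched,
               bold_truth = bold$series, gt_amplitude = bold$gt_amplitude),
          file.path(dir, "session.rds"))
  write_trace_tsv(motion, field, file.path(dir, "traces",
                                           "ground_truth.tsv"))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = seed,
         software = sprintf("epinav %s",
                            as.character(utils::packageVersion("epinav"))),
         config_md5 = unname(tools::md5sum(file.path(dir, "config.yaml"))),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Reconstruct a session's BOLD series
#'
#' Runs the navigator pipeline (GRAPPA, registration, field fit) to estimate
#' motion/field traces, then reconstructs the run volume-by-volume in the
#' requested mode. The estimated traces are written as TSV; the magnitude
#' series as 4D NIfTI with the volume TR in `pixdim[4]`.
#'
#' @param dir session directory from [simulate_session()].
#' @param mode `"corrected"` or `"uncorrected"`.
#' @param max_iter,tol CG settings shared by both modes.
#' @param quiet suppress progress messages.
#' @return the reconstructed [time_series_4d()], invisibly.
#' @export
recon_session <- function(dir, mode = c("corrected", "uncorrected"),
                          max_iter = 40, tol = 1e-6, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(sprintf(...))
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  ses <- readRDS(file.path(dir, "session.rds"))
  nav <- readRDS(file.path(dir, "nav", "frames.rds"))

  trace_path <- file.path(dir, "traces", "estimated.tsv")
  if (!file.exists(trace_path)) {
    say("navigator pipeline: %d frames", length(nav$frames))
    kern <- grappa_calibrate(nav$acs, ses$nav_sched$pattern$accel[1],
                             ses$nav_sched$pattern$accel[2],
                             ses$nav_sched$pattern$caipi_shift)
    est <- navigator_pipeline(nav$frames, kern, ses$nav_grid,
                              nav_te = ses$nav_sched$nav_te,
                              combine = ses$nav_coils,
                              frame_interval = ses$nav_sched$frame_interval)
    write_trace_tsv(est$motion, est$field, trace_path)
  }
  est_frames <- read_motion_tsv(trace_path)
  tsv <- read.delim(trace_path)
  motion <- structure(list(frames = est_frames,
                           frame_interval = ses$nav_sched$frame_interval),
                      class = "motion_trace")
  field <- structure(list(g0 = tsv$g0, gx = tsv$gx, gy = tsv$gy, gz = tsv$gz,
                          frame_interval = ses$nav_sched$frame_interval),
                     class = "field_trace")

  files <- sort(list.files(file.path(dir, "kspace"), pattern = "\\.rds$",
                           full.names = TRUE))
  run <- lapply(files, readRDS)
  say("reconstructing %d volumes (%s)", length(run), mode)
  series <- reconstruct_series(run, ses$coils, config$tr, motion, field,
                               mode = mode, max_iter = max_iter, tol = tol)
  write_nifti_vol(series$data, ses$grid,
                  file.path(dir, "recon", sprintf("bold_%s.nii.gz", mode)),
                  tr = series$tr_volume)
  invisible(series)
}

#' Compute the evaluation metrics of a reconstructed session
#'
#' For every reconstructed mode present: tSNR, FD of residual realignment
#' (registration of each reconstructed volume to the first), DVARS, outlier
#' flags, band-pass + confound-regression denoising, ALFF, ReHo and the
#' parcel FC matrix. Writes metric maps as NIfTI and a JSON report with
#' in-mask summaries and histograms, including the corrected-vs-uncorrected
#' comparison when both modes exist.
#'
#' @param dir session directory with at least one reconstruction.
#' @param quiet suppress progress messages.
#' @return the report list, invisibly.
#' @export
metrics_session <- function(dir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  ses <- readRDS(file.path(dir, "session.rds"))
  mask <- array(RNifti::readNifti(file.path(dir, "mask.nii.gz")) > 0,
                dim = ses$grid$shape)
  parcels <- array(as.integer(
    RNifti::readNifti(file.path(dir, "parcels.nii.gz"))),
    dim = ses$grid$shape)
  modes <- c("corrected", "uncorrected")
  modes <- modes[file.exists(file.path(dir, "recon",
                                       sprintf("bold_%s.nii.gz", modes)))]
  if (!length(modes)) stop("no reconstructions found; run recon_session()")
  report <- list()
  fcs <- list()
  for (mode in modes) {
    say("metrics for %s mode", mode)
    img <- RNifti::readNifti(file.path(dir, "recon",
                                       sprintf("bold_%s.nii.gz", mode)))
    tr_vol <- RNifti::pixdim(img)[4]
    series <- time_series_4d(array(img, dim = dim(img)), ses$grid, tr_vol)
    nvol <- dim(series$data)[4]

    # residual realignment of the reconstructed volumes themselves
    ref <- series$data[, , , 1]
    realign <- lapply(seq_len(nvol), function(v) {
      if (v == 1) rigid_identity() else {
        suppressWarnings(
          estimate_motion(series$data[, , , v], ref, ses$grid,
                          pyramid_levels = 1, max_iter = 40))
      }
    })
    fd <- framewise_displacement(rigid_params(realign))
    # resample every volume back to the reference pose (single
    # interpolation), as the preprocessing chain does after estimating
    # head-motion parameters
    for (v in seq_len(nvol)[-1]) {
      series$data[, , , v] <- apply_rigid(series$data[, , , v], ses$grid,
                                          invert_rigid(realign[[v]],
                                                       grid_center(ses$grid)))
    }
    sdv <- dvars(series, mask, standardize = TRUE)
    outliers <- flag_motion_outliers(fd, sdv)

    ts_map <- tsnr(series, mask)
    # 36P confounds from realignment parameters + tissue means
    mp <- rigid_params(realign)
    X <- series_matrix(series)
    # tissue surrogates from phantom intensity terciles inside the mask
    ph <- as.vector(RNifti::readNifti(file.path(dir, "phantom.nii.gz")))
    qv <- quantile(ph[as.vector(mask)], c(1 / 3, 2 / 3))
    base <- cbind(mp,
                  global_signal = colMeans(X[as.vector(mask), , drop = FALSE]),
                  wm = colMeans(X[as.vector(mask) & ph > qv[2], ,
                                  drop = FALSE]),
                  csf = colMeans(X[as.vector(mask) & ph <= qv[1], ,
                                   drop = FALSE]))
    # spend nuisance dof only when the run affords them: full 36P on long
    # runs, the 9 base signals on medium runs, global signal alone on the
    # shortest demo runs
    conf <- if (nvol > 45) expand_confounds_36p(base)
            else if (nvol > 12) base
            else base[, "global_signal", drop = FALSE]
    fs <- 1 / tr_vol
    band <- unlist(config$bold$band)
    # short demo runs cannot resolve the canonical low-frequency band; fall
    # back to the full resolvable band (first nonzero FFT bin to 0.45 fs)
    if (sum((0:(nvol %/% 2)) * fs / nvol >= band[1] &
            (0:(nvol %/% 2)) * fs / nvol <= band[2]) < 2) {
      band <- c(fs / nvol * 0.9, 0.45 * fs)
    }
    filt <- bandpass_butterworth(series, band[1], band[2], fs = fs)
    conf_f <- bandpass_butterworth(conf, band[1], band[2], fs = fs)
    den <- regress_confounds(filt, conf_f)
    alff_map <- alff(den, band, fs = fs, mask = mask)
    reho_map <- reho_kcc(den, mask)
    fc <- fc_matrix(den, parcels)
    fcs[[mode]] <- fc

    for (nm in c("tsnr", "alff", "reho")) {
      mp3 <- switch(nm, tsnr = ts_map, alff = alff_map, reho = reho_map)
      write_nifti_vol(array(mp3, dim = ses$grid$shape), ses$grid,
                      file.path(dir, "metrics",
                                sprintf("%s_%s.nii.gz", nm, mode)))
    }
    hist_t <- hist(ts_map[mask], breaks = 20, plot = FALSE)
    conf_out <- data.frame(conf, framewise_displacement = fd,
                           std_dvars = sdv, motion_outlier = as.integer(outliers))
    write.table(conf_out,
                file.path(dir, "metrics", sprintf("confounds_%s.tsv", mode)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report[[mode]] <- list(
      mean_tsnr = mean(ts_map[mask]),
      max_tsnr = max(ts_map[mask]),
      mean_fd = mean(fd),
      max_fd = max(fd),
      n_outliers = sum(outliers),
      mean_alff = mean(alff_map[mask]),
      max_alff = max(alff_map[mask]),
      mean_reho = mean(reho_map[mask]),
      mean_reho_parcels = mean(reho_map[parcels > 0]),
      tsnr_histogram = list(breaks = hist_t$breaks, counts = hist_t$counts))
  }
  if (length(modes) == 2) {
    report$comparison <- list(
      tsnr_gain = report$corrected$mean_tsnr / report$uncorrected$mean_tsnr,
      fd_reduction = 1 - report$corrected$mean_fd /
        max(report$uncorrected$mean_fd, .Machine$double.eps),
      fc_mean_abs_difference = compare_fc(fcs$corrected, fcs$uncorrected))
  }
  jsonlite::write_json(report, file.path(dir, "metrics", "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
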