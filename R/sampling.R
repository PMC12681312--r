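# CAIPI-accelerated 3D-EPI sampling patterns, navigator schedules and protocol
# timing arithmetic. k-space index convention: 0-based indices, DC at
# floor(N/2); ky/kz are phase encodes, kx is read fully every line.

#' Build a 2D-CAIPI phase-encode sampling pattern
#'
#' Samples the `(ky, kz)` plane on a controlled-aliasing lattice: kz every
#' `Rz`-th plane, and within the `j`-th sampled plane the ky comb is offset by
#' `caipi_shift * j mod Ry`. The sampled fraction is `1/(Ry*Rz)` up to
#' boundary truncation. Lines are grouped into shots (one kz plane splits
#' into `n_interleaves` shots over alternating ky lines), each shot occupying
#' one TR; within a TR each line gets an acquisition time
#' `te + (line_counter - center_counter) * echo_spacing`, placing the echo
#' train's center line at the echo time.
#'
#' @param matrix integer triple `(nx, ny, nz)`.
#' @param Ry,Rz acceleration factors along ky and kz (>= 1).
#' @param caipi_shift integer ky-offset increment per sampled kz plane; must
#'   be `< Rz` per the blipped-CAIPI constraint (0 = no controlled aliasing).
#' @param n_interleaves shots per kz plane.
#' @param echo_spacing seconds between consecutive ky lines in a shot.
#' @param te echo time in seconds assigned to the center line of each shot.
#' @return An object of class `sampling_pattern`: list with `lines` (data
#'   frame `ky, kz, shot, tr_index, t`, indices 0-based), `matrix`, `accel`,
#'   `caipi_shift`, `echo_spacing`, `te`.
#' @export
build_caipi_pattern <- function(matrix, Ry, Rz, caipi_shift = 1,
                                n_interleaves = 1, echo_spacing = 1e-3,
                                te = 0.021) {
  matrix <- as.integer(matrix)
  stopifnot(length(matrix) == 3, Ry >= 1, Rz >= 1, n_interleaves >= 1)
  ny <- matrix[2]; nz <- matrix[3]
  if (Ry > ny || Rz > nz) stop("acceleration factor exceeds matrix size")
  if (caipi_shift >= max(Rz, 1) && caipi_shift != 0) {
    stop("caipi_shift must be < Rz")
  }
  kz_s <- seq(0L, nz - 1L, by = Rz)
  rows <- vector("list", length(kz_s))
  for (j in seq_along(kz_s)) {
    offset <- (caipi_shift * (kz_s[j] %/% Rz)) %% Ry
    ky_s <- seq(offset, ny - 1L, by = Ry)
    rows[[j]] <- data.frame(ky = as.integer(ky_s),
                            kz = as.integer(kz_s[j]))
  }
  lines <- do.call(rbind, rows)
  # shots: each kz plane split across interleaves over alternating ky lines
  lines <- lines[order(lines$kz, lines$ky), ]
  shot <- integer(nrow(lines))
  tr_index <- integer(nrow(lines))
  t <- numeric(nrow(lines))
  shot_counter <- 0L
  for (j in seq_along(kz_s)) {
    sel <- which(lines$kz == kz_s[j])
    for (il in seq_len(n_interleaves)) {
      idx <- sel[seq(il, length(sel), by = n_interleaves)]
      shot[idx] <- shot_counter
      tr_index[idx] <- shot_counter
      ctr <- (length(idx) - 1) / 2
      t[idx] <- te + (seq_along(idx) - 1 - ctr) * echo_spacing
      shot_counter <- shot_counter + 1L
    }
  }
  lines$shot <- shot
  lines$tr_index <- tr_index
  lines$t <- t
  rownames(lines) <- NULL
  if (anyDuplicated(lines[, c("ky", "kz")]) > 0) {
    stop("internal error: duplicate (ky, kz) in pattern")
  }
  structure(list(lines = lines, matrix = matrix,
                 accel = c(Ry = as.integer(Ry), Rz = as.integer(Rz)),
                 caipi_shift = as.integer(caipi_shift),
                 n_interleaves = as.integer(n_interleaves),
                 echo_spacing = echo_spacing, te = te),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf(
    "sampling_pattern: %d x %d x %d matrix, R = %d x %d (shift %d), %d lines, %d shots\n",
    x$matrix[1], x$matrix[2], x$matrix[3], x$accel[1], x$accel[2],
    x$caipi_shift, nrow(x$lines), length(unique(x$lines$shot))))
  invisible(x)
}

#' Boolean ky-kz sampling mask of a pattern
#' @param pattern a [build_caipi_pattern()] result.
#' @return logical `ny x nz` matrix, `TRUE` where sampled.
#' @export
pattern_mask <- function(pattern) {
  m <- matrix(FALSE, pattern$matrix[2], pattern$matrix[3])
  m[cbind(pattern$lines$ky + 1L, pattern$lines$kz + 1L)] <- TRUE
  m
}

#' Write a sampling pattern's line table as TSV
#' @param pattern a [build_caipi_pattern()] result.
#' @param path output TSV path (columns `ky, kz, shot, tr_index, t`).
#' @export
write_pattern_tsv <- function(pattern, path) {
  write.table(pattern$lines, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Build the per-TR schedule of an embedded volumetric navigator
#'
#' The navigator acquires a small number of ky-kz lines of its CAIPI pattern
#' within each imaging TR, completing one low-resolution volume every
#' `trs_per_volume` TRs. The schedule records the navigator readout duration
#' per TR and the navigator frame interval (its motion-sampling period).
#'
#' @param nav_matrix navigator matrix `(nx, ny, nz)`.
#' @param accel `(Ry, Rz)` navigator acceleration.
#' @param lines_per_tr navigator ky-kz lines acquired per imaging TR.
#' @param echo_spacing navigator echo spacing in seconds.
#' @param tr imaging repetition time in seconds.
#' @param caipi_shift navigator CAIPI shift.
#' @param te seconds from excitation to the start of the navigator readout;
#'   line acquisition times are offset by it, and `nav_te` (the echo-center
#'   time used to scale navigator phase to Hz) is derived from it.
#' @return An object of class `navigator_schedule`: the navigator
#'   `sampling_pattern` plus `lines_per_tr`, `trs_per_volume`,
#'   `nav_duration_per_tr`, `nav_te` and `frame_interval` (seconds).
#' @export
build_navigator_schedule <- function(nav_matrix, accel, lines_per_tr,
                                     echo_spacing, tr, caipi_shift = 1,
                                     te = 0) {
  pattern <- build_caipi_pattern(nav_matrix, accel[1], accel[2],
                                 caipi_shift = caipi_shift,
                                 echo_spacing = echo_spacing, te = 0)
  n_lines <- nrow(pattern$lines)
  if (n_lines %% lines_per_tr != 0) {
    stop(sprintf(
      "navigator lines (%d) not divisible by lines_per_tr (%d): residue %d",
      n_lines, lines_per_tr, n_lines %% lines_per_tr))
  }
  trs_per_volume <- n_lines %/% lines_per_tr
  # assign each line to a TR slot, times strictly increasing within a TR
  lines <- pattern$lines[order(pattern$lines$kz, pattern$lines$ky), ]
  lines$tr_index <- rep(seq_len(trs_per_volume) - 1L, each = lines_per_tr)
  lines$shot <- lines$tr_index
  lines$t <- te + rep((seq_len(lines_per_tr) - 1) * echo_spacing,
                      times = trs_per_volume)
  rownames(lines) <- NULL
  pattern$lines <- lines
  structure(list(pattern = pattern,
                 lines_per_tr = as.integer(lines_per_tr),
                 trs_per_volume = as.integer(trs_per_volume),
                 echo_spacing = echo_spacing,
                 nav_duration_per_tr = lines_per_tr * echo_spacing,
                 te = te,
                 nav_te = te + (lines_per_tr - 1) / 2 * echo_spacing,
                 tr = tr,
                 frame_interval = trs_per_volume * tr),
            class = "navigator_schedule")
}

#' @export
print.navigator_schedule <- function(x, ...) {
  cat(sprintf(
    "navigator_schedule: %d lines/TR over %d TRs; %.3g ms readout/TR; frame every %.3g ms\n",
    x$lines_per_tr, x$trs_per_volume, 1e3 * x$nav_duration_per_tr,
    1e3 * x$frame_interval))
  invisible(x)
}

#' Volume timing of a kz-segmented 3D-EPI protocol
#'
#' One TR acquires one interleave of one (accelerated) kz plane, so a full
#' volume takes `(nz / Rz) * n_interleaves * tr` seconds.
#'
#' @param matrix imaging matrix `(nx, ny, nz)`.
#' @param Rz kz acceleration factor; `nz` must divide by it.
#' @param n_interleaves shots per kz plane.
#' @param tr repetition time in seconds.
#' @param te echo time in seconds (carried through for reporting).
#' @return An object of class `protocol_timing`: list with `tr`, `te`,
#'   `n_interleaves`, `trs_per_volume` and `volume_tr` (seconds).
#' @export
volume_timing <- function(matrix, Rz, n_interleaves, tr, te = NA_real_) {
  nz <- as.integer(matrix[3])
  if (nz %% Rz != 0) {
    stop(sprintf("nz = %d not divisible by Rz = %d", nz, Rz))
  }
  trs <- (nz %/% Rz) * n_interleaves
  structure(list(tr = tr, te = te, n_interleaves = as.integer(n_interleaves),
                 trs_per_volume = as.integer(trs), volume_tr = trs * tr),
            class = "protocol_timing")
}

#' Derived timing and geometry numbers of the acquisition protocol
#'
#' Computes, from the protocol parameters, the quantities that characterize
#' the motion-robust navigated 3D-EPI acquisition: imaging matrix from FOV
#' and resolution, volume TR, navigator resolution, navigator readout
#' duration per TR, TRs and temporal resolution per navigator frame, total
#' volumes per session, and the fat-water frequency shift at the scanner's
#' field strength.
#'
#' @param fov_mm field of view in mm (default `c(256, 237, 190)`).
#' @param resolution_mm isotropic imaging resolution (default 1.58).
#' @param tr,te repetition/echo time in seconds.
#' @param accel imaging acceleration `(Ry, Rz)`.
#' @param n_interleaves shots per kz plane.
#' @param nav_matrix navigator matrix.
#' @param nav_accel navigator acceleration `(Ry, Rz)`.
#' @param nav_lines_per_tr navigator lines per TR.
#' @param nav_echo_spacing navigator echo spacing in seconds.
#' @param volumes_per_run,n_runs image volumes per run and runs per session.
#' @param b0_tesla static field strength.
#' @return list of derived protocol quantities (see Details in the README).
#' @export
protocol_summary <- function(fov_mm = c(256, 237, 190), resolution_mm = 1.58,
                             tr = 0.039, te = 0.021, accel = c(3, 4),
                             n_interleaves = 2,
                             nav_matrix = c(48, 32, 24), nav_accel = c(4, 2),
                             nav_lines_per_tr = 8, nav_echo_spacing = 0.47e-3,
                             volumes_per_run = 150, n_runs = 2,
                             b0_tesla = 10.5) {
  matrix <- as.integer(round(fov_mm / resolution_mm))
  matrix <- matrix - (matrix %% accel[2] != 0) * (matrix %% accel[2]) *
    c(0, 0, 1)  # trim nz to a multiple of Rz as the sequence would
  timing <- volume_timing(matrix, accel[2], n_interleaves, tr, te)
  nav <- build_navigator_schedule(nav_matrix, nav_accel, nav_lines_per_tr,
                                  nav_echo_spacing, tr)
  list(matrix = matrix,
       volume_tr_s = timing$volume_tr,
       nav_resolution_mm = fov_mm / nav_matrix,
       nav_trs_per_volume = nav$trs_per_volume,
       nav_duration_per_tr_s = nav$nav_duration_per_tr,
       nav_frame_interval_s = nav$frame_interval,
       volumes_per_session = volumes_per_run * n_runs,
       session_duration_s = volumes_per_run * n_runs * timing$volume_tr,
       fat_shift_hz = fat_water_shift_hz(b0_tesla))
}
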