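# S3 containers for the pipeline's data types. Constructors validate the
# physical metadata (pixel sizes, rates) once so downstream code can trust it.

#' Vessel movie container
#'
#' A time-lapse of a single vessel: a numeric array indexed `[y, x, frame]`
#' with the pixel size in micrometres and the frame rate in Hz.
#'
#' @param data numeric array `[y, x, frame]` (a matrix is treated as a single
#'   frame).
#' @param pixel_size pixel size in µm (> 0).
#' @param frame_rate frame rate in Hz (> 0).
#' @return object of class `vessel_movie`.
#' @export
vessel_movie <- function(data, pixel_size, frame_rate) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_nv("`data` must be a [y, x, frame] array")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  structure(list(data = data, pixel_size = pixel_size, frame_rate = frame_rate),
            class = "vessel_movie")
}

#' @export
print.vessel_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vessel_movie> %d x %d px, %d frames @ %.3g Hz, %.3g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Line-scan kymograph container
#'
#' Repeated line scans stacked into a matrix `[line (time), position]`, with
#' the line rate in Hz and pixel size in µm. Moving red blood cells leave
#' sloped streaks whose slope encodes their velocity.
#'
#' @param data numeric matrix, rows = scan lines (time), columns = position.
#' @param line_rate lines per second (Hz).
#' @param pixel_size spatial pixel size along the scan line (µm).
#' @return object of class `kymograph`.
#' @export
kymograph <- function(data, line_rate, pixel_size) {
  if (!is.matrix(data)) stop_nv("`data` must be a matrix [line, position]")
  check_scalar(line_rate, "line_rate", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(data = data, line_rate = line_rate, pixel_size = pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d lines x %d px @ %.4g Hz, %.3g um/px (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$line_rate, x$pixel_size,
              nrow(x$data) / x$line_rate))
  invisible(x)
}

#' Diameter time series
#'
#' Per-frame vessel diameter in µm with validity flags. Invalid frames carry a
#' reason code instead of a value.
#'
#' @param values diameter per frame (µm); `NA` where invalid.
#' @param frame_rate frames per second (Hz).
#' @param valid logical per frame.
#' @param reason character per frame, `""` where valid.
#' @param n_valid_points number of skeleton points that produced a usable
#'   width in each frame (optional).
#' @return object of class `diameter_trace`.
#' @export
diameter_trace <- function(values, frame_rate, valid = !is.na(values),
                           reason = rep("", length(values)),
                           n_valid_points = NULL) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (any(values[valid] <= 0, na.rm = TRUE))
    stop_nv("valid diameters must be > 0")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 valid = valid, reason = reason,
                 n_valid_points = n_valid_points),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("<diameter_trace> %d frames @ %.3g Hz, %d valid, median %.2f um\n",
              length(x$values), x$frame_rate, sum(x$valid),
              median(x$values[x$valid])))
  invisible(x)
}

#' @export
as.data.frame.diameter_trace <- function(x, ...) {
  data.frame(time_s = (seq_along(x$values) - 1) / x$frame_rate,
             value = x$values, valid = x$valid, reason = x$reason)
}

#' @export
plot.diameter_trace <- function(x, ...) {
  t <- (seq_along(x$values) - 1) / x$frame_rate
  plot(t, x$values, type = "l", xlab = "time (s)", ylab = "diameter (um)", ...)
  if (any(!x$valid)) points(t[!x$valid], rep(min(x$values, na.rm = TRUE), sum(!x$valid)),
                            pch = 4, col = "red")
  invisible(x)
}

#' Red-blood-cell velocity time series
#'
#' One velocity estimate per analysis window. `quality` is the projection
#' variance contrast used to flag windows without a usable streak signal.
#'
#' @param values velocity per window (mm/s, sign = motion toward increasing
#'   position index).
#' @param window_centers window centre times (s), strictly increasing.
#' @param quality per-window contrast statistic.
#' @param flagged logical: `TRUE` where the window had no usable signal.
#' @return object of class `velocity_trace`.
#' @export
velocity_trace <- function(values, window_centers, quality, flagged) {
  if (is.unsorted(window_centers, strictly = TRUE))
    stop_nv("`window_centers` must be strictly increasing")
  structure(list(values = values, window_centers = window_centers,
                 quality = quality, flagged = flagged),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  ok <- !x$flagged
  cat(sprintf("<velocity_trace> %d windows, %d usable, median %.3g mm/s\n",
              length(x$values), sum(ok),
              if (any(ok)) median(x$values[ok]) else NA_real_))
  invisible(x)
}

#' Stimulus schedule
#'
#' Onset times of repeated visual stimuli. Defaults follow the 5 s drifting
#' grating / 25 s grey-screen protocol with 20 trials.
#'
#' @param onsets stimulus onset times (s), sorted. If missing, built from
#'   `first_onset`, `n_stims`, `stim_dur`, `isi`.
#' @param stim_dur stimulus duration (s).
#' @param isi inter-stimulus (grey screen) interval (s).
#' @param n_stims number of stimuli when `onsets` is missing.
#' @param first_onset time of the first onset when `onsets` is missing (s).
#' @return object of class `stim_schedule`.
#' @export
stim_schedule <- function(onsets = NULL, stim_dur = 5, isi = 25, n_stims = 20,
                          first_onset = 10) {
  check_scalar(stim_dur, "stim_dur", positive = TRUE)
  check_scalar(isi, "isi", positive = TRUE)
  if (is.null(onsets))
    onsets <- first_onset + (seq_len(n_stims) - 1) * (stim_dur + isi)
  if (is.unsorted(onsets)) stop_nv("`onsets` must be sorted")
  if (length(onsets) > 1L && any(diff(onsets) < stim_dur))
    stop_nv("onset spacing must be >= stim_dur")
  structure(list(onsets = onsets, stim_dur = stim_dur, isi = isi,
                 n_stims = length(onsets)),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d stimuli, %g s on / %g s off, first at %g s\n",
              x$n_stims, x$stim_dur, x$isi, x$onsets[1]))
  invisible(x)
}

#' Locomotion trace
#'
#' Rotary-encoder style speed trace. Units are arbitrary: only the
#' zero/non-zero distinction feeds trial gating and rest detection.
#'
#' @param speed numeric speed per sample.
#' @param sample_rate Hz.
#' @return object of class `locomotion_trace`.
#' @export
locomotion_trace <- function(speed, sample_rate) {
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  structure(list(speed = as.numeric(speed), sample_rate = sample_rate),
            class = "locomotion_trace")
}

#' @export
print.locomotion_trace <- function(x, ...) {
  cat(sprintf("<locomotion_trace> %.1f s @ %g Hz, moving %.1f%% of samples\n",
              length(x$speed) / x$sample_rate, x$sample_rate,
              100 * mean(x$speed != 0)))
  invisible(x)
}

#' Haemodynamic recording (Oxy-CBF probe channels)
#'
#' Multi-channel time series at a common sample rate; canonical channels are
#' `Flux`, `Speed`, `Hbo`, `Hbd`, `Hbt`, `sO2`. Construction warns when the
#' haemoglobin channels are inconsistent (|Hbt - (Hbo + Hbd)| / Hbt > 5%).
#'
#' @param channels data.frame of channel columns.
#' @param sample_rate Hz (default 40).
#' @return object of class `hemo_recording`.
#' @export
hemo_recording <- function(channels, sample_rate = 40) {
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  channels <- as.data.frame(channels)
  if ("sO2" %in% names(channels)) {
    s <- channels$sO2
    if (any(s < 0 | s > 100, na.rm = TRUE)) stop_nv("sO2 must lie in [0, 100]")
  }
  if (all(c("Hbo", "Hbd", "Hbt") %in% names(channels))) {
    rel <- abs(channels$Hbt - (channels$Hbo + channels$Hbd)) /
      pmax(channels$Hbt, .Machine$double.eps)
    if (mean(rel > 0.05, na.rm = TRUE) > 0)
      warn_nv("Hbt deviates from Hbo + Hbd by >5%% in %.1f%% of samples",
              100 * mean(rel > 0.05, na.rm = TRUE))
  }
  structure(list(channels = channels, sample_rate = sample_rate),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("<hemo_recording> %d samples @ %g Hz: %s\n",
              nrow(x$channels), x$sample_rate,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Vessel skeleton model
#'
#' Centreline points (pixel/voxel coordinates), unit tangents, branch points
#' and optional per-point radii. Shared by in vivo diametry (2D) and ex vivo
#' morphometry (3D).
#'
#' @param points numeric matrix, one row per centreline point (2 or 3 columns).
#' @param tangents unit tangent per point (same shape), or NULL.
#' @param branch_points indices into `points` flagged as branch voxels.
#' @param radius per-point radius in µm, or NULL.
#' @param spacing physical size of one pixel/voxel step per axis (µm).
#' @param total_length_um total centreline length (µm), if known.
#' @export
skeleton_model <- function(points, tangents = NULL, branch_points = integer(),
                           radius = NULL, spacing = NULL,
                           total_length_um = NA_real_) {
  points <- as.matrix(points)
  if (!is.null(tangents)) {
    tangents <- as.matrix(tangents)
    nrm <- sqrt(rowSums(tangents^2))
    if (any(abs(nrm - 1) > 1e-6)) stop_nv("tangents must be unit vectors")
  }
  structure(list(points = points, tangents = tangents,
                 branch_points = branch_points, radius = radius,
                 spacing = spacing, total_length_um = total_length_um),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model> %d points (%dD), %d branch voxels, length %.1f um\n",
              nrow(x$points), ncol(x$points), length(x$branch_points),
              x$total_length_um))
  invisible(x)
}

#' Power spectrum container
#'
#' Welch power spectral density interpolated onto a common frequency grid and
#' truncated at 1 Hz.
#'
#' @param freqs frequency grid (Hz), strictly increasing.
#' @param power spectral power (relative units), non-negative.
#' @param source_length_s length of the analysed trace (s).
#' @export
power_spectrum <- function(freqs, power, source_length_s) {
  if (is.unsorted(freqs, strictly = TRUE)) stop_nv("freqs must be increasing")
  if (any(power < 0)) stop_nv("power must be >= 0")
  structure(list(freqs = freqs, power = power,
                 source_length_s = source_length_s),
            class = "power_spectrum")
}

#' @export
plot.power_spectrum <- function(x, ...) {
  plot(x$freqs, x$power, type = "l", xlab = "frequency (Hz)",
       ylab = "power (rel.)", ...)
  abline(v = 0.1, lty = 2, col = "grey40")
  invisible(x)
}

#' Anatomy z-stack container
#'
#' Confocal-style stack of the gelatine-filled vasculature, array `[y, x, z]`
#' with the voxel size per array axis in µm.
#'
#' @param data numeric array `[y, x, z]`.
#' @param voxel_size length-3 voxel size per array axis (µm), e.g.
#'   `c(0.45, 0.45, 1)`.
#' @export
anatomy_stack <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_nv("`data` must be a [y, x, z] array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_nv("`voxel_size` must be 3 positive values (um per axis)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "anatomy_stack")
}

#' @export
print.anatomy_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<anatomy_stack> %d x %d x %d voxels @ (%s) um\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}
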