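# File interchange: multi-page TIFF with a JSON sidecar for physical
# metadata, and tidy CSV for traces and tables. Intensities are rescaled to
# [0, 1] on write (the scale is recorded in the sidecar) because TIFF float
# samples are stored normalised by the tiff package.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a vessel movie as multi-page TIFF
#'
#' Pixel size, frame rate and the intensity scale go to a `<path>.json`
#' sidecar.
#'
#' @param movie a [vessel_movie].
#' @param path output TIFF path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns a [vessel_movie].
#' @export
write_movie_tiff <- function(movie, path) {
  d <- movie$data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(d)[3]), function(f) (d[, , f] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  write_sidecar(path, list(kind = "vessel_movie", pixel_size = movie$pixel_size,
                           frame_rate = movie$frame_rate,
                           intensity_offset = lo, intensity_scale = scale))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param pixel_size,frame_rate metadata overrides when no sidecar exists.
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_rate = NULL) {
  meta <- read_sidecar(path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  d <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) d[, , f] <- frames[[f]]
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% 1
  d <- d * sc + off
  vessel_movie(d,
               pixel_size = pixel_size %||% meta$pixel_size,
               frame_rate = frame_rate %||% meta$frame_rate)
}

#' Write / read an anatomy stack as multi-page TIFF
#'
#' @param stack an [anatomy_stack].
#' @param path output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- stack$data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  slices <- lapply(seq_len(dim(d)[3]), function(k) (d[, , k] - lo) / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  write_sidecar(path, list(kind = "anatomy_stack", voxel_size = stack$voxel_size,
                           intensity_offset = lo, intensity_scale = scale))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_size override when no sidecar exists.
#' @export
read_stack_tiff <- function(path, voxel_size = NULL) {
  meta <- read_sidecar(path)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) d[, , k] <- slices[[k]]
  d <- d * (meta$intensity_scale %||% 1) + (meta$intensity_offset %||% 0)
  anatomy_stack(d, voxel_size %||% unlist(meta$voxel_size))
}

#' Write / read traces as tidy CSV
#'
#' Diameter traces go out as `time_s, value, valid, reason`; velocity traces
#' as `time_s, value, quality, flagged`.
#'
#' @param x a [diameter_trace] or [velocity_trace].
#' @param path CSV path.
#' @export
write_trace_csv <- function(x, path) {
  df <- if (inherits(x, "diameter_trace")) {
    as.data.frame(x)
  } else if (inherits(x, "velocity_trace")) {
    data.frame(time_s = x$window_centers, value = x$values,
               quality = x$quality, flagged = x$flagged)
  } else stop_nv("unsupported trace class: %s", class(x)[1])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param frame_rate sampling rate (Hz) of the stored diameter trace.
#' @export
read_diameter_csv <- function(path, frame_rate = NULL) {
  df <- read.csv(path)
  if (is.null(frame_rate)) {
    dt <- diff(df$time_s)
    frame_rate <- 1 / median(dt)
  }
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else !is.na(df$value)
  reason <- if ("reason" %in% names(df)) as.character(df$reason) else rep("", nrow(df))
  reason[is.na(reason)] <- ""
  diameter_trace(df$value, frame_rate, valid = valid, reason = reason)
}

#' Write / read a stimulus schedule as JSON
#'
#' @param schedule a [stim_schedule].
#' @param path JSON path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(onsets = schedule$onsets,
                            stim_dur = schedule$stim_dur, isi = schedule$isi),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_schedule(onsets = j$onsets, stim_dur = j$stim_dur, isi = j$isi)
}

# internal: simple two-column (time_s, value/speed) CSV helpers
write_ts_csv <- function(time_s, value, path, value_name = "value") {
  df <- data.frame(time_s = time_s, value)
  names(df)[2] <- value_name
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_locomotion_csv <- function(path) {
  df <- read.csv(path)
  fs <- 1 / median(diff(df$time_s))
  locomotion_trace(df$speed, fs)
}
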