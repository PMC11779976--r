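# Home-cage activity: pose-tracking tables -> likelihood filtering ->
# per-frame centroid + wheel displacement -> 10-minute window sums,
# 1%-trimmed daily totals and per-hour activity profiles.

#' Read a pose-estimation export CSV
#'
#' Accepts either the tidy layout (`frame, label, x, y, likelihood`) or the
#' common wide multi-level-header export (three header rows: scorer,
#' bodyparts, coords), which is flattened to tidy form.
#'
#' A `<path>.json` sidecar (with `fps` and `px_per_cm`) is honoured when the
#' arguments are not supplied.
#'
#' @param path CSV path.
#' @param fps frames per second (default 30, or the sidecar value).
#' @param px_per_cm camera scale (must be supplied for distances).
#' @return a `tracking_table` data.frame.
#' @export
read_tracking_csv <- function(path, fps = NULL, px_per_cm = NULL) {
  meta <- read_sidecar(path)
  fps <- fps %||% meta$fps %||% 30
  px_per_cm <- px_per_cm %||% meta$px_per_cm
  first <- readLines(path, n = 3)
  if (grepl("^\"?frame\"?,", first[1])) {
    tab <- read.csv(path)
  } else {
    # wide export: row1 scorer, row2 bodyparts, row3 coords
    parts <- strsplit(first[2], ",")[[1]][-1]
    coords <- strsplit(first[3], ",")[[1]][-1]
    raw <- read.csv(path, skip = 3, header = FALSE)
    frames <- raw[[1]]
    out <- list()
    for (lab in unique(parts)) {
      xi <- which(parts == lab & coords == "x") + 1L
      yi <- which(parts == lab & coords == "y") + 1L
      li <- which(parts == lab & coords == "likelihood") + 1L
      out[[lab]] <- data.frame(frame = frames, label = lab,
                               x = raw[[xi]], y = raw[[yi]],
                               likelihood = raw[[li]])
    }
    tab <- do.call(rbind, out)
    tab <- tab[order(tab$frame, tab$label), ]
    rownames(tab) <- NULL
  }
  attr(tab, "fps") <- fps
  attr(tab, "px_per_cm") <- px_per_cm
  class(tab) <- c("tracking_table", "data.frame")
  tab
}

#' Filter tracking rows by likelihood
#'
#' Removes rows whose pose-estimation likelihood falls below the threshold.
#' The default threshold of 1 keeps only maximally confident locations — a
#' deliberately strict rule; the retained fraction is reported so its effect
#' is visible.
#'
#' @param table a `tracking_table`.
#' @param likelihood_threshold rows with `likelihood < threshold` are
#'   dropped (default 1.0).
#' @return the filtered table, with attribute `removed_fraction`.
#' @export
filter_tracking <- function(table, likelihood_threshold = 1.0) {
  keep <- table$likelihood >= likelihood_threshold
  if (!any(keep))
    stop_nv("all rows removed at likelihood threshold %g; review the threshold",
            likelihood_threshold)
  out <- table[keep, , drop = FALSE]
  attr(out, "fps") <- attr(table, "fps")
  attr(out, "px_per_cm") <- attr(table, "px_per_cm")
  attr(out, "removed_fraction") <- 1 - mean(keep)
  class(out) <- class(table)
  out
}

body_labels <- c("head", "left_headplate", "right_headplate", "tail")
wheel_labels <- c("wheel_inner", "wheel_outer")

#' Per-frame displacement from a filtered tracking table
#'
#' The mouse centroid is the mean of whatever body labels survive filtering
#' in each frame (minimum one); the wheel marker is the mean of the inner
#' and outer markers (either alone suffices). Per-frame distance is
#' `|Δcentroid| + |Δwheel|` in cm; frames missing one of the two contribute
#' the other alone, and gaps are bridged by differencing across the gap.
#'
#' @param table a filtered `tracking_table`.
#' @param fps frames per second (defaults to the table attribute).
#' @param px_per_cm camera scale (defaults to the table attribute).
#' @return data.frame `frame`, `mouse_cm`, `wheel_cm`, `total_cm` (one row
#'   per frame present in the table, distances measured from the previous
#'   available frame), with attribute `fps`.
#' @export
frame_distance <- function(table, fps = NULL, px_per_cm = NULL) {
  fps <- fps %||% attr(table, "fps")
  px_per_cm <- px_per_cm %||% attr(table, "px_per_cm")
  if (is.null(px_per_cm)) stop_nv("px_per_cm must be supplied")
  centroid_of <- function(labels) {
    sub <- table[table$label %in% labels, c("frame", "x", "y")]
    if (!nrow(sub)) return(NULL)
    cx <- tapply(sub$x, sub$frame, mean)
    cy <- tapply(sub$y, sub$frame, mean)
    data.frame(frame = as.integer(names(cx)), x = as.numeric(cx),
               y = as.numeric(cy))
  }
  step_dist <- function(cf) {
    if (is.null(cf) || nrow(cf) < 2) return(NULL)
    data.frame(frame = cf$frame[-1],
               d = sqrt(diff(cf$x)^2 + diff(cf$y)^2) / px_per_cm)
  }
  mouse <- step_dist(centroid_of(body_labels))
  wheel <- step_dist(centroid_of(wheel_labels))
  frames <- sort(unique(c(mouse$frame, wheel$frame)))
  out <- data.frame(frame = frames,
                    mouse_cm = mouse$d[match(frames, mouse$frame)],
                    wheel_cm = wheel$d[match(frames, wheel$frame)])
  out$mouse_cm[is.na(out$mouse_cm)] <- 0
  out$wheel_cm[is.na(out$wheel_cm)] <- 0
  out$total_cm <- out$mouse_cm + out$wheel_cm
  attr(out, "fps") <- fps
  out
}

#' Summarise activity into 10-minute windows, daily totals and hourly means
#'
#' Sums per-frame distances over 10-minute windows, trims the top and bottom
#' `trim` fraction of the window-sum distribution (count per tail =
#' `floor(trim * n_windows)`, so fewer than `1/trim` windows trim nothing,
#' with a warning), then computes per-day totals and per-clock-hour means
#' from the surviving windows.
#'
#' @param distances data.frame from [frame_distance()] (or a numeric vector
#'   of per-frame distances in cm).
#' @param fps frames per second.
#' @param trim trimmed fraction per tail (default 0.01).
#' @param window_s window length in seconds (default 600).
#' @param start_hour clock hour at recording start (for the hourly profile).
#' @return list of class `activity_summary`: `windows` (data.frame with
#'   `window`, `start_s`, `distance_cm`, `retained`), `daily_totals_cm`,
#'   `hourly_means_cm`, `frames_used_fraction`.
#' @export
summarize_activity <- function(distances, fps = NULL, trim = 0.01,
                               window_s = 600, start_hour = 0) {
  if (is.data.frame(distances)) {
    fps <- fps %||% attr(distances, "fps")
    frame <- distances$frame
    d <- distances$total_cm
  } else {
    d <- as.numeric(distances)
    frame <- seq_along(d)
  }
  check_scalar(fps, "fps", positive = TRUE)
  wlen <- window_s * fps
  win <- floor((frame - 1) / wlen)
  n_complete <- floor(max(frame) / wlen)
  if (n_complete < 1) stop_nv("need at least one complete %g-s window", window_s)
  sums <- vapply(seq_len(n_complete) - 1L, function(w) sum(d[win == w]),
                 numeric(1))
  k <- floor(trim * n_complete)
  if (k == 0 && trim > 0)
    warn_nv("only %d windows; %g%% trimming removes no window", n_complete,
            100 * trim)
  retained <- rep(TRUE, n_complete)
  if (k > 0) {
    ord <- order(sums)
    retained[ord[seq_len(k)]] <- FALSE
    retained[ord[n_complete - seq_len(k) + 1L]] <- FALSE
  }
  wdf <- data.frame(window = seq_len(n_complete),
                    start_s = (seq_len(n_complete) - 1L) * window_s,
                    distance_cm = sums, retained = retained)
  day <- floor(wdf$start_s / 86400)
  daily <- tapply(wdf$distance_cm[retained], day[retained], sum)
  hour <- (start_hour + floor((wdf$start_s %% 86400) / 3600)) %% 24
  hourly <- tapply(wdf$distance_cm[retained], hour[retained], mean)
  structure(list(windows = wdf,
                 daily_totals_cm = daily,
                 hourly_means_cm = hourly,
                 frames_used_fraction = length(frame) / max(frame)),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> %d windows (%d retained), total %.0f cm\n",
              nrow(x$windows), sum(x$windows$retained),
              sum(x$windows$distance_cm[x$windows$retained])))
  invisible(x)
}
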