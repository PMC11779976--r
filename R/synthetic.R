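# Synthetic-data generators. Every input the pipeline consumes can be built
# here with known ground truth, so each downstream stage is testable without
# raw recordings. All generators are deterministic given (parameters, seed).

new_ground_truth <- function(...) {
  gt <- list(...)
  bad <- vapply(gt, function(v) is.numeric(v) && any(!is.finite(unlist(v))), logical(1))
  if (any(bad)) stop_nv("ground truth contains non-finite values: %s",
                        paste(names(gt)[bad], collapse = ", "))
  structure(gt, class = "nv_ground_truth")
}

#' @export
print.nv_ground_truth <- function(x, ...) {
  cat("<nv_ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# cross-section of a box of width w convolved with a Gaussian PSF of sd sigma,
# evaluated at signed distance d from the centreline; peak ~1 for w >> sigma
box_psf_profile <- function(d, w, sigma) {
  0.5 * (erf((w / 2 - d) / (sigma * sqrt(2))) + erf((w / 2 + d) / (sigma * sqrt(2))))
}

#' Generate a synthetic vessel movie
#'
#' Renders a single bright vessel on a dark background: at each frame the
#' cross-section is a box of the true width convolved with a Gaussian PSF,
#' plus additive Gaussian noise. The true width per frame is returned as
#' ground truth, so full-width-half-maximum diametry can be validated against
#' construction.
#'
#' @param width_fn vessel width in µm: either a single number or a function of
#'   time (s) returning µm per frame.
#' @param pixel_size µm per pixel.
#' @param frame_rate frames per second (Hz).
#' @param n_frames number of frames (>= 1).
#' @param psf_sigma Gaussian PSF sigma in µm.
#' @param noise_sd additive Gaussian noise SD (intensity units; vessel peak
#'   is ~1).
#' @param orientation vessel orientation in degrees (0 = along x).
#' @param img_um image side length in µm; default 5x the maximum width
#'   (leaves room for perpendicular profiles of halfwidth 2x diameter).
#' @param baseline background intensity.
#' @param seed integer RNG seed (same seed, same movie, bit for bit).
#' @return list with elements `movie` (a [vessel_movie]) and `truth`
#'   (ground truth with `true_diameter_trace` in µm per frame).
#' @export
gen_vessel_movie <- function(width_fn, pixel_size = 0.5, frame_rate = 7.63,
                             n_frames = 100, psf_sigma = 0.5, noise_sd = 0.02,
                             orientation = 0, img_um = NULL, baseline = 0.05,
                             seed = 1) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (n_frames < 1) stop_nv("n_frames must be >= 1")
  wf <- if (is.function(width_fn)) width_fn else function(t) rep(width_fn, length(t))
  t <- (seq_len(n_frames) - 1) / frame_rate
  widths <- wf(t)
  if (length(widths) == 1L) widths <- rep(widths, n_frames)
  limit <- 2 * pixel_size
  if (any(widths <= limit))
    stop_nv("vessel width must exceed the resolvable limit of 2 x pixel_size = %.3g um (min requested: %.3g um)",
            limit, min(widths))
  if (is.null(img_um)) img_um <- 5 * max(widths)
  n_px <- max(32L, as.integer(ceiling(img_um / pixel_size)))
  # signed distance (um) of each pixel centre from the centreline through the
  # image centre at the requested orientation
  th <- orientation * pi / 180
  cx <- (n_px + 1) / 2
  xs <- (seq_len(n_px) - cx) * pixel_size
  dmat <- outer(xs, xs, function(y, x) -x * sin(th) + y * cos(th))
  dvec <- as.vector(dmat)

  with_seed(seed, {
    data <- array(0, dim = c(n_px, n_px, n_frames))
    for (f in seq_len(n_frames)) {
      frame <- baseline + box_psf_profile(dvec, widths[f], psf_sigma)
      if (noise_sd > 0) frame <- frame + rnorm(length(frame), sd = noise_sd)
      data[, , f] <- frame
    }
    list(movie = vessel_movie(data, pixel_size, frame_rate),
         truth = new_ground_truth(true_diameter_trace = widths,
                                  orientation_deg = orientation,
                                  psf_sigma_um = psf_sigma, seed = seed))
  })
}

#' Generate a synthetic line-scan kymograph
#'
#' Dark streaks of known slope on a bright background: each streak is an
#' anti-aliased line whose column position advances by
#' `v * 1000 / (line_rate * pixel_size)` pixels per scan line, emulating red
#' blood cells moving through a line scan. Positive velocity moves toward
#' increasing position index.
#'
#' @param velocity_fn mm/s: a single number or a function of time (s)
#'   returning mm/s per line.
#' @param line_rate scan lines per second (Hz).
#' @param pixel_size µm per pixel along the line.
#' @param n_lines number of scan lines.
#' @param n_positions pixels per line.
#' @param streak_density streaks entering per second.
#' @param streak_contrast fractional darkening at streak centre.
#' @param streak_sigma_px streak half-thickness (Gaussian sigma, px).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return list with `kymo` (a [kymograph]) and `truth` (ground truth with
#'   `true_velocity_trace`, mm/s per line).
#' @export
gen_kymograph <- function(velocity_fn, line_rate = 1092, pixel_size = 0.2,
                          n_lines = 1024, n_positions = 96,
                          streak_density = 200, streak_contrast = 0.5,
                          streak_sigma_px = 1.2, noise_sd = 0.02, seed = 1) {
  check_scalar(line_rate, "line_rate", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  vf <- if (is.function(velocity_fn)) velocity_fn else function(t) rep(velocity_fn, length(t))
  t <- (seq_len(n_lines) - 1) / line_rate
  v <- vf(t)
  if (length(v) == 1L) v <- rep(v, n_lines)
  # column displacement per line and cumulative cell position (px)
  dx <- v * 1000 / (line_rate * pixel_size)
  X <- cumsum(dx)
  if (max(X) - min(X) < 1)
    stop_nv("velocity implies < 1 pixel displacement over the whole window; streak slope unresolvable")

  duration <- n_lines / line_rate
  n_streaks <- round(streak_density * duration)
  with_seed(seed, {
    img <- matrix(1, nrow = n_lines, ncol = n_positions)
    if (n_streaks > 0) {
      offs <- runif(n_streaks, 1 - max(X), n_positions - min(X))
      halo <- ceiling(3 * streak_sigma_px)
      for (k in seq_len(n_streaks)) {
        centre <- offs[k] + X
        vis <- which(centre > -halo & centre < n_positions + halo)
        if (!length(vis)) next
        for (off in -halo:halo) {
          col <- round(centre[vis]) + off
          ok <- col >= 1 & col <= n_positions
          if (!any(ok)) next
          w <- exp(-((col[ok] - centre[vis][ok])^2) / (2 * streak_sigma_px^2))
          idx <- cbind(vis[ok], col[ok])
          img[idx] <- img[idx] - streak_contrast * w
        }
      }
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
    list(kymo = kymograph(img, line_rate, pixel_size),
         truth = new_ground_truth(true_velocity_trace = v,
                                  n_streaks = n_streaks, seed = seed))
  })
}

# gamma-variate transient: 0 before `latency`, rises to peak 1 at
# latency + peak_time, smooth single-peaked decay (standard haemodynamic shape)
gamma_transient <- function(t, latency = 0.3, peak_time = 2, alpha = 2.5) {
  tt <- (t - latency) / peak_time
  out <- numeric(length(t))
  pos <- tt > 0
  out[pos] <- tt[pos]^alpha * exp(alpha * (1 - tt[pos]))
  out
}

#' Generate a haemodynamic recording with a stimulus schedule
#'
#' Multi-channel Oxy-CBF-style traces at `sample_rate` Hz. Each stimulus adds
#' a gamma-shaped transient of the stated percent amplitude to each channel.
#' `Hbt` is constructed as `Hbo + Hbd` (exactly, also after noise), `sO2` is
#' clipped to [0, 100].
#'
#' @param baseline_levels named vector of channel baselines; defaults cover
#'   Flux, Speed, Hbo, Hbd, sO2.
#' @param response_amps named vector, percent change at transient peak.
#' @param stim_n,stim_dur,isi schedule: number of stimuli, stimulus duration
#'   (s, default 5) and grey-screen interval (s, default 25).
#' @param sample_rate Hz (default 40).
#' @param noise_sd noise SD as a fraction of each channel baseline.
#' @param lead seconds of rest before the first onset.
#' @param latency,peak_time,alpha transient shape parameters (s, s, unitless).
#' @param seed integer RNG seed.
#' @return list with `hemo` ([hemo_recording]), `schedule`
#'   ([stim_schedule]) and `truth`.
#' @export
gen_hemo_and_stim <- function(baseline_levels = c(Flux = 100, Speed = 50,
                                                  Hbo = 60, Hbd = 40, sO2 = 70),
                              response_amps = c(Flux = 10, Speed = 5, Hbo = 5,
                                                Hbd = -3, sO2 = 1),
                              stim_n = 20, stim_dur = 5, isi = 25,
                              sample_rate = 40, noise_sd = 0, lead = 10,
                              latency = 0.3, peak_time = 2, alpha = 2.5,
                              seed = 1) {
  sched <- stim_schedule(stim_dur = stim_dur, isi = isi, n_stims = stim_n,
                         first_onset = lead)
  duration <- lead + stim_n * (stim_dur + isi)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  drive <- numeric(n)
  for (on in sched$onsets) drive <- drive + gamma_transient(t - on, latency, peak_time, alpha)

  with_seed(seed, {
    ch <- lapply(names(baseline_levels), function(nm) {
      base <- baseline_levels[[nm]]
      amp <- if (nm %in% names(response_amps)) response_amps[[nm]] else 0
      x <- base * (1 + amp / 100 * drive)
      if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd * base)
      x
    })
    names(ch) <- names(baseline_levels)
    ch$Hbt <- ch$Hbo + ch$Hbd
    if ("sO2" %in% names(ch)) ch$sO2 <- pmin(100, pmax(0, ch$sO2))
    ch <- as.data.frame(ch)[, c("Flux", "Speed", "Hbo", "Hbd", "Hbt", "sO2")]
    list(hemo = hemo_recording(ch, sample_rate), schedule = sched,
         truth = new_ground_truth(response_amps = response_amps,
                                  baseline_levels = baseline_levels,
                                  onsets = sched$onsets, seed = seed))
  })
}

# calcium kernel: fast rise, exponential decay, normalised to peak 1
calcium_kernel <- function(t, rise_tau = 0.07, decay_tau = 0.6) {
  out <- numeric(length(t))
  pos <- t > 0
  h <- (1 - exp(-t[pos] / rise_tau)) * exp(-t[pos] / decay_tau)
  out[pos] <- h
  pk <- max(out)
  if (pk > 0) out <- out / pk
  out
}

#' Generate synthetic calcium (ΔF/F) traces
#'
#' Builds one trace per requested cell class: `ON` cells fire a transient at
#' every stimulus onset, `OFF` cells at stimulus offset, `BOTH` at both, and
#' `NONE` cells stay silent. With `amp = 0` every class degenerates to NONE.
#'
#' @param classes character vector in {"ON","OFF","BOTH","NONE"}, one per
#'   cell.
#' @param schedule a [stim_schedule].
#' @param amp transient peak ΔF/F.
#' @param decay_tau indicator decay time constant (s).
#' @param noise_sd additive noise SD (ΔF/F units).
#' @param sample_rate Hz (default 7.63, matching frame-scan imaging).
#' @param duration_s recording length (s); default covers the schedule plus
#'   one full trial tail.
#' @param seed integer RNG seed.
#' @return object of class `calcium_traces`: list with `dff`
#'   (cells x samples), `sample_rate`, `cell_ids`, and `truth` (the class
#'   labels).
#' @export
gen_calcium <- function(classes, schedule, amp = 1, decay_tau = 0.6,
                        noise_sd = 0.05, sample_rate = 7.63,
                        duration_s = NULL, seed = 1) {
  if (length(classes) < 1L) stop_nv("need at least one cell")
  classes <- match.arg(toupper(classes), c("ON", "OFF", "BOTH", "NONE"),
                       several.ok = TRUE)
  if (is.null(duration_s))
    duration_s <- max(schedule$onsets) + schedule$stim_dur + schedule$isi
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  on_drive <- off_drive <- numeric(n)
  for (on in schedule$onsets) {
    on_drive <- on_drive + calcium_kernel(t - on - 0.1, decay_tau = decay_tau)
    off_drive <- off_drive + calcium_kernel(t - on - schedule$stim_dur - 0.1,
                                            decay_tau = decay_tau)
  }
  with_seed(seed, {
    dff <- t(vapply(classes, function(cl) {
      x <- switch(cl,
                  ON = amp * on_drive,
                  OFF = amp * off_drive,
                  BOTH = amp * (on_drive + off_drive),
                  NONE = numeric(n))
      if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
      x
    }, numeric(n)))
    rownames(dff) <- sprintf("cell_%02d", seq_along(classes))
    structure(list(dff = dff, sample_rate = sample_rate,
                   cell_ids = rownames(dff),
                   truth = new_ground_truth(classes = classes, amp = amp,
                                            seed = seed)),
              class = "calcium_traces")
  })
}

#' Generate a locomotion trace from bout descriptions
#'
#' Speed is non-zero exactly within the requested bouts. Overlapping bouts
#' are rejected.
#'
#' @param bouts data.frame (or list of length-3 vectors) with columns
#'   `start`, `end` (s) and `speed`.
#' @param duration total trace duration (s).
#' @param sample_rate Hz.
#' @return a [locomotion_trace].
#' @export
gen_locomotion <- function(bouts, duration, sample_rate = 40) {
  if (is.list(bouts) && !is.data.frame(bouts))
    bouts <- as.data.frame(do.call(rbind, lapply(bouts, function(b) {
      stats::setNames(as.list(b), c("start", "end", "speed"))
    })))
  bouts <- as.data.frame(lapply(bouts, as.numeric))
  n <- round(duration * sample_rate)
  speed <- numeric(n)
  if (nrow(bouts)) {
    if (any(bouts$end <= bouts$start)) stop_nv("bout end must exceed start")
    if (any(bouts$start < 0 | bouts$end > duration))
      stop_nv("bouts must lie within [0, duration]")
    o <- order(bouts$start)
    if (any(bouts$start[o][-1] < bouts$end[o][-nrow(bouts)]))
      stop_nv("overlapping locomotion bouts")
    t <- (seq_len(n) - 1) / sample_rate
    for (i in seq_len(nrow(bouts)))
      speed[t >= bouts$start[i] & t < bouts$end[i]] <- bouts$speed[i]
  }
  locomotion_trace(speed, sample_rate)
}

#' Generate a post-mortem anatomy stack phantom
#'
#' Voxelises a network of cylindrical tube segments with known radii into a
#' confocal-style z-stack. Optional pericytes locally constrict the tube:
#' the radius is reduced by `constriction` at the soma with a Gaussian
#' spatial profile of sigma `extent_um / 2` along the segment; the soma is
#' placed on the vessel surface at that point.
#'
#' @param segments list of `list(p0 =, p1 =, radius =)`: endpoints in µm
#'   (x, y, z) and radius in µm.
#' @param pericytes optional list of `list(segment =, at =, constriction =,
#'   extent_um =)`: segment index, fractional position along it, fractional
#'   radius reduction at the soma, spatial extent (µm).
#' @param voxel_size µm per voxel along (y, x, z) array axes.
#' @param margin_um padding around the network bounding box.
#' @param fg,bg foreground / background intensity levels.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer RNG seed.
#' @return list with `stack` ([anatomy_stack]), `pericytes` (data.frame of
#'   soma positions in µm), `true_mask` (the 50% occupancy mask) and
#'   `truth` (total network length, per-segment radii, volume).
#' @export
gen_anatomy_stack <- function(segments, pericytes = NULL,
                              voxel_size = c(1, 1, 1), margin_um = 6,
                              fg = 200, bg = 10, noise_sd = 0, seed = 1) {
  if (!length(segments)) stop_nv("need at least one segment")
  segs <- lapply(segments, function(s) {
    p0 <- as.numeric(s$p0); p1 <- as.numeric(s$p1); r <- as.numeric(s$radius)
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) stop_nv("degenerate zero-length segment")
    if (r < max(voxel_size))
      stop_nv("segment radius %.3g um is below one voxel (%.3g um)", r, max(voxel_size))
    list(p0 = p0, p1 = p1, r = r, L = L, u = (p1 - p0) / L)
  })
  # pericyte soma positions and per-segment radius modulation
  peri <- list()
  if (!is.null(pericytes)) {
    peri <- lapply(pericytes, function(p) {
      sg <- segs[[p$segment]]
      s_um <- p$at * sg$L
      centre <- sg$p0 + s_um * sg$u
      # radial direction: any unit vector perpendicular to the axis
      perp <- if (abs(sg$u[3]) < 0.9) {
        v <- c(-sg$u[2], sg$u[1], 0)
        v / sqrt(sum(v^2))
      } else c(1, 0, 0)
      r_at <- sg$r * (1 - p$constriction)
      list(segment = p$segment, s_um = s_um,
           constriction = p$constriction, extent_um = p$extent_um,
           soma = centre + perp * r_at)
    })
  }

  pts <- do.call(rbind, lapply(segs, function(s) rbind(s$p0, s$p1)))
  lo <- apply(pts, 2, min) - margin_um
  hi <- apply(pts, 2, max) + margin_um
  # array axes are (y, x, z); world coords are (x, y, z)
  vs <- voxel_size
  ny <- as.integer(ceiling((hi[2] - lo[2]) / vs[1]))
  nx <- as.integer(ceiling((hi[1] - lo[1]) / vs[2]))
  nz <- as.integer(ceiling((hi[3] - lo[3]) / vs[3]))
  ycoord <- lo[2] + (seq_len(ny) - 0.5) * vs[1]
  xcoord <- lo[1] + (seq_len(nx) - 0.5) * vs[2]
  zcoord <- lo[3] + (seq_len(nz) - 0.5) * vs[3]

  mask <- array(0, dim = c(ny, nx, nz))     # partial-volume occupancy in [0,1]
  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    mods <- Filter(function(p) p$segment == si, peri)
    rmax <- sg$r
    bb_lo <- pmin(sg$p0, sg$p1) - rmax - 1
    bb_hi <- pmax(sg$p0, sg$p1) + rmax + 1
    yi <- which(ycoord >= bb_lo[2] & ycoord <= bb_hi[2])
    xi <- which(xcoord >= bb_lo[1] & xcoord <= bb_hi[1])
    zi <- which(zcoord >= bb_lo[3] & zcoord <= bb_hi[3])
    if (!length(yi) || !length(xi) || !length(zi)) next
    g <- expand.grid(y = ycoord[yi], x = xcoord[xi], z = zcoord[zi])
    rel <- cbind(g$x - sg$p0[1], g$y - sg$p0[2], g$z - sg$p0[3])
    s <- pmin(pmax(rel %*% sg$u, 0), sg$L)
    ax <- outer(as.vector(s), sg$u)
    rad2 <- rowSums((rel - ax)^2)
    r_loc <- rep(sg$r, length(s))
    for (m in mods)
      r_loc <- r_loc * (1 - m$constriction *
                          exp(-(as.vector(s) - m$s_um)^2 / (2 * (m$extent_um / 2)^2)))
    # partial-volume edge: full inside r - w/2, linear ramp over one voxel
    w <- min(vs)
    frac <- pmin(1, pmax(0, (r_loc - sqrt(rad2)) / w + 0.5))
    inside <- frac > 0
    if (any(inside)) {
      gi <- expand.grid(y = yi, x = xi, z = zi)
      idx <- cbind(gi$y[inside], gi$x[inside], gi$z[inside])
      mask[idx] <- pmax(mask[idx], frac[inside])
    }
  }

  with_seed(seed, {
    data <- bg + (fg - bg) * mask
    if (noise_sd > 0) data <- data + array(rnorm(length(data), sd = noise_sd),
                                           dim = dim(data))
    soma_df <- if (length(peri)) {
      do.call(rbind, lapply(peri, function(p)
        data.frame(x_um = p$soma[1] - lo[1], y_um = p$soma[2] - lo[2],
                   z_um = p$soma[3] - lo[3], segment = p$segment,
                   constriction = p$constriction, extent_um = p$extent_um)))
    } else data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric())
    list(stack = anatomy_stack(data, vs),
         pericytes = soma_df,
         true_mask = mask >= 0.5,
         truth = new_ground_truth(
           true_network_length = sum(vapply(segs, `[[`, numeric(1), "L")),
           true_radii = vapply(segs, `[[`, numeric(1), "r"),
           volume_mm3 = prod(dim(mask)) * prod(vs) / 1e9,
           origin_um = lo, seed = seed))
  })
}

#' Generate a pose-tracking table
#'
#' Emulates a pose-estimation export: the mouse's four body labels (head,
#' tail, two headplates) move along a waypoint path at constant speed with
#' symmetric offsets (so the label centroid is exactly on the path), and two
#' wheel markers rotate about a fixed hub. A fraction of rows can be dropped
#' out: those rows get likelihood < 1 and corrupted coordinates, emulating
#' failed frames.
#'
#' @param path matrix of waypoints in cm (n x 2), the mouse trajectory.
#' @param wheel_rotations full wheel turns over the recording.
#' @param fps frames per second (default 30).
#' @param duration_s recording length (s).
#' @param px_per_cm camera scale.
#' @param dropout_rate fraction of rows corrupted.
#' @param seed integer RNG seed.
#' @return list with `table` (class `tracking_table`: data.frame
#'   `frame, label, x, y, likelihood` with `fps` and `px_per_cm` attributes)
#'   and `truth` (`true_path_length` in cm, wheel marker path length,
#'   dropout fraction).
#' @export
gen_tracking <- function(path, wheel_rotations = 0, fps = 30, duration_s = 60,
                         px_per_cm = 10, dropout_rate = 0, seed = 1) {
  path <- as.matrix(path)
  if (ncol(path) != 2L || nrow(path) < 1L) stop_nv("`path` must be an n x 2 matrix (cm)")
  n_frames <- round(duration_s * fps)
  seglen <- if (nrow(path) > 1L) sqrt(rowSums(diff(path)^2)) else numeric()
  L <- sum(seglen)
  tt <- seq(0, 1, length.out = n_frames)
  if (L > 0) {
    cum <- c(0, cumsum(seglen))
    s <- tt * L
    cx <- approx(cum, path[, 1], xout = s, rule = 2)$y
    cy <- approx(cum, path[, 2], xout = s, rule = 2)$y
    # heading from the local segment direction
    seg_i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(path) - 1L)
    hx <- (path[seg_i + 1L, 1] - path[seg_i, 1]) / seglen[seg_i]
    hy <- (path[seg_i + 1L, 2] - path[seg_i, 2]) / seglen[seg_i]
  } else {
    cx <- rep(path[1, 1], n_frames); cy <- rep(path[1, 2], n_frames)
    hx <- rep(1, n_frames); hy <- rep(0, n_frames)
  }
  body <- list(head = c(1, 0), tail = c(-1, 0),
               left_headplate = c(0, 0.5), right_headplate = c(0, -0.5))
  # wheel hub away from the path
  hub <- c(max(path[, 1]) + 15, max(path[, 2]) + 15)
  ang <- 2 * pi * wheel_rotations * tt
  wheel <- list(wheel_inner = 1.5, wheel_outer = 3)

  rows <- list()
  for (nm in names(body)) {
    off <- body[[nm]]
    # offsets rotate with heading; symmetric pairs cancel in the centroid
    rows[[nm]] <- data.frame(
      frame = seq_len(n_frames), label = nm,
      x = (cx + off[1] * hx - off[2] * hy) * px_per_cm,
      y = (cy + off[1] * hy + off[2] * hx) * px_per_cm,
      likelihood = 1)
  }
  for (nm in names(wheel)) {
    r <- wheel[[nm]]
    rows[[nm]] <- data.frame(
      frame = seq_len(n_frames), label = nm,
      x = (hub[1] + r * cos(ang)) * px_per_cm,
      y = (hub[2] + r * sin(ang)) * px_per_cm,
      likelihood = 1)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$frame, tab$label), ]
  rownames(tab) <- NULL

  with_seed(seed, {
    n_drop <- 0L
    if (dropout_rate > 0) {
      drop <- runif(nrow(tab)) < dropout_rate
      n_drop <- sum(drop)
      tab$likelihood[drop] <- runif(n_drop, 0.2, 0.99)
      tab$x[drop] <- tab$x[drop] + rnorm(n_drop, sd = 50)
      tab$y[drop] <- tab$y[drop] + rnorm(n_drop, sd = 50)
    }
    attr(tab, "fps") <- fps
    attr(tab, "px_per_cm") <- px_per_cm
    class(tab) <- c("tracking_table", "data.frame")
    # wheel-marker camera-plane path length (cm), mean of the two markers
    wheel_len <- mean(vapply(unlist(wheel), function(r)
      sum(sqrt(diff(r * cos(ang))^2 + diff(r * sin(ang))^2)), numeric(1)))
    list(table = tab,
         truth = new_ground_truth(true_path_length = L,
                                  wheel_marker_length = wheel_len,
                                  dropout_fraction = n_drop / nrow(tab),
                                  seed = seed))
  })
}
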