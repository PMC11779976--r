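# In vivo imaging extraction: vessel skeletonisation of the mean image,
# perpendicular-profile FWHM diametry, radon-style projection-variance
# velocimetry of line-scan kymographs, and calibre classification.

# Otsu's histogram threshold (maximises between-class variance)
otsu_threshold <- function(x, n_breaks = 256) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_breaks + 1), plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sb2 <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Skeletonise the mean image of a vessel movie
#'
#' Thresholds the mean image (Otsu), keeps the largest connected foreground
#' component (with a warning if more than one is present), thins it to a
#' one-pixel centreline, orders the centreline points along the vessel and
#' attaches per-point unit tangents estimated by local principal-direction
#' regression over a neighbourhood of skeleton points.
#'
#' @param mean_image numeric matrix `[y, x]` containing one dominant bright
#'   vessel.
#' @param pixel_size µm per pixel.
#' @param tangent_window number of skeleton points for the local tangent fit
#'   (default 5).
#' @return a [skeleton_model] with `points` columns (x, y) in pixel
#'   coordinates.
#' @export
skeletonize_2d <- function(mean_image, pixel_size, tangent_window = 5) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  thr <- otsu_threshold(mean_image)
  bw <- mean_image >= thr
  if (!any(bw))
    stop_nv("no foreground after thresholding (Otsu threshold = %.4g)", thr)
  d3 <- c(nrow(bw), ncol(bw), 1L)
  lab <- label26_cpp(as.vector(bw), as.integer(d3))
  tab <- tabulate(lab)
  if (length(tab) > 1L)
    warn_nv("%d foreground components; keeping the largest (%d px, next %d px)",
            length(tab), max(tab), sort(tab, decreasing = TRUE)[2])
  keep <- which.max(tab)
  bw <- array(lab == keep, dim = d3)
  pr <- edt3d_cpp(as.vector(bw), as.integer(d3), c(1, 1, 1))
  pr <- pr + tie_break_gradient(as.integer(d3))
  sk <- array(thin3d_cpp(as.vector(bw), as.integer(d3), pr), dim = d3)[, , 1]

  pts <- which(sk, arr.ind = TRUE)           # (row = y, col = x)
  # prune lateral spurs anchored by boundary bumps: anything shorter than
  # ~the vessel half-width hanging off the main path is an artefact
  pts3 <- cbind(pts, 1L)
  edges <- skeleton_edges(pts3, c(1, 1, 1))
  prune_px <- 1.5 * max(pr) + 1
  repeat {
    drop <- prune_spurs(nrow(pts3), edges, prune_px)
    if (!length(drop)) break
    pts3 <- pts3[-drop, , drop = FALSE]
    edges <- skeleton_edges(pts3, c(1, 1, 1))
  }
  pts <- pts3[, 1:2, drop = FALSE]
  ord <- order_skeleton_path(pts)
  pts <- pts[ord, , drop = FALSE]
  xy <- cbind(x = pts[, 2], y = pts[, 1])
  tg <- path_tangents(xy, tangent_window)
  skeleton_model(xy, tangents = tg, spacing = c(pixel_size, pixel_size))
}

# order skeleton pixels along the path by nearest-neighbour walking from an
# extremal endpoint; works for a single (possibly slightly branched) vessel
order_skeleton_path <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  # start from the point with fewest neighbours (an endpoint)
  dmat <- as.matrix(dist(pts))
  nb_count <- rowSums(dmat > 0 & dmat < 2)
  start <- which.min(nb_count + pts[, 1] * 1e-9)
  ord <- integer(n)
  used <- logical(n)
  cur <- start
  for (i in seq_len(n)) {
    ord[i] <- cur
    used[cur] <- TRUE
    cand <- which(!used)
    if (!length(cand)) break
    nxt <- cand[which.min(dmat[cur, cand])]
    if (dmat[cur, nxt] > 3) { ord <- ord[seq_len(i)]; break }  # stray spur
    cur <- nxt
  }
  ord[ord > 0]
}

# unit tangents from a local PCA over a sliding window of ordered points
path_tangents <- function(xy, window = 5) {
  n <- nrow(xy)
  half <- floor(window / 2)
  tg <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    w <- xy[lo:hi, , drop = FALSE]
    w <- sweep(w, 2, colMeans(w))
    v <- svd(w, nu = 0, nv = 1)$v[, 1]
    # orient along increasing path order
    ref <- xy[hi, ] - xy[lo, ]
    if (sum(v * ref) < 0) v <- -v
    tg[i, ] <- v
  }
  tg
}

#' Full width at half maximum of an intensity profile
#'
#' The baseline is the mean of the outer 10% of samples on each side; the
#' half-maximum level is `baseline + (peak - baseline) / 2`. The width is the
#' distance between the two half-maximum crossings flanking the global peak:
#' the profile is first refined by 10x cubic-spline interpolation and each
#' crossing is then located by linear sub-pixel interpolation on the refined
#' profile. Translation- and intensity-scale-invariant by construction.
#'
#' @param profile numeric intensity profile (>= 5 samples).
#' @param pixel_size µm per sample.
#' @return width in µm, or `NA` with a `"reason"` attribute when a crossing
#'   is missing on either side (vessel clipped by the window).
#' @export
fwhm <- function(profile, pixel_size) {
  if (length(profile) < 5L) stop_nv("profile must have at least 5 samples")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  w <- fwhm_mat(matrix(profile, nrow = 1), pixel_size)
  if (is.na(w$width)) return(structure(NA_real_, reason = w$reason))
  w$width
}

# vectorised FWHM over a matrix of profiles (rows = profiles); returns
# data.frame(width, reason). Profiles are upsampled 10x by cubic spline
# before the crossing search so the sub-pixel crossing stays accurate even
# when the transition spans only a couple of samples.
fwhm_mat <- function(P, pixel_size, refine = 10L) {
  n <- ncol(P)
  nb <- max(1L, ceiling(0.1 * n))
  baseline <- (rowMeans(P[, seq_len(nb), drop = FALSE]) +
                 rowMeans(P[, n - seq_len(nb) + 1L, drop = FALSE])) / 2
  width <- rep(NA_real_, nrow(P))
  reason <- rep("", nrow(P))
  for (r in seq_len(nrow(P))) {
    p0 <- P[r, ]
    if (anyNA(p0)) { reason[r] <- "profile_outside_image"; next }
    sp <- stats::spline(seq_len(n), p0, n = (n - 1L) * refine + 1L)
    p <- sp$y
    xs <- sp$x
    m <- length(p)
    k <- which.max(p)
    h <- baseline[r] + (p[k] - baseline[r]) / 2
    below_l <- which(p[seq_len(k)] < h)
    below_r <- which(p[k:m] < h)
    if (!length(below_l)) { reason[r] <- "no_left_crossing"; next }
    if (!length(below_r)) { reason[r] <- "no_right_crossing"; next }
    jl <- max(below_l)                       # crossing between jl and jl+1
    xl <- xs[jl] + (h - p[jl]) / (p[jl + 1] - p[jl]) * (xs[jl + 1] - xs[jl])
    jr <- k - 1L + min(below_r)              # crossing between jr-1 and jr
    xr <- xs[jr] - (h - p[jr]) / (p[jr - 1] - p[jr]) * (xs[jr] - xs[jr - 1])
    width[r] <- (xr - xl) * pixel_size
  }
  data.frame(width = width, reason = reason, stringsAsFactors = FALSE)
}

#' Vessel diameter time series by perpendicular FWHM
#'
#' For every frame, samples an intensity profile perpendicular to the local
#' tangent at each skeleton point (bilinear interpolation, one sample per
#' pixel), measures the FWHM of each profile, and averages the valid widths.
#' A frame is flagged invalid when fewer than 50% of the usable skeleton
#' points yield a width.
#'
#' @param movie a [vessel_movie].
#' @param skeleton a [skeleton_model] derived from this movie's mean image.
#' @param profile_halfwidth half-length of the sampled profile in µm;
#'   default 2x the diameter estimated at the central skeleton point of the
#'   mean image.
#' @param point_stride use every `point_stride`-th skeleton point (default 1).
#' @return a [diameter_trace].
#' @export
diameter_trace_fwhm <- function(movie, skeleton, profile_halfwidth = NULL,
                                point_stride = 1L) {
  if (nrow(skeleton$points) == 0L) stop_nv("skeleton is empty")
  px <- movie$pixel_size
  d <- dim(movie$data)
  ny <- d[1]; nx <- d[2]; nf <- d[3]
  pts <- skeleton$points[seq(1, nrow(skeleton$points), by = point_stride), , drop = FALSE]
  tgs <- skeleton$tangents[seq(1, nrow(skeleton$points), by = point_stride), , drop = FALSE]

  if (is.null(profile_halfwidth)) {
    mean_img <- apply(movie$data, c(1, 2), mean)
    mid <- ceiling(nrow(pts) / 2)
    est <- probe_fwhm(mean_img, pts[mid, ], tgs[mid, ], px, ny, nx)
    if (is.na(est)) est <- 10
    profile_halfwidth <- 2 * est
  }
  s_px <- seq(-profile_halfwidth, profile_halfwidth, by = px) / px
  ns <- length(s_px)
  # normals rotate tangents by 90 degrees
  nxv <- -tgs[, 2]; nyv <- tgs[, 1]
  X <- outer(pts[, 1], rep(1, ns)) + outer(nxv, s_px)
  Y <- outer(pts[, 2], rep(1, ns)) + outer(nyv, s_px)
  usable <- rowSums(X < 1 | X > nx | Y < 1 | Y > ny) == 0
  if (!any(usable))
    stop_nv("no skeleton point admits a full perpendicular profile; reduce profile_halfwidth")
  X <- X[usable, , drop = FALSE]; Y <- Y[usable, , drop = FALSE]

  # bilinear interpolation weights are identical for all frames
  x0 <- pmin(floor(X), nx - 1); y0 <- pmin(floor(Y), ny - 1)
  fx <- X - x0; fy <- Y - y0
  i00 <- y0 + (x0 - 1) * ny
  i10 <- i00 + 1
  i01 <- i00 + ny
  i11 <- i01 + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy); w11 <- fx * fy

  npts <- nrow(X)
  values <- rep(NA_real_, nf)
  valid <- logical(nf)
  reason <- rep("", nf)
  nvalid <- integer(nf)
  for (f in seq_len(nf)) {
    Fm <- movie$data[, , f]
    prof <- w00 * Fm[i00] + w10 * Fm[i10] + w01 * Fm[i01] + w11 * Fm[i11]
    dim(prof) <- c(npts, ns)
    res <- fwhm_mat(prof, px)
    ok <- !is.na(res$width)
    nvalid[f] <- sum(ok)
    if (sum(ok) < 0.5 * npts) {
      reason[f] <- "insufficient_valid_points"
    } else {
      values[f] <- mean(res$width[ok])
      valid[f] <- TRUE
    }
  }
  diameter_trace(values, movie$frame_rate, valid = valid, reason = reason,
                 n_valid_points = nvalid)
}

# one-off FWHM probe at a single skeleton point of a 2D image
probe_fwhm <- function(img, pt, tg, px, ny, nx) {
  hw <- min((min(nx, ny) / 2 - 2) * px, 40)
  s <- seq(-hw, hw, by = px) / px
  xs <- pt[1] - tg[2] * s
  ys <- pt[2] + tg[1] * s
  ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  if (sum(ok) < 5) return(NA_real_)
  x0 <- pmin(floor(xs[ok]), nx - 1); y0 <- pmin(floor(ys[ok]), ny - 1)
  fx <- xs[ok] - x0; fy <- ys[ok] - y0
  v <- (1 - fx) * (1 - fy) * img[cbind(y0, x0)] + (1 - fx) * fy * img[cbind(y0 + 1, x0)] +
    fx * (1 - fy) * img[cbind(y0, x0 + 1)] + fx * fy * img[cbind(y0 + 1, x0 + 1)]
  w <- fwhm_mat(matrix(v, nrow = 1), px)$width
  w
}

# projection variance of a tapered, mean-subtracted kymograph window at
# streak slope m (pixels of displacement per scan line). Fully vectorised:
# the window is fractionally sheared so streaks of slope m become vertical,
# then projected along the shear axis. The caller tapers the window to zero
# at its edges, so out-of-bounds samples contribute zero and every
# projection offset has identical support (no slope-dependent edge bias).
proj_variance <- function(W, m) {
  nt <- nrow(W); nc <- ncol(W)
  if (abs(m) <= sqrt(nc / nt)) {
    # offsets run over columns; sample along rows
    shift <- m * (seq_len(nt) - (nt + 1) / 2)
    pos0 <- floor(shift)
    fr <- shift - pos0
    C <- outer(pos0, seq_len(nc), `+`)              # nt x nc target column
    ok <- C >= 1 & C + 1 <= nc
    Cc <- pmax(pmin(C, nc - 1L), 1L)
    idx1 <- seq_len(nt) + nt * (Cc - 1)
    V <- (1 - fr) * W[idx1] + fr * W[idx1 + nt]
    dim(V) <- dim(ok)
    V[!ok] <- 0
    P <- colMeans(V)
  } else {
    # offsets run over rows; sample along columns with inverse slope
    shift <- (seq_len(nc) - (nc + 1) / 2) / m
    pos0 <- floor(shift)
    fr <- shift - pos0
    R <- outer(seq_len(nt), pos0, `+`)              # nt x nc target row
    ok <- R >= 1 & R + 1 <= nt
    Rc <- pmax(pmin(R, nt - 1L), 1L)
    idx1 <- Rc + nt * (col(Rc) - 1)
    frm <- matrix(fr, nt, nc, byrow = TRUE)
    V <- (1 - frm) * W[idx1] + frm * W[idx1 + 1]
    dim(V) <- dim(ok)
    V[!ok] <- 0
    P <- rowMeans(V)
  }
  var(P)
}

#' Red blood cell velocity from a kymograph (radon projection variance)
#'
#' Splits the kymograph into overlapping windows and, in each, finds the
#' streak slope whose line integrals have maximal variance — the angle of
#' maximum radon projection variance, parameterised directly by slope so the
#' velocity resolution stays uniform for steep streaks. The slope search is a
#' two-sided logarithmic sweep refined around the peak. Velocity is
#' `slope * pixel_size * line_rate / 1000` (mm/s); motion toward increasing
#' position index is positive.
#'
#' Window quality is the ratio of peak to median projection variance over
#' the sweep; a window is flagged when its contrast fails to exceed
#' `quality_floor` times the contrast of the same window with its pixels
#' deterministically shuffled (a no-signal surrogate).
#'
#' @param kymo a [kymograph].
#' @param window_len lines per analysis window (>= 64, default 128).
#' @param window_overlap fractional overlap between windows (default 0.5).
#' @param n_coarse slopes per sign in the coarse sweep.
#' @param quality_floor multiple of the surrogate contrast required to trust
#'   a window (default 2).
#' @return a [velocity_trace] (one value per window; flagged windows carry
#'   `NA`).
#' @export
rbcv_radon <- function(kymo, window_len = 128, window_overlap = 0.5,
                       n_coarse = 40, quality_floor = 2) {
  if (window_len < 64) stop_nv("window_len must be >= 64 lines")
  img <- kymo$data
  n <- nrow(img); nc <- ncol(img)
  step <- max(1L, round(window_len * (1 - window_overlap)))
  starts <- seq(1L, n - window_len + 1L, by = step)
  m_min <- 2 / window_len
  m_max <- nc / 2
  mgrid <- exp(seq(log(m_min), log(m_max), length.out = n_coarse))
  mgrid <- c(-rev(mgrid), mgrid)

  vel <- qual <- rep(NA_real_, length(starts))
  flagged <- rep(TRUE, length(starts))
  centres <- (starts + window_len / 2 - 1) / kymo$line_rate
  taper <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  tap <- outer(taper(window_len), taper(nc))
  for (wi in seq_along(starts)) {
    W <- img[starts[wi]:(starts[wi] + window_len - 1L), , drop = FALSE]
    if (stats::sd(W) == 0) { qual[wi] <- 0; next }    # blank/saturated window
    W <- (W - mean(W)) * tap
    vs <- vapply(mgrid, function(m) proj_variance(W, m), numeric(1))
    if (all(is.na(vs))) { qual[wi] <- 0; next }
    # multi-start multiplicative refinement from the top coarse candidates:
    # at steep slopes the variance curve can be bumpy and a single argmax
    # start occasionally locks onto a secondary peak
    starts_m <- mgrid[order(vs, decreasing = TRUE)[1:3]]
    best <- starts_m[1]; bestv <- -Inf
    for (m0 in starts_m) {
      cur <- m0
      for (span in c(0.25, 0.08, 0.02, 0.006)) {
        loc <- cur * exp(seq(-span, span, length.out = 9))
        lv <- vapply(loc, function(m) proj_variance(W, m), numeric(1))
        if (all(is.na(lv))) break
        cur <- loc[which.max(lv)]
      }
      fv <- proj_variance(W, cur)
      if (!is.na(fv) && fv > bestv) { bestv <- fv; best <- cur }
    }
    contrast <- max(vs, na.rm = TRUE) / stats::median(vs, na.rm = TRUE)
    # deterministic no-signal surrogate: fixed-seed pixel shuffle
    Ws <- matrix(W[with_seed(20240601L, sample.int(length(W)))], nrow(W), ncol(W))
    vs0 <- vapply(mgrid, function(m) proj_variance(Ws, m), numeric(1))
    contrast0 <- max(vs0, na.rm = TRUE) / stats::median(vs0, na.rm = TRUE)
    qual[wi] <- contrast / contrast0
    if (contrast >= quality_floor * contrast0) {
      flagged[wi] <- FALSE
      vel[wi] <- best * kymo$pixel_size * kymo$line_rate / 1000
    }
  }
  velocity_trace(vel, centres, qual, flagged)
}

#' Classify a vessel by calibre
#'
#' Diameters below 7 µm are capillaries; superficial vessels above 12 µm are
#' pial; everything else (including the 7 and 12 µm boundaries) is an
#' intermediate vessel. Deep vessels above 12 µm are classed intermediate
#' with a warning.
#'
#' @param diameter vessel diameter in µm (vectorised).
#' @param superficial logical: does the vessel lie at the cortical surface?
#' @return character vector in {"capillary", "intermediate", "pial"}.
#' @export
classify_vessel <- function(diameter, superficial = FALSE) {
  if (any(diameter <= 0)) stop_nv("diameter must be > 0")
  superficial <- rep_len(superficial, length(diameter))
  out <- rep("intermediate", length(diameter))
  out[diameter < 7] <- "capillary"
  out[diameter > 12 & superficial] <- "pial"
  if (any(diameter > 12 & !superficial))
    warn_nv("%d vessel(s) > 12 um but not superficial; classed intermediate",
            sum(diameter > 12 & !superficial))
  out
}

#' Integer-shift movie registration (optional pre-processing)
#'
#' Aligns each frame to the movie's mean image by maximising the
#' cross-correlation over integer shifts. Provided for unregistered inputs;
#' the pipeline otherwise assumes frames are pre-registered.
#'
#' @param movie a [vessel_movie].
#' @param max_shift largest shift searched (px).
#' @return a [vessel_movie] with shifted frames (edges padded with the frame
#'   median).
#' @export
register_movie <- function(movie, max_shift = 5) {
  d <- dim(movie$data)
  ref <- apply(movie$data, c(1, 2), mean)
  ref <- ref - mean(ref)
  shifts <- -max_shift:max_shift
  out <- movie$data
  for (f in seq_len(d[3])) {
    Fm <- movie$data[, , f] - mean(movie$data[, , f])
    best <- c(0L, 0L); bestv <- -Inf
    for (dy in shifts) for (dx in shifts) {
      ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
      xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
      v <- sum(Fm[ys - dy, xs - dx] * ref[ys, xs])
      if (v > bestv) { bestv <- v; best <- c(dy, dx) }
    }
    if (any(best != 0L)) {
      shifted <- matrix(median(movie$data[, , f]), d[1], d[2])
      ys <- max(1, 1 + best[1]):min(d[1], d[1] + best[1])
      xs <- max(1, 1 + best[2]):min(d[2], d[2] + best[2])
      shifted[ys, xs] <- movie$data[ys - best[1], xs - best[2], f]
      out[, , f] <- shifted
    }
  }
  vessel_movie(out, movie$pixel_size, movie$frame_rate)
}
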