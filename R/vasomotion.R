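# Vasomotion: spontaneous ~0.1 Hz diameter oscillations quantified as
# spectral power at 0.1 Hz from baseline recordings.

# Welch power spectral density: linear detrend, Hann-tapered segments with
# 50% overlap, mean of segment periodograms. Returns density per Hz.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  U <- sum(win^2)
  nf <- floor(seg_len / 2)
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg)
    sp <- abs(fft(seg * win))^2 / (U * fs)
    p <- sp[seq_len(nf + 1L)]
    # fold the two-sided spectrum (all bins except DC and Nyquist double)
    if (nf >= 2) p[2:(nf + if (seg_len %% 2 == 0) 0 else 1)] <-
        2 * p[2:(nf + if (seg_len %% 2 == 0) 0 else 1)]
    acc <- acc + p
  }
  list(freqs = (0:nf) * fs / seg_len, power = acc / length(starts))
}

#' Vasomotion power at 0.1 Hz
#'
#' Linearly detrends the diameter trace, estimates its Welch power spectral
#' density (Hann taper, 50% overlap, segment length chosen for `df` Hz
#' resolution), interpolates the spectrum linearly onto a common frequency
#' grid, discards everything above `fmax` (1 Hz), and reads out the power at
#' the grid point nearest `f0` (0.1 Hz). The relative power is that value
#' divided by the total power at or below `fmax`, making the readout
#' unit-free across vessels.
#'
#' @param trace a [diameter_trace] or numeric vector.
#' @param sample_rate Hz; taken from the trace when it is a
#'   `diameter_trace`.
#' @param df frequency-grid resolution (Hz, default 0.01). The nominal Welch
#'   segment length `sample_rate / df` is capped at two-thirds of the trace
#'   (with a warning) so at least two overlapping segments are averaged.
#' @param fmax upper frequency bound (Hz, default 1).
#' @param f0 readout frequency (Hz, default 0.1).
#' @return list with `spectrum` (a [power_spectrum] on the common grid),
#'   `power_0p1` (density at the grid point nearest `f0`) and
#'   `relative_power` (unit-free, in [0, 1]).
#' @export
vasomotion_power <- function(trace, sample_rate = NULL, df = 0.01, fmax = 1,
                             f0 = 0.1) {
  if (inherits(trace, "diameter_trace")) {
    sample_rate <- trace$frame_rate
    x <- trace$values
    # interpolate over flagged frames so gaps do not corrupt the spectrum
    if (any(!trace$valid) && any(trace$valid))
      x <- approx(which(trace$valid), x[trace$valid], xout = seq_along(x),
                  rule = 2)$y
  } else x <- as.numeric(trace)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  n <- length(x)
  seg_nominal <- round(sample_rate / df)
  seg_len <- min(seg_nominal, floor(2 * n / 3))
  if (seg_len < seg_nominal)
    warn_nv("trace (%.1f s) shorter than two Welch segments at df = %g Hz; segment reduced to %.1f s",
            n / sample_rate, df, seg_len / sample_rate)
  if (seg_len / sample_rate < 2 / f0)
    stop_nv("trace too short: Welch segment %.1f s cannot resolve %.2g Hz (need >= %.0f s)",
            seg_len / sample_rate, f0, 2 / f0 * 1.5)

  # linear detrend
  t <- seq_along(x)
  x <- stats::residuals(lm(x ~ t))
  w <- welch_psd(x, sample_rate, seg_len)
  grid <- seq(0, fmax, by = df)
  pw <- approx(w$freqs, w$power, xout = grid, rule = 2)$y
  pw[pw < 0] <- 0
  spec <- power_spectrum(grid, pw, n / sample_rate)
  i0 <- which.min(abs(grid - f0))
  total <- sum(pw)
  list(spectrum = spec, power_0p1 = pw[i0],
       relative_power = if (total > 0) pw[i0] / total else 0)
}
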