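# Neuronal calcium analysis: baseline event statistics during rest periods,
# ON/OFF/BOTH stimulus-response classification, and the neurovascular
# coupling index (vessel AUC / mean neuronal AUC).

#' Baseline calcium event statistics
#'
#' Within every rest period of at least `min_rest` seconds, detects events
#' as excursions above a threshold of `k` median-absolute-deviations over
#' the rest-period median; each excursion contributes one peak (its local
#' maximum), so noise wiggles riding on a transient's decay are not counted
#' again. Reports the event rate (peaks per minute) and the mean peak size
#' (peak minus median) per cell, averaged across rest periods weighted by
#' duration.
#'
#' @param traces a `calcium_traces` object (or list with `dff` cells x
#'   samples and `sample_rate`).
#' @param locomotion a [locomotion_trace] co-registered in time.
#' @param min_rest minimum rest duration (s, default 10).
#' @param k MAD multiplier for the peak threshold (default 3).
#' @param speed_eps stillness threshold.
#' @return data.frame per cell: `cell`, `peaks_per_min`, `mean_peak_size`,
#'   `threshold_k`; `NA` rows (with a warning) when no rest period
#'   qualifies.
#' @export
baseline_calcium_stats <- function(traces, locomotion, min_rest = 10, k = 3,
                                   speed_eps = 0) {
  rp <- rest_periods(locomotion, min_rest, speed_eps)
  cells <- rownames(traces$dff) %||% sprintf("cell_%02d", seq_len(nrow(traces$dff)))
  if (nrow(rp) == 0L) {
    warn_nv("no rest period of >= %g s; baseline calcium stats undefined", min_rest)
    return(data.frame(cell = cells, peaks_per_min = NA_real_,
                      mean_peak_size = NA_real_, threshold_k = k))
  }
  fs <- traces$sample_rate
  out <- lapply(seq_len(nrow(traces$dff)), function(ci) {
    x <- traces$dff[ci, ]
    rates <- sizes <- durs <- numeric(0)
    for (i in seq_len(nrow(rp))) {
      i0 <- max(1L, floor(rp$start_s[i] * fs) + 1L)
      i1 <- min(length(x), ceiling(rp$end_s[i] * fs))
      seg <- x[i0:i1]
      n <- length(seg)
      if (n < 3L) next
      med <- median(seg)
      spread <- mad(seg)
      dur <- (i1 - i0 + 1L) / fs
      if (spread == 0) {                      # degenerate constant segment
        rates <- c(rates, 0); sizes <- c(sizes, NA_real_); durs <- c(durs, dur)
        next
      }
      above <- seg > med + k * spread
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      epochs <- which(r$values)
      pk_sizes <- vapply(epochs, function(e)
        max(seg[starts[e]:ends[e]]) - med, numeric(1))
      rates <- c(rates, length(epochs) / dur * 60)
      sizes <- c(sizes, if (length(epochs)) mean(pk_sizes) else NA_real_)
      durs <- c(durs, dur)
    }
    w <- durs / sum(durs)
    data.frame(cell = cells[ci],
               peaks_per_min = sum(rates * w),
               mean_peak_size = if (all(is.na(sizes))) NA_real_
                                else sum(sizes * w, na.rm = TRUE) /
                                  sum(w[!is.na(sizes)]),
               threshold_k = k)
  })
  do.call(rbind, out)
}

#' Classify cells as ON / OFF / BOTH / NONE
#'
#' Applied to trial-averaged, baseline-normalised ΔF/F traces. A cell gets
#' the on-flag when its peak in the stimulus window exceeds twice the
#' baseline SD (the same rule as vessel responsiveness), and the off-flag
#' when its peak in the `off_win` seconds immediately after stimulus offset
#' exceeds the same threshold. `BOTH` requires both flags, `NONE` neither.
#'
#' @param trial_mean matrix `[cell, sample]` of mean normalised trials (30 s
#'   layout: baseline, stimulus, post).
#' @param sample_rate Hz.
#' @param baseline_span,stim_dur seconds (defaults 5 and 5).
#' @param off_win seconds after offset scanned for OFF responses (default 5).
#' @return data.frame per cell: `cell`, `label`, `on_flag`, `off_flag`,
#'   `on_peak`, `off_peak`, `baseline_sd`, `auc_stim`.
#' @export
classify_cells <- function(trial_mean, sample_rate, baseline_span = 5,
                           stim_dur = 5, off_win = 5) {
  if (is.null(dim(trial_mean))) trial_mean <- matrix(trial_mean, nrow = 1)
  i_on <- round(baseline_span * sample_rate)
  i_off <- i_on + round(stim_dur * sample_rate)
  i_post <- min(ncol(trial_mean), i_off + round(off_win * sample_rate))
  cells <- rownames(trial_mean) %||% sprintf("cell_%02d", seq_len(nrow(trial_mean)))
  out <- lapply(seq_len(nrow(trial_mean)), function(ci) {
    x <- trial_mean[ci, ]
    bl_sd <- sd(x[seq_len(i_on)])
    on_pk <- max(x[(i_on + 1L):i_off])
    off_pk <- max(x[(i_off + 1L):i_post])
    # floor the threshold at 1% of the trace's dynamic range so that, in the
    # (near-)noiseless limit, indicator decay tails are not called
    # responses; with real noise 2*SD always dominates the floor
    thr <- max(2 * bl_sd, 0.01 * max(abs(x)))
    on_f <- on_pk > thr
    off_f <- off_pk > thr
    lab <- if (on_f && off_f) "BOTH" else if (on_f) "ON" else if (off_f) "OFF" else "NONE"
    data.frame(cell = cells[ci], label = lab, on_flag = on_f, off_flag = off_f,
               on_peak = on_pk, off_peak = off_pk, baseline_sd = bl_sd,
               auc_stim = trapz_uniform(x[(i_on + 1L):i_off], 1 / sample_rate))
  })
  do.call(rbind, out)
}

#' Neurovascular coupling index
#'
#' The AUC of one vessel's stimulus response divided by the mean neuronal
#' AUC of its matching group (genotype by default, because calcium data is
#' not available for every animal). Linear in the vessel AUC; scaling all
#' neuronal AUCs by `c` scales the index by `1/c`.
#'
#' @param vessel_auc vessel response AUC (percent x s).
#' @param neuronal_aucs ΔF/F x s values for the matching group (non-empty).
#' @param group label recording which grouping was used.
#' @return list of class `nvc_index`: `value`, `group`, `n_neuronal`;
#'   `value` is `NA` (with a warning) when the mean neuronal AUC is <= 0.
#' @export
nvci <- function(vessel_auc, neuronal_aucs, group = "genotype") {
  if (!length(neuronal_aucs)) stop_nv("`neuronal_aucs` must be non-empty")
  m <- mean(neuronal_aucs, na.rm = TRUE)
  val <- if (is.na(m) || m <= 0) {
    warn_nv("mean neuronal AUC <= 0; NVCi undefined")
    NA_real_
  } else vessel_auc / m
  structure(list(value = val, group = group,
                 n_neuronal = sum(!is.na(neuronal_aucs))),
            class = "nvc_index")
}

#' @export
print.nvc_index <- function(x, ...) {
  cat(sprintf("<nvc_index> %.4g (group %s, n = %d neuronal AUCs)\n",
              x$value, x$group, x$n_neuronal))
  invisible(x)
}
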