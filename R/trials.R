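# Stimulus-locked trial analysis: cut any trace into 30 s trials (5 s
# baseline, 5 s stimulus, 20 s post), gate out trials with locomotion in the
# 2 s before or during the stimulus, normalise to the final 1 s of baseline,
# and compute peak / AUC / time-to-peak plus the 2-SD responsiveness rule.

#' Segment a trace into stimulus-locked trials
#'
#' One row per stimulus onset. Trials that would extend past the recording
#' edges are kept as rows but excluded (`retained = FALSE`, reason
#' `"partial"`). The trial length in samples is rounded once from
#' `(baseline_span + stim_dur + post_span) * sample_rate` and used for every
#' trial.
#'
#' @param trace numeric sample vector.
#' @param sample_rate Hz.
#' @param schedule a [stim_schedule].
#' @param baseline_span seconds before onset kept as baseline (default 5).
#' @param post_span seconds after stimulus offset (default 20).
#' @return object of class `trial_set`: trials matrix `[trial, sample]`,
#'   `sample_rate`, spans, `retained`, `exclusion_reason`.
#' @export
segment_trials <- function(trace, sample_rate, schedule, baseline_span = 5,
                           post_span = 20) {
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate * schedule$stim_dur < 2)
    stop_nv("sample_rate %.3g Hz cannot resolve a %.3g s stimulus window",
            sample_rate, schedule$stim_dur)
  trial_len <- round((baseline_span + schedule$stim_dur + post_span) * sample_rate)
  i_on <- round(baseline_span * sample_rate)     # samples before onset
  n <- length(trace)
  k <- length(schedule$onsets)
  trials <- matrix(NA_real_, k, trial_len)
  retained <- rep(TRUE, k)
  reason <- rep("", k)
  for (i in seq_len(k)) {
    start <- round((schedule$onsets[i] - baseline_span) * sample_rate) + 1L
    end <- start + trial_len - 1L
    if (start < 1L || end > n) {
      retained[i] <- FALSE
      reason[i] <- "partial"
      next
    }
    trials[i, ] <- trace[start:end]
  }
  structure(list(trials = trials, sample_rate = sample_rate,
                 baseline_span = baseline_span, stim_dur = schedule$stim_dur,
                 post_span = post_span, onsets = schedule$onsets,
                 onset_sample = i_on, retained = retained,
                 exclusion_reason = reason),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d samples @ %.3g Hz, %d retained\n",
              nrow(x$trials), ncol(x$trials), x$sample_rate, sum(x$retained)))
  invisible(x)
}

#' Exclude trials with locomotion around the stimulus
#'
#' A trial is excluded (reason `"locomotion"`) when speed exceeds
#' `speed_eps` anywhere in `[onset - pre_window, onset + stim_dur]`. The
#' post-stimulus interval is not gated. Idempotent.
#'
#' @param tset a `trial_set`.
#' @param locomotion a [locomotion_trace] co-registered in time with the
#'   segmented trace.
#' @param pre_window seconds before onset included in the gate (default 2).
#' @param speed_eps speed magnitude treated as "not running" (default 0).
#' @return the gated `trial_set`.
#' @export
gate_locomotion <- function(tset, locomotion, pre_window = 2, speed_eps = 0) {
  t_loco <- (seq_along(locomotion$speed) - 1) / locomotion$sample_rate
  for (i in seq_len(nrow(tset$trials))) {
    if (!tset$retained[i]) next
    on <- tset$onsets[i]
    idx <- t_loco >= on - pre_window & t_loco <= on + tset$stim_dur
    if (any(abs(locomotion$speed[idx]) > speed_eps)) {
      tset$retained[i] <- FALSE
      tset$exclusion_reason[i] <- "locomotion"
    }
  }
  tset
}

#' Normalise a trial to its pre-stimulus baseline
#'
#' In `"percent"` mode (vessel diameter, haemodynamics) the trial is divided
#' by the mean over the final `norm_span` seconds before onset and expressed
#' as percent change: `value / mean * 100 - 100`. In `"subtract"` mode
#' (ΔF/F calcium, already a relative quantity) the same baseline mean is
#' subtracted instead, since a near-zero baseline makes division
#' meaningless.
#'
#' @param trial numeric vector (one trial row).
#' @param sample_rate Hz.
#' @param baseline_span seconds of baseline at the start of the trial.
#' @param norm_span seconds immediately before onset used for the
#'   normalisation mean (default 1).
#' @param mode `"percent"` or `"subtract"`.
#' @return normalised trial; in percent mode, all-`NA` with attribute
#'   `reason = "nonpositive_baseline"` when the baseline mean is <= 0.
#' @export
normalize_trial <- function(trial, sample_rate, baseline_span = 5,
                            norm_span = 1, mode = c("percent", "subtract")) {
  mode <- match.arg(mode)
  i_on <- round(baseline_span * sample_rate)
  nb <- round(norm_span * sample_rate)
  if (nb < 1 || i_on < nb) stop_nv("need at least %g s of baseline", norm_span)
  b <- mean(trial[(i_on - nb + 1L):i_on])
  if (mode == "subtract") return(trial - b)
  if (is.na(b) || b <= 0)
    return(structure(rep(NA_real_, length(trial)), reason = "nonpositive_baseline"))
  trial / b * 100 - 100
}

#' Response metrics of a normalised trial
#'
#' `baseline_sd` is the SD over the full baseline span; `max_peak` is the
#' maximum of the stimulus window; `auc` its trapezoidal integral; and
#' `time_to_peak` the argmax time from onset. A trial is responsive when its
#' peak exceeds twice the baseline SD.
#'
#' @param trial normalised trial (percent change).
#' @param sample_rate Hz.
#' @param baseline_span seconds of baseline (default 5).
#' @param stim_dur stimulus duration in seconds (default 5).
#' @return data.frame row: `max_peak`, `auc`, `time_to_peak`,
#'   `baseline_sd`, `responsive`, `valid`.
#' @export
response_metrics <- function(trial, sample_rate, baseline_span = 5,
                             stim_dur = 5) {
  if (anyNA(trial))
    return(data.frame(max_peak = NA_real_, auc = NA_real_,
                      time_to_peak = NA_real_, baseline_sd = NA_real_,
                      responsive = NA, valid = FALSE))
  i_on <- round(baseline_span * sample_rate)
  i_off <- i_on + round(stim_dur * sample_rate)
  bl_sd <- sd(trial[seq_len(i_on)])
  win <- trial[(i_on + 1L):i_off]
  pk <- max(win)
  ttp <- which.max(win) / sample_rate
  auc <- trapz_uniform(win, 1 / sample_rate)
  data.frame(max_peak = pk, auc = auc, time_to_peak = ttp,
             baseline_sd = bl_sd, responsive = pk > 2 * bl_sd, valid = TRUE)
}

#' Per-trial and mean-trace response summary of a trial set
#'
#' Normalises every retained trial, computes per-trial metrics (the basis of
#' the responsiveness rate), and also the metrics of the mean normalised
#' trace across retained trials (the basis of group-average response
#' figures).
#'
#' @param tset a `trial_set` (after gating).
#' @param mode trial normalisation mode, see [normalize_trial()].
#' @return list with `per_trial` (data.frame, one row per trial; excluded
#'   trials carry `NA` metrics and their exclusion reason), `mean_trace`
#'   (one metrics row), `mean_response` (the mean normalised trace) and
#'   `responsiveness` (percent of retained trials responsive).
#' @export
vessel_response <- function(tset, mode = c("percent", "subtract")) {
  mode <- match.arg(mode)
  k <- nrow(tset$trials)
  fs <- tset$sample_rate
  norm <- matrix(NA_real_, k, ncol(tset$trials))
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    if (!tset$retained[i]) {
      rows[[i]] <- cbind(response_metrics(NA_real_, fs), retained = FALSE,
                         reason = tset$exclusion_reason[i])
      next
    }
    nt <- normalize_trial(tset$trials[i, ], fs, tset$baseline_span, mode = mode)
    norm[i, ] <- nt
    rows[[i]] <- cbind(response_metrics(nt, fs, tset$baseline_span, tset$stim_dur),
                       retained = TRUE, reason = "")
  }
  per_trial <- do.call(rbind, rows)
  per_trial$trial <- seq_len(k)
  keep <- tset$retained & per_trial$valid
  mean_trace <- if (any(keep)) colMeans(norm[keep, , drop = FALSE]) else NULL
  mt <- if (is.null(mean_trace)) response_metrics(NA_real_, fs)
        else response_metrics(mean_trace, fs, tset$baseline_span, tset$stim_dur)
  list(per_trial = per_trial, mean_trace = mt, mean_response = mean_trace,
       responsiveness = responsiveness(per_trial))
}

#' Responsiveness rate
#'
#' Percentage of retained trials classified responsive. Excluded trials do
#' not enter the denominator.
#'
#' @param metrics per-trial metrics data.frame with `responsive` and
#'   `retained` columns (as from [vessel_response()]).
#' @return percent in [0, 100]; `NA` with a warning when no trial is
#'   retained.
#' @export
responsiveness <- function(metrics) {
  keep <- metrics$retained & metrics$valid
  if (!any(keep)) {
    warn_nv("no retained trials; responsiveness undefined")
    return(NA_real_)
  }
  100 * sum(metrics$responsive[keep]) / sum(keep)
}
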