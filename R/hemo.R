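# Net haemodynamics: CMRO2 from flux and haemoglobin, rest-period channel
# baselines, and reference-group normalisation across timepoints.

#' Cerebral metabolic rate of oxygen
#'
#' `CMRO2 = CBF * Hbd / Hbt`, elementwise over samples or scalars. Invariant
#' to common rescaling of Hbd and Hbt and linear in CBF. Samples with
#' non-positive Hbt are returned as `NA` (flagged invalid).
#'
#' @param cbf blood flow (flux units).
#' @param hbd deoxy-haemoglobin (a.u.).
#' @param hbt total haemoglobin (a.u.).
#' @return CMRO2 in CBF units.
#' @export
cmro2 <- function(cbf, hbd, hbt) {
  out <- cbf * hbd / hbt
  bad <- !is.na(hbt) & hbt <= 0
  if (any(bad)) {
    warn_nv("%d sample(s) with Hbt <= 0 flagged invalid", sum(bad))
    out[bad] <- NA_real_
  }
  out
}

#' Rest-period baselines of a haemodynamic recording
#'
#' Identifies no-locomotion periods of at least `min_rest` seconds and
#' averages every channel over their union (so the mean is weighted by rest
#' duration). Intended for recordings collected without visual stimulation.
#'
#' @param rec a [hemo_recording] (or any data.frame-holding list with
#'   `channels` and `sample_rate`).
#' @param locomotion a [locomotion_trace] co-registered in time.
#' @param min_rest minimum rest duration (s, default 10).
#' @param speed_eps stillness threshold, as in [rest_periods()].
#' @return list with `means` (named per-channel baselines), `n_periods`,
#'   `total_rest_s`. When no period qualifies the means are `NA` and a
#'   warning is raised.
#' @export
rest_baseline <- function(rec, locomotion, min_rest = 10, speed_eps = 0) {
  rp <- rest_periods(locomotion, min_rest, speed_eps)
  ch <- rec$channels
  if (nrow(rp) == 0L) {
    warn_nv("no rest period of >= %g s; baseline undefined", min_rest)
    return(list(means = stats::setNames(rep(NA_real_, ncol(ch)), names(ch)),
                n_periods = 0L, total_rest_s = 0))
  }
  fs <- rec$sample_rate
  # map rest periods (defined on the locomotion clock) onto recording samples
  t_rec <- (seq_len(nrow(ch)) - 1) / fs
  in_rest <- rep(FALSE, nrow(ch))
  for (i in seq_len(nrow(rp)))
    in_rest <- in_rest | (t_rec >= rp$start_s[i] & t_rec < rp$end_s[i])
  list(means = vapply(ch, function(x) mean(x[in_rest]), numeric(1)),
       n_periods = nrow(rp), total_rest_s = sum(rp$duration_s))
}

#' Normalise per-mouse values to a reference group, within timepoint
#'
#' Each value is divided by the mean of the reference group at the same
#' timepoint, so the reference-group mean maps to 1 at every timepoint.
#' Used to remove probe-sensitivity drift between cohorts.
#'
#' @param values numeric per-mouse values.
#' @param group group id per value.
#' @param timepoint timepoint id per value (a single timepoint is assumed
#'   when omitted).
#' @param reference_group the group id to normalise to.
#' @return values divided by their timepoint's reference mean.
#' @export
normalize_to_reference <- function(values, group, reference_group,
                                   timepoint = NULL) {
  if (is.null(timepoint)) timepoint <- rep(1L, length(values))
  if (length(group) != length(values) || length(timepoint) != length(values))
    stop_nv("`group` and `timepoint` must match `values` in length")
  out <- rep(NA_real_, length(values))
  for (tp in unique(timepoint)) {
    sel <- timepoint == tp
    ref <- values[sel & group == reference_group]
    ref <- ref[!is.na(ref)]
    if (!length(ref))
      stop_nv("reference group '%s' empty at timepoint %s", reference_group, tp)
    m <- mean(ref)
    if (m <= 0)
      stop_nv("reference mean <= 0 at timepoint %s", tp)
    out[sel] <- values[sel] / m
  }
  out
}
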