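# Full synthetic study bundles: a directory on disk in the pipeline's input
# formats (trace/table CSVs, schedule JSON, ground-truth manifest) emulating
# a genotype x exercise cohort. The bundle works at the trace level; raw
# movies, kymographs and anatomy stacks are produced by their dedicated
# generators.

#' Default group effect table
#'
#' Multipliers per (genotype x exercise) group applied to vascular response
#' amplitude, per-trial responsiveness probability, neuronal response
#' amplitude and vasomotion amplitude. The default plants the qualitative
#' structure reported for this model system: responses weakest in sedentary
#' APOE4 mice, strongest in exercising APOE3 mice.
#'
#' @return data.frame with one row per group.
#' @export
default_effect_table <- function() {
  data.frame(
    genotype = c("APOE3", "APOE4", "APOE3", "APOE4"),
    exercise = c("wheel", "wheel", "no-wheel", "no-wheel"),
    resp_amp_mult = c(1.0, 0.80, 0.60, 0.40),
    resp_prob_mult = c(1.0, 0.75, 0.55, 0.35),
    neuro_amp_mult = c(1.0, 1.0, 1.0, 1.0),
    vaso_amp_mult = c(1.0, 0.90, 0.80, 0.70),
    stringsAsFactors = FALSE)
}

# non-overlapping random bouts over [0, duration]
random_bouts <- function(n, duration, len_range = c(3, 8), speed = 5) {
  bouts <- data.frame(start = numeric(), end = numeric(), speed = numeric())
  tries <- 0
  while (nrow(bouts) < n && tries < 200) {
    tries <- tries + 1
    len <- runif(1, len_range[1], len_range[2])
    st <- runif(1, 0, duration - len)
    if (!nrow(bouts) || all(st >= bouts$end + 1 | st + len <= bouts$start - 1))
      bouts <- rbind(bouts, data.frame(start = st, end = st + len, speed = speed))
  }
  bouts[order(bouts$start), ]
}

#' Generate a full synthetic cohort bundle on disk
#'
#' Writes, for each mouse of a 2 x 2 (genotype x exercise) design at one or
#' two timepoints: stimulus-session and baseline diameter traces per vessel,
#' calcium traces, haemodynamic recordings, locomotion traces, an optional
#' pose-tracking table, a shared stimulus schedule, cohort metadata, and a
#' ground-truth manifest (JSON) recording every planted parameter.
#'
#' Per-vessel stimulus traces are built trial by trial: each trial is
#' responsive with probability `base_resp_prob * resp_prob_mult`, and
#' responsive trials dilate by `base_amp_pct * resp_amp_mult` percent (with
#' 10% vessel-to-vessel jitter) following a gamma-shaped time course.
#'
#' @param out_dir bundle directory (created).
#' @param effect_table data.frame as [default_effect_table()].
#' @param n_mice_per_group mice per group per timepoint.
#' @param vessels_per_mouse vessels recorded per mouse.
#' @param timepoints 1 or 2.
#' @param n_trials stimulus trials per session (default 20).
#' @param base_resp_prob per-trial response probability in the reference
#'   group.
#' @param base_amp_pct peak dilation (percent of baseline diameter) in the
#'   reference group.
#' @param sample_rate two-photon frame rate, Hz.
#' @param baseline_duration no-stimulus session length (s) used for
#'   vasomotion.
#' @param cells_per_mouse calcium ROIs per mouse.
#' @param include_tracking write a pose-tracking table per mouse.
#' @param tracking_fps,tracking_duration tracking table rate (Hz) and length
#'   (s).
#' @param noise_frac white-noise SD of the diameter traces, as a fraction of
#'   the baseline diameter.
#' @param seed integer seed; the bundle is bit-reproducible given the seed.
#' @return (invisibly) the manifest list, also written to
#'   `out_dir/manifest.json`.
#' @export
gen_cohort <- function(out_dir, effect_table = default_effect_table(),
                       n_mice_per_group = 3, vessels_per_mouse = 3,
                       timepoints = 1, n_trials = 20, base_resp_prob = 0.85,
                       base_amp_pct = 10, sample_rate = 7.63,
                       baseline_duration = 240, cells_per_mouse = 6,
                       include_tracking = TRUE, tracking_fps = 2,
                       tracking_duration = 1800, noise_frac = 0.004,
                       seed = 1) {
  if (!timepoints %in% 1:2) stop_nv("timepoints must be 1 or 2")
  req <- c("genotype", "exercise", "resp_amp_mult", "resp_prob_mult",
           "neuro_amp_mult", "vaso_amp_mult")
  if (!all(req %in% names(effect_table)))
    stop_nv("effect_table must have columns: %s", paste(req, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "mice"), showWarnings = FALSE)

  lead <- 10
  sched <- stim_schedule(stim_dur = 5, isi = 25, n_stims = n_trials,
                         first_onset = lead)
  stim_duration <- lead + n_trials * 30
  write_schedule_json(sched, file.path(out_dir, "schedule.json"))

  with_seed(seed, {
    meta_rows <- list()
    mice_truth <- list()
    mouse_no <- 0L
    for (tp in seq_len(timepoints)) {
      for (g in seq_len(nrow(effect_table))) {
        eff <- effect_table[g, ]
        for (mi in seq_len(n_mice_per_group)) {
          mouse_no <- mouse_no + 1L
          id <- sprintf("m%03d", mouse_no)
          mdir <- file.path(out_dir, "mice", id)
          dir.create(mdir, showWarnings = FALSE)
          wheel <- as.character(eff$exercise) == "wheel"
          exercise_level <- if (wheel) runif(1, 0.8, 1.2) else runif(1, 0.05, 0.25)

          # --- locomotion: stimulus session (some bouts overlap stimuli)
          loco_stim <- gen_locomotion(random_bouts(4, stim_duration),
                                      stim_duration, sample_rate)
          t_stim <- (seq_along(loco_stim$speed) - 1) / sample_rate
          write_ts_csv(t_stim, loco_stim$speed,
                       file.path(mdir, "loco_stim.csv"), "speed")
          # baseline session: sparse bouts leave long rest periods
          loco_base <- gen_locomotion(random_bouts(2, baseline_duration),
                                      baseline_duration, sample_rate)
          t_base <- (seq_along(loco_base$speed) - 1) / sample_rate
          write_ts_csv(t_base, loco_base$speed,
                       file.path(mdir, "loco_baseline.csv"), "speed")

          # --- vessels
          n_s <- round(stim_duration * sample_rate)
          n_b <- round(baseline_duration * sample_rate)
          ts <- (seq_len(n_s) - 1) / sample_rate
          tb <- (seq_len(n_b) - 1) / sample_rate
          vtruth <- list()
          vmeta <- data.frame()
          for (v in seq_len(vessels_per_mouse)) {
            vid <- sprintf("v%02d", v)
            d0 <- runif(1, 4, 12)
            amp <- base_amp_pct * eff$resp_amp_mult * runif(1, 0.9, 1.1)
            p <- min(1, base_resp_prob * eff$resp_prob_mult)
            responsive <- runif(n_trials) < p
            drive <- numeric(n_s)
            for (k in which(responsive))
              drive <- drive + amp * gamma_transient(ts - sched$onsets[k])
            stim_vals <- d0 * (1 + drive / 100) + rnorm(n_s, sd = noise_frac * d0)
            write_ts_csv(ts, stim_vals,
                         file.path(mdir, sprintf("vessel_%s_stim.csv", vid)))
            vaso_amp <- 0.015 * eff$vaso_amp_mult
            base_vals <- d0 * (1 + vaso_amp * sin(2 * pi * 0.1 * tb + runif(1, 0, 2 * pi))) +
              rnorm(n_b, sd = noise_frac * d0)
            write_ts_csv(tb, base_vals,
                         file.path(mdir, sprintf("vessel_%s_baseline.csv", vid)))
            vtruth[[vid]] <- list(d0 = d0, amp_pct = amp, p_responsive = p,
                                  responsive = responsive,
                                  vaso_amp = vaso_amp)
            vmeta <- rbind(vmeta, data.frame(vessel = vid, d0_um = d0,
                                             superficial = d0 > 10))
          }
          write.csv(vmeta, file.path(mdir, "vessel_meta.csv"), row.names = FALSE)

          # --- calcium: fixed class proportions (50% ON, 20% OFF, 10% BOTH,
          # 20% NONE) so the per-mouse mean neuronal AUC reflects the
          # planted amplitude, not class-sampling noise
          classes <- rep(c("ON", "OFF", "BOTH", "NONE"),
                         c(ceiling(0.5 * cells_per_mouse),
                           floor(0.2 * cells_per_mouse),
                           ceiling(0.1 * cells_per_mouse),
                           floor(0.2 * cells_per_mouse)))[seq_len(cells_per_mouse)]
          classes[is.na(classes)] <- "ON"
          neuro_amp <- eff$neuro_amp_mult * runif(1, 0.9, 1.1)
          ca <- gen_calcium(classes, sched, amp = neuro_amp, noise_sd = 0.03,
                            sample_rate = sample_rate,
                            duration_s = stim_duration,
                            seed = sample.int(2^31 - 1, 1))
          ca_df <- data.frame(time_s = (seq_len(ncol(ca$dff)) - 1) / sample_rate,
                              t(ca$dff))
          write.csv(ca_df, file.path(mdir, "calcium_stim.csv"), row.names = FALSE)

          # --- haemodynamics
          hh <- gen_hemo_and_stim(stim_n = n_trials,
                                  response_amps = c(Flux = 10 * eff$resp_amp_mult,
                                                    Speed = 5 * eff$resp_amp_mult,
                                                    Hbo = 5 * eff$resp_amp_mult,
                                                    Hbd = -3 * eff$resp_amp_mult,
                                                    sO2 = 1 * eff$resp_amp_mult),
                                  noise_sd = 0.005, lead = lead,
                                  seed = sample.int(2^31 - 1, 1))
          hdf <- cbind(time_s = (seq_len(nrow(hh$hemo$channels)) - 1) / 40,
                       hh$hemo$channels)
          write.csv(hdf, file.path(mdir, "hemo_stim.csv"), row.names = FALSE)
          hb <- gen_hemo_and_stim(stim_n = 1, response_amps = c(Flux = 0),
                                  noise_sd = 0.01, lead = lead,
                                  seed = sample.int(2^31 - 1, 1))
          nb40 <- min(nrow(hb$hemo$channels), round(baseline_duration * 40))
          hbdf <- cbind(time_s = (seq_len(nb40) - 1) / 40,
                        hb$hemo$channels[seq_len(nb40), ])
          write.csv(hbdf, file.path(mdir, "hemo_baseline.csv"), row.names = FALSE)

          # --- tracking
          track_len <- NA_real_
          if (include_tracking) {
            n_way <- 3 + round(12 * exercise_level)
            path <- cbind(runif(n_way, 0, 30), runif(n_way, 0, 30))
            tr <- gen_tracking(path,
                               wheel_rotations = if (wheel) round(40 * exercise_level) else 0,
                               fps = tracking_fps,
                               duration_s = tracking_duration,
                               px_per_cm = 10, dropout_rate = 0.02,
                               seed = sample.int(2^31 - 1, 1))
            write.csv(as.data.frame(tr$table),
                      file.path(mdir, "tracking.csv"), row.names = FALSE)
            write_sidecar(file.path(mdir, "tracking.csv"),
                          list(fps = tracking_fps, px_per_cm = 10))
            track_len <- tr$truth$true_path_length + tr$truth$wheel_marker_length
          }

          meta_rows[[length(meta_rows) + 1L]] <- data.frame(
            mouse = id, genotype = eff$genotype, exercise = eff$exercise,
            timepoint = tp,
            group = paste(eff$genotype, eff$exercise, sep = "_"))
          mice_truth[[id]] <- list(
            genotype = eff$genotype, exercise = eff$exercise, timepoint = tp,
            exercise_level = exercise_level, track_length_cm = track_len,
            neuro_amp = neuro_amp, calcium_classes = classes,
            vessels = vtruth)
        }
      }
    }
    metadata <- do.call(rbind, meta_rows)
    write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    manifest <- list(
      seed = seed,
      params = list(n_mice_per_group = n_mice_per_group,
                    vessels_per_mouse = vessels_per_mouse,
                    timepoints = timepoints, n_trials = n_trials,
                    base_resp_prob = base_resp_prob,
                    base_amp_pct = base_amp_pct, sample_rate = sample_rate,
                    baseline_duration = baseline_duration,
                    noise_frac = noise_frac),
      effect_table = effect_table,
      mice = mice_truth)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  })
}
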