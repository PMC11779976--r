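# End-to-end orchestration: a cohort bundle directory in, a results
# directory out (per-vessel, per-cell and per-mouse tables, correlations,
# PCA, run manifest). Deterministic given config + seed; a failure aborts
# with the stage name.

pipeline_defaults <- function() {
  list(input_dir = NULL, out_dir = NULL, seed = 1,
       reference_group = "APOE3_wheel",
       speed_eps = 0, pre_window = 2, min_rest = 10,
       vasomotion_df = 0.0125, likelihood_threshold = 1.0,
       px_per_cm = 10, tracking_fps = NULL, nvci_grouping = "genotype",
       missing_cutoff = 0.20)
}

#' Run the full analysis pipeline over a cohort bundle
#'
#' Consumes a directory written by [gen_cohort()] (or any directory in the
#' same layout) and produces per-vessel responses and responsiveness,
#' vasomotion power, cell classifications and per-mouse neuronal AUC,
#' per-vessel NVCi, haemodynamic rest baselines (reference-normalised) and
#' CMRO2, activity summaries, exercise correlations and a PCA — each stage
#' written as a tidy CSV under `out_dir` plus a JSON run manifest.
#'
#' @param config named list (or path to a JSON file) with keys among:
#'   `input_dir`, `out_dir`, `seed`, `reference_group`, `speed_eps`,
#'   `pre_window`, `min_rest`, `vasomotion_df`, `likelihood_threshold`,
#'   `px_per_cm`, `tracking_fps`, `nvci_grouping`, `missing_cutoff`.
#'   Unknown keys are rejected.
#' @return (invisibly) list with the per-stage data.frames and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop_nv("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config)
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stop_nv("config must set input_dir and out_dir")
  if (!dir.exists(cfg$input_dir)) stop_nv("input_dir does not exist: %s", cfg$input_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_nv("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  meta <- stage("metadata", {
    m <- read.csv(file.path(cfg$input_dir, "metadata.csv"))
    if (!all(c("mouse", "genotype", "exercise", "timepoint") %in% names(m)))
      stop_nv("metadata.csv lacks required columns")
    m
  })
  sched <- stage("schedule", read_schedule_json(file.path(cfg$input_dir, "schedule.json")))

  vessel_rows <- list(); cell_rows <- list(); mouse_rows <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$mouse[i]
    mdir <- file.path(cfg$input_dir, "mice", id)
    loco_s <- stage(paste0(id, "/loco_stim"),
                    read_locomotion_csv(file.path(mdir, "loco_stim.csv")))
    loco_b <- stage(paste0(id, "/loco_baseline"),
                    read_locomotion_csv(file.path(mdir, "loco_baseline.csv")))

    # --- vessels: responses + vasomotion
    vfiles <- sort(list.files(mdir, pattern = "^vessel_v[0-9]+_stim\\.csv$"))
    for (vf in vfiles) {
      vid <- sub("^vessel_(v[0-9]+)_stim\\.csv$", "\\1", vf)
      stage(paste(id, vid, sep = "/"), {
        df <- read.csv(file.path(mdir, vf))
        fs <- 1 / median(diff(df$time_s))
        tset <- segment_trials(df$value, fs, sched)
        tset <- gate_locomotion(tset, loco_s, cfg$pre_window, cfg$speed_eps)
        resp <- vessel_response(tset)
        bfile <- file.path(mdir, sprintf("vessel_%s_baseline.csv", vid))
        vaso <- if (file.exists(bfile)) {
          bt <- read.csv(bfile)
          vasomotion_power(bt$value, sample_rate = 1 / median(diff(bt$time_s)),
                           df = cfg$vasomotion_df)
        } else NULL
        d0 <- median(df$value[df$time_s < sched$onsets[1]])
        vessel_rows[[paste(id, vid)]] <- data.frame(
          mouse = id, vessel = vid, baseline_diameter_um = d0,
          vessel_class = classify_vessel(d0, superficial = d0 > 10),
          n_retained = sum(tset$retained),
          responsiveness_pct = resp$responsiveness,
          max_peak_pct = resp$mean_trace$max_peak,
          auc_pct_s = resp$mean_trace$auc,
          time_to_peak_s = resp$mean_trace$time_to_peak,
          vasomotion_rel_power = if (is.null(vaso)) NA_real_ else vaso$relative_power)
      })
    }

    # --- calcium
    cafile <- file.path(mdir, "calcium_stim.csv")
    neuronal_auc <- NA_real_
    if (file.exists(cafile)) {
      stage(paste0(id, "/calcium"), {
        ca <- read.csv(cafile)
        fs <- 1 / median(diff(ca$time_s))
        cells <- setdiff(names(ca), "time_s")
        tm <- t(vapply(cells, function(cn) {
          tset <- segment_trials(ca[[cn]], fs, sched)
          tset <- gate_locomotion(tset, loco_s, cfg$pre_window, cfg$speed_eps)
          resp <- vessel_response(tset, mode = "subtract")
          resp$mean_response %||% rep(NA_real_, ncol(tset$trials))
        }, numeric(round(30 * fs))))
        rownames(tm) <- cells
        cl <- classify_cells(tm, fs)
        cl$mouse <- id
        cell_rows[[id]] <- cl
        neuronal_auc <- mean(cl$auc_stim, na.rm = TRUE)
      })
    }

    # --- haemodynamics
    hemo_means <- NULL; cmro2_baseline <- NA_real_
    hb <- file.path(mdir, "hemo_baseline.csv")
    if (file.exists(hb)) {
      stage(paste0(id, "/hemo"), {
        hdf <- read.csv(hb)
        fs <- 1 / median(diff(hdf$time_s))
        rec <- suppressWarnings(
          hemo_recording(hdf[, setdiff(names(hdf), "time_s")], fs))
        rb <- rest_baseline(rec, loco_b, cfg$min_rest, cfg$speed_eps)
        hemo_means <- rb$means
        cm <- cmro2(rec$channels$Flux, rec$channels$Hbd, rec$channels$Hbt)
        cmro2_baseline <- mean(cm, na.rm = TRUE)
      })
    }

    # --- activity
    dist_cm <- NA_real_
    trfile <- file.path(mdir, "tracking.csv")
    if (file.exists(trfile)) {
      stage(paste0(id, "/activity"), {
        tab <- read_tracking_csv(trfile, fps = cfg$tracking_fps,
                                 px_per_cm = cfg$px_per_cm)
        tab <- filter_tracking(tab, cfg$likelihood_threshold)
        fd <- frame_distance(tab)
        act <- suppressWarnings(summarize_activity(fd))
        dist_cm <- sum(act$windows$distance_cm[act$windows$retained])
      })
    }

    mouse_rows[[id]] <- cbind(
      meta[i, c("mouse", "genotype", "exercise", "timepoint")],
      data.frame(neuronal_auc = neuronal_auc, cmro2_baseline = cmro2_baseline,
                 distance_cm = dist_cm,
                 sO2_baseline = hemo_means[["sO2"]] %||% NA_real_,
                 Flux_baseline = hemo_means[["Flux"]] %||% NA_real_,
                 Hbt_baseline = hemo_means[["Hbt"]] %||% NA_real_))
  }

  vessels <- do.call(rbind, vessel_rows); rownames(vessels) <- NULL
  cells <- if (length(cell_rows)) do.call(rbind, cell_rows) else NULL
  mice <- do.call(rbind, mouse_rows); rownames(mice) <- NULL

  # --- reference normalisation of baseline haemodynamics
  mice$group <- paste(mice$genotype, mice$exercise, sep = "_")
  stage("reference_normalisation", {
    for (ch in c("sO2_baseline", "Flux_baseline", "Hbt_baseline", "cmro2_baseline")) {
      if (all(is.na(mice[[ch]]))) next
      mice[[paste0(ch, "_norm")]] <- normalize_to_reference(
        mice[[ch]], mice$group, cfg$reference_group, mice$timepoint)
    }
  })

  # --- NVCi per vessel
  stage("nvci", {
    key_of <- function(df) switch(cfg$nvci_grouping,
      genotype = paste(df$genotype, df$timepoint),
      group = paste(df$genotype, df$exercise, df$timepoint),
      stop_nv("nvci_grouping must be 'genotype' or 'group'"))
    mkey <- key_of(mice)
    vkey <- mkey[match(vessels$mouse, mice$mouse)]
    nv <- vapply(seq_len(nrow(vessels)), function(r) {
      aucs <- mice$neuronal_auc[mkey == vkey[r] & !is.na(mice$neuronal_auc)]
      if (!length(aucs)) return(NA_real_)
      suppressWarnings(nvci(vessels$auc_pct_s[r], aucs, vkey[r])$value)
    }, numeric(1))
    vessels$nvci <- nv
  })

  # --- per-mouse measure table, correlations, PCA
  agg <- stage("aggregate", {
    vm <- aggregate(cbind(responsiveness_pct, max_peak_pct, auc_pct_s, nvci,
                          vasomotion_rel_power) ~ mouse, vessels, mean,
                    na.action = stats::na.pass, na.rm = TRUE)
    merge(mice, vm, by = "mouse", all.x = TRUE)
  })
  corr <- stage("correlations", {
    tab <- agg
    tab$exercise <- tab$distance_cm
    mcols <- c("responsiveness_pct", "max_peak_pct", "auc_pct_s", "nvci",
               "vasomotion_rel_power", "sO2_baseline", "cmro2_baseline")
    mcols <- mcols[vapply(mcols, function(cn) sum(!is.na(tab[[cn]])) >= 3, logical(1))]
    if (all(is.na(tab$exercise)) || !length(mcols)) NULL
    else correlate_measures(tab[, c("mouse", "timepoint", "exercise", mcols)],
                            measures = mcols)
  })
  pca <- stage("pca", {
    pcols <- c("responsiveness_pct", "max_peak_pct", "auc_pct_s", "nvci",
               "vasomotion_rel_power", "sO2_baseline", "cmro2_baseline",
               "distance_cm")
    M <- agg[, pcols]
    usable <- vapply(M, function(v) sum(!is.na(v)) >= 3 &&
                       sd(v, na.rm = TRUE) > 0, logical(1))
    if (sum(usable) >= 2 && nrow(M) >= 3)
      prepare_pca(M[, usable, drop = FALSE], cfg$missing_cutoff) else NULL
  })

  stage("write", {
    write.csv(vessels, file.path(cfg$out_dir, "vessels.csv"), row.names = FALSE)
    if (!is.null(cells))
      write.csv(cells, file.path(cfg$out_dir, "cells.csv"), row.names = FALSE)
    write.csv(agg, file.path(cfg$out_dir, "mice.csv"), row.names = FALSE)
    if (!is.null(corr))
      write.csv(corr$results, file.path(cfg$out_dir, "correlations.csv"),
                row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("nvpipe")),
      config = cfg,
      rows = list(vessels = nrow(vessels),
                  cells = if (is.null(cells)) 0L else nrow(cells),
                  mice = nrow(mice)),
      pca = if (is.null(pca)) NULL else list(
        retained_vars = pca$retained_vars,
        eigenvalues = pca$eigenvalues,
        retained_pcs = pca$retained_pcs))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }) -> manifest

  invisible(list(vessels = vessels, cells = cells, mice = agg,
                 correlations = corr, pca = pca, manifest = manifest))
}
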