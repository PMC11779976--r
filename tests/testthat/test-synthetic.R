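# Generators: determinism, physical validation, and that each construction
# carries the ground truth it claims.

test_that("every generator is bit-reproducible under a fixed seed", {
  a <- gen_vessel_movie(10, n_frames = 3, seed = 7)
  b <- gen_vessel_movie(10, n_frames = 3, seed = 7)
  expect_identical(a$movie$data, b$movie$data)

  k1 <- gen_kymograph(2, n_lines = 256, seed = 7)
  k2 <- gen_kymograph(2, n_lines = 256, seed = 7)
  expect_identical(k1$kymo$data, k2$kymo$data)

  h1 <- gen_hemo_and_stim(stim_n = 2, noise_sd = 0.01, seed = 7)
  h2 <- gen_hemo_and_stim(stim_n = 2, noise_sd = 0.01, seed = 7)
  expect_identical(h1$hemo$channels, h2$hemo$channels)

  t1 <- gen_tracking(cbind(c(0, 10), c(0, 0)), duration_s = 5, dropout_rate = 0.2, seed = 7)
  t2 <- gen_tracking(cbind(c(0, 10), c(0, 0)), duration_s = 5, dropout_rate = 0.2, seed = 7)
  expect_identical(t1$table$x, t2$table$x)

  s1 <- tube_phantom(seed = 7)
  s2 <- tube_phantom(seed = 7)
  expect_identical(s1$stack$data, s2$stack$data)
})

test_that("vessel movie rejects widths below the resolvable limit", {
  expect_error(gen_vessel_movie(0.8, pixel_size = 0.5, n_frames = 2),
               "resolvable limit")
  expect_error(gen_vessel_movie(function(t) 10 - 2 * t, frame_rate = 1,
                                pixel_size = 0.5, n_frames = 10),
               "resolvable limit")
})

test_that("kymograph streaks have the constructed slope sign and density", {
  g <- gen_kymograph(2, n_lines = 512, noise_sd = 0, seed = 3)
  expect_true(all(g$truth$true_velocity_trace == 2))
  # velocity implying sub-pixel displacement over the window is rejected
  expect_error(gen_kymograph(0.00001, n_lines = 128), "1 pixel")
  # zero streak density leaves a blank (noise-only) image
  g0 <- gen_kymograph(2, streak_density = 0, noise_sd = 0, n_lines = 128, seed = 1)
  expect_true(all(g0$kymo$data == 1))
})

test_that("haemodynamic construction: Hbt additivity, schedule, peak amplitude", {
  g <- gen_hemo_and_stim(stim_n = 20, noise_sd = 0, seed = 1)
  ch <- g$hemo$channels
  expect_equal(ch$Hbt, ch$Hbo + ch$Hbd)
  # 20 onsets, 30 s period
  expect_length(g$schedule$onsets, 20)
  expect_equal(unique(diff(g$schedule$onsets)), 30)
  # noiseless trial max peak equals the stated percent amplitude
  tset <- segment_trials(ch$Flux, 40, g$schedule)
  vr <- vessel_response(tset)
  expect_equal(max(vr$per_trial$max_peak), 10, tolerance = 1e-6)
  # additivity with noise too (Hbt built from the noisy channels)
  gn <- gen_hemo_and_stim(stim_n = 2, noise_sd = 0.02, seed = 1)
  expect_equal(gn$hemo$channels$Hbt, gn$hemo$channels$Hbo + gn$hemo$channels$Hbd)
})

test_that("noiseless calcium constructions classify as built; amp 0 gives NONE", {
  sched <- default_schedule()
  ca <- gen_calcium(c("ON", "OFF", "BOTH", "NONE"), sched, noise_sd = 0,
                    sample_rate = 7.63, seed = 2)
  tm <- t(vapply(seq_len(4), function(ci) {
    tset <- segment_trials(ca$dff[ci, ], 7.63, sched)
    vessel_response(tset, mode = "subtract")$mean_response
  }, numeric(round(30 * 7.63))))
  expect_equal(classify_cells(tm, 7.63)$label, c("ON", "OFF", "BOTH", "NONE"))

  ca0 <- gen_calcium(c("ON", "OFF"), sched, amp = 0, noise_sd = 0, seed = 2)
  tm0 <- t(vapply(1:2, function(ci) {
    tset <- segment_trials(ca0$dff[ci, ], 7.63, sched)
    vessel_response(tset, mode = "subtract")$mean_response
  }, numeric(round(30 * 7.63))))
  expect_equal(classify_cells(tm0, 7.63)$label, c("NONE", "NONE"))
})

test_that("locomotion bouts: speed nonzero exactly inside bouts; overlaps rejected", {
  lt <- gen_locomotion(list(c(2, 4, 3), c(6, 7, 1)), duration = 10, sample_rate = 10)
  t <- (seq_along(lt$speed) - 1) / 10
  expect_true(all(lt$speed[t >= 2 & t < 4] == 3))
  expect_true(all(lt$speed[t >= 6 & t < 7] == 1))
  expect_true(all(lt$speed[t < 2 | (t >= 4 & t < 6) | t >= 7] == 0))
  expect_error(gen_locomotion(list(c(1, 5, 1), c(4, 8, 1)), duration = 10),
               "overlap")
})

test_that("anatomy phantom carries its construction truth", {
  g <- tube_phantom(radius = 3, length_um = 150)
  expect_equal(g$truth$true_network_length, 150)
  expect_equal(g$truth$true_radii, 3)
  expect_error(gen_anatomy_stack(list(list(p0 = c(0, 0, 0), p1 = c(0, 0, 0),
                                           radius = 3))),
               "zero-length")
  expect_error(gen_anatomy_stack(list(list(p0 = c(0, 0, 0), p1 = c(50, 0, 0),
                                           radius = 0.3))),
               "below one voxel")
})

test_that("tracking: dropout marks ~the requested fraction; wheel-only motion", {
  g <- gen_tracking(cbind(c(0, 100), c(0, 0)), fps = 30, duration_s = 60,
                    dropout_rate = 0.1, seed = 4)
  expect_equal(g$truth$dropout_fraction, 0.1, tolerance = 0.15)
  expect_equal(mean(g$table$likelihood < 1), g$truth$dropout_fraction)

  st <- gen_tracking(cbind(50, 50), wheel_rotations = 10, fps = 30,
                     duration_s = 30, seed = 4)
  fd <- frame_distance(st$table)
  expect_equal(sum(fd$mouse_cm), 0)
  expect_gt(sum(fd$wheel_cm), 0)
  expect_equal(sum(fd$wheel_cm), st$truth$wheel_marker_length, tolerance = 1e-6)
})

test_that("cohort group effects are monotone in the responsiveness multiplier", {
  rec <- vapply(c(0.4, 0.7, 1.0), function(mult) {
    et <- default_effect_table()[1, ]
    et$resp_prob_mult <- mult
    dir <- file.path(tempdir(), sprintf("mono%02d", round(mult * 10)))
    unlink(dir, recursive = TRUE)
    gen_cohort(dir, effect_table = et, n_mice_per_group = 1,
               vessels_per_mouse = 3, include_tracking = FALSE, seed = 42)
    res <- run_pipeline(list(input_dir = dir,
                             out_dir = file.path(dir, "out"),
                             reference_group = "APOE3_wheel"))
    mean(res$vessels$responsiveness_pct)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})
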