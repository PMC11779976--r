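# Baseline calcium event statistics, ON/OFF/BOTH classification structure,
# and the neurovascular coupling index.

test_that("baseline event rate counts injected transients per rest minute", {
  fs <- 10
  t <- (seq_len(70 * fs) - 1) / fs
  # small deterministic baseline wiggle keeps the MAD finite without ever
  # crossing the event threshold
  x <- 0.005 * sin(2 * pi * 0.7 * t)
  for (pk in c(15, 30, 50))                 # 3 transients inside the rest period
    x <- x + nvpipe:::calcium_kernel(t - pk)
  traces <- list(dff = matrix(x, 1), sample_rate = fs)
  loco <- gen_locomotion(list(c(60, 69, 1)), 70, fs)   # rest = first 60 s
  st <- baseline_calcium_stats(traces, loco)
  expect_equal(st$peaks_per_min, 3, tolerance = 1e-6)
  expect_equal(st$mean_peak_size, 1, tolerance = 0.05)

  flat <- list(dff = matrix(0.005 * sin(2 * pi * 0.7 * t), 1), sample_rate = fs)
  expect_equal(baseline_calcium_stats(flat, loco)$peaks_per_min, 0)
})

test_that("doubling amplitudes doubles peak size but not the rate", {
  fs <- 10
  t <- (seq_len(80 * fs) - 1) / fs
  x <- 0.004 * sin(2 * pi * 0.9 * t)
  for (pk in c(10, 25, 40, 60)) x <- x + nvpipe:::calcium_kernel(t - pk)
  loco <- gen_locomotion(data.frame(start = numeric(), end = numeric(),
                                    speed = numeric()), 80, fs)
  s1 <- baseline_calcium_stats(list(dff = matrix(x, 1), sample_rate = fs), loco)
  s2 <- baseline_calcium_stats(list(dff = matrix(2 * x, 1), sample_rate = fs), loco)
  expect_equal(s2$peaks_per_min, s1$peaks_per_min)
  expect_equal(s2$mean_peak_size / s1$mean_peak_size, 2, tolerance = 0.05)
})

test_that("rest periods below 10 s yield flagged NA statistics", {
  fs <- 10
  traces <- list(dff = matrix(rnorm(800), 1), sample_rate = fs)
  busy <- gen_locomotion(data.frame(start = seq(0, 72, by = 9),
                                    end = seq(8, 80, by = 9), speed = 1),
                         80, fs)
  expect_warning(st <- baseline_calcium_stats(traces, busy), "undefined")
  expect_true(is.na(st$peaks_per_min))
})

test_that("classification label frequencies are invariant to cell order", {
  sched <- default_schedule(6)
  ca <- gen_calcium(c("ON", "ON", "OFF", "BOTH", "NONE", "ON"), sched,
                    noise_sd = 0.05, sample_rate = 7.63, seed = 9)
  tm <- t(vapply(seq_len(6), function(ci) {
    tset <- segment_trials(ca$dff[ci, ], 7.63, sched)
    vessel_response(tset, mode = "subtract")$mean_response
  }, numeric(round(30 * 7.63))))
  lab <- classify_cells(tm, 7.63)$label
  perm <- c(3, 1, 6, 2, 5, 4)
  lab_p <- classify_cells(tm[perm, ], 7.63)$label
  expect_equal(lab[perm], lab_p)
  expect_equal(sort(unname(table(lab))), sort(unname(table(lab_p))))
})

test_that("nvci arithmetic, homogeneity and degenerate flags", {
  expect_equal(nvci(8, c(2, 2))$value, 4)
  # scaling the neuronal AUCs by c scales the index by 1/c
  expect_equal(nvci(8, 3 * c(2, 2))$value, 4 / 3)
  # linear in vessel AUC
  expect_equal(nvci(16, c(2, 2))$value, 2 * nvci(8, c(2, 2))$value)
  expect_warning(bad <- nvci(8, c(-1, 1)), "undefined")
  expect_true(is.na(bad$value))
  expect_error(nvci(8, numeric()), "non-empty")
})
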