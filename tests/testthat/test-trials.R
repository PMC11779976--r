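# Trial segmentation, locomotion gating (hand-enumerated layouts),
# normalisation and the 2-SD response metrics.

test_that("segmentation yields one row per stimulus and drops partial trials", {
  fs <- 10
  sched <- stim_schedule(n_stims = 20, first_onset = 10)
  trace <- rnorm(round((10 + 20 * 30 + 25) * fs))
  ts <- segment_trials(trace, fs, sched)
  expect_equal(nrow(ts$trials), 20)
  expect_equal(sum(ts$retained), 20)
  expect_equal(ncol(ts$trials), 300)

  # first onset at 3 s: insufficient baseline, that trial dropped
  sched3 <- stim_schedule(onsets = c(3, seq(40, 40 + 18 * 30, by = 30)))
  ts3 <- segment_trials(trace, fs, sched3)
  expect_equal(nrow(ts3$trials), 20)
  expect_equal(sum(ts3$retained), 19)
  expect_equal(ts3$exclusion_reason[1], "partial")

  # constant trace: every retained row constant
  tsc <- segment_trials(rep(4, length(trace)), fs, sched)
  expect_true(all(apply(tsc$trials, 1, function(r) all(r == 4))))
})

test_that("locomotion gating matches hand-enumerated layouts incl. boundaries", {
  fs <- 40
  sched <- stim_schedule(onsets = c(10, 40, 70, 100))
  trace <- rep(5, round(130 * fs))
  base <- segment_trials(trace, fs, sched)
  # bout spanning onset 1; bout ending exactly 2.5 s before onset 2 (kept);
  # bout ending 3 s before onset 3 (kept); bout in post-window of trial 4 (kept)
  loco <- gen_locomotion(list(c(9, 11, 1), c(35, 37.5, 1), c(64, 67, 1),
                              c(110, 112, 1)),
                         duration = 130, sample_rate = fs)
  g <- gate_locomotion(base, loco)
  expect_equal(g$retained, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(g$exclusion_reason[1], "locomotion")

  # bout inside the 2 s pre-window is excluded; bout during stimulus excluded
  loco2 <- gen_locomotion(list(c(38.5, 39.5, 1), c(71, 73, 1)),
                          duration = 130, sample_rate = fs)
  g2 <- gate_locomotion(base, loco2)
  expect_equal(g2$retained, c(TRUE, FALSE, FALSE, TRUE))

  # gating is idempotent
  g2b <- gate_locomotion(g2, loco2)
  expect_identical(g2$retained, g2b$retained)

  # no bouts: everything retained
  loco0 <- gen_locomotion(data.frame(start = numeric(), end = numeric(),
                                     speed = numeric()), 130, fs)
  expect_true(all(gate_locomotion(base, loco0)$retained))
})

test_that("normalisation: identity, arithmetic, scale invariance", {
  fs <- 10
  trial <- rep(10, 300)
  expect_equal(normalize_trial(trial, fs), rep(0, 300))

  trial2 <- c(rep(10, 50), rep(11, 50), rep(10, 200))
  n2 <- normalize_trial(trial2, fs)
  expect_equal(n2[51:100], rep(10, 50))    # +10% plateau
  expect_equal(normalize_trial(2 * trial2, fs), n2)

  bad <- rep(-1, 300)
  nb <- normalize_trial(bad, fs)
  expect_true(all(is.na(nb)))
  expect_equal(attr(nb, "reason"), "nonpositive_baseline")
})

test_that("response metrics implement the 2-SD rule and AUC window", {
  fs <- 10
  # baseline sd = 1 by construction, peak 2.5 -> responsive
  nvpipe:::with_seed(1, {
    bl <- rnorm(50)
    bl <- (bl - mean(bl)) / sd(bl)
  })
  trial <- c(bl, rep(0, 250))
  trial[60] <- 2.5
  m <- response_metrics(trial, fs)
  expect_equal(m$baseline_sd, 1)
  expect_equal(m$max_peak, 2.5)
  expect_true(m$responsive)
  expect_equal(m$time_to_peak, 1)
  trial[60] <- 1.9
  expect_false(response_metrics(trial, fs)$responsive)

  # AUC covers the stimulus window only (trapezoid of a constant = value x 4.9 s)
  plateau <- c(rep(0, 50), rep(2, 50), rep(0, 200))
  expect_equal(response_metrics(plateau, fs)$auc, 2 * 4.9)
})

test_that("responsiveness is the retained-trial percentage and is permutation-invariant", {
  m <- data.frame(responsive = c(TRUE, TRUE, TRUE, FALSE, NA),
                  retained = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                  valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(responsiveness(m), 75)
  perm <- m[c(4, 2, 5, 1, 3), ]
  expect_equal(responsiveness(perm), 75)
  expect_equal(responsiveness(m[m$responsive %in% TRUE, ]), 100)
  none <- data.frame(responsive = NA, retained = FALSE, valid = FALSE)
  expect_warning(r0 <- responsiveness(none), "undefined")
  expect_true(is.na(r0))
})

test_that("null max-peak distribution is stable under time reversal", {
  fs <- 7.63
  tr <- null_trials(300, fs, seed = 8)
  fwd <- vapply(seq_len(nrow(tr)), function(i)
    response_metrics(normalize_trial(tr[i, ], fs, mode = "subtract"), fs)$max_peak,
    numeric(1))
  rev_ <- vapply(seq_len(nrow(tr)), function(i)
    response_metrics(normalize_trial(rev(tr[i, ]), fs, mode = "subtract"), fs)$max_peak,
    numeric(1))
  expect_gt(stats::ks.test(fwd, rev_)$p.value, 0.001)
})
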