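# Welch-based vasomotion power: spectral peak location, detrending
# invariances, and the relative-power normalisation.

make_trace <- function(amp = 0.02, noise = 0.02, fs = 7.63, dur = 240,
                       f = 0.1, seed = 1) {
  nvpipe:::with_seed(seed, {
    t <- (seq_len(round(dur * fs)) - 1) / fs
    10 * (1 + amp * sin(2 * pi * f * t)) + rnorm(length(t), sd = noise)
  })
}

test_that("a 0.1 Hz oscillation produces the spectral peak at the 0.1 Hz grid point", {
  vp <- vasomotion_power(make_trace(), sample_rate = 7.63, df = 0.0125)
  nz <- vp$spectrum$freqs > 0
  expect_equal(vp$spectrum$freqs[nz][which.max(vp$spectrum$power[nz])], 0.1)
  expect_gt(vp$relative_power, 0.3)
})

test_that("output is invariant to offsets and linear trends (detrending)", {
  x <- make_trace(seed = 2)
  fs <- 7.63
  base <- vasomotion_power(x, sample_rate = fs, df = 0.0125)
  t <- seq_along(x)
  shifted <- vasomotion_power(x + 100, sample_rate = fs, df = 0.0125)
  ramped <- vasomotion_power(x + 0.05 * t / fs, sample_rate = fs, df = 0.0125)
  expect_equal(base$relative_power, shifted$relative_power, tolerance = 1e-8)
  expect_equal(base$relative_power, ramped$relative_power, tolerance = 1e-8)

  # a pure ramp has ~no 0.1 Hz power after detrending
  ramp_only <- vasomotion_power(10 + 0.05 * t / fs + rnorm(length(t), sd = 1e-3),
                                sample_rate = fs, df = 0.0125)
  expect_lt(ramp_only$relative_power, 0.1)
})

test_that("relative power lies in [0,1] and grows with oscillation amplitude", {
  rels <- vapply(1:25, function(s) {
    lo <- vasomotion_power(make_trace(amp = 0.01, seed = s),
                           sample_rate = 7.63, df = 0.0125)$relative_power
    hi <- vasomotion_power(make_trace(amp = 0.02, seed = s),
                           sample_rate = 7.63, df = 0.0125)$relative_power
    c(lo, hi)
  }, numeric(2))
  expect_true(all(rels >= 0 & rels <= 1))
  expect_true(all(rels[2, ] > rels[1, ]))
})

test_that("relative power agrees across sampling rates within 10%", {
  fs1 <- 7; fs2 <- 14
  t1 <- (seq_len(240 * fs1) - 1) / fs1
  t2 <- (seq_len(240 * fs2) - 1) / fs2
  sig <- function(t, fs) 10 + 0.2 * sin(2 * pi * 0.1 * t) +
    nvpipe:::with_seed(3, rnorm(length(t), sd = 0.05))
  r1 <- vasomotion_power(sig(t1, fs1), sample_rate = fs1, df = 0.0125)$relative_power
  r2 <- vasomotion_power(sig(t2, fs2), sample_rate = fs2, df = 0.0125)$relative_power
  expect_equal(r1, r2, tolerance = 0.1)
})

test_that("short traces reduce the segment with a warning; too-short errors", {
  fs <- 7.63
  x <- make_trace(dur = 100)
  expect_warning(vasomotion_power(x, sample_rate = fs, df = 0.01), "segment reduced")
  expect_error(suppressWarnings(
    vasomotion_power(make_trace(dur = 20), sample_rate = fs)), "too short")
})
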