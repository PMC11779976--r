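# CMRO2 arithmetic and invariances, rest-period baselines, and
# reference-group normalisation.

test_that("cmro2 substitutes exactly and has the ratio invariances", {
  expect_identical(cmro2(100, 20, 100), 20)
  expect_identical(cmro2(50, 30, 30), 50)            # Hbd = Hbt
  expect_identical(cmro2(80, 2 * 20, 2 * 100), cmro2(80, 20, 100))
  # linear in CBF
  expect_equal(cmro2(c(1, 2, 4), 20, 100), c(0.2, 0.4, 0.8))
  expect_warning(out <- cmro2(c(10, 10), c(5, 5), c(100, 0)), "flagged")
  expect_true(is.na(out[2]) && out[1] == 0.5)
})

test_that("rest baselines are duration-weighted means over qualifying periods", {
  fs <- 40
  # flux: level 1 over [0,30), level 9 over [30,45) (running), level 4 after
  flux <- c(rep(1, 30 * fs), rep(9, 15 * fs), rep(4, 55 * fs))
  rec <- hemo_recording(data.frame(Flux = flux, Hbo = 60, Hbd = 40,
                                   Hbt = 100, sO2 = 70), fs)
  loco <- gen_locomotion(list(c(30, 45, 3)), duration = 100, sample_rate = fs)
  rb <- rest_baseline(rec, loco)
  expect_equal(rb$n_periods, 2)
  expect_equal(rb$total_rest_s, 85)
  expect_equal(unname(rb$means["Flux"]), (30 * 1 + 55 * 4) / 85)
  expect_equal(unname(rb$means["Hbt"]), 100)

  # continuous rest: plain mean over the whole recording
  loco0 <- gen_locomotion(data.frame(start = numeric(), end = numeric(),
                                     speed = numeric()), 100, fs)
  expect_equal(unname(rest_baseline(rec, loco0)$means["Flux"]), mean(flux))

  # rest bouts below 10 s never qualify
  loco8 <- gen_locomotion(data.frame(start = seq(0, 91, by = 9.5),
                                     end = seq(8.5, 99.5, by = 9.5),
                                     speed = 1), 100, fs)
  expect_warning(rb8 <- rest_baseline(rec, loco8), "undefined")
  expect_true(all(is.na(rb8$means)))
})

test_that("rest baseline is invariant to rest-period order", {
  fs <- 10
  x <- c(rep(2, 20 * fs), rep(0, 12 * fs), rep(6, 20 * fs))
  rec <- hemo_recording(data.frame(Flux = x), fs)
  run_mid <- gen_locomotion(list(c(20, 32, 1)), 52, fs)
  rb <- rest_baseline(rec, run_mid)
  # same samples, same mean regardless of which period came first
  x2 <- c(rep(6, 20 * fs), rep(0, 12 * fs), rep(2, 20 * fs))
  rb2 <- rest_baseline(hemo_recording(data.frame(Flux = x2), fs), run_mid)
  expect_equal(rb$means, rb2$means)
})

test_that("reference normalisation maps the reference mean to 1, per timepoint", {
  v <- c(2, 4, 6, 3)
  g <- c("ref", "ref", "other", "ref")
  out <- normalize_to_reference(v, g, "ref")
  expect_equal(out, c(2, 4, 6, 3) / 3)
  expect_equal(mean(out[g == "ref"]), 1)

  # two timepoints with different reference means
  v2 <- c(2, 4, 6, 10, 10, 5)
  g2 <- c("ref", "ref", "x", "ref", "ref", "x")
  tp <- c(1, 1, 1, 2, 2, 2)
  out2 <- normalize_to_reference(v2, g2, "ref", tp)
  expect_equal(out2, c(2 / 3, 4 / 3, 2, 1, 1, 0.5))

  expect_error(normalize_to_reference(v, c("a", "a", "b", "b"), "missing"),
               "empty")
})

test_that("hemo recording validates sO2 range and warns on Hbt inconsistency", {
  expect_error(hemo_recording(data.frame(sO2 = c(50, 120))), "0, 100")
  expect_warning(hemo_recording(data.frame(Hbo = 60, Hbd = 40, Hbt = 120,
                                           sO2 = 70)), "Hbt")
})
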