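# FWHM diametry and radon velocimetry against closed forms and
# constructions.

test_that("fwhm matches the Gaussian closed form and box width", {
  px <- 0.5
  x <- seq(-30, 30)
  for (s in c(1, 2, 4)) {
    w <- fwhm(exp(-x^2 / (2 * s^2)), px)
    expect_equal(w, 2 * sqrt(2 * log(2)) * s * px, tolerance = 0.01)
  }
  # rectangular profile: width recovered within one pixel
  rect <- c(rep(0, 12), rep(1, 10), rep(0, 12))
  expect_equal(fwhm(rect, 1), 10, tolerance = 1)
})

test_that("fwhm is translation- and intensity-scale-invariant", {
  x <- seq(-25, 25)
  g <- exp(-x^2 / 8)
  w0 <- fwhm(g, 0.4)
  expect_identical(fwhm(5 * g, 0.4), w0)
  shifted <- exp(-(x - 4)^2 / 8)
  expect_equal(fwhm(shifted, 0.4), w0, tolerance = 1e-9)
})

test_that("fwhm flags clipped profiles with a reason", {
  half_vessel <- exp(-(seq(0, 20))^2 / 50)   # peak at the window edge
  w <- fwhm(half_vessel, 1)
  expect_true(is.na(w))
  expect_match(attr(w, "reason"), "crossing")
})

test_that("fwhm under 5% noise stays within 2% of the noiseless width", {
  x <- seq(-30, 30)
  g <- exp(-x^2 / (2 * 9))
  w0 <- fwhm(g, 0.5)
  ws <- nvpipe:::with_seed(99, vapply(1:100, function(i)
    fwhm(g + rnorm(length(g), sd = 0.05), 0.5), numeric(1)))
  expect_equal(mean(ws, na.rm = TRUE), w0, tolerance = 0.02)
})

test_that("skeleton tangents follow the vessel orientation", {
  vm <- gen_vessel_movie(10, pixel_size = 0.5, n_frames = 3, noise_sd = 0, seed = 1)
  sk <- skeletonize_2d(apply(vm$movie$data, c(1, 2), mean), 0.5)
  # horizontal ridge: tangents ~ (1, 0)
  expect_true(all(abs(sk$tangents[, 1]) > 0.99))

  vm45 <- gen_vessel_movie(10, pixel_size = 0.5, n_frames = 3, noise_sd = 0,
                           orientation = 45, seed = 1)
  sk45 <- skeletonize_2d(apply(vm45$movie$data, c(1, 2), mean), 0.5)
  mid <- seq(5, nrow(sk45$points) - 5)   # away from path ends
  expect_true(all(abs(abs(sk45$tangents[mid, 1]) - sqrt(2) / 2) < 0.1))
})

test_that("two disjoint ridges: the larger component is kept with a warning", {
  img <- matrix(0, 60, 60)
  img[10:14, 5:55] <- 1            # 5 x 51 ridge
  img[40:42, 20:34] <- 1           # 3 x 15 ridge
  expect_warning(sk <- skeletonize_2d(img, 1), "largest")
  expect_true(all(sk$points[, 2] >= 10 & sk$points[, 2] <= 14))
})

test_that("diameter trace recovers constant width and a step dilation", {
  vm <- gen_vessel_movie(10, pixel_size = 0.5, n_frames = 6, noise_sd = 0, seed = 2)
  sk <- skeletonize_2d(apply(vm$movie$data, c(1, 2), mean), 0.5)
  dt <- diameter_trace_fwhm(vm$movie, sk)
  expect_true(all(dt$valid))
  expect_equal(dt$values, rep(10, 6), tolerance = 0.02)

  step_fn <- function(t) ifelse(t < 2, 10, 12)
  vs <- gen_vessel_movie(step_fn, pixel_size = 0.5, frame_rate = 2,
                         n_frames = 8, noise_sd = 0, seed = 2)
  sks <- skeletonize_2d(apply(vs$movie$data, c(1, 2), mean), 0.5)
  ds <- diameter_trace_fwhm(vs$movie, sks)
  expect_equal(ds$values[1:4], rep(10, 4), tolerance = 0.03)
  expect_equal(ds$values[5:8], rep(12, 4), tolerance = 0.03)
})

test_that("diameter trace is invariant to a 90-degree rotation of the movie", {
  vm <- gen_vessel_movie(8, pixel_size = 0.5, n_frames = 4, noise_sd = 0.01, seed = 3)
  sk <- skeletonize_2d(apply(vm$movie$data, c(1, 2), mean), 0.5)
  dt <- diameter_trace_fwhm(vm$movie, sk)
  rot <- vessel_movie(aperm(vm$movie$data, c(2, 1, 3)), 0.5, vm$movie$frame_rate)
  skr <- skeletonize_2d(apply(rot$data, c(1, 2), mean), 0.5)
  dtr <- diameter_trace_fwhm(rot, skr)
  expect_equal(dt$values, dtr$values, tolerance = 0.01)
})

test_that("radon velocimetry recovers magnitude and sign; noise is flagged", {
  g <- gen_kymograph(2, n_lines = 384, seed = 5)
  vt <- rbcv_radon(g$kymo)
  expect_true(all(!vt$flagged))
  expect_true(all(abs(vt$values - 2) / 2 < 0.05))

  gm <- gen_kymograph(-2, n_lines = 384, seed = 5)
  vtm <- rbcv_radon(gm$kymo)
  expect_true(all(vtm$values < 0))
  expect_true(all(abs(vtm$values + 2) / 2 < 0.05))

  g0 <- gen_kymograph(2, streak_density = 0, noise_sd = 0.05,
                      n_lines = 384, seed = 5)
  vt0 <- rbcv_radon(g0$kymo)
  expect_true(all(vt0$flagged))
  expect_true(all(is.na(vt0$values)))
})

test_that("vessel calibre classification follows the 7/12 um rules", {
  expect_equal(classify_vessel(6), "capillary")
  expect_equal(classify_vessel(13, superficial = TRUE), "pial")
  expect_equal(classify_vessel(7), "intermediate")     # boundary tie-break
  expect_equal(classify_vessel(12, superficial = TRUE), "intermediate")
  expect_warning(cls <- classify_vessel(14, superficial = FALSE), "superficial")
  expect_equal(cls, "intermediate")
  expect_error(classify_vessel(0), "> 0")
})
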