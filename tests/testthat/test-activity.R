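# Pose-table filtering, per-frame distances and activity summaries.

test_that("likelihood filter removes exactly the sub-threshold rows", {
  g <- gen_tracking(cbind(c(0, 50), c(0, 0)), fps = 30, duration_s = 30,
                    dropout_rate = 0.1, seed = 11)
  ft <- filter_tracking(g$table)
  expect_equal(attr(ft, "removed_fraction"), g$truth$dropout_fraction)
  expect_true(all(ft$likelihood == 1))
  # a row with likelihood 0.99 is removed at the default threshold of 1
  expect_false(any(ft$likelihood < 1))
  # threshold 0 is the identity
  expect_equal(nrow(filter_tracking(g$table, 0)), nrow(g$table))
  zero <- g$table
  zero$likelihood <- 0.5
  expect_error(filter_tracking(zero), "review the threshold")
})

test_that("per-frame distances: stationary zero, known path length within 1%", {
  st <- gen_tracking(cbind(25, 25), fps = 30, duration_s = 10, seed = 1)
  fd0 <- frame_distance(st$table)
  expect_equal(sum(fd0$total_cm), 0)

  g <- gen_tracking(cbind(c(0, 100), c(0, 0)), fps = 30, duration_s = 60, seed = 1)
  fd <- frame_distance(g$table)
  expect_equal(sum(fd$mouse_cm), 100, tolerance = 0.01)

  # distances are invariant to rigid translation and scale with px_per_cm
  tr <- g$table
  tr$x <- tr$x + 500; tr$y <- tr$y - 120
  fd_t <- frame_distance(tr)
  expect_equal(sum(fd_t$total_cm), sum(fd$total_cm))
  fd_half <- frame_distance(g$table, px_per_cm = 2 * attr(g$table, "px_per_cm"))
  expect_equal(sum(fd_half$total_cm), sum(fd$total_cm) / 2)
})

test_that("trimming removes floor(trim*n) windows per tail; monotone in trim", {
  # 100 equal windows at 2 Hz
  d <- rep(1, 100 * 600 * 2)
  s <- summarize_activity(d, fps = 2)
  expect_equal(nrow(s$windows), 100)
  expect_equal(sum(s$windows$retained), 98)
  expect_equal(unname(s$daily_totals_cm["0"]), 98 * 1200)

  # a single extreme window is removed by trimming
  d2 <- d
  d2[1:1200] <- 100
  s2 <- summarize_activity(d2, fps = 2)
  expect_false(s2$windows$retained[1])

  # enlarging trim never increases a daily total
  s5 <- summarize_activity(d2, fps = 2, trim = 0.05)
  expect_lte(sum(s5$windows$distance_cm[s5$windows$retained]),
             sum(s2$windows$distance_cm[s2$windows$retained]))

  # with few windows, 1% trimming removes nothing (with a warning)
  expect_warning(s3 <- summarize_activity(rep(1, 3 * 1200), fps = 2), "no window")
  expect_true(all(s3$windows$retained))
})

test_that("constant activity gives a flat per-hour profile", {
  d <- rep(0.5, 24 * 6 * 600 * 2)            # 24 h at 2 fps
  s <- summarize_activity(d, fps = 2)
  hourly <- s$hourly_means_cm
  expect_equal(unname(diff(range(hourly))), 0)
  expect_length(hourly, 24)
})

test_that("wide pose-export CSVs are flattened to the tidy layout", {
  g <- gen_tracking(cbind(c(0, 30), c(0, 10)), fps = 10, duration_s = 5, seed = 2)
  tidy <- as.data.frame(g$table)
  labs <- unique(tidy$label)
  wide <- data.frame(frame = sort(unique(tidy$frame)))
  hdr2 <- c("frame"); hdr3 <- c("coords")
  for (lab in labs) {
    sub <- tidy[tidy$label == lab, ]
    wide[[paste0(lab, "_x")]] <- sub$x
    wide[[paste0(lab, "_y")]] <- sub$y
    wide[[paste0(lab, "_l")]] <- sub$likelihood
    hdr2 <- c(hdr2, rep(lab, 3)); hdr3 <- c(hdr3, "x", "y", "likelihood")
  }
  f <- tempfile(fileext = ".csv")
  writeLines(c(paste(rep("scorer", ncol(wide)), collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), f)
  write.table(wide, f, sep = ",", append = TRUE, col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  tab <- read_tracking_csv(f, fps = 10, px_per_cm = 10)
  fd_wide <- frame_distance(tab)
  fd_tidy <- frame_distance(g$table)
  expect_equal(sum(fd_wide$total_cm), sum(fd_tidy$total_cm), tolerance = 1e-6)
})
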