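# Fisher-Z correlations and PCA preparation rules.

test_that("fisher z: exact values, odd symmetry, round trip", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(max(abs(fisher_z_inv(fisher_z(r)) - r)) < 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("correlations recover a planted linear relation and flag tiny n", {
  df <- nvpipe:::with_seed(3, {
    d <- data.frame(mouse = sprintf("m%02d", 1:15), exercise = rnorm(15))
    d$strong <- 2 * d$exercise + rnorm(15, sd = 0.01)
    d$null <- rnorm(15)
    d$sparse <- c(rnorm(2), rep(NA, 13))
    d
  })
  out <- correlate_measures(df)
  res <- out$results
  expect_gt(res$r[res$measure == "strong"], 0.99)
  expect_gt(res$z[res$measure == "strong"], 2)
  expect_true(res$flagged[res$measure == "sparse"])
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))
  expect_true(all(res$ci_lo >= -1 & res$ci_hi <= 1, na.rm = TRUE))
})

test_that("correlation is invariant to affine rescaling of a measure", {
  df <- nvpipe:::with_seed(4, data.frame(mouse = 1:12, exercise = rnorm(12),
                                         m = rnorm(12)))
  r1 <- correlate_measures(df)$results
  df$m <- 7 * df$m - 3
  r2 <- correlate_measures(df)$results
  expect_equal(r1$r, r2$r)
})

test_that("duplicated mouse rows are rejected", {
  df <- data.frame(mouse = c("a", "a", "b"), exercise = 1:3, m = 4:6)
  expect_error(correlate_measures(df), "duplicated")
})

test_that("null cohorts give a mean Fisher Z near zero", {
  df <- nvpipe:::with_seed(5, {
    d <- data.frame(mouse = 1:24, exercise = rnorm(24))
    for (j in 1:22) d[[paste0("v", j)]] <- rnorm(24)
    d
  })
  out <- correlate_measures(df)
  ci <- out$z_test$conf.int
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("pca prep: missingness exclusion, eigen sum, contribution split", {
  X <- nvpipe:::with_seed(6, {
    M <- matrix(rnorm(200), 20, 10)
    colnames(M) <- paste0("v", 1:10)
    M[, 2] <- M[, 1] + rnorm(20, sd = 0.01)     # near-duplicate pair
    M[1:7, 5] <- NA                              # 35% missing -> excluded
    M[1, 6] <- NA                                # 5% missing -> imputed
    M
  })
  pp <- prepare_pca(X)
  expect_equal(pp$excluded$variable, "v5")
  expect_equal(length(pp$retained_vars), 9)
  expect_equal(sum(pp$eigenvalues), 9, tolerance = 1e-9)
  expect_true(all(pp$eigenvalues[pp$retained_pcs] > 1))
  # the correlated pair shares PC1 roughly equally
  expect_equal(pp$contributions["v1", 1], pp$contributions["v2", 1],
               tolerance = 0.02)
  expect_true(all(abs(colSums(pp$contributions) - 1) < 1e-9))
  expect_true(all(pp$variance_fraction >= 0 & pp$variance_fraction <= 1))

  # exactly-20% missing is retained (exclusion requires strictly more)
  X2 <- X[, 1:4]
  X2[1:4, 3] <- NA
  pp2 <- prepare_pca(X2)
  expect_equal(nrow(pp2$excluded), 0)

  # a retained zero-variance variable is a named error
  X3 <- cbind(X[, 1:3], flatvar = 1)
  expect_error(prepare_pca(X3), "flatvar")
})

test_that("mean imputation with no missing data equals plain standardised PCA", {
  X <- nvpipe:::with_seed(7, matrix(rnorm(120), 20, 6))
  colnames(X) <- paste0("v", 1:6)
  pp <- prepare_pca(X)
  ref <- prcomp(X, scale. = TRUE)
  expect_equal(sort(pp$eigenvalues), sort(ref$sdev^2), tolerance = 1e-9)
})

test_that("chained imputation is deterministic under a fixed seed", {
  X <- nvpipe:::with_seed(8, {
    M <- matrix(rnorm(150), 30, 5)
    colnames(M) <- paste0("v", 1:5)
    M[1:3, 2] <- NA
    M
  })
  a <- prepare_pca(X, impute = "chained", seed = 5)
  b <- prepare_pca(X, impute = "chained", seed = 5)
  expect_identical(a$matrix, b$matrix)
})
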