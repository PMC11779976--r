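# Cross-measure statistics: Fisher-Z transformed correlations of derived
# measures against exercise, and PCA preparation (missingness exclusion,
# imputation, eigenvalue-1 retention, variable contributions).

#' Fisher's Z transform and its inverse
#'
#' `Z = 1/2 ln((1 + r) / (1 - r))`; the inverse is `tanh`. Errors for
#' |r| >= 1.
#'
#' @param r Pearson correlation coefficient(s), |r| < 1.
#' @return Fisher Z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop_nv("|r| must be < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @param z Fisher Z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Correlate per-mouse measures with exercise
#'
#' The exercise variable is z-scored across the cohort within each
#' timepoint, then every measure column is correlated with it
#' (pairwise-complete Pearson, two-sided, 95% CI), transformed to Fisher Z,
#' and the distribution of Z values is location-tested against 0. P-values
#' are also Benjamini-Hochberg adjusted across measures.
#'
#' @param data data.frame with columns `mouse`, `exercise`, optionally
#'   `timepoint`, plus one column per measure.
#' @param measures character vector of measure column names; defaults to
#'   every numeric column except `exercise` and `timepoint`.
#' @param min_pairs minimum complete pairs per correlation (default 3);
#'   measures with fewer pairs are flagged and excluded from the Z summary.
#' @return list: `results` (per measure: `r`, `ci_lo`, `ci_hi`, `z`, `n`,
#'   `p`, `p_adj`, `flagged`), `z_test` (one-sample t-test of Z against 0),
#'   `mean_z`.
#' @export
correlate_measures <- function(data, measures = NULL, min_pairs = 3) {
  if (!all(c("mouse", "exercise") %in% names(data)))
    stop_nv("`data` needs `mouse` and `exercise` columns")
  tp <- if ("timepoint" %in% names(data)) data$timepoint else rep(1L, nrow(data))
  key <- paste(data$mouse, tp)
  if (anyDuplicated(key))
    stop_nv("duplicated mouse/timepoint rows: %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(measures)) {
    num <- vapply(data, is.numeric, logical(1))
    measures <- setdiff(names(data)[num], c("exercise", "timepoint"))
  }
  # z-score exercise within timepoint (the choice does not affect Pearson r)
  ex <- ave(data$exercise, tp, FUN = function(v) {
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) v * 0 else (v - mean(v, na.rm = TRUE)) / s
  })
  rows <- lapply(measures, function(mm) {
    y <- data[[mm]]
    ok <- !is.na(y) & !is.na(ex)
    n <- sum(ok)
    if (n < min_pairs || sd(y[ok]) == 0 || sd(ex[ok]) == 0)
      return(data.frame(measure = mm, r = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, z = NA_real_, n = n, p = NA_real_,
                        flagged = TRUE))
    ct <- cor.test(ex[ok], y[ok], method = "pearson")
    r <- unname(ct$estimate)
    data.frame(measure = mm, r = r,
               ci_lo = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
               ci_hi = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
               z = if (abs(r) < 1) fisher_z(r) else NA_real_,
               n = n, p = ct$p.value, flagged = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  zs <- res$z[!res$flagged & !is.na(res$z)]
  zt <- if (length(zs) >= 2) t.test(zs, mu = 0) else NULL
  list(results = res, z_test = zt,
       mean_z = if (length(zs)) mean(zs) else NA_real_)
}

#' Prepare and run a principal component analysis
#'
#' Excludes variables with more than `missing_cutoff` missing values,
#' imputes the remaining missing entries (column mean by default, or a
#' seeded chained-regression scheme), standardises, and eigendecomposes the
#' correlation matrix. Components with eigenvalue strictly greater than 1
#' are retained; per-variable contributions are squared loadings as a
#' fraction per component.
#'
#' @param table data.frame or matrix, rows = mice, columns = variables.
#' @param missing_cutoff exclusion threshold on the missing fraction
#'   (default 0.20; exclusion requires strictly more than this).
#' @param impute `"mean"` (deterministic) or `"chained"` (iterated
#'   regression imputation, seeded).
#' @param seed seed for chained imputation.
#' @return list of class `pca_prep`: `retained_vars`, `excluded`
#'   (data.frame with missing fractions), `imputation`, `scores`,
#'   `loadings`, `eigenvalues`, `variance_fraction`, `retained_pcs`,
#'   `contributions` (variables x PCs, columns sum to 1), `matrix` (the
#'   standardised data).
#' @export
prepare_pca <- function(table, missing_cutoff = 0.20,
                        impute = c("mean", "chained"), seed = 1) {
  impute <- match.arg(impute)
  X <- as.matrix(as.data.frame(table))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  miss <- colMeans(is.na(X))
  excl <- miss > missing_cutoff
  excluded <- data.frame(variable = colnames(X)[excl],
                         missing_fraction = miss[excl])
  X <- X[, !excl, drop = FALSE]
  if (ncol(X) < 2) stop_nv("fewer than 2 variables survive the missingness cutoff")
  zero_var <- apply(X, 2, function(v) sd(v, na.rm = TRUE) == 0 ||
                      all(is.na(v)))
  if (any(zero_var))
    stop_nv("retained variable(s) with zero variance: %s",
            paste(colnames(X)[zero_var], collapse = ", "))
  # imputation
  if (anyNA(X)) {
    na_mask <- is.na(X)
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[na_mask[, j], j] <- mu[j]
    if (impute == "chained") {
      # iterated column-wise regression on the other variables, from the
      # mean-imputed start; deterministic given the seed
      with_seed(seed, for (it in 1:5) {
        for (j in seq_len(ncol(X))) {
          if (!any(na_mask[, j])) next
          fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
          X[na_mask[, j], j] <- stats::fitted(fit)[na_mask[, j]]
        }
      })
    }
  }
  Z <- scale(X)
  R <- stats::cor(Z)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  load <- eig$vectors
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_along(ev))
  retained_pcs <- which(ev > 1)
  contrib <- sweep(load^2, 2, colSums(load^2), "/")
  scores <- Z %*% load
  structure(list(retained_vars = colnames(X), excluded = excluded,
                 imputation = impute, scores = scores, loadings = load,
                 eigenvalues = ev, variance_fraction = ev / sum(ev),
                 retained_pcs = retained_pcs, contributions = contrib,
                 matrix = Z),
            class = "pca_prep")
}

#' @export
print.pca_prep <- function(x, ...) {
  cat(sprintf("<pca_prep> %d variables (%d excluded), %d PCs with eigenvalue > 1\n",
              length(x$retained_vars), nrow(x$excluded), length(x$retained_pcs)))
  ev <- signif(x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))], 3)
  cat("  leading eigenvalues:", paste(ev, collapse = ", "), "\n")
  invisible(x)
}
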