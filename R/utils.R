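# Shared internal helpers: seeded evaluation, validation, rest-period
# detection shared by the hemo and neuro modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_nv <- function(...) stop(sprintf(...), call. = FALSE)
warn_nv <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_nv("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_nv("`%s` must be > 0", name)
  invisible(x)
}

#' Locate rest (no-locomotion) periods in a speed trace
#'
#' Finds maximal runs where speed stays at or below `speed_eps` and keeps the
#' runs lasting at least `min_rest` seconds. Used for baseline haemodynamic
#' averaging and baseline calcium event statistics.
#'
#' @param locomotion a `locomotion_trace` (or list with `speed` and
#'   `sample_rate`).
#' @param min_rest minimum rest duration in seconds to qualify (default 10).
#' @param speed_eps speed magnitude at or below which the animal counts as
#'   still (default 0: any encoder motion breaks a rest period).
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `start_idx`, `end_idx` (sample indices, inclusive). Zero rows when no
#'   period qualifies.
#' @export
rest_periods <- function(locomotion, min_rest = 10, speed_eps = 0) {
  speed <- locomotion$speed
  fs <- locomotion$sample_rate
  check_scalar(fs, "sample_rate", positive = TRUE)
  still <- abs(speed) <= speed_eps
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= min_rest)
  data.frame(
    start_s = (starts[keep] - 1L) / fs,
    end_s = ends[keep] / fs,
    duration_s = r$lengths[keep] / fs,
    start_idx = starts[keep],
    end_idx = ends[keep]
  )
}

# linear index <-> voxel coordinate helpers for 3D arrays (dim order preserved)
arr_which <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  z <- (idx - 1L) %/% (d[1] * d[2])
  rest <- (idx - 1L) %% (d[1] * d[2])
  cbind(i = rest %% d[1] + 1L, j = rest %/% d[1] + 1L, k = z + 1L)
}

# trapezoidal integral of y sampled at uniform spacing dx
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}


# tiny deterministic gradient over voxel coordinates (max ~1e-3), used to
# break exact distance-transform ties during thinning
tie_break_gradient <- function(d3) {
  i <- rep.int(seq_len(d3[1]), d3[2] * d3[3])
  j <- rep.int(rep(seq_len(d3[2]), each = d3[1]), d3[3])
  k <- rep(seq_len(d3[3]), each = d3[1] * d3[2])
  (k / d3[3] * 1e-3) + (j / d3[2] * 1e-5) + (i / d3[1] * 1e-7)
}
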