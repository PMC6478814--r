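#' Uniform time grid
#'
#' All signal blocks in a simulation share one uniform sampling grid.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param n_samples Number of samples (>= 1).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(dt = 1e-4, n_samples = 1000)
#' range(grid_times(g))
#' @export
time_grid <- function(dt, n_samples, t0 = 0) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt))
  if (dt <= 0) stop("`dt` must be positive")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("`n_samples` must be >= 1")
  structure(list(dt = dt, n_samples = n_samples, t0 = t0),
            class = "time_grid")
}

#' Sample times of a grid
#'
#' @param grid A [time_grid()].
#' @return Numeric vector of length `n_samples` (seconds).
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (seq_len(grid$n_samples) - 1) * grid$dt
}

#' Grid duration in seconds
#' @param grid A [time_grid()].
#' @return Length of the grid, `n_samples * dt`.
#' @export
grid_duration <- function(grid) grid$n_samples * grid$dt

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> dt = %g s (%.6g Hz), %d samples, %g s from t0 = %g s\n",
              x$dt, 1 / x$dt, x$n_samples, grid_duration(x), x$t0))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && a$n_samples == b$n_samples &&
    isTRUE(all.equal(a$t0, b$t0))
}
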