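#' Maturation-corrected fluorescent-reporter production rate
#'
#' Fluorescent proteins are synthesized dark and become fluorescent with
#' first-order kinetics, so the visible (mature) abundance lags
#' production. Assuming no active degradation and a maturation half-time
#' \eqn{t_{1/2}}, the production rate follows from the mature-abundance
#' trace \eqn{A(t)} as
#' \deqn{r(t) = \frac{t_{1/2}}{\ln 2} \frac{d^2 A}{dt^2} + \frac{dA}{dt},}
#' with both derivatives taken analytically from the natural cubic spline
#' through the points. Without maturation correction the rate is just
#' \eqn{dA/dt}. Negative values are permitted: two successive derivatives
#' propagate measurement noise.
#'
#' The abundance should come from multiplying LOWESS-smoothed
#' fluorescence and volume traces assembled with adjacent-cycle context
#' ([assemble_continuous_series()]), so spline boundary effects fall
#' outside the cycle of interest.
#'
#' @param abundance reporter abundance trace (fluorescence x volume).
#' @param time_min matching regular time grid (min).
#' @param t_half maturation half-time (min), > 0; 6 min is the typical
#'   value for superfolder GFP.
#' @param correct_maturation apply the maturation term?
#' @return numeric rate series on `time_min`.
#' @export
production_rate <- function(abundance, time_min = NULL, t_half = 6,
                            correct_maturation = TRUE) {
  if (correct_maturation && t_half <= 0)
    cf_stop("t_half must be positive")
  d1 <- trace_derivative(abundance, time_min, order = 1L,
                         method = "spline")
  if (!correct_maturation) return(d1)
  d2 <- trace_derivative(abundance, time_min, order = 2L,
                         method = "spline")
  (t_half / log(2)) * d2 + d1
}

#' Per-cycle min-max normalized phase matrix
#'
#' Interpolates each cycle's rate trace with a cubic spline at `n_phase`
#' evenly spaced phase points and min-max normalizes each row to `[0, 1]`
#' -- the representation used for cell-cycle heat maps, where shape, not
#' amplitude, is compared across cycles.
#'
#' @param rate_traces list of per-cycle data.frames/lists with `phase`
#'   (in `[0, 1]`) and `rate`.
#' @param n_phase number of evenly spaced phase points (default 17).
#' @return numeric matrix, one row per cycle; a cycle with `max == min`
#'   yields a row of zeros with a warning.
#' @export
minmax_phase_matrix <- function(rate_traces, n_phase = 17L) {
  grid <- seq(0, 1, length.out = n_phase)
  rows <- lapply(rate_traces, function(tr) {
    ok <- !is.na(tr$rate) & !is.na(tr$phase)
    f <- stats::splinefun(tr$phase[ok], tr$rate[ok], method = "natural")
    v <- f(grid)
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant cycle: min-max normalization undefined, row set to 0")
      return(rep(0, n_phase))
    }
    (v - rng[1]) / diff(rng)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- sprintf("phi_%.3f", grid)
  out
}

#' Count interior local maxima of a curve
#'
#' Boundary extrema are ignored: curve edges from regression are
#' unconstrained, so only maxima strictly inside the grid count.
#'
#' @param values numeric vector on an ordered grid.
#' @param min_prominence minimum drop on both sides (same units).
#' @return integer count, with attribute `at` (indices of the maxima).
#' @export
count_interior_maxima <- function(values, min_prominence = 0) {
  n <- length(values)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (values[i] > values[i - 1L] && values[i] >= values[i + 1L]) {
      # walk over a possible plateau
      j <- i
      while (j < n && values[j + 1L] == values[i]) j <- j + 1L
      if (j < n && values[j + 1L] < values[i]) {
        left_min <- min(values[1:i])
        right_min <- min(values[j:n])
        if (values[i] - max(left_min, right_min) >= min_prominence)
          idx <- c(idx, i)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  structure(length(idx), at = idx)
}
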