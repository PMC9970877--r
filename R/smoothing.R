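#' LOWESS smoothing with the window given in points
#'
#' Locally weighted linear regression (tricube weights) evaluated at every
#' grid point, wrapping [stats::lowess()]. The smoothing window is given as
#' a number of data points and converted internally to the span fraction.
#' A single fitting pass is used (no robustness reweighting), which keeps
#' the smoother an exactly linear operator. Missing values are ignored
#' during fitting and stay missing in the output.
#'
#' @param series numeric vector on a regular grid; may contain `NA`.
#' @param window_pts window size of the local line fits, in points
#'   (>= 3, <= number of non-missing points).
#' @param iter robustness iterations passed to [stats::lowess()]
#'   (default 0; robustness iterations make the smoother nonlinear).
#' @return A `cycleflux_smoothed` object: numeric vector of the same length
#'   as `series`, with attributes `method` and `window_pts`.
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 40))
#' lowess_smooth(x + rnorm(40, sd = 0.05), window_pts = 8)
#' @export
lowess_smooth <- function(series, window_pts, iter = 0L) {
  series <- as.numeric(series)
  obs <- which(!is.na(series))
  if (length(obs) == 0L) cf_stop("all values are missing")
  if (window_pts < 3 || window_pts > length(obs))
    cf_stop("window_pts must be in [3, number of observed points]")
  f <- window_pts / length(obs)
  fit <- stats::lowess(obs, series[obs], f = f, iter = iter)
  out <- rep(NA_real_, length(series))
  out[obs] <- fit$y
  smoothed_series(out, method = "lowess", window_pts = window_pts)
}

#' Savitzky-Golay smoothing with nearest-edge padding
#'
#' Least-squares polynomial convolution smoothing (default window 7,
#' polynomial order 3), the standard filter for oscillatory signals whose
#' crests and troughs a running mean would flatten. Edges are handled by
#' acting as if `(window-1)/2` extra points with the edge value existed on
#' each side (nearest-mode padding). A declared discontinuity (for example
#' a medium switch in a perturbation experiment) can be protected by
#' smoothing the pieces before and after it separately and re-merging.
#'
#' @param series numeric vector on a regular grid.
#' @param window odd filter length, > `polyorder`.
#' @param polyorder polynomial order of the local fits.
#' @param split_before optional index (1-based) of the first point of the
#'   second piece; the series is smoothed piecewise on
#'   `[1, split_before - 1]` and `[split_before, n]`.
#' @return A `cycleflux_smoothed` numeric vector, same length as input.
#' @export
savgol_smooth <- function(series, window = 7L, polyorder = 3L,
                          split_before = NULL) {
  series <- as.numeric(series)
  if (window %% 2L != 1L) cf_stop("window must be odd")
  if (polyorder >= window) cf_stop("polyorder must be < window")
  smooth1 <- function(x) {
    n <- length(x)
    if (n == 0L) return(x)
    half <- (window - 1L) %/% 2L
    if (n <= polyorder) return(x)  # too short to fit; identity
    coef <- signal::sgolay(p = polyorder, n = window)[half + 1L, ]
    pad <- c(rep(x[1L], half), x, rep(x[n], half))
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(coef * pad[i:(i + window - 1L)])
    out
  }
  if (is.null(split_before)) {
    out <- smooth1(series)
  } else {
    split_before <- as.integer(split_before)
    if (split_before < 2L || split_before > length(series))
      cf_stop("split_before out of range")
    out <- c(smooth1(series[seq_len(split_before - 1L)]),
             smooth1(series[split_before:length(series)]))
  }
  smoothed_series(out, method = sprintf("savgol(%d,%d)", window, polyorder),
                  window_pts = window)
}

smoothed_series <- function(values, method, window_pts,
                            extension_used = NA_real_) {
  structure(as.numeric(values), method = method, window_pts = window_pts,
            extension_used = extension_used,
            class = "cycleflux_smoothed")
}

#' @export
print.cycleflux_smoothed <- function(x, ...) {
  cat("<smoothed series> n =", length(x), " method:", attr(x, "method"),
      "\n")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Differentiate a series by interpolating spline or midpoint differences
#'
#' Two conventions used at different pipeline stages:
#' \describe{
#'   \item{`spline`}{a natural cubic interpolating spline through the
#'     points, differentiated analytically and evaluated on the original
#'     grid. Used for volume, surface-area and reporter-abundance traces,
#'     which are smoothed on a context-extended window first so the
#'     natural boundary condition acts outside the cycle of interest.}
#'   \item{`midpoint`}{forward differences \eqn{(x_{i+1}-x_i)/\delta t}
#'     assigned to the midpoints \eqn{t_i + \delta t/2}; the convention of
#'     the stop-and-respond NAD(P)H derivative.}
#' }
#'
#' @param series numeric vector.
#' @param time_min time grid (regular, strictly increasing); defaults to
#'   `0, dt, 2 dt, ...`.
#' @param dt grid step in minutes, used when `time_min` is missing.
#' @param order derivative order, 1 or 2 (`spline` only).
#' @param method `"spline"` or `"midpoint"`.
#' @return For `spline`: numeric vector on `time_min`. For `midpoint`: a
#'   list with `time` (midpoints) and `value` (length `n - 1`).
#' @export
trace_derivative <- function(series, time_min = NULL, dt = 6,
                             order = 1L, method = c("spline", "midpoint")) {
  method <- match.arg(method)
  series <- as.numeric(series)
  n <- length(series)
  if (is.null(time_min)) time_min <- (seq_len(n) - 1) * dt
  if (length(time_min) != n) cf_stop("time grid length mismatch")
  dt <- grid_step(time_min)
  if (method == "midpoint") {
    if (order != 1L) cf_stop("midpoint method gives first derivatives only")
    return(list(time = time_min[-n] + dt / 2, value = diff(series) / dt))
  }
  if (!order %in% c(1L, 2L)) cf_stop("order must be 1 or 2")
  obs <- !is.na(series)
  f <- stats::splinefun(time_min[obs], series[obs], method = "natural")
  out <- rep(NA_real_, n)
  out[obs] <- f(time_min[obs], deriv = order)
  out
}

#' Detrend an oscillatory trace by LOWESS division
#'
#' Removes slow trends (photobleaching, focus drift, expression build-up)
#' from a single-cell NAD(P)H trace by dividing the raw values by a LOWESS
#' curve fitted with a large window; the detrended series fluctuates around
#' 1. A second, small-window LOWESS then smooths the detrended series for
#' crest/trough readout.
#'
#' @param series raw fluorescence trace.
#' @param window_large LOWESS window (points) for the trend.
#' @param window_small LOWESS window (points) for smoothing the detrended
#'   values.
#' @return list with `detrended` and `smoothed_detrended` vectors.
#' @export
detrend_by_lowess <- function(series, window_large, window_small) {
  trend <- lowess_smooth(series, window_large)
  if (any(trend <= 0, na.rm = TRUE))
    cf_stop("LOWESS trend is non-positive; cannot divide")
  detrended <- as.numeric(series) / as.numeric(trend)
  list(detrended = detrended,
       smoothed_detrended = as.numeric(lowess_smooth(detrended,
                                                     window_small)))
}
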