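#' Periodic activity waveforms on the unit phase interval
#'
#' Dimensionless, non-negative biosynthetic activity as a function of
#' cell-cycle phase \eqn{\varphi \in [0, 1]}, built from circularly
#' wrapped Gaussian bumps on a constant floor so the waveform is exactly
#' periodic with period 1. `two_peak_waveform()` mimics the two waves of
#' protein biosynthesis (one around START, one mid S/G2/M);
#' `one_peak_waveform()` mimics the single S/G2/M wave of lipid and
#' polysaccharide biosynthesis; `constant_waveform()` is the null shape.
#'
#' @param peaks,peak peak phase(s) in `[0, 1)`.
#' @param widths,width Gaussian s.d. of each bump (phase units).
#' @param heights bump heights (dimensionless).
#' @param floor activity floor added everywhere (>= 0).
#' @param value constant level for `constant_waveform()`.
#' @return a function `f(phase)` vectorized over phase, periodic with
#'   period 1, non-negative.
#' @export
two_peak_waveform <- function(peaks = c(0.15, 0.60),
                              widths = c(0.06, 0.09),
                              heights = c(1, 0.9), floor = 0.15) {
  make_bump_waveform(peaks, widths, heights, floor)
}

#' @rdname two_peak_waveform
#' @export
one_peak_waveform <- function(peak = 0.60, width = 0.10, floor = 0.15) {
  make_bump_waveform(peak, width, 1, floor)
}

#' @rdname two_peak_waveform
#' @export
constant_waveform <- function(value = 1) {
  force(value)
  f <- function(phase) rep(value, length(phase))
  attr(f, "periodic") <- TRUE
  f
}

make_bump_waveform <- function(peaks, widths, heights, floor) {
  stopifnot(length(peaks) == length(widths),
            length(peaks) == length(heights), floor >= 0)
  f <- function(phase) {
    phase <- phase %% 1
    out <- rep(floor, length(phase))
    for (j in seq_along(peaks)) {
      for (k in -1:1) {  # wrap neighbors for exact periodicity
        out <- out + heights[j] *
          exp(-((phase - peaks[j] - k)^2) / (2 * widths[j]^2))
      }
    }
    out
  }
  attr(f, "periodic") <- TRUE
  f
}

#' Periodic baseline oscillation from control points
#'
#' Smooth phase-locked baseline (used for the NAD(P)H cell-cycle
#' oscillation) built as a periodic cubic spline through user-supplied
#' control points.
#'
#' @param phases control-point phases in `[0, 1)`.
#' @param values control-point values.
#' @return periodic function of phase.
#' @export
periodic_spline_waveform <- function(phases = c(0, 0.2, 0.45, 0.7, 0.9),
                                     values = c(1, 0.4, -0.6, 0.9, -0.2)) {
  stopifnot(length(phases) == length(values))
  o <- order(phases)
  phases <- phases[o]; values <- values[o]
  f0 <- stats::splinefun(c(phases, phases[1] + 1), c(values, values[1]),
                         method = "periodic")
  f <- function(phase) f0(((phase - phases[1]) %% 1) + phases[1])
  attr(f, "periodic") <- TRUE
  f
}

# check that a waveform is periodic with period 1 (generator precondition)
assert_periodic <- function(f, name = "waveform", tol = 1e-6) {
  if (!is.function(f)) cf_stop(paste(name, "must be a function of phase"))
  probe <- c(0, 0.25, 0.5, 0.999999)
  if (max(abs(f(probe) - f(probe + 1))) > tol * (1 + max(abs(f(probe)))))
    cf_stop(paste(name, "is not periodic with period 1"))
  invisible(TRUE)
}
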