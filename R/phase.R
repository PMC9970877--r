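#' Population-mean relative phases of cell-cycle events
#'
#' For each reference event \eqn{e \in \{ME, START, BUD, next\ ME\}} the
#' mean relative timing over \eqn{N} cycles is
#' \deqn{\bar\varphi^e = \frac{1}{N} \sum_{cc=1}^{N}
#'   \frac{t^e_{cc} - t^{ME}_{cc}}{t^{nextME}_{cc} - t^{ME}_{cc}},}
#' so \eqn{\bar\varphi^{ME} = 0} and \eqn{\bar\varphi^{nextME} = 1} by
#' construction.
#'
#' @param cycles a data.frame with one row per cycle and columns `ME`,
#'   `START`, `BUD`, `next_ME` (times in min), or a list of such
#'   per-cycle named vectors.
#' @return named numeric vector `c(ME, START, BUD, next_ME)` of mean
#'   relative phases.
#' @examples
#' mean_event_phases(data.frame(ME = 0, START = 10, BUD = 20,
#'                              next_ME = 100))
#' @export
mean_event_phases <- function(cycles) {
  if (is.list(cycles) && !is.data.frame(cycles))
    cycles <- do.call(rbind, lapply(cycles, function(x)
      as.data.frame(as.list(x))))
  need <- c("ME", "START", "BUD", "next_ME")
  if (!all(need %in% names(cycles)))
    cf_stop("cycles must contain columns ME, START, BUD, next_ME")
  dur <- cycles$next_ME - cycles$ME
  if (any(dur <= 0)) cf_stop("next_ME must exceed ME in every cycle")
  bad <- cycles$START <= cycles$ME | cycles$BUD <= cycles$START |
    cycles$next_ME <= cycles$BUD
  if (any(bad))
    cf_stop("event times must be strictly ordered ME < START < BUD < next_ME")
  vapply(need, function(e) mean((cycles[[e]] - cycles$ME) / dur),
         numeric(1))
}

#' Map absolute time to cell-cycle phase by multi-event alignment
#'
#' Converts a time \eqn{t} within the cycle \eqn{(ME_i, ME_{i+1}]} to the
#' phase \eqn{\varphi \in [0, 1]} by piecewise-linear interpolation
#' between consecutive reference events, anchored at the population-mean
#' event phases:
#' \deqn{\varphi(t) = (\bar\varphi^{E[i+1]} - \bar\varphi^{E[i]})
#'   \frac{t - t^{E[i]}}{t^{E[i+1]} - t^{E[i]}} + \bar\varphi^{E[i]}.}
#' The map is continuous, monotone, exact at the reference events, and
#' sends \eqn{ME_i} to 0 and \eqn{ME_{i+1}} to 1.
#'
#' @param t time(s) in minutes; must lie within `[ME, next_ME]`.
#' @param cycle_events named vector with this cycle's `ME`, `START`,
#'   `BUD`, `next_ME` times (min), strictly increasing.
#' @param phase_means population-mean phases from [mean_event_phases()].
#' @return numeric phase(s) in `[0, 1]`.
#' @export
time_to_phase <- function(t, cycle_events, phase_means) {
  need <- c("ME", "START", "BUD", "next_ME")
  te <- as.numeric(cycle_events[need])
  pe <- as.numeric(phase_means[need])
  if (any(is.na(te)) || any(diff(te) <= 0))
    cf_stop("cycle_events must contain strictly increasing ME, START, BUD, next_ME")
  if (any(t < te[1] | t > te[4]))
    cf_stop("t outside the cycle (ME, next_ME]")
  # piecewise-linear with knots at the four events
  stats::approx(te, pe, xout = t, method = "linear", ties = "ordered")$y
}

#' Invert the phase map within one cycle
#'
#' @param phase phase value(s) in `[0, 1]`.
#' @inheritParams time_to_phase
#' @return time(s) in minutes.
#' @export
phase_to_time <- function(phase, cycle_events, phase_means) {
  need <- c("ME", "START", "BUD", "next_ME")
  te <- as.numeric(cycle_events[need])
  pe <- as.numeric(phase_means[need])
  if (any(phase < 0 | phase > 1)) cf_stop("phase outside [0, 1]")
  stats::approx(pe, te, xout = phase, method = "linear",
                ties = "ordered")$y
}
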