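#' Detect mitotic exit and START from Whi5 reporter pixel statistics
#'
#' Whi5 concentrates in the nucleus at mitotic exit (ME) and re-localizes
#' to the cytoplasm at START, so the ratio between the standard deviation
#' and the mean of the reporter pixel intensities in the mother-cell
#' segmentation rises sharply at ME and falls at START. Candidate events
#' are the time points \emph{before} the local extrema of the ratio's
#' midpoint derivative: maxima give ME, minima give START. Extrema are
#' located with a symmetric comparison window of `x` points on each side,
#' with `x = 12` when \eqn{\delta t = 6} min and `x = 24` when
#' \eqn{\delta t = 3} min (i.e. 72 min of context); ties are broken by the
#' earliest time point. A flat ratio yields no candidates.
#'
#' Automatic calls are candidates for curation: `filter_event_candidates()`
#' applies the ME before START before BUD ordering, and manual overrides
#' can replace calls via the `source` column of an events table.
#'
#' @param pixel_sd,pixel_mean per-frame standard deviation and mean of the
#'   reporter pixels in the mother-cell segmentation.
#' @param time_min regular time grid (min).
#' @param x comparison half-window in points; default chosen from the
#'   cadence (`12` at 6 min, `24` at 3 min, otherwise `round(72/dt)`).
#' @return data.frame with columns `event` (`"ME"`/`"START"`) and
#'   `time_min`, ordered in time; zero rows when no extrema exist.
#' @export
detect_whi5_events <- function(pixel_sd, pixel_mean, time_min, x = NULL) {
  dt <- grid_step(time_min)
  if (is.null(x)) {
    x <- if (isTRUE(all.equal(dt, 6))) 12L else
      if (isTRUE(all.equal(dt, 3))) 24L else max(1L, round(72 / dt))
  }
  ratio <- pixel_sd / pixel_mean
  n <- length(ratio)
  if (n <= 2L * x + 1L)
    cf_stop("series too short for the comparison window")
  d <- trace_derivative(ratio, time_min, method = "midpoint")
  loc_ext <- function(v, cmp) {
    # index i is an extremum if cmp(v[i], v[j]) holds for every j within
    # x steps; exact ties are broken by the earliest index, plateaus
    # (all-equal windows) yield nothing
    out <- integer(0)
    if (length(v) < 3L) return(out)
    for (i in 2:(length(v) - 1L)) {  # series edges cannot be extrema
      lo <- max(1L, i - x); hi <- min(length(v), i + x)
      nb <- v[lo:hi][-(i - lo + 1L)]
      if (length(nb) == 0L || all(v[i] == nb)) next
      if (all(cmp(v[i], nb) | v[i] == nb)) {
        ties <- which(v[lo:hi] == v[i]) + lo - 1L
        if (min(ties) == i) out <- c(out, i)
      }
    }
    out
  }
  imax <- loc_ext(d$value, `>`)
  imin <- loc_ext(d$value, `<`)
  # the event is assigned to the time point before the extremum of the
  # derivative; the derivative at index i sits between frames i and i+1
  ev <- rbind(
    if (length(imax)) data.frame(event = "ME", time_min = time_min[imax]),
    if (length(imin)) data.frame(event = "START", time_min = time_min[imin]))
  if (is.null(ev)) ev <- data.frame(event = character(0),
                                    time_min = numeric(0))
  ev[order(ev$time_min), , drop = FALSE]
}

#' Order-filter candidate cell-cycle events
#'
#' Machine proxy for the visual curation of reporter-derived event calls:
#' enforces the canonical ordering ME before START before BUD within each
#' cycle, and drops cycles whose inter-ME gap falls outside
#' median +/- `k_sd` standard deviations of the population. Events from an
#' override table (`source == "manual"`) replace automatic calls at the
#' same position in time.
#'
#' @param events data.frame with columns `cell_id`, `event`
#'   (ME/START/BUD/KARYO), `time_min` and optionally `source`
#'   (`"auto"`/`"manual"`).
#' @param k_sd width of the accepted inter-ME gap window (default 2).
#' @return the filtered events data.frame, with a logical `kept` column on
#'   cycles and an attribute `rejected_cycles`.
#' @export
filter_event_candidates <- function(events, k_sd = 2) {
  stopifnot(all(c("cell_id", "event", "time_min") %in% names(events)))
  if (!"source" %in% names(events)) events$source <- "auto"
  events <- events[order(events$cell_id, events$time_min), ]
  keep <- rep(TRUE, nrow(events))
  # manual calls displace auto calls of the same kind within half a gap
  for (cid in unique(events$cell_id)) {
    sub <- which(events$cell_id == cid)
    man <- sub[events$source[sub] == "manual"]
    for (m in man) {
      same <- sub[events$event[sub] == events$event[m] &
                    events$source[sub] == "auto"]
      if (length(same))
        keep[same[which.min(abs(events$time_min[same] -
                                  events$time_min[m]))]] <- FALSE
    }
  }
  events <- events[keep, ]
  # ordering filter per cycle (between consecutive MEs)
  rejected <- character(0)
  out <- list()
  gaps <- c()
  for (cid in unique(events$cell_id)) {
    sub <- events[events$cell_id == cid, ]
    mes <- sub$time_min[sub$event == "ME"]
    if (length(mes) >= 2) gaps <- c(gaps, diff(sort(mes)))
  }
  gap_ok <- function(g) {
    if (length(gaps) < 3) return(TRUE)
    abs(g - stats::median(gaps)) <= k_sd * stats::sd(gaps)
  }
  for (cid in unique(events$cell_id)) {
    sub <- events[events$cell_id == cid, ]
    mes <- sort(sub$time_min[sub$event == "ME"])
    if (length(mes) < 2) { out[[length(out) + 1L]] <- sub; next }
    for (i in seq_len(length(mes) - 1L)) {
      cyc <- sub[sub$time_min > mes[i] & sub$time_min <= mes[i + 1L] |
                   (sub$event == "ME" & sub$time_min == mes[i]), ]
      st <- cyc$time_min[cyc$event == "START"]
      bd <- cyc$time_min[cyc$event == "BUD"]
      ordered <- (length(st) == 0 || all(st > mes[i])) &&
        (length(bd) == 0 || length(st) == 0 || min(bd) > min(st))
      if (!ordered || !gap_ok(mes[i + 1L] - mes[i]))
        rejected <- c(rejected, sprintf("%s@%g", cid, mes[i]))
      else out[[length(out) + 1L]] <- cyc
    }
  }
  res <- unique(do.call(rbind, c(out, list(events[0, ]))))
  attr(res, "rejected_cycles") <- rejected
  res
}
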