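#' Assemble a continuous per-cycle series across cytokinesis
#'
#' Cell volume and surface area drop abruptly at cytokinesis when the
#' daughter detaches. To smooth and differentiate a cycle
#' \eqn{t \in (ME_i, ME_{i+1}]} without edge artifacts, up to
#' `context_min` minutes of the adjacent cycles are appended after a
#' geometric translation that removes the discontinuity: preceding-context
#' values are shifted down by the previous daughter's size at \eqn{ME_i},
#' following-context values are shifted up by the current daughter's size
#' at \eqn{ME_{i+1}}. Within the cycle, daughter values that are missing in
#' the first frames after budding (buds too small to segment) are linearly
#' interpolated from zero at budding to the first measured value.
#'
#' @param time_min regular time grid (min) covering the cycle and any
#'   available adjacent context.
#' @param mother mother-compartment quantity (volume fl or surface
#'   \eqn{\mu m^2}) on `time_min`.
#' @param daughter daughter-compartment quantity on `time_min`; `0` where
#'   no bud exists, `NA` where a bud exists but was not measurable.
#' @param me_start,me_end times of \eqn{ME_i} and \eqn{ME_{i+1}} (min);
#'   must lie on the grid.
#' @param t_bud budding time within the cycle (min), or `NULL` if the
#'   cycle has no bud (no interpolation is then attempted).
#' @param context_min context length taken from each adjacent cycle (min).
#' @return list with `time`, `value` (translated, interpolated series on
#'   `(me_start - context, me_end + context]`), `in_cycle` (logical mask
#'   of the core cycle) and `extension_used` (min of context actually
#'   available on each side).
#' @export
assemble_continuous_series <- function(time_min, mother, daughter,
                                       me_start, me_end, t_bud = NULL,
                                       context_min = 50) {
  time_min <- as.numeric(time_min)
  grid_step(time_min)
  mother <- as.numeric(mother)
  daughter <- as.numeric(daughter)
  cyc <- time_min > me_start & time_min <= me_end
  if (!any(cyc)) cf_stop("no data points inside the cycle")

  # interpolate unmeasurable early-bud frames: 0 at budding -> first value
  if (!is.null(t_bud)) {
    post_bud <- which(cyc & time_min > t_bud)
    miss <- post_bud[is.na(daughter[post_bud])]
    first_obs <- post_bud[!is.na(daughter[post_bud])][1]
    if (length(miss) > 0 && !is.na(first_obs)) {
      miss <- miss[miss < first_obs]
      if (length(miss) > 0)
        daughter[miss] <- daughter[first_obs] *
          (time_min[miss] - t_bud) / (time_min[first_obs] - t_bud)
    }
    pre_bud <- which(cyc & time_min <= t_bud)
    daughter[pre_bud][is.na(daughter[pre_bud])] <- 0
  }
  total <- mother + daughter

  pre <- which(time_min > me_start - context_min & time_min <= me_start)
  post <- which(time_min > me_end & time_min <= me_end + context_min)

  # daughter size "at ME" = last measured frame at or before the ME
  # (cytokinesis empties the bud compartment right after it)
  d_at <- function(t_me) {
    i <- which(time_min <= t_me)
    if (length(i) == 0) return(NA_real_)
    daughter[max(i)]
  }
  # previous daughter's size at ME_i shifts the preceding context down
  if (length(pre) > 0) {
    d_at_start <- d_at(me_start)
    if (is.na(d_at_start)) {
      warning("daughter size at cycle start unavailable; ",
              "preceding context dropped")
      pre <- integer(0)
    } else {
      total[pre] <- total[pre] - d_at_start
    }
  } else {
    warning("no preceding-cycle context available; proceeding unextended")
  }
  # current daughter's size at ME_{i+1} shifts the following context up
  if (length(post) > 0) {
    d_at_end <- d_at(me_end)
    if (is.na(d_at_end)) {
      warning("daughter size at cycle end unavailable; ",
              "following context dropped")
      post <- integer(0)
    } else {
      total[post] <- total[post] + d_at_end
    }
  } else {
    warning("no following-cycle context available; proceeding unextended")
  }

  keep <- sort(c(pre, which(cyc), post))
  list(time = time_min[keep],
       value = total[keep],
       in_cycle = cyc[keep],
       extension_used = c(pre = length(pre), post = length(post)) *
         grid_step(time_min))
}

#' Per-cycle geometric series from a long-format trace
#'
#' Computes mother and bud volume or surface area from the ellipse radii
#' of a long-format trace, assigns bud measurements to their cycle
#' (a bud exists from its budding event until the next mitotic exit,
#' zero otherwise), and assembles the continuous context-extended series
#' for one cycle via [assemble_continuous_series()].
#'
#' @param trace one cell's rows of the long trace table (`time_min`,
#'   `R_major_um`, `r_minor_um`, `bud_R_major_um`, `bud_r_minor_um`).
#' @param events that cell's events (`event`, `time_min`).
#' @param cycle which cycle (1 = between the first and second ME).
#' @param quantity `"volume"` (fl) or `"surface"` (um^2).
#' @param context_min adjacent-cycle context (min).
#' @return as [assemble_continuous_series()], plus `me_start`, `me_end`,
#'   `t_bud`.
#' @export
cycle_quantity_series <- function(trace, events, cycle = 1L,
                                  quantity = c("volume", "surface"),
                                  context_min = 50) {
  quantity <- match.arg(quantity)
  trace <- trace[order(trace$time_min), ]
  mes <- sort(events$time_min[events$event == "ME"])
  buds <- sort(events$time_min[events$event == "BUD"])
  if (length(mes) < cycle + 1L) cf_stop("cycle not covered by ME events")
  gm <- spheroid_geometry(trace$R_major_um, trace$r_minor_um)
  has_bud_radii <- !is.na(trace$bud_R_major_um) &
    !is.na(trace$bud_r_minor_um)
  gb <- suppressWarnings(spheroid_geometry(
    ifelse(has_bud_radii, trace$bud_R_major_um, 1),
    ifelse(has_bud_radii, trace$bud_r_minor_um, 1)))
  mother <- gm[[quantity]]
  daughter <- ifelse(has_bud_radii, gb[[quantity]], NA_real_)
  # a bud exists from its budding event until the next ME; within each
  # bud window, unmeasurable early frames are interpolated from zero at
  # budding to the first measured value
  in_bud_window <- rep(FALSE, nrow(trace))
  for (i in seq_len(length(mes) - 1L)) {
    b <- buds[buds > mes[i] & buds <= mes[i + 1L]]
    if (length(b) == 0L) next
    win <- which(trace$time_min > b[1] & trace$time_min <= mes[i + 1L])
    in_bud_window[win] <- TRUE
    first_obs <- win[!is.na(daughter[win])][1]
    if (!is.na(first_obs)) {
      miss <- win[win < first_obs & is.na(daughter[win])]
      if (length(miss))
        daughter[miss] <- daughter[first_obs] *
          (trace$time_min[miss] - b[1]) /
          (trace$time_min[first_obs] - b[1])
    }
  }
  daughter[!in_bud_window] <- 0
  t_bud <- buds[buds > mes[cycle] & buds <= mes[cycle + 1L]]
  t_bud <- if (length(t_bud)) t_bud[1] else NULL
  out <- assemble_continuous_series(trace$time_min, mother, daughter,
                                    mes[cycle], mes[cycle + 1L],
                                    t_bud = t_bud,
                                    context_min = context_min)
  out$me_start <- mes[cycle]; out$me_end <- mes[cycle + 1L]
  out$t_bud <- t_bud
  out
}

#' Maturation-corrected production rate for one cell cycle
#'
#' The full reporter pipeline for a single cycle: assemble the
#' context-extended cell volume, LOWESS-smooth volume and fluorescence,
#' multiply them into the reporter abundance, differentiate by spline
#' and apply the maturation correction; values are then restricted to
#' the cycle of interest.
#'
#' @param trace one cell's trace rows (needs a fluorescence column).
#' @param events that cell's events.
#' @param cycle cycle index.
#' @param channel fluorescence column name (default `"gfp"`).
#' @param t_half maturation half-time (min).
#' @param window_volume,window_fluor LOWESS windows in points.
#' @param context_min adjacent-cycle context (min).
#' @return data.frame `time_min`, `phase_lin` (linear phase in the
#'   cycle), `rate`, plus attributes `me_start`, `me_end`.
#' @export
reporter_production_cycle <- function(trace, events, cycle = 1L,
                                      channel = "gfp", t_half = 6,
                                      window_volume = 6L,
                                      window_fluor = 7L,
                                      context_min = 50) {
  va <- cycle_quantity_series(trace, events, cycle, "volume",
                              context_min)
  f_raw <- trace[[channel]][match(va$time, trace$time_min)]
  vs <- lowess_smooth(va$value, window_volume)
  fs <- lowess_smooth(f_raw, window_fluor)
  abundance <- as.numeric(vs) * as.numeric(fs)
  rate <- production_rate(abundance, va$time, t_half = t_half)
  out <- data.frame(time_min = va$time[va$in_cycle],
                    rate = rate[va$in_cycle])
  out$phase_lin <- (out$time_min - va$me_start) /
    (va$me_end - va$me_start)
  attr(out, "me_start") <- va$me_start
  attr(out, "me_end") <- va$me_end
  out
}
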