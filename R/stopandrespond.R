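#' Select steadily cycling cells before a perturbation
#'
#' Focuses the stop-and-respond analysis on the predominant subpopulation
#' of fast-dividing cells: for each cell the duration between its two
#' latest budding events before `t_switch` is computed, and cells within
#' median +/- one standard deviation of that distribution are kept
#' (set S1). The same two latest pre-switch cycles provide the mean
#' absolute event timings with mitotic exit at 0 min:
#' \eqn{\Delta\bar t_{START}}, \eqn{\Delta\bar t_{BUD}} (START and
#' budding relative to the ME between the two buddings) and
#' \eqn{\Delta\bar t_{CC}} (the inter-budding duration itself).
#'
#' @param events data.frame with `cell_id`, `event`
#'   (ME/START/BUD/KARYO), `time_min`; cells need >= 2 buddings before
#'   `t_switch` (set S0).
#' @param t_switch medium switch time (min).
#' @return list with `S1` (kept cell ids), `per_cell` (data.frame:
#'   `cell_id`, `interbud_min`, `kept`), and `timing`
#'   (`dt_START`, `dt_BUD`, `dt_CC` means in min).
#' @export
select_steady_cycling_cells <- function(events, t_switch) {
  cells <- unique(events$cell_id)
  rows <- lapply(cells, function(cid) {
    buds <- sort(events$time_min[events$cell_id == cid &
                                   events$event == "BUD" &
                                   events$time_min < t_switch])
    if (length(buds) < 2) return(NULL)
    b2 <- tail(buds, 2)
    mes <- events$time_min[events$cell_id == cid & events$event == "ME" &
                             events$time_min > b2[1] &
                             events$time_min <= b2[2]]
    sts <- events$time_min[events$cell_id == cid &
                             events$event == "START" &
                             events$time_min > b2[1] &
                             events$time_min <= b2[2]]
    data.frame(cell_id = cid, interbud_min = diff(b2),
               me = if (length(mes)) min(mes) else NA_real_,
               start = if (length(sts)) min(sts) else NA_real_,
               bud = b2[2])
  })
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell)) cf_stop("no cell has two pre-switch buddings")
  med <- stats::median(per_cell$interbud_min)
  s <- stats::sd(per_cell$interbud_min)
  if (is.na(s)) s <- 0
  per_cell$kept <- abs(per_cell$interbud_min - med) <= s
  kept <- per_cell[per_cell$kept, ]
  timing <- c(
    dt_START = mean(kept$start - kept$me, na.rm = TRUE),
    dt_BUD = mean(kept$bud - kept$me, na.rm = TRUE),
    dt_CC = mean(kept$interbud_min))
  list(S1 = kept$cell_id, per_cell = per_cell, timing = timing)
}

#' Cell-cycle position of a cell at the moment of perturbation
#'
#' The phase of cell `c` at the perturbation readout time
#' \eqn{t_p - \delta t/2} is anchored to its most recent cell-cycle event:
#' with \eqn{\theta^c_e} the time elapsed since the latest event of kind
#' \eqn{e \in \{ME, START, BUD\}}, the nearest event
#' \eqn{E^c = \arg\min_e \theta^c_e} describes the position most
#' reliably, and \eqn{\varphi^c = \min_e \theta^c_e + \Delta\bar t_{E^c}}
#' expresses it in minutes since (population-mean) mitotic exit. Cells
#' whose nearest event is abnormally delayed are excluded:
#' \eqn{\varphi^c > \Delta\bar t_{START}} with \eqn{E^c = ME},
#' \eqn{\varphi^c > \Delta\bar t_{BUD}} with \eqn{E^c = START}, or
#' \eqn{\varphi^c > \Delta\bar t_{CC}} with \eqn{E^c = BUD}.
#'
#' @param cell_events data.frame of one cell's events (`event`,
#'   `time_min`).
#' @param t_p first frame of severe perturbation (min).
#' @param dt imaging cadence (min).
#' @param timing named vector `dt_START`, `dt_BUD`, `dt_CC` from
#'   [select_steady_cycling_cells()].
#' @return list with `phi` (min since ME-equivalent), `E` (nearest event
#'   kind), `theta` (named elapsed times), `kept`, `reason`.
#' @export
perturbation_phase <- function(cell_events, t_p, dt, timing) {
  t_ref <- t_p - dt / 2
  theta <- vapply(c(ME = "ME", START = "START", BUD = "BUD"),
                  function(e) {
                    tt <- cell_events$time_min[cell_events$event == e &
                                                 cell_events$time_min <= t_ref]
                    if (length(tt) == 0) NA_real_ else t_ref - max(tt)
                  }, numeric(1))
  if (all(is.na(theta)))
    return(list(phi = NA_real_, E = NA_character_, theta = theta,
                kept = FALSE, reason = "no pre-perturbation events"))
  ec <- names(theta)[which.min(theta)]
  offset <- unname(c(ME = 0, START = unname(timing["dt_START"]),
                     BUD = unname(timing["dt_BUD"]))[ec])
  phi <- min(theta, na.rm = TRUE) + offset
  lim <- unname(c(ME = unname(timing["dt_START"]),
                  START = unname(timing["dt_BUD"]),
                  BUD = unname(timing["dt_CC"]))[ec])
  if (phi > lim)
    return(list(phi = phi, E = ec, theta = theta, kept = FALSE,
                reason = sprintf("nearest event %s abnormally delayed", ec)))
  list(phi = phi, E = ec, theta = theta, kept = TRUE, reason = NA_character_)
}

#' Normal (unperturbed) NAD(P)H derivative profile
#'
#' The median, across steadily cycling cells, of the smoothed NAD(P)H
#' derivative at the time comparable to phase \eqn{\phi} in the
#' \emph{preceding} cell cycle, anchored at each cell's second-latest
#' event of the relevant kind:
#' \deqn{N(\phi) = \mathrm{median}_x \dot F^x(L_e(x)_{[-2]} + \phi -
#'   \Delta\bar t_e),}
#' with \eqn{e = ME} on \eqn{(0, \Delta\bar t_{START}]}, \eqn{e = START}
#' on \eqn{(\Delta\bar t_{START}, \Delta\bar t_{BUD}]} and \eqn{e = BUD}
#' on \eqn{(\Delta\bar t_{BUD}, \Delta\bar t_{CC}]}. Derivatives live on
#' frame midpoints and are linearly interpolated in between.
#'
#' @param deriv_by_cell named list (by cell id) of lists with `time` and
#'   `value`: midpoint derivatives of the smoothed NAD(P)H traces.
#' @param events events data.frame covering those cells.
#' @param t_switch medium switch time (min); second-latest events are
#'   taken before it.
#' @param timing named vector `dt_START`, `dt_BUD`, `dt_CC`.
#' @return list with `N` (vectorized function of phi on
#'   `(0, dt_CC]`), `amplitude` (max - min of N over that interval) and
#'   `grid` (data.frame phi/value used for the amplitude).
#' @export
normal_derivative_profile <- function(deriv_by_cell, events, t_switch,
                                      timing) {
  second_latest <- function(cid, e) {
    tt <- sort(events$time_min[events$cell_id == cid &
                                 events$event == e &
                                 events$time_min < t_switch])
    if (length(tt) < 2) NA_real_ else tt[length(tt) - 1L]
  }
  cells <- names(deriv_by_cell)
  anchors <- lapply(c(ME = "ME", START = "START", BUD = "BUD"),
                    function(e) vapply(cells, second_latest, numeric(1),
                                       e = e))
  deriv_at <- function(cid, tt) {
    d <- deriv_by_cell[[cid]]
    stats::approx(d$time, d$value, xout = tt, rule = 1)$y
  }
  N <- function(phi) {
    vapply(phi, function(p) {
      if (p <= 0 || p > timing["dt_CC"]) return(NA_real_)
      if (p <= timing["dt_START"]) { e <- "ME"; off <- 0 }
      else if (p <= timing["dt_BUD"]) {
        e <- "START"; off <- timing[["dt_START"]]
      } else { e <- "BUD"; off <- timing[["dt_BUD"]] }
      vals <- vapply(cells, function(cid) {
        a <- anchors[[e]][[cid]]
        if (is.na(a)) return(NA_real_)
        deriv_at(cid, a + p - off)
      }, numeric(1))
      stats::median(vals, na.rm = TRUE)
    }, numeric(1))
  }
  phi_grid <- seq(1e-9, timing[["dt_CC"]], length.out = 241L)
  vals <- N(phi_grid)
  amp <- diff(range(vals, na.rm = TRUE))
  list(N = N, amplitude = amp,
       grid = data.frame(phi = phi_grid, value = vals))
}

#' Normalized NAD(P)H response of one cell
#'
#' \deqn{R^c = \frac{\alpha (P^c - N(\varphi^c))}{\max_\phi N - \min_\phi N},}
#' the deviation of the cell's NAD(P)H derivative at perturbation from
#' the unperturbed same-phase median, in units of the NAD(P)H oscillation
#' amplitude. \eqn{\alpha = -1} when the population-average NAD(P)H drops
#' at the perturbation (so responses are on average non-negative),
#' otherwise \eqn{+1}.
#'
#' @param P derivative at `t_p - dt/2` for the cell(s).
#' @param phi matching phase(s) in minutes.
#' @param profile result of [normal_derivative_profile()].
#' @param alpha +1 or -1.
#' @return numeric response value(s).
#' @export
nadph_response <- function(P, phi, profile, alpha = -1) {
  if (!alpha %in% c(-1, 1)) cf_stop("alpha must be +1 or -1")
  if (!is.finite(profile$amplitude) || profile$amplitude <= 0)
    cf_stop("degenerate normal profile: zero oscillation amplitude")
  alpha * (P - profile$N(phi)) / profile$amplitude
}

#' Run the stop-and-respond pipeline end to end
#'
#' From raw NAD(P)H traces and event tables to the cell-cycle activity
#' pattern of the inhibited process: cell selection (S0 to S1 to S2),
#' piecewise Savitzky-Golay smoothing split at the medium switch,
#' midpoint derivatives, per-cell perturbation phase and response, and a
#' Gaussian-process summary with RBF length scale bounded in
#' `[2 dt, ls_upper_mult * dt]`.
#'
#' @param experiment list with `traces` (`cell_id`, `time_min`, `nadph`),
#'   `events`, `t_switch`, `dt` (e.g. from
#'   [simulate_perturbation_experiment()]).
#' @param t_p first frame of severe perturbation; `NULL` auto-detects it
#'   as the first post-switch frame where the absolute population-mean
#'   derivative exceeds `k_detect` pre-switch standard deviations.
#' @param alpha `"auto"`, `-1` or `+1`.
#' @param ls_upper_mult upper RBF length-scale bound in units of `dt`
#'   (default 5).
#' @param k_detect threshold (in pre-switch sds) for auto-detecting
#'   `t_p`.
#' @param split `"auto"`, `"always"` or `"never"`: split the smoothing
#'   at the medium switch. Splitting protects a sharp fluorescence drop
#'   (as under translation-inhibitor or degron perturbations) from being
#'   blurred by the filter, but costs edge accuracy, so `"auto"` splits
#'   only when the population shows a step at the switch larger than
#'   three times the typical frame-to-frame change.
#' @param gp_seed seed for the GP hyperparameter restarts.
#' @return object of class `cycleflux_sar`: list with `cells`
#'   (per-cell table: `cell_id`, `P`, `phi`, `E`, `R`, `kept`, `reason`),
#'   `profile`, `alpha`, `t_p`, `timing`, `pattern`
#'   (the [fit_phase_gp()] result on the kept cells).
#' @export
stop_and_respond <- function(experiment, t_p = NULL, alpha = "auto",
                             ls_upper_mult = 5, k_detect = 3,
                             split = c("auto", "always", "never"),
                             gp_seed = 1L) {
  split <- match.arg(split)
  tr <- experiment$traces
  ev <- experiment$events
  dt <- experiment$dt
  t_switch <- experiment$t_switch
  sel <- select_steady_cycling_cells(ev, t_switch)
  s1 <- sel$S1
  if (split == "auto") {
    # split only if the switch produced a sharp population-level step
    steps <- vapply(s1, function(cid) {
      sub <- tr[tr$cell_id == cid, ]
      sub <- sub[order(sub$time_min), ]
      i <- which(sub$time_min >= t_switch)[1]
      pre_d <- diff(sub$nadph[sub$time_min < t_switch])
      if (is.na(i) || i < 2 || length(pre_d) < 3) return(NA_real_)
      abs(sub$nadph[i] - sub$nadph[i - 1]) /
        max(stats::median(abs(pre_d)), 1e-12)
    }, numeric(1))
    split <- if (stats::median(steps, na.rm = TRUE) > 3) "always" else
      "never"
  }
  # smooth (optionally split at the medium switch) and differentiate
  deriv_by_cell <- list()
  for (cid in s1) {
    sub <- tr[tr$cell_id == cid, ]
    sub <- sub[order(sub$time_min), ]
    split_idx <- if (split == "always")
      which(sub$time_min >= t_switch)[1] else NULL
    sm <- savgol_smooth(sub$nadph, split_before = split_idx)
    deriv_by_cell[[cid]] <- trace_derivative(as.numeric(sm),
                                             sub$time_min,
                                             method = "midpoint")
  }
  # population-mean derivative, for t_p detection and the alpha sign
  all_t <- sort(unique(unlist(lapply(deriv_by_cell, `[[`, "time"))))
  pop_mean <- vapply(all_t, function(tt) {
    mean(vapply(deriv_by_cell, function(d) {
      i <- which(abs(d$time - tt) < 1e-6)
      if (length(i)) d$value[i] else NA_real_
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  if (is.null(t_p)) {
    pre <- all_t < t_switch
    thr <- k_detect * stats::sd(pop_mean[pre], na.rm = TRUE)
    cand <- which(!pre & abs(pop_mean - mean(pop_mean[pre])) > thr)
    if (length(cand) == 0)
      cf_stop("could not auto-detect t_p: no sharp population change")
    t_p <- all_t[cand[1]] + dt / 2  # midpoint -> frame after it
  }
  if (identical(alpha, "auto")) {
    i_p <- which.min(abs(all_t - (t_p - dt / 2)))
    alpha <- if (pop_mean[i_p] < 0) -1 else 1
  }
  profile <- normal_derivative_profile(deriv_by_cell, ev, t_switch,
                                       sel$timing)
  rows <- lapply(s1, function(cid) {
    pp <- perturbation_phase(ev[ev$cell_id == cid, ], t_p, dt,
                             sel$timing)
    d <- deriv_by_cell[[cid]]
    i <- which(abs(d$time - (t_p - dt / 2)) < 1e-6)
    P <- if (length(i)) d$value[i] else NA_real_
    data.frame(cell_id = cid, P = P, phi = pp$phi,
               E = if (is.na(pp$E)) NA_character_ else pp$E,
               kept = pp$kept && !is.na(P),
               reason = pp$reason, stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  cells$R <- NA_real_
  ok <- cells$kept
  cells$R[ok] <- nadph_response(cells$P[ok], cells$phi[ok], profile,
                                alpha)
  ok <- ok & is.finite(cells$R)
  cells$kept <- ok
  pattern <- fit_phase_gp(cells$phi[ok], cells$R[ok],
                          lengthscale_bounds = c(2 * dt,
                                                 ls_upper_mult * dt),
                          seed = gp_seed)
  structure(list(cells = cells, profile = profile, alpha = alpha,
                 t_p = t_p, timing = sel$timing, S1 = s1,
                 pattern = pattern),
            class = "cycleflux_sar")
}

#' @export
print.cycleflux_sar <- function(x, ...) {
  cat("<stop-and-respond> t_p =", x$t_p, "min, alpha =", x$alpha, ";",
      sum(x$cells$kept), "of", nrow(x$cells), "S1 cells kept\n")
  invisible(x)
}

#' Correct and normalize a pulsed glucose-analog uptake readout
#'
#' For a pulse of a fluorescent glucose analog: per-cell autofluorescence
#' (the mean of the five frames before the pulse began, Switch 1) is
#' subtracted from the readout frame (the first frame after the pulse
#' ended, Switch 2); acquisition-time decay between stage-position
#' batches is removed by dividing each cell by the median of its batch
#' (up to four positions imaged back-to-back).
#'
#' @param cell_series data.frame with `cell_id`, `time_min`, `value`
#'   (fluorescence), `batch` (acquisition batch id).
#' @param switch1,switch2 times (min) of pulse start and end.
#' @return data.frame `cell_id`, `batch`, `raw`, `autofluo`, `corrected`,
#'   `normalized`.
#' @export
nbdg_signal_correction <- function(cell_series, switch1, switch2) {
  out <- lapply(split(cell_series, cell_series$cell_id), function(sub) {
    sub <- sub[order(sub$time_min), ]
    pre <- tail(sub$value[sub$time_min < switch1], 5)
    post <- sub$value[sub$time_min >= switch2]
    if (length(pre) == 0 || length(post) == 0) return(NULL)
    data.frame(cell_id = sub$cell_id[1], batch = sub$batch[1],
               raw = post[1], autofluo = mean(pre),
               corrected = post[1] - mean(pre))
  })
  res <- do.call(rbind, out)
  med <- tapply(res$corrected, res$batch, stats::median)
  res$normalized <- res$corrected / as.numeric(med[as.character(res$batch)])
  rownames(res) <- NULL
  res
}
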