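#' Simulate a stop-and-respond perturbation experiment
#'
#' Emulates an asynchronously cycling population whose NAD(P)H
#' fluorescence follows a phase-locked periodic baseline oscillation until
#' an inhibitor arrives. The medium switch happens at `t_switch`; severe
#' perturbation starts at the first frame `t_p >= t_switch + lag`. From
#' `t_p` on, each cell's NAD(P)H derivative is offset by
#' `sign * perturbation_gain * a(phi_c(t_p))`, where `a` is the inhibited
#' process's activity waveform evaluated at the phase that cell occupied
#' at `t_p` -- exactly the signal the stop-and-respond statistic is
#' designed to read out. Additive Gaussian noise is applied to the whole
#' trace. Cells are born at uniformly random phases; every cell completes
#' at least two budding events before `t_switch`.
#'
#' @param truth a [ground_truth()] object; `truth$activity[[process]]`
#'   defines the perturbed activity and `truth$perturbation_gain` its
#'   gain.
#' @param n_cells number of cells.
#' @param t_switch medium-switch time (min); must allow >= 2 pre-switch
#'   buddings (about 2.5 cycles).
#' @param lag minutes between the switch and severe perturbation
#'   (`>= 0`).
#' @param process which activity waveform is perturbed.
#' @param sign direction of the NAD(P)H derivative offset (+1 or -1);
#'   `-1` emulates inhibitors under which NAD(P)H drops.
#' @param dt imaging cadence (min).
#' @param tail_min recording time kept after `t_p`.
#' @param seed seed; defaults to `truth$seed`.
#' @return object of class `cycleflux_perturbation`: list with `traces`
#'   (`cell_id`, `time_min`, `nadph`), `events`, `t_switch`, `t_p`, `dt`
#'   and `truth` (per-cell phase and activity at `t_p`, gain, sign).
#' @export
simulate_perturbation_experiment <- function(truth, n_cells, t_switch,
                                             lag = 0,
                                             process = "protein",
                                             sign = -1, dt = 6,
                                             tail_min = 30,
                                             seed = truth$seed) {
  if (lag < 0) cf_stop("lag must be non-negative")
  if (t_switch < 2.5 * truth$cycle_min)
    cf_stop("t_switch too early: most cells need >= 2 pre-switch buddings")
  if (!process %in% names(truth$activity))
    cf_stop("unknown perturbed process")
  set.seed(seed)
  act <- truth$activity[[process]]
  grid <- seq(0, t_switch + lag + tail_min, by = dt)
  t_p <- grid[grid >= t_switch + lag][1L]
  n_cyc <- ceiling((t_switch + lag + tail_min) / truth$cycle_min) + 3L
  traces <- vector("list", n_cells)
  events <- vector("list", n_cells)
  cell_truth <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    # born mid-cycle: shift the schedule left by a uniform phase offset
    off <- stats::runif(1) * truth$cycle_min
    sched <- draw_schedule(truth, n_cyc, t0 = -off)
    phi <- schedule_phase(sched, grid)
    base <- truth$nadph_level +
      truth$nadph_amplitude * truth$nadph_baseline(phi)
    phi_p <- schedule_phase(sched, t_p)
    a_p <- act(phi_p)
    # the derivative offset develops over the frame interval ending at
    # t_p, which is what makes t_p the first frame of severe
    # perturbation as read by the midpoint derivative at t_p - dt/2
    t_on <- t_p - dt
    f <- base + (grid >= t_on) * sign * truth$perturbation_gain * a_p *
      (grid - t_on)
    f <- f + stats::rnorm(length(grid), 0, truth$noise_frac * mean(base))
    cid <- sprintf("cell%03d", ci)
    traces[[ci]] <- data.frame(cell_id = cid, time_min = grid, nadph = f)
    ev <- data.frame(
      cell_id = cid,
      event = rep(c("ME", "START", "BUD", "KARYO"), each = nrow(sched)),
      time_min = c(sched$ME, sched$START, sched$BUD, sched$KARYO))
    events[[ci]] <- ev[ev$time_min >= 0 &
                         ev$time_min <= max(grid), , drop = FALSE]
    cell_truth[[ci]] <- data.frame(cell_id = cid, phase_at_tp = phi_p,
                                   activity_at_tp = a_p)
  }
  structure(list(traces = do.call(rbind, traces),
                 events = do.call(rbind, events),
                 t_switch = t_switch, t_p = t_p, dt = dt,
                 truth = list(cells = do.call(rbind, cell_truth),
                              gain = truth$perturbation_gain,
                              sign = sign, activity = act,
                              baseline = truth$nadph_baseline,
                              amplitude = truth$nadph_amplitude,
                              cycle_min = truth$cycle_min)),
            class = "cycleflux_perturbation")
}

#' @export
print.cycleflux_perturbation <- function(x, ...) {
  cat("<perturbation experiment>",
      length(unique(x$traces$cell_id)), "cells, t_switch =", x$t_switch,
      "min, t_p =", x$t_p, "min\n")
  invisible(x)
}

#' Synthetic nuclear images for segmentation fixtures
#'
#' Builds an integer-intensity 2-D image containing one bright blob (the
#' nucleus) on a uniform background, optionally with small decoy specks
#' below the size filter, plus Gaussian noise; returns the true mask
#' alongside.
#'
#' @param blob list with `center` (row, col), `radius_px` and `contrast`
#'   (intensity above background).
#' @param size image dimensions `c(rows, cols)`.
#' @param background_level background intensity counts.
#' @param noise_sd Gaussian noise sd (counts).
#' @param decoys list of lists like `blob` (use small radii to stay below
#'   the downstream 25-pixel filter).
#' @param seed integer seed.
#' @return list with `image` (integer matrix), `mask` (logical matrix,
#'   the true nucleus), `decoy_mask`.
#' @export
simulate_nuclear_images <- function(blob = list(center = c(32, 32),
                                                radius_px = 3.5,
                                                contrast = 200),
                                    size = c(64, 64),
                                    background_level = 100,
                                    noise_sd = 2,
                                    decoys = list(), seed = 1L) {
  set.seed(seed)
  rows <- row(matrix(0, size[1], size[2]))
  cols <- col(matrix(0, size[1], size[2]))
  disk <- function(b) {
    if (b$center[1] + b$radius_px > size[1] ||
        b$center[2] + b$radius_px > size[2] ||
        min(b$center) - b$radius_px < 1)
      cf_stop("blob does not fit inside the image")
    (rows - b$center[1])^2 + (cols - b$center[2])^2 <= b$radius_px^2
  }
  mask <- disk(blob)
  img <- matrix(background_level, size[1], size[2])
  img[mask] <- img[mask] + blob$contrast
  dmask <- matrix(FALSE, size[1], size[2])
  for (d in decoys) {
    dm <- disk(d)
    img[dm] <- img[dm] + d$contrast
    dmask <- dmask | dm
  }
  img <- img + stats::rnorm(length(img), 0, noise_sd)
  list(image = matrix(as.integer(round(pmax(img, 0))), size[1], size[2]),
       mask = mask, decoy_mask = dmask)
}

#' Synthetic illumination-field frames for flat-field fixtures
#'
#' Each frame is `baseline + G(x, y) * scene + noise`, with `G` a 2-D
#' Gaussian illumination field. A `scene` of 1 everywhere gives pure
#' field frames; per-frame random scenes emulate different stage
#' positions.
#'
#' @param gaussian list with `A`, `x0`, `y0`, `sx`, `sy` (an infinite
#'   `sx`/`sy` gives a flat field of height `A`).
#' @param n_frames number of frames.
#' @param size image dimensions.
#' @param baseline camera baseline counts (default 500).
#' @param scene_level mean scene intensity.
#' @param noise_sd Gaussian noise sd (counts).
#' @param seed integer seed.
#' @return list of matrices (the stack).
#' @export
simulate_flatfield_frames <- function(gaussian = list(A = 1, x0 = 32,
                                                      y0 = 32, sx = 40,
                                                      sy = 40),
                                      n_frames = 9, size = c(64, 64),
                                      baseline = 500, scene_level = 1000,
                                      noise_sd = 0, seed = 1L) {
  set.seed(seed)
  rows <- row(matrix(0, size[1], size[2]))
  cols <- col(matrix(0, size[1], size[2]))
  g <- gaussian$A * exp(-((rows - gaussian$x0)^2) / (2 * gaussian$sx^2) -
                          ((cols - gaussian$y0)^2) / (2 * gaussian$sy^2))
  lapply(seq_len(n_frames), function(k)
    baseline + g * scene_level +
      matrix(stats::rnorm(length(g), 0, noise_sd), size[1], size[2]))
}
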