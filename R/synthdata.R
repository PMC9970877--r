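#' Ground truth for synthetic single-cell experiments
#'
#' Bundles everything the generator needs to produce synthetic time-lapse
#' experiments with a known answer: per-process activity waveforms,
#' the cell-cycle event schedule, first-order fluorophore maturation, the
#' noise model, and the perturbation gain of the stop-and-respond
#' emulation. The seed fully determines every generated dataset.
#'
#' Defaults encode the study conditions the pipeline assumes: a ~100-min
#' cell cycle sampled every 6 min, START at 11 min (the early-G1 duration
#' of a mature cell), budding at one third of the cycle, karyokinesis at
#' 85%, a 6-min maturation half-time, additive Gaussian channel noise of
#' 2% of the channel mean, and 1% lognormal noise on ellipse radii. The
#' within-population variability of cycle duration is a free knob
#' (`cycle_cv`), 5% by default.
#'
#' @param activity named list of periodic waveforms (functions of phase)
#'   for `protein`, `lipid`, `polysacch`.
#' @param cycle_min mean cell-cycle duration (min).
#' @param cycle_cv coefficient of variation of per-cycle duration.
#' @param start_min early-G1 duration, ME to START, in a mature cell (min).
#' @param bud_frac,karyo_frac relative timing of budding and karyokinesis.
#' @param maturation_halftime fluorophore maturation half-time (min);
#'   `0` means instantaneous maturation.
#' @param rate_scale per-process conversion of activity to mass rate
#'   (pg/min per activity unit), named as `activity`.
#' @param noise_frac additive Gaussian channel noise, as a fraction of the
#'   channel mean.
#' @param radii_sdlog lognormal sd applied multiplicatively to radii.
#' @param perturbation_gain NAD(P)H derivative jump per unit activity
#'   (fluorescence/min).
#' @param nadph_baseline periodic function of phase: the unperturbed
#'   NAD(P)H oscillation (fluorescence units around `nadph_level`).
#' @param nadph_level,nadph_amplitude level and amplitude scaling of the
#'   NAD(P)H channel.
#' @param density_pg_fl density of newly made biomass (pg/fl) used to
#'   translate mass gain into volume growth.
#' @param seed integer seed.
#' @return object of class `cycleflux_truth`.
#' @export
ground_truth <- function(activity = list(protein = two_peak_waveform(),
                                         lipid = one_peak_waveform(),
                                         polysacch = one_peak_waveform()),
                         cycle_min = 100, cycle_cv = 0.05,
                         start_min = 11, bud_frac = 0.33,
                         karyo_frac = 0.85,
                         maturation_halftime = 6,
                         rate_scale = c(protein = 0.30, lipid = 0.06,
                                        polysacch = 0.06),
                         noise_frac = 0.02, radii_sdlog = 0.01,
                         perturbation_gain = 1,
                         nadph_baseline = periodic_spline_waveform(),
                         nadph_level = 100, nadph_amplitude = 8,
                         density_pg_fl = 1.1,
                         seed = 1L) {
  for (nm in names(activity)) assert_periodic(activity[[nm]], nm)
  assert_periodic(nadph_baseline, "nadph_baseline")
  if (maturation_halftime < 0) cf_stop("maturation halftime must be >= 0")
  stopifnot(cycle_min > 0, start_min > 0, bud_frac > start_min / cycle_min,
            karyo_frac > bud_frac, karyo_frac < 1)
  structure(list(activity = activity, cycle_min = cycle_min,
                 cycle_cv = cycle_cv, start_min = start_min,
                 bud_frac = bud_frac, karyo_frac = karyo_frac,
                 maturation_halftime = maturation_halftime,
                 rate_scale = rate_scale, noise_frac = noise_frac,
                 radii_sdlog = radii_sdlog,
                 perturbation_gain = perturbation_gain,
                 nadph_baseline = nadph_baseline,
                 nadph_level = nadph_level,
                 nadph_amplitude = nadph_amplitude,
                 density_pg_fl = density_pg_fl,
                 seed = as.integer(seed)),
            class = "cycleflux_truth")
}

#' @export
print.cycleflux_truth <- function(x, ...) {
  cat("<ground truth> cycle", x$cycle_min, "min, maturation t1/2",
      x$maturation_halftime, "min, seed", x$seed, "\n")
  invisible(x)
}

# draw one cell's event schedule: list of cycles with ME/START/BUD/KARYO
draw_schedule <- function(truth, n_cycles, t0 = 0) {
  sdlog <- sqrt(log(1 + truth$cycle_cv^2))
  durations <- stats::rlnorm(n_cycles, log(truth$cycle_min) - sdlog^2 / 2,
                             sdlog)
  me <- t0 + c(0, cumsum(durations))
  data.frame(cycle = seq_len(n_cycles),
             ME = me[-length(me)],
             START = me[-length(me)] +
               truth$start_min * durations / truth$cycle_min,
             BUD = me[-length(me)] + truth$bud_frac * durations,
             KARYO = me[-length(me)] + truth$karyo_frac * durations,
             next_ME = me[-1])
}

# true phase (generator convention: linear in time within a cycle)
schedule_phase <- function(sched, t) {
  i <- findInterval(t, sched$ME, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(sched))
  (t - sched$ME[i]) / (sched$next_ME[i] - sched$ME[i])
}

#' Simulate a population of single-cell traces with known ground truth
#'
#' Forward-simulates reporter fluorescence, mother/bud geometry and
#' component mass accumulation for `n_cells` cells over `n_cycles` cycles
#' each, on a regular `dt` grid. The reporter obeys first-order
#' maturation, \eqn{dA_{imm}/dt = r(t) - (\ln 2 / t_{1/2}) A_{imm}},
#' with fluorescence proportional to the mature pool; volume growth
#' integrates the mass waveforms (divided by density), directed to the
#' mother before budding and to the bud afterwards; radii follow from
#' prolate-spheroid geometry at a fixed aspect ratio before multiplicative
#' lognormal noise; bud radii are missing (`NA`) for the first
#' `bud_blind_frames` frames after budding.
#'
#' @param truth a [ground_truth()] object.
#' @param n_cells,n_cycles population size and cycles per cell.
#' @param dt imaging cadence (min), default 6.
#' @param bud_blind_frames frames after budding with unmeasurable bud.
#' @param aspect fixed major/minor radius ratio of the spheroids.
#' @param v0_fl newborn mother volume (fl).
#' @param fine_dt internal integration step (min).
#' @param seed seed; defaults to `truth$seed`.
#' @return list with `traces` (long data.frame: `cell_id`, `time_min`,
#'   `gfp`, `R_major_um`, `r_minor_um`, `bud_R_major_um`,
#'   `bud_r_minor_um`), `events` (`cell_id`, `event`, `time_min`),
#'   `truth_rates` (per cell/time: true production rate and phase) and
#'   `truth_masses` (per-component mass gain per cycle, for conservation
#'   checks).
#' @export
simulate_population <- function(truth, n_cells, n_cycles, dt = 6,
                                bud_blind_frames = 3L, aspect = 1.25,
                                v0_fl = 30, fine_dt = 0.05,
                                seed = truth$seed) {
  if (dt <= 0 || fine_dt <= 0) cf_stop("time steps must be positive")
  if (n_cells < 1) cf_stop("need at least one cell")
  set.seed(seed)
  k_mat <- if (truth$maturation_halftime > 0)
    log(2) / truth$maturation_halftime else Inf
  traces <- vector("list", n_cells)
  events <- vector("list", n_cells)
  rates <- vector("list", n_cells)
  massrec <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    sched <- draw_schedule(truth, n_cycles)
    t_end <- max(sched$next_ME)
    tf <- seq(0, t_end, by = fine_dt)
    phi <- schedule_phase(sched, tf)
    # component mass rates (pg/min) on the fine grid
    comp <- names(truth$activity)
    rj <- vapply(comp, function(j)
      truth$rate_scale[[j]] * truth$activity[[j]](phi), numeric(length(tf)))
    mass_gain <- apply(rj, 2, function(v) cumsum(v) * fine_dt)
    # volume: growth = total mass rate / density; mother before BUD,
    # bud afterwards; bud leaves at next ME
    growth <- rowSums(rj) / truth$density_pg_fl
    vol_g <- cumsum(growth) * fine_dt
    v_m <- numeric(length(tf)); v_d <- numeric(length(tf))
    for (cyc in seq_len(nrow(sched))) {
      in_cyc <- tf > sched$ME[cyc] & tf <= sched$next_ME[cyc]
      if (cyc == 1L) in_cyc <- in_cyc | tf == 0
      idx <- which(in_cyc)
      if (length(idx) == 0L) next
      g0 <- vol_g[idx[1L]]
      vm_start <- if (cyc == 1L) v0_fl else v_m[idx[1L] - 1L]
      pre <- tf[idx] <= sched$BUD[cyc]
      g_at_bud <- if (any(!pre)) vol_g[idx[!pre][1L] - 1L] - g0 else
        vol_g[idx[length(idx)]] - g0
      v_m[idx] <- vm_start + pmin(vol_g[idx] - g0, g_at_bud)
      v_d[idx] <- pmax(vol_g[idx] - g0 - g_at_bud, 0)
    }
    # reporter production follows protein activity (arbitrary units);
    # pools partition with the departing daughter at each division so
    # concentration is continuous across cytokinesis
    r_rep <- truth$activity$protein(phi)
    a_imm <- numeric(length(tf)); a_mat <- numeric(length(tf))
    div_idx <- vapply(sched$next_ME[-nrow(sched)], function(tme)
      which(tf > tme)[1L], integer(1))
    decay <- if (is.finite(k_mat)) exp(-k_mat * fine_dt) else 0
    for (i in seq_len(length(tf) - 1L)) {
      if (is.finite(k_mat)) {
        a_imm[i + 1L] <- a_imm[i] * decay +
          r_rep[i] * (1 - decay) / k_mat
        a_mat[i + 1L] <- a_mat[i] + a_imm[i] * (1 - decay) +
          r_rep[i] * (fine_dt - (1 - decay) / k_mat)
      } else {
        a_mat[i + 1L] <- a_mat[i] + r_rep[i] * fine_dt
      }
      if ((i + 1L) %in% div_idx) {
        keep <- v_m[i + 1L] / (v_m[i] + v_d[i])
        a_imm[i + 1L] <- a_imm[i + 1L] * keep
        a_mat[i + 1L] <- a_mat[i + 1L] * keep
      }
    }
    # sample onto the imaging grid
    ts <- seq(0, t_end, by = dt)
    si <- findInterval(ts, tf)
    v_tot <- v_m[si] + v_d[si]
    f_gfp <- a_mat[si] / v_tot
    f_gfp <- f_gfp + stats::rnorm(length(ts), 0,
                                  truth$noise_frac * mean(f_gfp))
    to_radii <- function(v) {
      r <- (3 * v / (4 * pi * aspect))^(1 / 3)
      cbind(R = aspect * r, r = r)
    }
    rad_m <- to_radii(v_m[si]) *
      matrix(stats::rlnorm(2 * length(ts), 0, truth$radii_sdlog), ncol = 2)
    rad_d <- to_radii(v_d[si])
    rad_d[v_d[si] <= 0, ] <- NA
    rad_d <- rad_d *
      matrix(stats::rlnorm(2 * length(ts), 0, truth$radii_sdlog), ncol = 2)
    # bud unmeasurable in the first frames after each budding
    for (cyc in seq_len(nrow(sched))) {
      blind <- which(ts > sched$BUD[cyc] &
                       ts <= sched$BUD[cyc] + bud_blind_frames * dt &
                       ts <= sched$next_ME[cyc])
      rad_d[blind, ] <- NA
    }
    cid <- sprintf("cell%03d", ci)
    traces[[ci]] <- data.frame(cell_id = cid, time_min = ts,
                               gfp = f_gfp,
                               R_major_um = rad_m[, 1],
                               r_minor_um = rad_m[, 2],
                               bud_R_major_um = rad_d[, 1],
                               bud_r_minor_um = rad_d[, 2])
    events[[ci]] <- data.frame(
      cell_id = cid,
      event = rep(c("ME", "START", "BUD", "KARYO"), each = nrow(sched)),
      time_min = c(sched$ME, sched$START, sched$BUD, sched$KARYO))
    rates[[ci]] <- data.frame(cell_id = cid, time_min = ts,
                              rate = r_rep[si],
                              phase = schedule_phase(sched, ts),
                              volume_fl = v_tot,
                              mother_fl = v_m[si], bud_fl = v_d[si])
    gain_per_cycle <- do.call(rbind, lapply(seq_len(nrow(sched)),
      function(cyc) {
        i0 <- max(which(tf <= sched$ME[cyc]))
        i1 <- max(which(tf <= sched$next_ME[cyc]))
        data.frame(cell_id = cid, cycle = cyc,
                   component = colnames(mass_gain),
                   gain_pg = mass_gain[i1, ] - mass_gain[i0, ],
                   integral_pg = vapply(seq_len(ncol(rj)), function(jj)
                     sum(rj[(i0 + 1L):i1, jj]) * fine_dt, numeric(1)))
      }))
    massrec[[ci]] <- gain_per_cycle
  }
  list(traces = do.call(rbind, traces),
       events = do.call(rbind, events),
       truth_rates = do.call(rbind, rates),
       truth_masses = do.call(rbind, massrec),
       dt = dt)
}
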