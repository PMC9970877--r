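# Shared fixtures: run the reporter pipeline over a simulated population
# and pool per-cycle rates by phase (the input of the GP summary).
pool_population_rates <- function(pop, cycles = 1:2) {
  phases <- c(); rates <- c()
  for (cid in unique(pop$traces$cell_id)) {
    tr <- pop$traces[pop$traces$cell_id == cid, ]
    ev <- pop$events[pop$events$cell_id == cid, ]
    for (cyc in cycles) {
      rec <- suppressWarnings(
        reporter_production_cycle(tr, ev, cycle = cyc))
      phases <- c(phases, rec$phase_lin)
      rates <- c(rates, rec$rate)
    }
  }
  data.frame(phase = phases, rate = rates)
}

# Savitzky-Golay read-out attenuation of a derivative ramp starting one
# frame before the read point (first principles: apply the filter's
# central coefficients to the ideal ramp).
savgol_ramp_attenuation <- function(window = 7L, polyorder = 3L) {
  half <- (window - 1L) %/% 2L
  co <- signal::sgolay(p = polyorder, n = window)[half + 1L, ]
  ramp <- function(k) pmax(0, k + 1)   # slope 1, onset at k = -1
  s_at <- function(k0) sum(co * ramp(k0 + (-half:half)))
  s_at(0) - s_at(-1)                   # midpoint derivative estimate
}

# brute-force reference for time_to_phase: explicit per-segment search
brute_time_to_phase <- function(t, te, pe) {
  vapply(t, function(tt) {
    for (i in 1:3) {
      if (tt >= te[i] && tt <= te[i + 1]) {
        return((pe[i + 1] - pe[i]) * (tt - te[i]) /
                 (te[i + 1] - te[i]) + pe[i])
      }
    }
    NA_real_
  }, numeric(1))
}
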