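# Algebraic cell-mass model: converts dimensionless biosynthetic
# activities into absolute rates (pg/min) by fitting the implied
# cell-mass trajectory to empirical mass (volume x density).
#
# Model structure (one cell cycle, ME at t = 0, next ME at t = T):
#   * protein/lipid/polysaccharide rates: r_j = k_j * (a_j(t) + b_j),
#     conversion factor k_j >= 0, vertical translation b_j bounded by the
#     activity uncertainty, clipped at zero (clipping is flagged);
#   * DNA: constant rate between budding and karyokinesis summing to
#     dM_DNA, zero elsewhere;
#   * RNA = rRNA + non-rRNA; non-rRNA constant; rRNA proportional to the
#     protein rate from `rrna_lead_min` before ME through budding
#     (gamma * r_protein), held at its budding value until karyokinesis
#     (continuity), zero otherwise;
#   * masses: M_j(t) = M_j(0) + integral of r_j (trapezoid), with initial
#     masses closed by division periodicity M_j(0) = f_j * M_j(T)
#     (f = mother volume fraction for protein/RNA, mother surface
#     fraction for lipid/polysaccharide; DNA keeps one genome copy);
#   * estimate(t) = sum_j M_j(t) (1 + h_j) + w * V(t): hydration shells
#     h_j (config, literature-window stand-ins) and free water plus
#     metabolites scaling with total volume.

#' Default configuration of the cell-mass model
#'
#' Hydration-shell fractions, the genome mass, the rRNA coupling lead and
#' the water-coefficient bounds are configuration, not fitted constants;
#' the defaults are literature-scale values meant to be overridden per
#' dataset.
#'
#' @param hydration named hydration-shell mass fractions per component.
#' @param dna_initial_pg mass of one genome copy (pg).
#' @param rrna_lead_min minutes before mitotic exit at which the
#'   rRNA/protein-rate coupling begins (default 15).
#' @param water_bounds bounds of the free-water + metabolite coefficient
#'   (pg per fl of cell volume).
#' @param composition_windows optional named list of `c(lo, hi)` windows
#'   for the cycle-average dry-mass fraction of components.
#' @return list used by the cellmass functions.
#' @export
cellmass_config <- function(hydration = c(protein = 0.30, lipid = 0.10,
                                          polysacch = 0.35, DNA = 0.35,
                                          RNA = 0.35),
                            dna_initial_pg = 0.013,
                            rrna_lead_min = 15,
                            water_bounds = c(0.05, 1.0),
                            composition_windows = NULL) {
  list(hydration = hydration, dna_initial_pg = dna_initial_pg,
       rrna_lead_min = rrna_lead_min, water_bounds = water_bounds,
       composition_windows = composition_windows)
}

#' Component biosynthetic rates from model parameters
#'
#' @param params named list/vector with `k_protein`, `k_lipid`,
#'   `k_polysacch`, `b_protein`, `b_lipid`, `b_polysacch`, `dM_DNA`,
#'   `r_nonrRNA`, `gamma_rRNA`.
#' @param activities named list of data.frames (`time_min`, `mean`) for
#'   protein, lipid, polysacch on a common regular grid spanning the
#'   cycle.
#' @param events named vector `ME`, `START`, `BUD`, `KARYO`, `next_ME`
#'   (min, ME = 0).
#' @param rrna_lead_min lead of the rRNA/protein coupling (min).
#' @return matrix time x component (`protein`, `lipid`, `polysacch`,
#'   `DNA`, `RNA`), pg/min, with attributes `time_min` and `clipped`
#'   (TRUE if zero-clipping was active).
#' @export
component_rates <- function(params, activities, events,
                            rrna_lead_min = 15) {
  p <- as.list(params)
  tt <- activities$protein$time_min
  T_cc <- events[["next_ME"]]
  raw <- cbind(
    protein = p$k_protein * (activities$protein$mean + p$b_protein),
    lipid = p$k_lipid * (activities$lipid$mean + p$b_lipid),
    polysacch = p$k_polysacch * (activities$polysacch$mean + p$b_polysacch))
  clipped <- any(raw < 0)
  raw[raw < 0] <- 0
  dna <- ifelse(tt > events[["BUD"]] & tt <= events[["KARYO"]],
                p$dM_DNA / (events[["KARYO"]] - events[["BUD"]]), 0)
  coupled <- tt <= events[["BUD"]] | tt > T_cc - rrna_lead_min
  plateau_idx <- max(which(tt <= events[["BUD"]]))
  rrna <- numeric(length(tt))
  rrna[coupled] <- p$gamma_rRNA * raw[coupled, "protein"]
  mid <- tt > events[["BUD"]] & tt <= events[["KARYO"]]
  rrna[mid] <- p$gamma_rRNA * raw[plateau_idx, "protein"]
  rna <- rrna + p$r_nonrRNA
  out <- cbind(raw, DNA = dna, RNA = rna)
  attr(out, "time_min") <- tt
  attr(out, "clipped") <- clipped
  out
}

# trapezoid cumulative integral on a regular grid
cumtrapz <- function(t, y) {
  c(0, cumsum((head(y, -1) + tail(y, -1)) / 2 * diff(t)))
}

#' Component mass trajectories and the cell-mass estimate
#'
#' @param rates matrix from [component_rates()].
#' @param split_fractions named vector: `volume` (mother volume fraction
#'   at division, for protein and RNA) and `surface` (mother surface
#'   fraction, for lipid and polysaccharide).
#' @param config a [cellmass_config()] list.
#' @param water_coef free-water + metabolite coefficient (pg/fl).
#' @param volume cell volume V(t) (fl) on the rate grid.
#' @return list with `masses` (matrix time x component, pg), `estimate`
#'   (pg), `initial` (named initial masses).
#' @export
mass_trajectories <- function(rates, split_fractions, config,
                              water_coef, volume) {
  tt <- attr(rates, "time_min")
  comp <- colnames(rates)
  f <- c(protein = split_fractions[["volume"]],
         lipid = split_fractions[["surface"]],
         polysacch = split_fractions[["surface"]],
         DNA = NA, RNA = split_fractions[["volume"]])
  gains <- apply(rates, 2, function(r) cumtrapz(tt, r))
  total_gain <- gains[nrow(gains), ]
  m0 <- vapply(comp, function(j) {
    if (j == "DNA") return(config$dna_initial_pg)
    # periodic closure: M(0) = f * M(T) = f * (M(0) + gain)
    f[j] * total_gain[j] / (1 - f[j])
  }, numeric(1))
  masses <- sweep(gains, 2, m0, `+`)
  h <- config$hydration[comp]
  estimate <- as.numeric(masses %*% (1 + h)) + water_coef * volume
  list(masses = masses, estimate = estimate, initial = m0)
}

#' Empirical cell mass from volume and density
#'
#' @param volume_series V(t) in fl.
#' @param density_series density in pg/fl at matching phases.
#' @return mass in pg (pointwise product).
#' @export
empirical_mass <- function(volume_series, density_series) {
  as.numeric(volume_series) * as.numeric(density_series)
}

#' Total biomass production rate and relative contributions
#'
#' \eqn{r_{biomass}(t) = \sum_j r_j(t)} over protein, RNA, lipid,
#' polysaccharide and DNA, and \eqn{c^j(t) = r_j(t)/r_{biomass}(t)}.
#' Contributions sum to 1 wherever the total rate is positive; points
#' with zero total rate are flagged `undefined`.
#'
#' @param rates matrix from [component_rates()].
#' @return list with `r_biomass` (pg/min), `contributions` (matrix,
#'   rows summing to 1), `undefined` (logical).
#' @export
contributions <- function(rates) {
  r_bio <- rowSums(rates)
  undef <- r_bio <= 0
  cc <- sweep(rates, 1, ifelse(undef, NA, r_bio), `/`)
  list(r_biomass = r_bio, contributions = cc, undefined = undef)
}
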