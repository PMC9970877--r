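# Phase-resolved FBA under a Gibbs-energy dissipation cap.
#
# The LP at each cell-cycle phase: maximize the biomass-assembly flux
# subject to steady state (S v = 0), flux bounds, and a linear
# dissipation constraint over the boundary (exchange) reactions,
#   g(v) = sum_i v_i * gamma_i / M_biomass <= g_lim,
# with gamma_i the formation-energy content of what reaction i moves
# across the boundary (fixed external conditions keep this linear; the
# concentration-coupled nonconvex formulation of the source model is out
# of scope). The biomass species' formation energy follows from the
# zero-Gibbs-error convention for the assembly reaction:
# dfG_biomass(t) = sum_j x_j(t) dfG_j.

# bounded-variable LP via boot::simplex (shift x = v - lb >= 0)
solve_lp <- function(obj, A_eq, b_eq, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), all(ub >= lb))
  # conserved moieties make S rank-deficient; keep an independent row set
  # (dropped rows are linear combinations, so S v = 0 still holds fully)
  qrA <- qr(t(A_eq))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  A_eq <- A_eq[keep, , drop = FALSE]
  b_eq <- b_eq[keep]
  shift_b_eq <- b_eq - as.numeric(A_eq %*% lb)
  flip <- shift_b_eq < 0
  A_eq[flip, ] <- -A_eq[flip, , drop = FALSE]
  shift_b_eq[flip] <- -shift_b_eq[flip]
  A1 <- diag(n)
  b1 <- ub - lb
  if (!is.null(A_le)) {
    bb <- b_le - as.numeric(A_le %*% lb)
    A1 <- rbind(A1, A_le)
    b1 <- c(b1, bb)
  }
  neg <- b1 < 0
  A2 <- NULL; b2 <- NULL
  if (any(neg)) {
    A2 <- -A1[neg, , drop = FALSE]; b2 <- -b1[neg]
    A1 <- A1[!neg, , drop = FALSE]; b1 <- b1[!neg]
  }
  s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = A_eq, b3 = shift_b_eq, maxi = maximize,
                     n.iter = 50 * (n + nrow(A_eq) + length(b1)),
                     eps = 1e-10)
  status <- unname(c("-1" = "infeasible", "0" = "iteration-limit",
                     "1" = "optimal")[as.character(s$solved)])
  v <- as.numeric(s$soln) + lb
  list(v = stats::setNames(v, names(lb)),
       objective = sum(obj * v), status = status)
}

#' Phase-dependent biomass stoichiometry from relative contributions
#'
#' Converts the cell-mass model's relative contributions \eqn{c^j(t)}
#' into per-phase multipliers \eqn{c^j(t)/c_{model}^j} of the model's
#' reference biomass stoichiometry, with the storage coefficient fixed
#' to zero throughout (no storage turnover under high glucose).
#'
#' @param contrib matrix phases x components of relative contributions
#'   (rows summing to 1 over protein, lipid, polysacch, DNA, RNA).
#' @param c_model named reference mass fractions of the network.
#' @return matrix phases x components of multipliers, including a zero
#'   `storage` column.
#' @export
phase_biomass_coefficients <- function(contrib, c_model) {
  comp <- colnames(contrib)
  if (!all(comp %in% names(c_model)))
    cf_stop("contribution components missing from c_model")
  out <- sweep(contrib, 2, c_model[comp], `/`)
  out <- cbind(out, storage = 0)
  out
}

# assemble the full S matrix with the phase's biomass column
fba_matrices <- function(network, multipliers) {
  sp <- network$species
  comp <- names(network$c_model)
  x_base <- network$c_model * network$M_biomass /
    stats::setNames(sp$mass_g_mmol[match(comp, sp$id)], comp)
  x <- x_base * multipliers[comp]
  S <- cbind(network$S, BIOMASS = 0)
  S[comp, "BIOMASS"] <- -x
  S["biomass", "BIOMASS"] <- 1
  dfG <- stats::setNames(sp$dfG, sp$id)
  dfG["biomass"] <- sum(x * dfG[comp])
  carbon <- stats::setNames(sp$carbon, sp$id)
  carbon["biomass"] <- sum(x * carbon[comp])
  lb <- c(network$lb, BIOMASS = 0)
  ub <- c(network$ub, BIOMASS = 1000)
  boundary <- c(network$boundary, FALSE)
  gamma <- as.numeric(t(S) %*% ifelse(is.na(dfG), 0, dfG))
  gamma[!boundary] <- 0
  list(S = S, lb = lb, ub = ub, gamma = gamma, dfG = dfG,
       carbon = carbon, x = x, boundary = boundary)
}

#' Solve one phase's dissipation-constrained FBA
#'
#' Maximizes the biomass-assembly flux subject to steady state, bounds
#' and the Gibbs-dissipation cap. Glucose is the sole carbon and energy
#' source (the shipped network admits no other).
#'
#' @param network a `cycleflux_network`.
#' @param multipliers named per-component multipliers of the reference
#'   biomass stoichiometry (one row of [phase_biomass_coefficients()]).
#' @param g_lim dissipation cap (J/gDW/h); default the network's.
#'   `Inf` disables the constraint (plain FBA).
#' @return object of class `cycleflux_fba`: `fluxes`
#'   (mmol (mmol biomass)^-1 h^-1, `BIOMASS` included), `v_biomass`
#'   (1/h), `dissipation` (J/gDW/h), `status`, `binding` (is the cap
#'   active), `matrices` (for downstream bookkeeping).
#' @export
solve_phase_fba <- function(network, multipliers,
                            g_lim = network$g_lim) {
  m <- fba_matrices(network, multipliers)
  obj <- stats::setNames(as.numeric(colnames(m$S) == "BIOMASS"),
                         colnames(m$S))
  A_le <- NULL; b_le <- NULL
  if (is.finite(g_lim)) {
    A_le <- matrix(m$gamma / network$M_biomass, 1)
    b_le <- g_lim
  }
  sol <- solve_lp(obj, A_eq = m$S, b_eq = rep(0, nrow(m$S)),
                  A_le = A_le, b_le = b_le, lb = m$lb, ub = m$ub)
  if (sol$status != "optimal") {
    return(structure(list(fluxes = sol$v, v_biomass = NA_real_,
                          dissipation = NA_real_, status = sol$status,
                          binding = NA, matrices = m),
                     class = "cycleflux_fba"))
  }
  diss <- sum(sol$v * m$gamma) / network$M_biomass
  structure(list(fluxes = sol$v, v_biomass = sol$v[["BIOMASS"]],
                 dissipation = diss, status = sol$status,
                 binding = is.finite(g_lim) && diss > g_lim - 1e-6,
                 g_lim = g_lim, matrices = m),
            class = "cycleflux_fba")
}

#' @export
print.cycleflux_fba <- function(x, ...) {
  cat("<FBA solution>", x$status, "; v_biomass =",
      signif(x$v_biomass, 5), "/h; dissipation =",
      signif(x$dissipation, 5), "J/gDW/h",
      if (isTRUE(x$binding)) "(cap binding)" else "", "\n")
  invisible(x)
}

#' Translate FBA flux units into absolute per-cell fluxes
#'
#' \deqn{v^{cell}_i = 10^{-3} \frac{v^{FBA}_i}{v^{FBA}_{biomass}}
#'   \frac{1}{M_{biomass}} r_{biomass},}
#' converting mmol (mmol biomass)^-1 h^-1 into pmol cell^-1 h^-1 using
#' the total biomass synthesis rate of the cell-mass model. By
#' construction the biomass reaction's own absolute flux equals
#' \eqn{r_{biomass} / (1000 M_{biomass})} identically.
#'
#' @param v_fba flux vector (mmol (mmol biomass)^-1 h^-1).
#' @param v_biomass_fba biomass flux (1/h), > 0.
#' @param M_biomass biomass molar mass (g/mmol).
#' @param r_biomass total biomass synthesis rate (pg cell^-1 h^-1).
#' @return fluxes in pmol cell^-1 h^-1.
#' @export
convert_flux_units <- function(v_fba, v_biomass_fba, M_biomass,
                               r_biomass) {
  if (!is.finite(v_biomass_fba) || v_biomass_fba <= 0)
    cf_stop("biomass flux must be positive for unit conversion")
  1e-3 * (v_fba / v_biomass_fba) * (1 / M_biomass) * r_biomass
}

#' Newborn-weighted cell-cycle-average exchange yield
#'
#' Population-level yield of an exchanged metabolite with respect to
#' glucose, weighting early-G1 phases by the newborn/mature early-G1
#' duration ratio (newborns dominate an exponentially growing culture
#' and dwell long between ME and START):
#' \deqn{Y = \frac{\sum_t v_{met}(t) M_{met} \varphi^P(t)}
#'   {-\sum_t v_{glc}(t) M_{glc} \varphi^P(t)}.}
#' Default weights: 79.75/11 at t in \{3, 9\} min, 1 elsewhere.
#'
#' @param v_met,v_glc per-phase absolute fluxes (pmol cell^-1 h^-1);
#'   uptakes negative.
#' @param M_met,M_glc molar masses (any common unit).
#' @param phases phase times (min).
#' @param phase_weights weights \eqn{\varphi^P(t)}; `NULL` gives the
#'   defaults.
#' @param early_g1 list with `newborn_min` (79.75), `mature_min` (11)
#'   and `phases` (c(3, 9)) used to build default weights.
#' @return the yield (g per g glucose).
#' @export
newborn_weighted_yield <- function(v_met, v_glc, M_met, M_glc, phases,
                                   phase_weights = NULL,
                                   early_g1 = list(newborn_min = 79.75,
                                                   mature_min = 11,
                                                   phases = c(3, 9))) {
  if (is.null(phase_weights)) {
    phase_weights <- rep(1, length(phases))
    phase_weights[phases %in% early_g1$phases] <-
      early_g1$newborn_min / early_g1$mature_min
  }
  if (all(v_glc >= 0)) cf_stop("glucose uptake must be negative somewhere")
  sum(v_met * M_met * phase_weights) /
    (-sum(v_glc * M_glc * phase_weights))
}

#' Metabolite turnover and per-reaction fluxes
#'
#' Turnover of a metabolite is the summed production,
#' \eqn{\sum_i S_{i,met} v_i} over reactions with
#' \eqn{S_{i,met} v_i > 0}; at steady state this equals the summed
#' consumption with opposite sign.
#'
#' @param solution a `cycleflux_fba` (solved).
#' @param met species id.
#' @param producer_threshold report reactions whose absolute metabolite
#'   flux exceeds this (same units as `v`).
#' @return list with `turnover`, `per_reaction` (named
#'   \eqn{S_{i,met} v_i}), `reported` (ids above threshold).
#' @export
flux_aggregates <- function(solution, met, producer_threshold = 0.09) {
  S <- solution$matrices$S
  if (!met %in% rownames(S)) cf_stop("unknown metabolite")
  per <- S[met, ] * solution$fluxes
  list(turnover = sum(per[per > 0]),
       per_reaction = per,
       reported = names(per)[abs(per) > producer_threshold])
}

#' Summed sink flux of a precursor into a reaction subset
#'
#' @param solution a `cycleflux_fba`.
#' @param met precursor species id.
#' @param reactions character vector of reaction ids (the biosynthetic
#'   sinks of interest).
#' @return summed \eqn{S_{i,met} v_i} over the subset (negative =
#'   net consumption by the subset).
#' @export
precursor_sink <- function(solution, met, reactions) {
  S <- solution$matrices$S
  if (!met %in% rownames(S)) cf_stop("unknown metabolite")
  if (!all(reactions %in% colnames(S))) cf_stop("unknown reaction id")
  sum(S[met, reactions] * solution$fluxes[reactions])
}

#' Carbon closure across the boundary of a solved phase
#'
#' @param solution a `cycleflux_fba`.
#' @return net carbon flux across boundary reactions (should be 0 at
#'   steady state up to numerical tolerance).
#' @export
carbon_closure <- function(solution) {
  m <- solution$matrices
  idx <- which(m$boundary)
  sum(vapply(idx, function(i)
    solution$fluxes[i] * sum(m$S[, i] * m$carbon), numeric(1)))
}

#' Run phase-resolved FBA over the whole cell cycle
#'
#' Solves one dissipation-capped LP per phase (default the 17 moments
#' t = 3, 9, ..., 99 min) with the biomass stoichiometry rescaled by the
#' cell-mass model's relative contributions, then converts fluxes to
#' absolute units with the total biomass synthesis rate.
#'
#' @param network a `cycleflux_network`.
#' @param contrib matrix phases x components (relative contributions).
#' @param r_biomass per-phase total biomass synthesis rate
#'   (pg cell^-1 h^-1).
#' @param phases phase times (min); default `seq(3, 99, by = 6)`.
#' @param g_lim dissipation cap override.
#' @return list with `solutions` (per phase), `fluxes_fba` and
#'   `fluxes_cell` (matrices phase x reaction), `v_biomass`,
#'   `dissipation`, `phases`.
#' @export
run_cycle_fba <- function(network, contrib, r_biomass,
                          phases = seq(3, 99, by = 6),
                          g_lim = network$g_lim) {
  stopifnot(nrow(contrib) == length(phases),
            length(r_biomass) == length(phases))
  mult <- phase_biomass_coefficients(contrib, network$c_model)
  sols <- lapply(seq_along(phases), function(i)
    solve_phase_fba(network, mult[i, ], g_lim))
  vf <- do.call(rbind, lapply(sols, `[[`, "fluxes"))
  vc <- do.call(rbind, lapply(seq_along(sols), function(i)
    convert_flux_units(sols[[i]]$fluxes, sols[[i]]$v_biomass,
                       network$M_biomass, r_biomass[i])))
  rownames(vf) <- rownames(vc) <- phases
  list(solutions = sols, fluxes_fba = vf, fluxes_cell = vc,
       v_biomass = vapply(sols, `[[`, numeric(1), "v_biomass"),
       dissipation = vapply(sols, `[[`, numeric(1), "dissipation"),
       phases = phases)
}
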