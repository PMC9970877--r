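net <- example_network()
ref_mult <- local({
  m <- setNames(rep(1, length(net$c_model)), names(net$c_model))
  m["storage"] <- 0
  m
})

test_that("network loads, validates carbon balance and rejects bad
          input", {
  expect_s3_class(net, "cycleflux_network")
  expect_equal(net$g_lim, 12.3)
  expect_equal(net$M_biomass, 0.966)
  # tampering with stoichiometry is caught by the carbon audit
  sp <- net$species
  bad_rxn <- list(list(id = "BADGLYC",
                       stoich = c(glc = -1, pyr = 1), lb = 0, ub = 10))
  expect_error(network(sp, bad_rxn,
                       c_model = net$c_model, g_lim = 12.3),
               "carbon-unbalanced")
  expect_error(network(sp, list(list(id = "X", stoich = c(foo = 1),
                                     lb = 0, ub = 1)),
                       net$c_model), "unknown species")
})

test_that("phase biomass coefficients: reference composition gives
          unit multipliers, arithmetic holds, storage is zero", {
  contrib <- matrix(rep(net$c_model[c("protein", "lipid", "polysacch",
                                      "DNA", "RNA")], each = 2),
                    nrow = 2,
                    dimnames = list(NULL, c("protein", "lipid",
                                            "polysacch", "DNA", "RNA")))
  mult <- phase_biomass_coefficients(contrib, net$c_model)
  expect_equal(unname(mult[1, c("protein", "lipid", "polysacch",
                                "DNA", "RNA")]), rep(1, 5))
  expect_equal(unname(mult[, "storage"]), c(0, 0))
  contrib2 <- contrib; contrib2[1, "protein"] <- 0.6
  m2 <- phase_biomass_coefficients(contrib2, c(net$c_model["protein"],
                                               net$c_model))
  expect_equal(unname(m2[1, "protein"]), 0.6 / 0.5)
})

test_that("solved phases satisfy steady state, the dissipation cap and
          carbon closure", {
  sol <- solve_phase_fba(net, ref_mult)
  expect_equal(sol$status, "optimal")
  expect_lt(max(abs(sol$matrices$S %*% sol$fluxes)), 1e-8)
  expect_lte(sol$dissipation, net$g_lim + 1e-6)
  expect_lt(abs(carbon_closure(sol)), 1e-6)
  # sign conventions: uptakes non-positive, excretions non-negative
  expect_lte(sol$fluxes[["EX_glc"]], 0)
  expect_lte(sol$fluxes[["EX_o2"]], 0)
  expect_gte(sol$fluxes[["EX_co2"]], -1e-12)
  expect_gte(sol$fluxes[["EX_etoh"]], -1e-12)
})

test_that("optimal biomass flux is nondecreasing in the dissipation cap
          and slack-cap solutions equal plain FBA", {
  caps <- c(5, 12.3, 50, 200, 1000, 1e5)
  vb <- sapply(caps, function(g)
    solve_phase_fba(net, ref_mult, g_lim = g)$v_biomass)
  expect_true(all(diff(vb) >= -1e-9))
  plain <- solve_phase_fba(net, ref_mult, g_lim = Inf)
  slack <- solve_phase_fba(net, ref_mult, g_lim = 1e7)
  expect_equal(slack$v_biomass, plain$v_biomass, tolerance = 1e-8)
  expect_false(slack$binding)
  # a zero-ish cap cannot sustain the ATP maintenance demand
  starved <- solve_phase_fba(net, ref_mult, g_lim = 0.01)
  expect_true(starved$status != "optimal" ||
                starved$v_biomass < 1e-9)
})

test_that("composition shifts steer oxygen demand in the direction of
          the components' energy costs", {
  # derive the expected direction from the stoichiometry itself: the
  # ATP-equivalent cost of assembling one biomass unit (ATP consumed
  # plus NADH consumed, valued at the respiratory-chain ATP yield).
  # The costlier composition must demand more oxygen per biomass under
  # the same network.
  energy_cost <- function(mult) {
    m <- cycleflux:::fba_matrices(net, mult)
    syn <- c(protein = "PROT_SYN", lipid = "LIP_SYN",
             polysacch = "POLY_SYN", RNA = "RNA_SYN", DNA = "DNA_SYN")
    po <- m$S["atp", "ETC"]  # ATP produced per NADH in the chain
    sum(vapply(names(syn), function(j)
      m$x[[j]] * (-m$S["atp", syn[j]] - po * min(m$S["nadh", syn[j]], 0)),
      numeric(1)))
  }
  lipid_heavy <- ref_mult; protein_heavy <- ref_mult
  lipid_heavy["lipid"] <- 3; lipid_heavy["protein"] <- 0.68
  protein_heavy["lipid"] <- 0.2; protein_heavy["protein"] <- 1.13
  costlier_is_lipid <- energy_cost(lipid_heavy) >
    energy_cost(protein_heavy)
  o2_per_bio <- function(mult) {
    s <- solve_phase_fba(net, mult)
    -s$fluxes[["EX_o2"]] / s$v_biomass
  }
  diff_o2 <- o2_per_bio(lipid_heavy) - o2_per_bio(protein_heavy)
  expect_true(if (costlier_is_lipid) diff_o2 > 0 else diff_o2 < 0)
})

test_that("unit conversion implements the printed formula and its
          biomass identity", {
  expect_equal(convert_flux_units(1, 1, 0.966, 9.66), 0.01)
  set.seed(3)
  v <- rnorm(10); vb <- 0.4; r <- 12
  got <- convert_flux_units(v, vb, 0.966, r)
  expect_equal(got, 1e-3 * (v / vb) / 0.966 * r, tolerance = 1e-14)
  # biomass reaction's own absolute flux identity
  expect_equal(convert_flux_units(vb, vb, 0.966, r),
               r / (1000 * 0.966))
  # doubling r_biomass doubles every absolute flux
  expect_equal(convert_flux_units(v, vb, 0.966, 2 * r), 2 * got)
  expect_error(convert_flux_units(1, 0, 0.966, 1), "positive")
})

test_that("newborn-weighted yields: weights cancel for constant fluxes,
          glucose self-yield is -1, toy case matches hand computation", {
  phases <- seq(3, 99, by = 6)
  y_const <- newborn_weighted_yield(rep(2, 17), rep(-4, 17), 46, 180,
                                    phases)
  expect_equal(y_const, 2 * 46 / (4 * 180), tolerance = 1e-12)
  y_unw <- newborn_weighted_yield(rep(2, 17), rep(-4, 17), 46, 180,
                                  phases,
                                  phase_weights = rep(1, 17))
  expect_equal(y_const, y_unw, tolerance = 1e-12)
  y_self <- newborn_weighted_yield(rep(-4, 17), rep(-4, 17), 180, 180,
                                   phases)
  expect_equal(y_self, -1)
  # two-phase toy with unequal fluxes against a hand-computed ratio
  w <- c(79.75 / 11, 1)
  y_toy <- newborn_weighted_yield(c(1, 3), c(-2, -5), 46, 180,
                                  phases = c(3, 15))
  expect_equal(y_toy,
               (1 * 46 * w[1] + 3 * 46 * w[2]) /
                 (2 * 180 * w[1] + 5 * 180 * w[2]), tolerance = 1e-12)
  expect_error(newborn_weighted_yield(1, 2, 1, 1, 3), "negative")
})

test_that("ATP turnover balances producers against consumers and
          precursor sinks match the matrix product", {
  sol <- solve_phase_fba(net, ref_mult)
  agg <- flux_aggregates(sol, "atp", producer_threshold = 0.001)
  per <- agg$per_reaction
  expect_equal(sum(per[per > 0]), -sum(per[per < 0]), tolerance = 1e-8)
  expect_equal(agg$turnover, sum(per[per > 0]))
  # direct matrix-product oracle for a precursor sink
  sink <- precursor_sink(sol, "pyr", c("PROT_SYN", "LIP_SYN"))
  oracle <- sum(sol$matrices$S["pyr", c("PROT_SYN", "LIP_SYN")] *
                  sol$fluxes[c("PROT_SYN", "LIP_SYN")])
  expect_equal(sink, oracle, tolerance = 1e-12)
  expect_error(precursor_sink(sol, "nope", "PROT_SYN"), "unknown")
})

test_that("run_cycle_fba solves all 17 phases with phase-dependent
          composition and converts units consistently", {
  phases <- seq(3, 99, by = 6)
  wf <- two_peak_waveform()(phases / 100)
  contrib <- cbind(protein = 0.4 + 0.1 * wf / max(wf),
                   lipid = 0.1, polysacch = 0.2, DNA = 0.02,
                   RNA = 0.28 - 0.1 * wf / max(wf))
  contrib <- contrib / rowSums(contrib)
  r_bio <- (8 + 4 * wf) * 60 / 10   # pg/cell/h scale
  out <- run_cycle_fba(net, contrib, r_bio, phases)
  expect_equal(length(out$solutions), 17)
  for (i in c(1, 9, 17)) {
    s <- out$solutions[[i]]
    expect_equal(s$status, "optimal")
    expect_lt(max(abs(s$matrices$S %*% s$fluxes)), 1e-8)
    expect_lte(s$dissipation, net$g_lim + 1e-6)
  }
  expect_equal(unname(out$fluxes_cell[, "BIOMASS"]),
               r_bio / (1000 * net$M_biomass), tolerance = 1e-10)
})
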