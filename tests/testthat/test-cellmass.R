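base_ds <- simulate_mass_dataset(seed = 1, param_jitter = 0)

test_that("component rates follow the stated piecewise rules", {
  p <- base_ds$true_params
  rates <- component_rates(p, base_ds$activities, base_ds$events)
  tt <- attr(rates, "time_min")
  ev <- base_ds$events
  # DNA zero outside (BUD, KARYO], constant inside, integrating to dM
  outside <- tt <= ev[["BUD"]] | tt > ev[["KARYO"]]
  expect_true(all(rates[outside, "DNA"] == 0))
  inside <- !outside
  expect_equal(unique(rates[inside, "DNA"]),
               p[["dM_DNA"]] / (ev[["KARYO"]] - ev[["BUD"]]))
  # protein: k * (a + b)
  expect_equal(rates[, "protein"],
               p[["k_protein"]] * (base_ds$activities$protein$mean +
                                     p[["b_protein"]]))
  # rRNA coupling: doubling k_protein doubles the coupled rRNA part
  p2 <- p; p2[["k_protein"]] <- 2 * p[["k_protein"]]
  r2 <- component_rates(p2, base_ds$activities, base_ds$events)
  coupled <- tt <= ev[["BUD"]]
  expect_equal(r2[coupled, "RNA"] - p[["r_nonrRNA"]],
               2 * (rates[coupled, "RNA"] - p[["r_nonrRNA"]]),
               tolerance = 1e-12)
})

test_that("mass trajectories: zero rates stay constant, constant rates
          integrate exactly, smooth rates match fine quadrature", {
  ev <- base_ds$events
  tt <- base_ds$activities$protein$time_min
  zero <- component_rates(
    c(k_protein = 0, k_lipid = 0, k_polysacch = 0, b_protein = 0,
      b_lipid = 0, b_polysacch = 0, dM_DNA = 0, r_nonrRNA = 0,
      gamma_rRNA = 0),
    base_ds$activities, ev)
  mt0 <- mass_trajectories(zero, base_ds$split_fractions,
                           base_ds$config, 0, base_ds$volume)
  for (j in colnames(mt0$masses))
    expect_equal(diff(range(mt0$masses[, j])), 0)
  # constant-rate gain is exact under the trapezoid rule
  const <- zero; const[, "protein"] <- 0.2
  mtc <- mass_trajectories(const, base_ds$split_fractions,
                           base_ds$config, 0, base_ds$volume)
  expect_equal(unname(mtc$masses[nrow(mtc$masses), "protein"] -
                        mtc$masses[1, "protein"]),
               0.2 * diff(range(tt)), tolerance = 1e-12)
  # smooth waveform vs 0.01-min quadrature oracle
  rates <- component_rates(base_ds$true_params, base_ds$activities, ev)
  mt <- mass_trajectories(rates, base_ds$split_fractions,
                          base_ds$config,
                          base_ds$true_params[["water"]],
                          base_ds$volume)
  wf <- two_peak_waveform()
  fine <- seq(0, 100, by = 0.01)
  p <- base_ds$true_params
  r_fine <- p[["k_protein"]] * (wf(fine / 100) + p[["b_protein"]])
  oracle_gain <- sum((head(r_fine, -1) + tail(r_fine, -1)) / 2) * 0.01
  got_gain <- unname(mt$masses[nrow(mt$masses), "protein"] -
                       mt$masses[1, "protein"])
  expect_equal(got_gain, oracle_gain, tolerance = 0.001 * oracle_gain)
})

test_that("empirical mass is the pointwise volume-density product", {
  expect_equal(empirical_mass(100, 1.1), 110)
  v <- c(40, 50, 60); rho <- c(1.1, 1.05, 1.12)
  expect_equal(empirical_mass(v, rho), v * rho)
})

test_that("mass balance closes over the cycle", {
  rates <- component_rates(base_ds$true_params, base_ds$activities,
                           base_ds$events)
  mt <- mass_trajectories(rates, base_ds$split_fractions,
                          base_ds$config,
                          base_ds$true_params[["water"]],
                          base_ds$volume)
  tt <- attr(rates, "time_min")
  h <- base_ds$config$hydration[colnames(rates)]
  lhs <- mt$estimate[length(tt)] - mt$estimate[1]
  integrals <- apply(rates, 2, function(r)
    sum((head(r, -1) + tail(r, -1)) / 2 * diff(tt)))
  rhs <- sum((1 + h) * integrals) +
    base_ds$true_params[["water"]] * diff(range(base_ds$volume))
  expect_equal(lhs, rhs, tolerance = 1e-8 * abs(rhs))
})

test_that("contributions sum to one wherever total rate is positive and
          scaling the empirical mass scales the linear parameters", {
  fit <- fit_mass_model(base_ds$activities, base_ds$volume,
                        base_ds$density, base_ds$events,
                        base_ds$split_fractions, base_ds$config,
                        n_starts = 4, seed = 1)
  ct <- fit$contributions
  sums <- rowSums(ct$contributions[!ct$undefined, , drop = FALSE])
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  expect_equal(as.numeric(ct$r_biomass), rowSums(fit$rates))
  # homogeneity: x2 empirical mass -> x2 k_j and water (bounds widened
  # so the doubled water coefficient stays interior)
  cfg2 <- cellmass_config(water_bounds = c(0.05, 2.5))
  fit2 <- fit_mass_model(base_ds$activities, base_ds$volume,
                         2 * base_ds$density, base_ds$events,
                         base_ds$split_fractions, cfg2,
                         n_starts = 4, seed = 1)
  for (nm in c("k_protein", "k_lipid", "k_polysacch", "water"))
    expect_equal(fit2$parameters[[nm]], 2 * fit$parameters[[nm]],
                 tolerance = 0.05)
})

test_that("replicate ensemble band contains the averaged-input
          solution", {
  mk_rep <- function(seed) {
    set.seed(seed)
    lapply(base_ds$activities, function(a) {
      # replicates differ in shape, not only scale
      a$mean <- a$mean + 0.05 * sin(2 * pi * a$time_min / 100 +
                                      runif(1, 0, 2 * pi))
      a
    })
  }
  r1 <- mk_rep(101); r2 <- mk_rep(202)
  reps <- list(protein = list(r1$protein, r2$protein),
               lipid = list(r1$lipid, r2$lipid),
               polysacch = list(r1$polysacch, r2$polysacch))
  ens <- fit_mass_model_ensemble(reps, base_ds$volume, base_ds$density,
                                 base_ds$events,
                                 base_ds$split_fractions,
                                 base_ds$config, n_starts = 3, seed = 1)
  expect_length(ens$fits, 8)
  tol <- 0.05 * max(ens$band$rate_max)
  inside <- ens$averaged$rates >= ens$band$rate_min - tol &
    ens$averaged$rates <= ens$band$rate_max + tol
  expect_gt(mean(inside), 0.9)
})
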