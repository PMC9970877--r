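#' Fit the cell-mass model to empirical mass dynamics
#'
#' Finds conversion factors and the remaining rate parameters by
#' minimizing the sum of squared distances between the model's cell-mass
#' estimate and the empirical mass (volume x density) over the cycle,
#' with box bounds on every parameter (vertical translations are bounded
#' by the mean activity uncertainty) and optional cycle-average
#' composition windows enforced by a quadratic penalty whose binding is
#' reported. Multi-start local optimization (L-BFGS-B) with
#' deterministically seeded starts replaces a global solver; what matters
#' downstream is parameter recovery, verified on self-consistent
#' synthetic data.
#'
#' @param activities named list of data.frames (`time_min`, `mean`,
#'   optional `sd`) for `protein`, `lipid`, `polysacch` on the cycle
#'   grid.
#' @param volume V(t) (fl) on the same grid.
#' @param density density (pg/fl) on the same grid.
#' @param events named vector `ME`, `START`, `BUD`, `KARYO`, `next_ME`.
#' @param split_fractions named vector `volume`, `surface`: mother
#'   fractions at division.
#' @param config a [cellmass_config()] list.
#' @param n_starts multi-start count (default 20).
#' @param seed seed for start generation.
#' @param fixed named list of parameters to freeze (used by the profile
#'   likelihood).
#' @param free_hydration optionally free the protein hydration fraction
#'   (wide bounds); this deliberately creates a (1 + h) k scale
#'   degeneracy useful for identifiability checks.
#' @param start optional named parameter vector used as an extra
#'   (first) start -- the warm-start channel of the profile likelihood.
#' @return object of class `cycleflux_massfit`: `parameters`,
#'   `objective`, `rates`, `masses`, `estimate`, `empirical`,
#'   `contributions`, `binding_constraints`, `clipped`, plus the inputs
#'   needed for refits.
#' @export
fit_mass_model <- function(activities, volume, density, events,
                           split_fractions, config = cellmass_config(),
                           n_starts = 12L, seed = 1L, fixed = list(),
                           free_hydration = FALSE, start = NULL) {
  tt <- activities$protein$time_min
  stopifnot(length(volume) == length(tt), length(density) == length(tt))
  emp <- empirical_mass(volume, density)
  scale_obj <- sum(emp^2)
  b_bound <- vapply(activities, function(a)
    if (!is.null(a$sd)) mean(a$sd) else 0.1 * diff(range(a$mean)),
    numeric(1))
  # a rate integrated over the cycle cannot exceed the final mass, so
  # 2 * max(emp) / (T * mean activity) generously bounds every k_j
  abar <- mean(vapply(activities, function(a) mean(a$mean), numeric(1)))
  T_cc <- diff(range(tt))
  k_hi <- 2 * max(emp) / (T_cc * max(abar, 1e-12))
  r_hi <- 2 * max(emp) / T_cc
  par_lo <- c(k_protein = 0, k_lipid = 0, k_polysacch = 0,
              b_protein = -b_bound[["protein"]],
              b_lipid = -b_bound[["lipid"]],
              b_polysacch = -b_bound[["polysacch"]],
              dM_DNA = 0, r_nonrRNA = 0, gamma_rRNA = 0,
              water = config$water_bounds[1])
  par_hi <- c(k_protein = k_hi, k_lipid = k_hi, k_polysacch = k_hi,
              b_protein = b_bound[["protein"]],
              b_lipid = b_bound[["lipid"]],
              b_polysacch = b_bound[["polysacch"]],
              dM_DNA = 0.2, r_nonrRNA = r_hi, gamma_rRNA = 1,
              water = config$water_bounds[2])
  if (free_hydration) {
    par_lo <- c(par_lo, h_protein = 0)
    par_hi <- c(par_hi, h_protein = 2)
  }
  for (nm in names(fixed)) {
    if (!nm %in% names(par_lo)) cf_stop(paste("unknown parameter", nm))
    par_lo[nm] <- par_hi[nm] <- fixed[[nm]]
  }
  model_eval <- function(par) {
    cfg <- config
    if (free_hydration) cfg$hydration["protein"] <- par[["h_protein"]]
    rates <- component_rates(par, activities, events,
                             config$rrna_lead_min)
    mt <- mass_trajectories(rates, split_fractions, cfg,
                            par[["water"]], volume)
    list(rates = rates, mt = mt, cfg = cfg)
  }
  penalty <- function(mt) {
    if (is.null(config$composition_windows)) return(list(p = 0, b = character(0)))
    dry <- rowSums(mt$masses)
    p <- 0; binding <- character(0)
    for (nm in names(config$composition_windows)) {
      win <- config$composition_windows[[nm]]
      frac <- mean(mt$masses[, nm] / dry)
      ex <- max(0, win[1] - frac, frac - win[2])
      if (ex > 0) binding <- c(binding, nm)
      p <- p + ex^2
    }
    list(p = p, b = binding)
  }
  obj <- function(par) {
    names(par) <- names(par_lo)
    me <- model_eval(par)
    pen <- penalty(me$mt)
    sum((me$mt$estimate - emp)^2) + 1e4 * scale_obj * pen$p
  }
  set.seed(seed)
  k <- length(par_lo)
  # informed start: the estimate is linear in (k_j, dM_DNA, r_nonrRNA,
  # gamma*k_protein, water) at b_j = 0, so non-negative least squares on
  # the component basis trajectories gives a start already close to the
  # optimum; random starts guard against the NNLS corner cases
  init <- tryCatch(
    mass_fit_init(activities, emp, events, split_fractions, config,
                  volume, par_lo, par_hi, free_hydration),
    error = function(e) NULL)
  warm <- if (!is.null(start))
    matrix(pmin(pmax(start[names(par_lo)], par_lo), par_hi), 1,
           dimnames = list(NULL, names(par_lo)))
  starts <- rbind(warm, init,
                  (par_lo + par_hi) / 2,
                  matrix(stats::runif((n_starts - 1) * k,
                                      rep(par_lo, each = n_starts - 1),
                                      rep(par_hi, each = n_starts - 1)),
                         ncol = k))
  # frozen parameters (profile likelihood) are excluded from the search
  free <- par_hi > par_lo
  full_par <- function(p_free) {
    p <- par_lo
    p[free] <- p_free
    p
  }
  obj_free <- function(p_free) obj(full_par(p_free))
  parscale <- pmax(par_hi[free] - par_lo[free], 1e-6)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, free], obj_free, method = "L-BFGS-B",
                   lower = par_lo[free], upper = par_hi[free],
                   control = list(maxit = if (i <= 3) 150 else 50,
                                  parscale = parscale, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) cf_stop("cell-mass optimization failed from all starts")
  par <- full_par(best$par)
  names(par) <- names(par_lo)
  me <- model_eval(par)
  pen <- penalty(me$mt)
  if (pen$p > 0)
    warning("composition constraint(s) binding at the optimum: ",
            paste(pen$b, collapse = ", "))
  ctr <- contributions(me$rates)
  structure(list(parameters = par, objective = best$value,
                 rates = me$rates, masses = me$mt$masses,
                 estimate = me$mt$estimate, empirical = emp,
                 initial_masses = me$mt$initial,
                 contributions = ctr,
                 binding_constraints = pen$b,
                 clipped = attr(me$rates, "clipped"),
                 inputs = list(activities = activities, volume = volume,
                               density = density, events = events,
                               split_fractions = split_fractions,
                               config = config, n_starts = n_starts,
                               seed = seed,
                               free_hydration = free_hydration),
                 bounds = list(lower = par_lo, upper = par_hi)),
            class = "cycleflux_massfit")
}

# NNLS initialization on the linear parameterization of the estimate
mass_fit_init <- function(activities, emp, events, split_fractions,
                          config, volume, par_lo, par_hi,
                          free_hydration) {
  base_par <- list(k_protein = 1, k_lipid = 0, k_polysacch = 0,
                   b_protein = 0, b_lipid = 0, b_polysacch = 0,
                   dM_DNA = 0, r_nonrRNA = 0, gamma_rRNA = 0)
  traj <- function(par) {
    rates <- component_rates(par, activities, events,
                             config$rrna_lead_min)
    mass_trajectories(rates, split_fractions, config, 0,
                      volume)$estimate
  }
  basis <- cbind(
    k_protein = traj(base_par),
    k_lipid = traj(utils::modifyList(base_par,
                                     list(k_protein = 0, k_lipid = 1))),
    k_polysacch = traj(utils::modifyList(base_par,
                                         list(k_protein = 0,
                                              k_polysacch = 1))),
    dM_DNA = traj(utils::modifyList(base_par,
                                    list(k_protein = 0, dM_DNA = 1))),
    r_nonrRNA = traj(utils::modifyList(base_par,
                                       list(k_protein = 0,
                                            r_nonrRNA = 1))),
    g_rrna = traj(utils::modifyList(base_par, list(gamma_rRNA = 1))) -
      traj(base_par),
    water = volume)
  # plain least squares, clipped into the box (a cheap NNLS stand-in
  # good enough for a start; the polishing step enforces the bounds)
  cc <- tryCatch(stats::coef(stats::lm.fit(basis, emp)),
                 error = function(e) NULL)
  if (is.null(cc) || any(is.na(cc))) return(NULL)
  k_p <- max(cc[["k_protein"]], 1e-6)
  par <- c(k_protein = k_p, k_lipid = max(cc[["k_lipid"]], 0),
           k_polysacch = max(cc[["k_polysacch"]], 0),
           b_protein = 0, b_lipid = 0, b_polysacch = 0,
           dM_DNA = max(cc[["dM_DNA"]], 0),
           r_nonrRNA = max(cc[["r_nonrRNA"]], 0),
           gamma_rRNA = max(cc[["g_rrna"]], 0) / k_p,
           water = cc[["water"]])
  if (free_hydration)
    par <- c(par, h_protein = config$hydration[["protein"]])
  pmin(pmax(par[names(par_lo)], par_lo), par_hi)
}

#' @export
print.cycleflux_massfit <- function(x, ...) {
  cat("<cell-mass fit> objective =", signif(x$objective, 6), "\n")
  print(signif(x$parameters, 4))
  invisible(x)
}

#' Ensemble of cell-mass fits over replicate-activity combinations
#'
#' Refits the model for every combination of replicate activity
#' measurements (plus the averaged-replicates input) and reports the
#' min-max band of each inferred quantity across the ensemble.
#'
#' @param replicates named list (per process) of lists of activity
#'   data.frames (the replicates).
#' @inheritParams fit_mass_model
#' @return list with `fits` (one per combination), `averaged` (fit on
#'   replicate means), `band` (list of min/max matrices for rates and
#'   contributions).
#' @export
fit_mass_model_ensemble <- function(replicates, volume, density, events,
                                    split_fractions,
                                    config = cellmass_config(),
                                    n_starts = 10L, seed = 1L) {
  combos <- expand.grid(lapply(replicates, seq_along))
  fits <- lapply(seq_len(nrow(combos)), function(i) {
    acts <- lapply(names(replicates), function(nm)
      replicates[[nm]][[combos[i, nm]]])
    names(acts) <- names(replicates)
    fit_mass_model(acts, volume, density, events, split_fractions,
                   config, n_starts, seed)
  })
  avg_act <- lapply(replicates, function(reps) {
    m <- rowMeans(sapply(reps, `[[`, "mean"))
    data.frame(time_min = reps[[1]]$time_min, mean = m,
               sd = apply(sapply(reps, `[[`, "mean"), 1, stats::sd))
  })
  averaged <- fit_mass_model(avg_act, volume, density, events,
                             split_fractions, config, n_starts, seed)
  rate_arr <- simplify2array(lapply(fits, `[[`, "rates"))
  band <- list(rate_min = apply(rate_arr, c(1, 2), min),
               rate_max = apply(rate_arr, c(1, 2), max))
  list(fits = fits, averaged = averaged, band = band)
}

#' Profile likelihood of a cell-mass parameter
#'
#' Fixes one parameter at each grid value, re-optimizes all others and
#' records the objective. A parameter is declared identifiable when the
#' profile rises above `objective_min + threshold` on both sides of the
#' optimum within the grid; a flat profile (as produced by freeing the
#' protein hydration fraction, which multiplies the same term as
#' `k_protein`) yields `non-identifiable`.
#'
#' @param fit a `cycleflux_massfit`.
#' @param param_name parameter to profile.
#' @param grid values at which to fix it.
#' @param threshold objective increase that counts as exceeding; default
#'   is the 95% chi-square(1) quantile scaled by the estimated residual
#'   variance, floored at 1% of the optimum objective.
#' @param n_starts restarts per refit (default 8).
#' @return object of class `cycleflux_profile`: data.frame `value`,
#'   `objective`; `verdict` (`"identifiable"`/`"non-identifiable"`);
#'   `threshold`.
#' @export
profile_likelihood <- function(fit, param_name, grid, threshold = NULL,
                               n_starts = 8L) {
  inp <- fit$inputs
  grid <- sort(grid)
  # walk outward from the optimum, warm-starting each refit from its
  # neighbor so the search tracks any compensating valley
  i0 <- which.min(abs(grid - fit$parameters[[param_name]]))
  prof <- numeric(length(grid))
  refit <- function(v, warm) {
    fit_mass_model(inp$activities, inp$volume, inp$density,
                   inp$events, inp$split_fractions, inp$config,
                   n_starts = n_starts, seed = inp$seed,
                   fixed = stats::setNames(list(v), param_name),
                   free_hydration = inp$free_hydration, start = warm)
  }
  for (dir in list(i0:1, if (i0 < length(grid)) (i0 + 1):length(grid))) {
    warm <- fit$parameters
    for (i in dir) {
      f <- refit(grid[i], warm)
      prof[i] <- f$objective
      warm <- f$parameters
    }
  }
  obj_min <- min(c(prof, fit$objective))
  if (is.null(threshold)) {
    n <- length(fit$empirical)
    p <- length(fit$parameters)
    sigma2 <- obj_min / max(n - p, 1)
    # floor: objective differences smaller than ~1e-5 of the centered
    # data sum of squares are below the refit resolution and cannot
    # support an identifiability claim
    emp_ss <- sum((fit$empirical - mean(fit$empirical))^2)
    threshold <- max(stats::qchisq(0.95, 1) * sigma2, 1e-5 * emp_ss)
  }
  i_min <- which.min(prof)
  rises_left <- any(prof[seq_len(i_min)] > obj_min + threshold)
  rises_right <- any(prof[i_min:length(prof)] > obj_min + threshold)
  verdict <- if (rises_left && rises_right) "identifiable" else
    "non-identifiable"
  structure(list(profile = data.frame(value = grid, objective = prof),
                 verdict = verdict, threshold = threshold,
                 objective_min = obj_min, param = param_name),
            class = "cycleflux_profile")
}

#' @export
print.cycleflux_profile <- function(x, ...) {
  cat("<profile>", x$param, ":", x$verdict, "(threshold",
      signif(x$threshold, 3), ")\n")
  invisible(x)
}

#' Self-consistent synthetic dataset for the cell-mass model
#'
#' Generates activities from the canonical waveforms, picks ground-truth
#' parameters, runs the model forward and returns its own estimate as the
#' empirical mass (with density defined as estimate/volume), so the
#' fitting problem has a known exact solution.
#'
#' @param true_params named vector of model parameters (defaults are
#'   plausible yeast-scale values).
#' @param events event times (min).
#' @param dt grid step (min).
#' @param activity_sd uncertainty band attached to the activities (also
#'   bounds the vertical translations in fitting).
#' @param config a [cellmass_config()] list.
#' @param seed integer seed; with `param_jitter > 0` it draws the
#'   dataset's true parameters around the defaults (lognormal, that
#'   coefficient of variation), keeping the data exactly
#'   self-consistent.
#' @param param_jitter CV of the seeded true-parameter draw (default
#'   0.2; 0 reproduces `true_params` exactly).
#' @param jitter_frac multiplicative observation noise on the empirical
#'   mass (default 0: self-consistent data with an exact solution).
#' @return list with all `fit_mass_model()` inputs plus `true_params`.
#' @export
simulate_mass_dataset <- function(true_params = c(
                                    k_protein = 0.30, k_lipid = 0.08,
                                    k_polysacch = 0.10,
                                    b_protein = 0.02, b_lipid = -0.02,
                                    b_polysacch = 0.01,
                                    dM_DNA = 0.013, r_nonrRNA = 0.02,
                                    gamma_rRNA = 0.25, water = 0.55),
                                  events = c(ME = 0, START = 11,
                                             BUD = 33, KARYO = 85,
                                             next_ME = 100),
                                  dt = 6, activity_sd = 0.05,
                                  config = cellmass_config(),
                                  seed = 1L, param_jitter = 0.2,
                                  jitter_frac = 0) {
  set.seed(seed)
  if (param_jitter > 0) {
    sdlog <- sqrt(log(1 + param_jitter^2))
    pos <- c("k_protein", "k_lipid", "k_polysacch", "dM_DNA",
             "r_nonrRNA", "gamma_rRNA", "water")
    true_params[pos] <- true_params[pos] *
      stats::rlnorm(length(pos), -sdlog^2 / 2, sdlog)
    bs <- c("b_protein", "b_lipid", "b_polysacch")
    true_params[bs] <- stats::runif(3, -0.8 * activity_sd,
                                    0.8 * activity_sd)
  }
  tt <- seq(0, events[["next_ME"]], by = dt)
  acts <- list(
    protein = data.frame(time_min = tt,
                         mean = two_peak_waveform()(tt / events[["next_ME"]]),
                         sd = activity_sd),
    lipid = data.frame(time_min = tt,
                       mean = one_peak_waveform()(tt / events[["next_ME"]]),
                       sd = activity_sd),
    polysacch = data.frame(time_min = tt,
                           mean = one_peak_waveform(peak = 0.55)(
                             tt / events[["next_ME"]]),
                           sd = activity_sd))
  split_fractions <- c(volume = 0.62, surface = 0.58)
  # volume: grows smoothly over the cycle (fl)
  volume <- 40 + 25 * (tt / events[["next_ME"]])^1.2
  rates <- component_rates(true_params, acts, events,
                           config$rrna_lead_min)
  mt <- mass_trajectories(rates, split_fractions, config,
                          true_params[["water"]], volume)
  emp <- mt$estimate
  if (jitter_frac > 0)
    emp <- emp * (1 + stats::rnorm(length(emp), 0, jitter_frac))
  list(activities = acts, volume = volume,
       density = emp / volume, events = events,
       split_fractions = split_fractions, config = config,
       true_params = true_params, true_rates = rates)
}
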