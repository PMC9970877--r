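make_events <- function(cell_id, buds, mes = NULL, starts = NULL) {
  ev <- c(rep("BUD", length(buds)), rep("ME", length(mes)),
          rep("START", length(starts)))
  data.frame(cell_id = rep(cell_id, length(ev)),
             event = ev,
             time_min = c(buds, mes, starts))
}

test_that("steady-cycler selection: identical durations keep all, a
          3-sd outlier is excluded, mixed matches brute force", {
  ev <- do.call(rbind, lapply(1:6, function(i)
    make_events(paste0("c", i), c(50, 150))))
  sel <- select_steady_cycling_cells(ev, t_switch = 200)
  expect_equal(sort(sel$S1), paste0("c", 1:6))
  expect_equal(unname(sel$timing["dt_CC"]), 100)
  # mixed population with an outlier
  durs <- c(95, 100, 100, 102, 105, 180)
  ev2 <- do.call(rbind, lapply(seq_along(durs), function(i)
    make_events(paste0("c", i), c(50, 50 + durs[i]))))
  sel2 <- select_steady_cycling_cells(ev2, t_switch = 300)
  keep_oracle <- abs(durs - median(durs)) <= sd(durs)
  expect_equal(sel2$per_cell$kept, keep_oracle)
  expect_false("c6" %in% sel2$S1)
})

test_that("perturbation phase: arithmetic, the kept/rejected rules and
          the no-event rejection", {
  timing <- c(dt_START = 11, dt_BUD = 30, dt_CC = 100)
  # perturbation 2 min (at midpoint) after BUD
  ev <- make_events("c", buds = 100, mes = 60, starts = 75)
  pp <- perturbation_phase(ev, t_p = 105, dt = 6, timing)
  expect_equal(pp$E, "BUD")
  expect_equal(pp$phi, 2 + 30)
  expect_true(pp$kept)
  # theta_ME = 5 <= dt_START -> kept with phi = 5
  ev2 <- make_events("c", buds = 1, mes = 100)
  pp2 <- perturbation_phase(ev2, t_p = 108, dt = 6, timing)
  expect_equal(pp2$E, "ME"); expect_equal(pp2$phi, 5)
  expect_true(pp2$kept)
  # E = BUD and phi > dt_CC -> rejected
  ev3 <- make_events("c", buds = 10)
  pp3 <- perturbation_phase(ev3, t_p = 120, dt = 6, timing)
  expect_equal(pp3$E, "BUD")
  expect_gt(pp3$phi, timing[["dt_CC"]])
  expect_false(pp3$kept)
  pp4 <- perturbation_phase(make_events("c", buds = numeric(0)),
                            t_p = 60, dt = 6, timing)
  expect_false(pp4$kept)
  expect_match(pp4$reason, "no pre-perturbation")
})

test_that("normal derivative profile equals a brute-force median loop
          and is robust to corrupting a minority of cells", {
  set.seed(12)
  dt <- 6
  timing <- c(dt_START = 12, dt_BUD = 36, dt_CC = 96)
  tt <- seq(0, 400, by = dt)
  cells <- paste0("c", 1:9)
  deriv <- list(); evl <- list()
  for (i in seq_along(cells)) {
    off <- runif(1, 0, 90)
    f <- 100 + 8 * sin(2 * pi * (tt - off) / 96)
    sm <- savgol_smooth(f)
    deriv[[cells[i]]] <- trace_derivative(as.numeric(sm), tt,
                                          method = "midpoint")
    evl[[i]] <- data.frame(
      cell_id = cells[i], event = rep(c("ME", "START", "BUD"), 4),
      time_min = rep(off + c(0, 12, 36), 4) +
        rep(c(0, 96, 192, 288), each = 3))
  }
  events <- do.call(rbind, evl)
  prof <- normal_derivative_profile(deriv, events, t_switch = 390,
                                    timing)
  # brute-force loop at a few phases
  for (p in c(5, 20, 60)) {
    e <- if (p <= 12) "ME" else if (p <= 36) "START" else "BUD"
    off <- c(ME = 0, START = 12, BUD = 36)[e]
    vals <- sapply(cells, function(cid) {
      te <- sort(events$time_min[events$cell_id == cid &
                                   events$event == e &
                                   events$time_min < 390])
      anchor <- te[length(te) - 1]
      d <- deriv[[cid]]
      approx(d$time, d$value, xout = anchor + p - off)$y
    })
    expect_equal(prof$N(p), median(vals, na.rm = TRUE),
                 tolerance = 1e-12)
  }
  # bounded influence: corrupting 4 of 9 cells keeps the median within
  # the range of the uncorrupted values, while the mean is dragged far
  # outside
  deriv_bad <- deriv
  for (cid in cells[1:4])
    deriv_bad[[cid]]$value <- deriv_bad[[cid]]$value + 100
  prof_bad <- normal_derivative_profile(deriv_bad, events, 390, timing)
  for (p in c(5, 20, 60)) {
    e <- if (p <= 12) "ME" else if (p <= 36) "START" else "BUD"
    off <- c(ME = 0, START = 12, BUD = 36)[e]
    clean_vals <- sapply(cells[5:9], function(cid) {
      te <- sort(events$time_min[events$cell_id == cid &
                                   events$event == e &
                                   events$time_min < 390])
      d <- deriv[[cid]]
      approx(d$time, d$value, xout = te[length(te) - 1] + p - off)$y
    })
    expect_gte(prof_bad$N(p), min(clean_vals))
    expect_lte(prof_bad$N(p), max(clean_vals))
  }
})

test_that("NAD(P)H response arithmetic and degenerate amplitude", {
  prof <- list(N = function(p) rep(1, length(p)), amplitude = 2)
  expect_equal(nadph_response(1, 10, prof, alpha = -1), 0)
  expect_equal(nadph_response(0.5, 10, prof, alpha = -1), 0.25)
  expect_equal(nadph_response(0.5, 10, prof, alpha = 1), -0.25)
  expect_error(nadph_response(1, 1, list(N = function(p) 0,
                                         amplitude = 0), -1),
               "degenerate")
  expect_error(nadph_response(1, 1, prof, alpha = 2), "alpha")
})

test_that("end-to-end pipeline equals a straight-line reimplementation
          of the analysis steps on the same experiment", {
  truth <- ground_truth(seed = 23, perturbation_gain = 2)
  expt <- simulate_perturbation_experiment(truth, n_cells = 40,
                                           t_switch = 280, lag = 6)
  res <- stop_and_respond(expt, t_p = expt$t_p, gp_seed = 1)
  ## ---- independent straight-line oracle ----------------------------
  tr <- expt$traces; ev <- expt$events; dt <- expt$dt
  t_sw <- expt$t_switch; t_p <- expt$t_p
  # S1 selection
  ib <- sapply(unique(ev$cell_id), function(cid) {
    b <- sort(ev$time_min[ev$cell_id == cid & ev$event == "BUD" &
                            ev$time_min < t_sw])
    if (length(b) < 2) NA else diff(tail(b, 2))
  })
  keep <- names(ib)[!is.na(ib) & abs(ib - median(ib, na.rm = TRUE)) <=
                      sd(ib, na.rm = TRUE)]
  expect_setequal(res$S1, keep)
  # timing means
  tim <- t(sapply(keep, function(cid) {
    b <- tail(sort(ev$time_min[ev$cell_id == cid & ev$event == "BUD" &
                                 ev$time_min < t_sw]), 2)
    me <- min(ev$time_min[ev$cell_id == cid & ev$event == "ME" &
                            ev$time_min > b[1] & ev$time_min <= b[2]])
    st <- min(ev$time_min[ev$cell_id == cid & ev$event == "START" &
                            ev$time_min > b[1] & ev$time_min <= b[2]])
    c(st - me, b[2] - me, diff(b))
  }))
  expect_equal(unname(res$timing),
               unname(colMeans(tim)), tolerance = 1e-12)
  # per-cell P and R for a handful of cells
  half <- 3L
  co <- signal::sgolay(p = 3, n = 7)[half + 1L, ]
  smooth_nearest <- function(x) {
    pad <- c(rep(x[1], half), x, rep(x[length(x)], half))
    sapply(seq_along(x), function(i) sum(co * pad[i:(i + 6)]))
  }
  for (cid in head(keep, 5)) {
    sub <- tr[tr$cell_id == cid, ]
    sub <- sub[order(sub$time_min), ]
    sm <- smooth_nearest(sub$nadph)   # no split: no step at the switch
    dmid <- diff(sm) / dt
    tmid <- head(sub$time_min, -1) + dt / 2
    P_oracle <- dmid[which(abs(tmid - (t_p - dt / 2)) < 1e-9)]
    got <- res$cells[res$cells$cell_id == cid, ]
    expect_equal(got$P, P_oracle, tolerance = 1e-10)
    if (got$kept) {
      R_oracle <- res$alpha * (P_oracle - res$profile$N(got$phi)) /
        res$profile$amplitude
      expect_equal(got$R, R_oracle, tolerance = 1e-10)
    }
  }
})

test_that("constant activity gives a flat response at the predicted
          level (closed form from the generator equations)", {
  gain <- 2; cval <- 0.8
  truth <- ground_truth(activity = list(protein = constant_waveform(cval),
                                        lipid = constant_waveform(1),
                                        polysacch = constant_waveform(1)),
                        perturbation_gain = gain, seed = 31)
  expt <- simulate_perturbation_experiment(truth, n_cells = 120,
                                           t_switch = 280, lag = 6,
                                           sign = -1)
  res <- stop_and_respond(expt, t_p = expt$t_p, gp_seed = 1)
  kept <- res$cells[res$cells$kept, ]
  # expected level: attenuated derivative offset over the oscillation
  # amplitude of the unperturbed profile
  att <- savgol_ramp_attenuation()
  expected <- att * gain * cval / res$profile$amplitude
  expect_equal(mean(kept$R), expected, tolerance = 0.15 * expected)
  # flat in phase: GP posterior amplitude well below its mean level
  expect_lt(diff(range(res$pattern$mean)), 0.5 * mean(res$pattern$mean))
})

test_that("2-NBDG correction removes autofluorescence and equalizes
          batch medians while preserving within-batch ranking", {
  set.seed(5)
  mk_cell <- function(cid, auto, uptake, batch) {
    data.frame(cell_id = cid,
               time_min = c(seq(0, 24, by = 6), 40, 46),
               value = c(rep(auto, 5), auto + uptake, auto + uptake),
               batch = batch)
  }
  cells <- rbind(mk_cell("a", 50, 0, 1), mk_cell("b", 80, 100, 1),
                 mk_cell("c", 20, 150, 1),
                 mk_cell("d", 60, 50, 2), mk_cell("e", 10, 75, 2),
                 mk_cell("f", 30, 60, 2))
  # batch 2 measured later: 2x acquisition decay
  cells$value[cells$batch == 2 & cells$time_min >= 40] <-
    cells$value[cells$batch == 2 & cells$time_min >= 40] * 0.5 +
    0.5 * rep(c(60, 10, 30), each = 2)
  out <- nbdg_signal_correction(cells, switch1 = 30, switch2 = 40)
  expect_equal(out$corrected[out$cell_id == "a"], 0)
  m1 <- median(out$normalized[out$batch == 1])
  m2 <- median(out$normalized[out$batch == 2])
  expect_equal(m1, m2, tolerance = 1e-12)
  r2 <- out[out$batch == 2, ]
  expect_equal(order(r2$corrected), order(r2$normalized))
})
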