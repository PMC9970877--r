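test_that("mean event phases match direct arithmetic and a brute-force
          loop", {
  one <- data.frame(ME = 0, START = 10, BUD = 20, next_ME = 100)
  expect_equal(mean_event_phases(one),
               c(ME = 0, START = 0.1, BUD = 0.2, next_ME = 1))
  # two identical cycles: mean is idempotent
  expect_equal(mean_event_phases(rbind(one, one)),
               mean_event_phases(one))
  # random schedules against an explicit loop
  set.seed(21)
  cyc <- data.frame(ME = runif(3, 0, 50))
  cyc$START <- cyc$ME + runif(3, 5, 20)
  cyc$BUD <- cyc$START + runif(3, 5, 30)
  cyc$next_ME <- cyc$BUD + runif(3, 30, 80)
  got <- mean_event_phases(cyc)
  oracle <- c(ME = 0, START = 0, BUD = 0, next_ME = 0)
  for (i in 1:3) {
    dur <- cyc$next_ME[i] - cyc$ME[i]
    for (e in names(oracle))
      oracle[e] <- oracle[e] + (cyc[[e]][i] - cyc$ME[i]) / dur / 3
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  bad <- one; bad$START <- 25; bad$BUD <- 20
  expect_error(mean_event_phases(bad), "ordered")
})

test_that("time_to_phase is exact at anchors, linear for proportional
          schedules, and matches the brute-force oracle", {
  pm <- c(ME = 0, START = 0.12, BUD = 0.3, next_ME = 1)
  ce <- c(ME = 10, START = 30, BUD = 55, next_ME = 130)
  expect_equal(time_to_phase(ce[["BUD"]], ce, pm), pm[["BUD"]])
  expect_equal(time_to_phase(ce[["ME"]], ce, pm), 0)
  expect_equal(time_to_phase(ce[["next_ME"]], ce, pm), 1)
  # proportional schedule -> exactly linear in t
  ce_prop <- c(ME = 0, START = 12, BUD = 30, next_ME = 100)
  tt <- seq(0, 100, by = 2.5)
  expect_equal(time_to_phase(tt, ce_prop, pm), tt / 100,
               tolerance = 1e-12)
  # random times vs brute force
  set.seed(9)
  tr <- runif(100, ce[1], ce[4])
  expect_equal(time_to_phase(tr, ce, pm),
               brute_time_to_phase(tr, as.numeric(ce), as.numeric(pm)),
               tolerance = 1e-12)
  expect_error(time_to_phase(500, ce, pm), "outside")
})

test_that("phase map is monotone, continuous and inverts to 1e-9", {
  pm <- c(ME = 0, START = 0.15, BUD = 0.35, next_ME = 1)
  set.seed(4)
  for (rep in 1:20) {
    ce <- cumsum(c(runif(1, 0, 20), runif(3, 5, 60)))
    names(ce) <- c("ME", "START", "BUD", "next_ME")
    tt <- sort(runif(50, ce[1], ce[4]))
    ph <- time_to_phase(tt, ce, pm)
    expect_true(all(diff(ph) >= 0))
    back <- phase_to_time(ph, ce, pm)
    expect_equal(back, tt, tolerance = 1e-9)
  }
})

test_that("Whi5 sd/mean ratio events: cadence window defaults, flat
          series, and a synthetic rise/fall", {
  tt <- seq(0, 600, by = 6)
  # constant ratio -> no events
  flat <- detect_whi5_events(rep(2, length(tt)), rep(4, length(tt)), tt)
  expect_equal(nrow(flat), 0)
  # one sharp derivative max (ME) then min (START)
  src <- exp(-((tt - 200)^2) / 300) - exp(-((tt - 290)^2) / 300)
  ratio <- cumsum(src)
  ev <- detect_whi5_events(ratio, rep(1, length(tt)), tt)
  me <- ev$time_min[ev$event == "ME"]
  st <- ev$time_min[ev$event == "START"]
  expect_true(any(abs(me - 194) <= 6))
  expect_true(any(abs(st - 284) <= 6))
  # series too short for the 72-min comparison window
  expect_error(detect_whi5_events(rep(1, 10), rep(1, 10),
                                  seq(0, 54, by = 6)), "short")
})

test_that("event ordering filter keeps well-ordered cycles and drops
          inverted ones", {
  ev <- data.frame(
    cell_id = c(rep("a", 5), rep("b", 5)),
    event = c("ME", "START", "BUD", "ME", "START",
              "ME", "BUD", "START", "ME", "START"),
    time_min = c(0, 10, 30, 100, 110,
                 0, 10, 30, 100, 110))
  out <- filter_event_candidates(ev)
  expect_true("a@0" %in% setdiff(paste0(unique(ev$cell_id), "@0"),
                                 attr(out, "rejected_cycles")))
  expect_true("b@0" %in% attr(out, "rejected_cycles"))
})

test_that("karyokinesis is the steepest smoothed abundance drop", {
  t3 <- seq(0, 135, by = 3)
  step <- ifelse(t3 < 60, 1000, 420)
  kt <- karyokinesis_time(step, t3)
  expect_lt(abs(kt - 58.5), 3.1)
  # two drops, second steeper -> second one wins
  two <- 1000 - 100 * pmin(pmax(t3 - 30, 0), 9) / 9 -
    300 * pmin(pmax(t3 - 90, 0), 9) / 9
  kt2 <- karyokinesis_time(two, t3)
  expect_gt(kt2, 85)
  expect_true(is.na(karyokinesis_time(rep(5, length(t3)), t3)))
})
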