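test_that("urine volumes are spread uniformly and normalised by weight", {
  # single 240 mL charting covering 6 h at 80 kg -> 0.5 mL/kg/h for 6 hours
  enc <- make_encounter(rbind(ev(0, "weight", 80),
                              ev(6, "urine_output", 240)))
  r <- hourly_uo_rate(enc)
  expect_equal(nrow(r), 6)
  expect_equal(r$rate_ml_kg_h, rep(0.5, 6))
  expect_false(any(r$missing))

  # weight change mid-stream: later hours divided by the new weight
  enc2 <- make_encounter(rbind(ev(0, "weight", 80),
                               ev(5.5, "weight", 100),
                               uo_events(rep(1, 10), weight = 80)))
  r2 <- hourly_uo_rate(enc2)
  expect_equal(r2$rate_ml_kg_h[1:5], rep(1, 5))
  expect_equal(r2$rate_ml_kg_h[6:10], rep(0.8, 5))

  # a charting gap beyond the pooling cap leaves missing hours
  enc3 <- make_encounter(rbind(ev(0, "weight", 80),
                               uo_events(rep(0.5, 4)),
                               ev(14, "urine_output", 240)))
  r3 <- hourly_uo_rate(enc3)
  expect_equal(which(r3$missing), 5:8)
  expect_equal(r3$rate_ml_kg_h[9:14], rep(0.5, 6))

  # no weight -> UO staging uncomputable, not an exception
  expect_null(hourly_uo_rate(make_encounter(uo_events(rep(1, 6)))))
})

test_that("UO staging emits the expected stages on hand-built profiles", {
  # sustained low output starting at hour 4: the trailing-6 h mean first
  # drops below 0.5 at hour 7
  rates <- rep(0.6, 24)
  rates[4:10] <- 0.4
  s <- stage_uo(rate_grid(rates))
  expect_identical(s, oracle_stage_uo(rate_grid(rates)))
  first1 <- s$timestamp[s$stage == 1][1]
  expect_equal(as.numeric(first1 - T0, units = "hours"), 7)

  # 12 consecutive anuric hours -> stage 3
  rates2 <- rep(0.8, 24)
  rates2[5:16] <- 0
  s2 <- stage_uo(rate_grid(rates2))
  expect_identical(s2, oracle_stage_uo(rate_grid(rates2)))
  expect_equal(max(s2$stage), 3)
  expect_equal(stage_at(s2, T0 + 16 * 3600), 3L)

  # healthy output -> stage 0 throughout, single opening point
  s3 <- stage_uo(rate_grid(rep(0.8, 24)))
  expect_equal(nrow(s3), 1)
  expect_equal(s3$stage, 0L)
  expect_equal(as.numeric(s3$timestamp - T0, units = "hours"), 6)

  # a missing hour invalidates every window containing it
  rates4 <- rep(0.4, 12)
  rates4[3] <- NA
  s4 <- stage_uo(rate_grid(rates4))
  expect_equal(as.numeric(s4$timestamp[1] - T0, units = "hours"), 9)
  expect_equal(s4$stage[1], 1L)
})

test_that("the all-hours window mode differs from the mean mode as designed", {
  rules_all <- staging_rules(uo_window_mode = "all_hours")
  alternating <- rate_grid(rep(c(0.3, 0.55), 12))
  # mean over any 6-h window is 0.425 < 0.5 -> stage 1 in mean mode
  expect_gte(max(stage_uo(alternating)$stage), 1)
  # but not every hour is below threshold -> stage 0 in all-hours mode
  expect_equal(max(stage_uo(alternating, rules_all)$stage), 0)
  # sustained low output stages identically in both modes
  low <- rate_grid(rep(0.45, 10))
  expect_equal(max(stage_uo(low)$stage), 1)
  expect_equal(max(stage_uo(low, rules_all)$stage), 1)
})

test_that("creatinine staging follows the AKIN thresholds and boundaries", {
  stage_of <- function(scr, baseline) {
    stage_cr(tibble::tibble(timestamp = T0, value = scr), baseline)$stage
  }
  expect_equal(stage_of(1.6, 1.0), 1L)           # ratio 1.6
  expect_equal(stage_of(0.71, 0.4), 1L)          # rise 0.31, ratio 1.775
  expect_equal(stage_of(1.0, 1.0), 0L)           # unchanged
  expect_equal(stage_of(1.5, 1.0), 1L)           # ratio boundary >= 1.5
  expect_equal(stage_of(2.0, 1.0), 1L)           # stage 2 needs > 2x
  expect_equal(stage_of(2.01, 1.0), 2L)
  expect_equal(stage_of(3.0, 1.0), 2L)           # stage 3 needs > 3x
  expect_equal(stage_of(3.01, 1.0), 3L)
  expect_equal(stage_of(4.0, 3.6), 1L)           # rise 0.4 < 0.5: not stage 3
  expect_equal(stage_of(4.0, 3.5), 3L)           # >= 4.0 with rise >= 0.5
  expect_equal(stage_of(1.25, 0.9), 1L)          # absolute rise 0.35
  expect_error(stage_of(1.0, 0), "positive")
  # stages fall when creatinine falls (no ratchet)
  s <- stage_cr(tibble::tibble(timestamp = T0 + (1:3) * 3600,
                               value = c(2.5, 1.6, 0.9)), 1.0)
  expect_equal(s$stage, c(2L, 1L, 0L))
})

test_that("combined stage is the maximum of the most recent values", {
  t1 <- T0 + 3600
  t2 <- T0 + 7200
  t3 <- T0 + 10800
  uo <- tibble::tibble(timestamp = t1, stage = 1L)
  cr <- tibble::tibble(timestamp = t2, stage = 2L)
  cmb <- combined_stage(uo, cr)
  expect_equal(cmb$stage, c(1L, 2L))
  expect_equal(cmb$timestamp, c(t1, t2))

  # a component falling back to 0 does not drag the combined stage below the
  # other component's latest value
  cr2 <- tibble::tibble(timestamp = c(t2, t3), stage = c(2L, 0L))
  cmb2 <- combined_stage(uo, cr2)
  expect_equal(cmb2$stage, c(1L, 2L, 1L))

  # an empty component contributes nothing
  empty <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          stage = integer())
  expect_equal(combined_stage(uo, empty)$stage, uo$stage)
  expect_equal(nrow(combined_stage(empty, empty)), 0)
})

test_that("UO staging matches the brute-force window oracle on random grids", {
  withr::local_seed(401)
  for (i in 1:120) {
    g <- random_rate_grid()
    expect_identical(stage_uo(g), oracle_stage_uo(g))
  }
})

test_that("staging is monotone in urine volume and creatinine", {
  withr::local_seed(402)
  hrs <- T0 + (1:72) * 3600
  for (i in 1:60) {
    g <- random_rate_grid()
    g_up <- g
    g_up$rate_ml_kg_h <- g$rate_ml_kg_h * 1.5
    g_up$ml_per_h <- g$ml_per_h * 1.5
    s <- stage_at(stage_uo(g), hrs, default = NA_integer_)
    s_up <- stage_at(stage_uo(g_up), hrs, default = NA_integer_)
    both <- !is.na(s) & !is.na(s_up)
    expect_true(all(s_up[both] <= s[both]))
  }
  for (i in 1:60) {
    scr <- round(stats::runif(8, 0.5, 4), 2)
    evs <- tibble::tibble(timestamp = T0 + (1:8) * 3600, value = scr)
    evs_up <- dplyr::mutate(evs, value = value + 0.4)
    expect_true(all(stage_cr(evs_up, 1.0)$stage >= stage_cr(evs, 1.0)$stage))
  }
})

test_that("combined stage dominates both components and equals one of them", {
  withr::local_seed(403)
  for (i in 1:60) {
    uo <- tibble::tibble(timestamp = T0 + sort(sample(1:72, 6)) * 3600,
                         stage = sample(0:3, 6, replace = TRUE))
    cr <- tibble::tibble(timestamp = T0 + sort(sample(1:72, 4)) * 3600,
                         stage = sample(0:3, 4, replace = TRUE))
    cmb <- combined_stage(uo, cr)
    u <- stage_at(uo, cmb$timestamp, default = 0L)
    cc <- stage_at(cr, cmb$timestamp, default = 0L)
    expect_true(all(cmb$stage >= u & cmb$stage >= cc))
    expect_true(all(cmb$stage == u | cmb$stage == cc))
  }
})

test_that("stage_encounter handles partial data and healthy trajectories", {
  # creatinine only: UO series empty, combined equals the Cr series
  enc <- make_encounter(rbind(ev(2, "creatinine", 1.8),
                              ev(20, "creatinine", 0.95)),
                        baseline = 0.9)
  s <- stage_encounter(enc)
  expect_equal(nrow(s$uo), 0)
  expect_equal(s$combined$stage, s$cr$stage)

  # healthy trajectory: stage 0 everywhere in all three series
  healthy <- make_encounter(rbind(ev(0, "weight", 80),
                                  uo_events(rep(1, 48)),
                                  ev(6, "creatinine", 0.9),
                                  ev(30, "creatinine", 0.92)),
                            baseline = 0.9)
  sh <- stage_encounter(healthy)
  expect_equal(max(sh$combined$stage), 0)

  # an injected 12-h stage-2 UO episode surfaces in the combined series
  rates <- c(rep(1, 10), rep(0.4, 14), rep(1, 24))
  enc2 <- make_encounter(rbind(ev(0, "weight", 80), uo_events(rates)),
                         baseline = 0.9)
  s2 <- stage_encounter(enc2)
  expect_gte(max(s2$combined$stage), 2)
})
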