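test_that("segmentation recovers breath count and analytic tidal volume", {
  # eupnea at 85 breaths/min for ~60 s
  cfg <- synth_config(duration = 61, seed = 4, apnea_rate = 0,
                      hypopnea_rate = 0, sigh_rate = 0)
  rec <- generate_breathing(cfg)
  ser <- segment_breaths(rec$flow, cfg$body_mass)
  n60 <- sum(ser$breaths$onset < 60)
  expect_gte(n60, 83L)
  expect_lte(n60, 87L)

  # half-sine inspiration of amplitude A and duration Ti: VT = 2 A Ti / pi
  a <- 5; ti <- 0.3; te <- 0.4
  tr <- build_flow(20, ti, te, a, function(t, te) (a / 2) * exp(-t / 0.2))
  s2 <- segment_breaths(tr, 250)
  expect_equal(mean(s2$breaths$vt), 2 * a * ti / pi, tolerance = 1e-3)
  expect_equal(stats::median(s2$breaths$ti), ti, tolerance = 0.01)

  flat <- signal_trace(rep(0, 1000), 100, "mL/s")
  expect_error(segment_breaths(flat, 250), "no breaths")
})

test_that("per-breath VT matches the generator schedule", {
  cfg <- synth_config(duration = 120, seed = 8, apnea_rate = 0,
                      hypopnea_rate = 0, sigh_rate = 0, noise_sd_flow = 0)
  rec <- generate_breathing(cfg)
  ser <- segment_breaths(rec$flow, cfg$body_mass)
  sched <- rec$breaths
  m <- min(nrow(sched), nrow(ser$breaths))
  expect_equal(ser$breaths$vt[2:(m - 1L)], sched$vt[2:(m - 1L)],
               tolerance = 0.01)
})

test_that("ventilation summaries follow the definition and scaling rules", {
  iv <- rep(1000, 60)                 # 60 breaths/min
  ser <- breath_series_from_intervals(iv, vt = 0.93, body_mass = 300)
  vs <- ventilation_summary(ser, c(0, 10))
  expect_equal(vs$vt_per100g, 0.31)
  expect_equal(vs$rf, 60)
  expect_equal(vs$ve, 18.6)
  expect_identical(vs$ve, vs$vt_per100g * vs$rf)   # exact by construction

  ser2 <- breath_series_from_intervals(iv, vt = 0.93, body_mass = 600)
  vs2 <- ventilation_summary(ser2, c(0, 10))
  expect_equal(vs2$vt_per100g, vs$vt_per100g / 2)
  expect_equal(vs2$ve, vs$ve / 2)

  # 13 cycles in a 10-s window violates the 10 +/- 2 convention
  ser3 <- breath_series_from_intervals(rep(1000 * 10 / 13, 40), vt = 1)
  vs3 <- ventilation_summary(ser3, c(0, 10), ten_second_rule = TRUE)
  expect_false(vs3$valid)
  expect_error(ventilation_summary(ser, c(5, 5)), "empty window")
})

test_that("event scoring honors thresholds and local-cycle definitions", {
  # constant eupnea: nothing to score
  ser <- breath_series_from_intervals(rep(700, 60), vt = 1)
  expect_equal(nrow(detect_events(ser)), 0L)

  # one breath at 49% of the 3-breath reference: exactly one hypopnea
  vt <- rep(1, 60); vt[30] <- 0.49
  ser <- breath_series_from_intervals(rep(700, 60), vt = vt)
  ev <- detect_events(ser)
  expect_equal(ev$kind, "hypopnea")
  expect_equal(nrow(ev), 1L)
  # at 51% nothing is scored
  vt[30] <- 0.51
  ev2 <- detect_events(breath_series_from_intervals(rep(700, 60), vt = vt))
  expect_equal(nrow(ev2), 0L)
  # 151% of reference is a sigh
  vt[30] <- 1.51
  ev3 <- detect_events(breath_series_from_intervals(rep(700, 60), vt = vt))
  expect_equal(ev3$kind, "sigh")

  expect_error(detect_events(breath_series_from_intervals(rep(700, 5))),
               "at least 10")
})

test_that("detected events match ground truth on a synthetic recording", {
  cfg <- synth_config(duration = 1800, seed = 21, apnea_rate = 8,
                      hypopnea_rate = 4, sigh_rate = 12)
  rec <- generate_breathing(cfg)
  ser <- segment_breaths(rec$flow, cfg$body_mass)
  ev <- detect_events(ser)
  cycle <- 60 / cfg$rf
  for (k in c("apnea", "hypopnea", "sigh", "post_sigh_apnea")) {
    m <- match_events(rec$truth, ev, k, cycle)
    expect_equal(m$tp, m$n_truth, info = k)
    expect_equal(m$n_det, m$n_truth, info = k)
  }
})

test_that("event_summary arithmetic and scaling", {
  tab <- annotation_table(rep(c("apnea", "hypopnea"), c(4, 2)),
                          onset = 1:6 * 100, duration = c(3, 3, 4, 3, 2, 2))
  es <- event_summary(tab, 1800)
  expect_equal(es$apnea_rate, 8)
  expect_equal(es$hypopnea_rate, 4)
  expect_equal(es$ahi, 12)
  expect_equal(es$mean_durations[["apnea"]], 3.25)
  expect_true(is.na(es$mean_durations[["sigh"]]))

  es2 <- event_summary(tab, 3600)
  expect_equal(es2$ahi, es$ahi / 2)

  empty <- event_summary(annotation_table(), 600)
  expect_equal(empty$ahi, 0)
  expect_error(event_summary(tab, -5), "duration")
})

test_that("Poincare statistics match closed forms and the ellipse identity", {
  cons <- breath_series_from_intervals(rep(700, 301))
  ps <- poincare_stats(cons, 300)
  expect_equal(ps$sd1, 0)
  expect_equal(ps$sd2, 0)

  # n chosen so the lag-pair count is even and the closed form is exact
  alt <- breath_series_from_intervals(rep(c(300, 400), 152))
  pa <- poincare_stats(alt, 301)
  expect_equal(pa$sd1, 100 / sqrt(2), tolerance = 1e-6)
  expect_equal(pa$sd2, 0, tolerance = 1e-6)

  set.seed(99)
  iid <- breath_series_from_intervals(700 + stats::rnorm(320, 0, 40))
  pi300 <- poincare_stats(iid, 300)
  expect_equal(pi300$sd1, 40, tolerance = 0.05 * 40)
  expect_equal(pi300$sd2, 40, tolerance = 0.05 * 40)

  # SD1^2 + SD2^2 equals the total lag-scatter variance for arbitrary series
  for (s in 1:5) {
    set.seed(s)
    x <- 700 + as.numeric(stats::arima.sim(list(ar = 0.5), 300, sd = 20))
    ser <- breath_series_from_intervals(x)
    p <- poincare_stats(ser, 299)
    xx <- x[seq_len(299)]
    tot <- pop_sd_test(xx[-299])^2 + pop_sd_test(xx[-1L])^2
    expect_equal(p$sd1^2 + p$sd2^2, tot, tolerance = 1e-9)
  }
  expect_error(poincare_stats(cons, 400), "at least 400")
})

test_that("cv_vt recovers a programmed VT coefficient of variation", {
  cfg <- synth_config(duration = 400, seed = 13, vt_cv = 15, apnea_rate = 0,
                      hypopnea_rate = 0, sigh_rate = 0)
  rec <- generate_breathing(cfg)
  ser <- segment_breaths(rec$flow, cfg$body_mass)
  ps <- poincare_stats(ser, 300)
  expect_equal(ps$cv_vt, 15, tolerance = 0.12 * 15)
})
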