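test_that("tachogram construction: constants, grid, and depth fidelity", {
  cons <- beats_from_times(cumsum(rep(0.2, 400)))
  tach <- build_tachogram(cons)
  expect_true(all(abs(tach$samples - 200) < 1e-9))
  expect_equal(diff(trace_times(tach))[1L], 0.1, tolerance = 1e-12)

  mod <- modulated_beats(120, 200, mods = list(list(freq = 0.3, depth = 10)))
  tm <- build_tachogram(mod)
  mid <- tm$samples[200:900]
  expect_equal(max(mid) - min(mid), 20, tolerance = 0.02 * 20)
  expect_error(build_tachogram(beats_from_times(cumsum(rep(0.2, 10)))),
               "too few")
})

test_that("AR spectra locate modulation peaks and vanish on silence", {
  mod <- modulated_beats(660, 200, mods = list(list(freq = 0.3, depth = 8)),
                         noise_ms = 0.5, seed = 2)
  psd <- psd_ar(build_tachogram(mod), 600, 60)
  expect_equal(psd$freqs[which.max(psd$power)], 0.30, tolerance = 0.02)
  expect_equal(psd$meta$n_segments, 19L)

  silent <- signal_trace(rep(200, 6001), 10, "ms")
  p0 <- psd_ar(silent, 600, 60)
  expect_true(all(p0$power == 0))
  expect_error(psd_ar(build_tachogram(modulated_beats(120, 200)), 600, 60),
               "shorter")
  expect_error(psd_ar(silent, 600, 60, ar_order = 700L), "order")
})

test_that("AR-on-noise spectra are flat across the physiological bands", {
  # averaged over 20 seeds, max/min < 3 over 0.04-2.4 Hz at order 16
  acc <- NULL
  for (s in 1:20) {
    set.seed(s)
    tach <- signal_trace(200 + stats::rnorm(6001, 0, 5), 10, "ms")
    p <- psd_ar(tach, 600, 60)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  sel <- p$freqs >= 0.04 & p$freqs <= 2.4
  expect_lt(max(acc[sel]) / min(acc[sel]), 3)
})

test_that("Parseval: spectral integral matches tapered variance within 5%", {
  for (s in c(3, 17)) {
    set.seed(s)
    x <- 200 + as.numeric(stats::arima.sim(list(ar = c(0.5, -0.2)), 6001,
                                           sd = 4))
    tach <- signal_trace(x, 10, "ms")
    psd <- psd_ar(tach, 600, 60)
    integral <- sum(diff(psd$freqs) *
                    (psd$power[-1L] + psd$power[-length(psd$power)]) / 2)
    ref <- tapered_variance(x, 10, 600, 60)
    expect_equal(integral, ref, tolerance = 0.05)
  }
})

test_that("band powers: normalized units, ratios, and edge behavior", {
  mod <- modulated_beats(660, 200,
                         mods = list(list(freq = 0.3, depth = 6),
                                     list(freq = 1.5, depth = 6)),
                         noise_ms = 0.5, seed = 4)
  bp <- band_powers(psd_ar(build_tachogram(mod), 600, 60))
  expect_equal(bp$lf_hf, 1, tolerance = 0.15)
  expect_equal(bp$lf_nu + bp$hf_nu, 100, tolerance = 1e-9)

  hf_only <- modulated_beats(660, 200,
                             mods = list(list(freq = 1.5, depth = 8)),
                             noise_ms = 0.2, seed = 5)
  bp2 <- band_powers(psd_ar(build_tachogram(hf_only), 600, 60))
  expect_gte(bp2$hf_nu, 95)

  silent <- signal_trace(rep(200, 6001), 10, "ms")
  expect_error(band_powers(psd_ar(silent, 600, 60)), "zero HF power")
})

test_that("time-varying HRV tracks stationarity and modulation switches", {
  mod <- modulated_beats(900, 200,
                         mods = list(list(freq = 0.3, depth = 5),
                                     list(freq = 1.5, depth = 5)),
                         noise_ms = 0.5, seed = 6)
  tach <- build_tachogram(mod)
  tv <- time_varying_hrv(tach, step_s = 60, window_s = 240, subwindow_s = 60)
  span <- trace_duration(tach)
  expect_equal(nrow(tv), floor((span - 240) / 60) + 1L)
  expect_true(all(abs(tv$lf_hf - mean(tv$lf_hf)) <= 0.2 * mean(tv$lf_hf) +
                    0.2))

  # HF-only first half, LF-only second half: ratio rises across the switch
  t1 <- modulated_beats(450, 200, mods = list(list(freq = 1.5, depth = 8)),
                        noise_ms = 0.5, seed = 7)
  t2 <- modulated_beats(450, 200, mods = list(list(freq = 0.3, depth = 8)),
                        noise_ms = 0.5, seed = 8)
  times <- c(t1$beats$time, t2$beats$time + 450.2)
  sw <- beats_from_times(times)
  tvs <- time_varying_hrv(build_tachogram(sw), step_s = 120, window_s = 240,
                          subwindow_s = 60)
  expect_gt(utils::tail(tvs$lf_hf, 1L), utils::head(tvs$lf_hf, 1L))
  expect_error(time_varying_hrv(tach, step_s = 0), "step")
})
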