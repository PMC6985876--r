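test_that("generation is deterministic and silent when rates are zero", {
  cfg <- synth_config(duration = 90, seed = 11, apnea_rate = 0,
                      hypopnea_rate = 0, sigh_rate = 0)
  a <- generate_breathing(cfg)
  b <- generate_breathing(cfg)
  expect_identical(a$flow$samples, b$flow$samples)
  expect_equal(nrow(a$truth), 0L)
  pa <- generate_pressure(cfg, a$breaths, duration = 60)
  pb <- generate_pressure(cfg, b$breaths, duration = 60)
  expect_identical(pa$pressure$samples, pb$pressure$samples)
})

test_that("truth event counts follow the programmed Poisson law", {
  # scaled down from the spec-sheet replicate count (200 x 2 h) to stay
  # within the test budget: 40 seeded 1-h schedules at 6 events/h
  rate <- 6
  counts <- vapply(1:40, function(s) {
    cfg <- synth_config(duration = 3600, seed = s, fs_flow = 40,
                        apnea_rate = rate, hypopnea_rate = 0, sigh_rate = 0,
                        noise_sd_flow = 0)
    sum(generate_breathing(cfg)$truth$kind == "apnea")
  }, 0)
  ci <- rate + c(-1, 1) * 1.96 * sqrt(rate / length(counts))
  expect_gt(mean(counts), ci[1L])
  expect_lt(mean(counts), ci[2L])
})

test_that("truth apneas are flow-silent for their full duration", {
  cfg <- synth_config(duration = 1200, seed = 5, apnea_rate = 15,
                      sigh_rate = 0, hypopnea_rate = 0)
  rec <- generate_breathing(cfg)
  th <- 0.05 * stats::quantile(abs(rec$flow$samples), 0.95, names = FALSE)
  ap <- rec$truth[rec$truth$kind == "apnea", ]
  expect_gt(nrow(ap), 0L)
  for (i in seq_len(nrow(ap))) {
    seg <- slice_trace(rec$flow, ap$onset[i] + 0.005,
                       ap$onset[i] + ap$duration[i] - 0.005)
    expect_lt(max(abs(seg$samples)), th)
  }
})

test_that("impossible event loads are rejected", {
  cfg <- synth_config(duration = 600, seed = 1, apnea_rate = 2000)
  expect_error(generate_breathing(cfg), "event rates too high")
})

test_that("unmodulated pressure gives exact beat spacing and programmed pressures", {
  cfg <- synth_config(duration = 60, seed = 2, hr = 300, sbp = 120, dbp = 80,
                      lf_mod = list(freq = 0.3, depth = 0),
                      hf_mod = list(depth = 0), rr_noise_sd = 0,
                      noise_sd_pressure = 0)
  pr <- generate_pressure(cfg, NULL)
  expect_equal(diff(pr$beats$time), rep(0.2, nrow(pr$beats) - 1L),
               tolerance = 1e-12)
  beats <- detect_beats(pr$pressure)
  b <- beats$beats
  expect_equal(stats::median(b$pp), 40, tolerance = 0.5)
  expect_equal(stats::median(b$sbp), 120, tolerance = 0.5)
  expect_error(synth_config(sbp = 80, dbp = 90), "sbp > dbp")
})

test_that("HF-only modulation concentrates tachogram power in the HF band", {
  cfg <- synth_config(duration = 660, seed = 3,
                      lf_mod = list(freq = 0.3, depth = 0),
                      hf_mod = list(depth = 4), rr_noise_sd = 0.2)
  pr <- generate_pressure(cfg, NULL)
  bt <- beats_from_times(pr$beats$time)
  bp <- band_powers(psd_ar(build_tachogram(bt), 600, 60))
  expect_gte(bp$hf_nu, 95)
})

test_that("chemo sessions track first-order targets and order by gain", {
  still <- gas_protocol(0, 900, fio2 = 21, fico2 = 0.03)
  cfg <- synth_config(seed = 7, apnea_rate = 0, hypopnea_rate = 0,
                      sigh_rate = 0)
  ses <- generate_chemo_session(cfg, still)
  ve <- ses$breaths$ve
  expect_lt(diff(range(ve)) / mean(ve), 0.01)   # stationary under normoxia

  prot <- gas_protocol(c(0, 600), c(600, 1500), fio2 = c(21, 21),
                       fico2 = c(0.03, 7))
  plateau <- function(g) {
    cfg <- synth_config(seed = 7, hcvr_gain = g, apnea_rate = 0,
                        hypopnea_rate = 0, sigh_rate = 0)
    s <- generate_chemo_session(cfg, prot)
    utils::tail(s$breaths$ve, 50L)
  }
  base <- cfg$vt * cfg$rf
  p4 <- plateau(4)
  # first-order closed form: plateau VE = baseline + gain x FICO2
  expect_equal(mean(p4), base + 4 * 7, tolerance = 0.02 * (base + 28))
  expect_lt(mean(p4), mean(plateau(6)))
  expect_error(generate_chemo_session(cfg, data.frame()), "protocol")
})

test_that("AR(1) interval simulator hits its closed-form Poincare targets", {
  iv <- simulate_intervals(20000, 700, sd_ms = 50, ar1 = 0.4, seed = 1)
  expect_equal(stats::sd(iv), 50, tolerance = 0.03 * 50)
  expect_equal(stats::cor(iv[-1L], iv[-length(iv)]), 0.4, tolerance = 0.05)
})
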