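test_that("beat detection matches generator truth and per-beat pressures", {
  cfg <- synth_config(duration = 600, seed = 14)
  pr <- generate_pressure(cfg, NULL)
  beats <- detect_beats(pr$pressure)
  expect_equal(nrow(beats$beats), nrow(pr$beats))   # exact beat count
  b <- beats$beats
  expect_equal(60000 / mean(b$rr, na.rm = TRUE), cfg$hr, tolerance = 0.01 * cfg$hr)
  expect_equal(b$pp, b$sbp - b$dbp)
  expect_true(all(diff(b$time) > 0))
  # rr agrees with ground truth to within ~one sample at 500 Hz; the first
  # cycle is excluded (the trace starts mid-beat, a boundary effect)
  err <- b$rr[-(1:2)] - pr$beats$rr[-(1:2)]
  expect_lt(max(abs(err)), 2000 / cfg$fs_pressure + 1)
  low <- signal_trace(b$sbp, 1, "mmHg")
  expect_error(detect_beats(low), "too low")
})

test_that("MAP rule options behave as documented", {
  cfg <- synth_config(duration = 60, seed = 3, noise_sd_pressure = 0,
                      lf_mod = list(freq = 0.3, depth = 0),
                      hf_mod = list(depth = 0), rr_noise_sd = 0)
  pr <- generate_pressure(cfg, NULL)
  wf <- detect_beats(pr$pressure)$beats
  third <- detect_beats(pr$pressure, map_rule = "third")$beats
  expect_equal(third$map, third$dbp + third$pp / 3)
  expect_false(isTRUE(all.equal(wf$map, third$map)))
})

test_that("Kalman smoothing is a fixed point on constant RR and contracts noise", {
  times <- cumsum(rep(0.2, 200))
  cons <- beats_from_times(times)
  sm <- smooth_hr(cons)
  expect_equal(sm$beats$rr, cons$beats$rr, tolerance = 1e-9)

  set.seed(7)
  noisy_t <- cumsum(c(0.2, 0.2 + stats::rnorm(400, 0, 0.004)))
  noisy <- beats_from_times(noisy_t)
  smn <- smooth_hr(noisy)
  expect_equal(nrow(smn$beats), nrow(noisy$beats))   # beat count preserved
  expect_lt(stats::var(smn$beats$rr[-1L]), stats::var(noisy$beats$rr[-1L]))
})

test_that("an 8-SD RR outlier is attenuated below 25% of its raw deviation", {
  set.seed(12)
  rr <- 200 + stats::rnorm(300, 0, 2)
  rr[150] <- 200 + 16    # 8 SD
  times <- cumsum(rr) / 1000
  beats <- beats_from_times(times)
  beats$beats$rr <- c(NA, rr[-1L])
  sm <- smooth_hr(beats)
  raw_dev <- abs(rr[150] - 200)
  smooth_dev <- abs(sm$beats$rr[150] - 200)
  expect_lt(smooth_dev, 0.25 * raw_dev)
})

test_that("fixed-variance smoothing matches a penalized-regression oracle", {
  # the RTS-smoothed local level equals the minimizer of
  # sum (y - a)^2 / r + sum (diff a)^2 / q  (diffuse initial level), a
  # banded least-squares problem solved here directly with solve()
  set.seed(31)
  n <- 250L
  level <- cumsum(stats::rnorm(n, 0, 0.5))
  y <- 200 + level + stats::rnorm(n, 0, 3)
  beats <- beats_from_times(cumsum(rep(0.2, n + 1L)))
  beats$beats$rr <- c(NA, y)
  q <- 0.25; r <- 9
  mine <- smooth_hr(beats, variances = c(q, r))$beats$rr[-1L]
  d <- diff(diag(n))
  a_hat <- solve(diag(n) / r + crossprod(d) / q, y / r)
  mid <- 20:(n - 20L)
  expect_equal(mine[mid], a_hat[mid], tolerance = 1e-6)
})

test_that("Teichholz volumes, EF, FS and the volume-overload criterion", {
  eq <- teichholz(0.5, 0.5)
  expect_equal(eq$sv, 0)
  expect_equal(eq$ef, 0)
  expect_equal(eq$fs, 0)

  t1 <- teichholz(0.60, 0.30)
  expect_equal(t1$lvedv, 7 * 0.216 / 3.0 * 1000, tolerance = 1e-9)  # 504 uL
  expect_equal(t1$lvesv, 70, tolerance = 1e-9)
  expect_equal(t1$sv, 434, tolerance = 1e-9)
  expect_equal(t1$ef, 100 * 434 / 504, tolerance = 1e-9)            # 86.1%
  expect_equal(t1$fs, 50)

  # V(D) strictly increasing; FS scale-free while EF is not
  d <- seq(0.2, 1.2, by = 0.1)
  v <- vapply(d, function(x) teichholz(x, x / 2)$lvedv, 0)
  expect_true(all(diff(v) > 0))
  expect_equal(teichholz(1.2, 0.6)$fs, teichholz(0.6, 0.3)$fs)

  ref <- list(lvedv = 273.7, sv = 208.1)
  expect_true(teichholz(0.60, 0.30, reference = ref)$hf_criterion)
  expect_false(teichholz(0.45, 0.25, reference = ref)$hf_criterion)
  expect_error(teichholz(0.3, 0.6), "lvesd")
  expect_error(teichholz(-1, 0.5), "positive")
})
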