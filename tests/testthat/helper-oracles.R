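# Shared fixtures and independent oracles.

# Match truth to detected events of one kind by onset proximity.
match_events <- function(truth, det, kind, tol) {
  tt <- truth$onset[truth$kind == kind]
  dd <- det$onset[det$kind == kind]
  used <- rep(FALSE, length(dd))
  tp <- 0L
  for (o in tt) {
    j <- which(!used & abs(dd - o) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, n_truth = length(tt), n_det = length(dd))
}

# Brute-force Poincare oracle: rotate the lag-1 scatter by 45 degrees and
# take population SDs along the rotated axes.
poincare_oracle <- function(x) {
  n <- length(x)
  p <- cbind(x[-n], x[-1L])
  rot <- matrix(c(cos(pi / 4), -sin(pi / 4), sin(pi / 4), cos(pi / 4)), 2L)
  q <- p %*% t(rot)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  # column 2 is the difference (perpendicular) axis, column 1 the identity
  c(sd1 = pop_sd(q[, 2L]), sd2 = pop_sd(q[, 1L]))
}

# Build a flow trace from explicit breath shapes: half-sine inspiration and
# a caller-supplied expiratory shape function exp_fun(t_local, te) >= 0.
build_flow <- function(n_breaths, ti, te, amp, exp_fun, fs = 1000,
                       pause = 0) {
  period <- ti + te + pause
  total <- n_breaths * period + 0.5
  t <- seq(0, total, by = 1 / fs)
  x <- numeric(length(t))
  for (b in seq_len(n_breaths) - 1L) {
    on <- b * period
    ph <- t - on
    ins <- ph >= 0 & ph < ti
    x[ins] <- x[ins] + amp * sin(pi * ph[ins] / ti)
    ex <- ph >= ti & ph < ti + te
    x[ex] <- x[ex] - exp_fun(ph[ex] - ti, te)
  }
  signal_trace(x, fs, "mL/s", label = "synthetic")
}

# Construct a beat series directly from beat times and per-beat SBP.
beats_from_times <- function(times, sbp = 120, dbp = 80) {
  sbp <- rep_len(sbp, length(times))
  beat_series(data.frame(time = times, rr = c(NA, diff(times)) * 1000,
                         sbp = sbp, dbp = dbp, map = (sbp + 2 * dbp) / 3,
                         pp = sbp - dbp))
}

# Beat series with sinusoidally modulated RR (ms) sampled at beat onsets.
modulated_beats <- function(duration, mean_rr_ms, mods = list(),
                            noise_ms = 0, seed = 1L) {
  set.seed(seed)
  t <- 0
  times <- numeric(0)
  while (t < duration) {
    times <- c(times, t)
    rr <- mean_rr_ms
    for (m in mods) rr <- rr + m$depth * sin(2 * pi * m$freq * t)
    rr <- rr + stats::rnorm(1L, 0, noise_ms)
    t <- t + rr / 1000
  }
  beats_from_times(times)
}

# Mean tapered-subwindow variance, the Parseval reference for psd_ar.
tapered_variance <- function(x, rate, window_s, subwindow_s) {
  n <- round(window_s * rate)
  m <- round(subwindow_s * rate)
  w <- hann_test(m)
  w <- w / sqrt(mean(w^2))
  starts <- seq(1L, n - m + 1L, by = m %/% 2L)
  mean(vapply(starts, function(s) {
    seg <- x[s:(s + m - 1L)]
    seg <- (seg - mean(seg)) * w
    mean(seg^2)
  }, 0))
}

hann_test <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

# Periodogram argmax, an FFT oracle independent of the AR/Welch code paths.
welch_peak <- function(trace, fmin = 0.02, fmax = 0.6) {
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  p <- Mod(stats::fft(x)[seq_len(n %/% 2L)])^2
  f <- (seq_len(n %/% 2L) - 1L) * trace$rate / n
  sel <- f >= fmin & f <= fmax
  f[sel][which.max(p[sel])]
}

pop_sd_test <- function(v) sqrt(mean((v - mean(v))^2))
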