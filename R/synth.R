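# Synthetic coupled respiratory-flow / arterial-pressure recordings with
# exact ground truth.
#
# The stated world: eupneic rat breathing as an inspiratory half-sine
# followed by an exponential expiration (two parameters give analytic
# control of VT and of the late/early expiratory area ratio E2/E1),
# AR(1)-correlated breath-interval jitter (maps monotonically onto the
# Poincare SD2/SD1 asymmetry), lognormal per-breath tidal volume with a
# programmed coefficient of variation, homogeneous-Poisson insertion of
# apneas / hypopneas / sighs (with post-sigh apneas), a pulse waveform with
# LF and respiration-locked HF heart-period modulation, a per-beat systolic
# offset proportional to the tidal-volume deviation (coupling gain), and a
# first-order minute-ventilation response to inspired-gas steps.

#' Configuration for the synthetic recording generator
#'
#' Defaults are the resting ("Sham-like") values of the conscious rat:
#' 85 breaths/min, VT 0.31 mL/100 g, 250 g body mass, breath-interval SD
#' 45 ms with AR(1) coefficient 0.4 (long-term variability SD2 ~ 53 ms),
#' VT coefficient of variation 8.7 %, apneas 3.4/h, hypopneas 1.2/h, sighs
#' 12.8/h with post-sigh apnea probability 0.94, E2/E1 0.68, heart rate
#' 298 beats/min with SBP/DBP 124/88 mmHg, LF heart-period modulation at
#' 0.3 Hz, HF modulation locked to the respiratory rate, LF/HF band-power
#' ratio ~ 1.1, no VT-to-SBP coupling, HCVR gain 4.1 and HVR gain 1.0
#' mL·100 g^-1·min^-1 per percent.
#'
#' @param duration recording length (s)
#' @param rf respiratory frequency (breaths/min, > 0)
#' @param vt tidal volume (mL/100 g)
#' @param body_mass body mass (g)
#' @param fs_flow flow sampling rate (Hz); 1000 by default
#' @param fs_pressure pressure sampling rate (Hz); 500 by default
#' @param interval_jitter_sd marginal SD of breath-interval jitter (ms)
#' @param interval_ar1 AR(1) coefficient of the jitter, in [0, 1)
#' @param vt_cv coefficient of variation of per-breath VT (%)
#' @param apnea_rate,hypopnea_rate,sigh_rate programmed event rates (events/h)
#' @param post_sigh_apnea_prob probability a sigh is followed by an apnea
#' @param e2e1_target noise-free late/early expiratory area ratio (> 0)
#' @param ti_frac inspiratory fraction of the breath cycle
#' @param hr heart rate (beats/min)
#' @param sbp,dbp systolic / diastolic pressure (mmHg, sbp > dbp)
#' @param lf_mod list(freq, depth): LF heart-period modulation, freq in
#'   0.04-0.6 Hz, depth in ms
#' @param hf_mod list(depth): HF modulation depth in ms, locked to `rf`
#' @param rr_noise_sd white heart-period noise (ms)
#' @param coupling_gain per-beat systolic offset, mmHg per mL of VT deviation
#' @param hcvr_gain steady-state minute-ventilation gain per % FICO2
#' @param hvr_gain gain per % FIO2 decrease below 21
#' @param tau_resp ventilatory first-order time constant (s)
#' @param noise_sd_flow,noise_sd_pressure additive white noise SD per channel
#' @param seed integer seed; one global seed drives independent substreams
#'   per channel
#' @return a validated list of class `synth_config`
#' @export
synth_config <- function(duration = 3600, rf = 85, vt = 0.31, body_mass = 250,
                         fs_flow = 1000, fs_pressure = 500,
                         interval_jitter_sd = 45, interval_ar1 = 0.4,
                         vt_cv = 8.7,
                         apnea_rate = 3.4, hypopnea_rate = 1.2,
                         sigh_rate = 12.8, post_sigh_apnea_prob = 0.94,
                         e2e1_target = 0.68, ti_frac = 0.4,
                         hr = 298, sbp = 124, dbp = 88,
                         lf_mod = list(freq = 0.3, depth = 3.15),
                         hf_mod = list(depth = 3),
                         rr_noise_sd = 0.5,
                         coupling_gain = 0,
                         hcvr_gain = 4.1, hvr_gain = 1.0, tau_resp = 30,
                         noise_sd_flow = 0.05, noise_sd_pressure = 0.5,
                         seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(duration > 0, rf > 0, hr > 0, vt > 0, body_mass > 0)
    stopifnot(apnea_rate >= 0, hypopnea_rate >= 0, sigh_rate >= 0)
    stopifnot(post_sigh_apnea_prob >= 0, post_sigh_apnea_prob <= 1)
    stopifnot(interval_ar1 >= 0, interval_ar1 < 1, interval_jitter_sd >= 0)
    stopifnot(e2e1_target > 0, ti_frac > 0, ti_frac < 1)
    stopifnot(sbp > dbp)
    if (lf_mod$depth > 0 &&
        (lf_mod$freq < 0.04 || lf_mod$freq > 0.6))
      stopf("lf_mod$freq must lie in the LF band 0.04-0.6 Hz")
  })
  class(cfg) <- "synth_config"
  cfg
}

# AR(1) jitter (seconds) with exact stationary marginal SD `sd_ms`.
ar1_jitter <- function(n, sd_ms, phi) {
  if (sd_ms <= 0) return(numeric(n))
  sd_s <- sd_ms / 1000
  innov <- stats::rnorm(n, 0, sd_s * sqrt(1 - phi^2))
  j0 <- stats::rnorm(1, 0, sd_s)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = j0))
}

# Lognormal multiplicative VT noise with mean exactly 1 and CV = cv.
vt_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# Build the per-breath schedule for a stationary recording: nominal breath
# cycles tile the time axis; scored events are inserted at Poisson counts on
# breaths separated by >= 18 cycles so detection references stay clean.
schedule_breaths <- function(cfg) {
  T0 <- 60 / cfg$rf
  dur <- cfg$duration
  n_est <- ceiling(dur / T0) + 30L
  Ti <- pmax(T0 + ar1_jitter(n_est, cfg$interval_jitter_sd, cfg$interval_ar1),
             0.3 * T0)
  vt_ml <- cfg$vt * cfg$body_mass / 100
  vt <- vt_ml * vt_noise(n_est, cfg$vt_cv / 100)
  kind <- rep("normal", n_est)
  gap <- numeric(n_est)
  psa <- logical(n_est)

  lambda <- c(apnea = cfg$apnea_rate, sigh = cfg$sigh_rate,
              hypopnea = cfg$hypopnea_rate) * dur / 3600
  counts <- stats::rpois(3L, lambda)
  names(counts) <- names(lambda)
  expected_event_s <- counts[["apnea"]] * 4.4 * T0 +
    counts[["sigh"]] * (1 + cfg$post_sigh_apnea_prob * 6.2) * T0 +
    counts[["hypopnea"]] * T0
  if (expected_event_s > 0.5 * dur)
    stopf("event rates too high: > 50%% of recording time in events")

  nominal_onset <- cumsum(c(0, Ti[-n_est]))
  eligible <- which(nominal_onset > 30 & nominal_onset < dur - 10 - 7 * T0)
  picks <- integer(0)
  pool <- eligible
  for (k in seq_len(sum(counts))) {
    if (!length(pool))
      stopf("event rates too high: cannot place events %d breaths apart", 18L)
    p <- pool[sample.int(length(pool), 1L)]
    picks <- c(picks, p)
    pool <- pool[abs(pool - p) > 18L]
  }
  kinds_assigned <- rep(names(counts), counts)
  for (k in seq_along(picks)) {
    i <- picks[k]
    switch(kinds_assigned[k],
      apnea = { gap[i] <- stats::runif(1, 3.3, 5.5) * T0 },
      sigh = {
        kind[i] <- "sigh"; vt[i] <- vt[i] * 1.9
        if (stats::runif(1) < cfg$post_sigh_apnea_prob) {
          gap[i] <- stats::runif(1, 5.5, 7.0) * T0
          psa[i] <- TRUE
        }
      },
      hypopnea = { kind[i] <- "hypopnea"; vt[i] <- vt[i] * 0.4 })
  }

  onset <- cumsum(c(0, Ti[-n_est] + gap[-n_est]))
  keep <- onset + Ti <= dur
  df <- data.frame(onset = onset[keep], dur = Ti[keep],
                   ti = cfg$ti_frac * Ti[keep], te = (1 - cfg$ti_frac) * Ti[keep],
                   vt = vt[keep], kind = kind[keep], gap_after = gap[keep],
                   post_sigh = psa[keep], stringsAsFactors = FALSE)
  df
}

schedule_truth <- function(sched) {
  ev_kind <- character(0); ev_on <- numeric(0); ev_dur <- numeric(0)
  end <- sched$onset + sched$dur
  hyp <- sched$kind == "hypopnea"
  sig <- sched$kind == "sigh"
  apn <- sched$gap_after > 0 & !sched$post_sigh
  psa <- sched$post_sigh
  add <- function(kind, onset, duration) {
    ev_kind <<- c(ev_kind, rep(kind, length(onset)))
    ev_on <<- c(ev_on, onset); ev_dur <<- c(ev_dur, duration)
  }
  add("hypopnea", sched$onset[hyp], sched$dur[hyp])
  add("sigh", sched$onset[sig], sched$dur[sig])
  add("apnea", end[apn], sched$gap_after[apn])
  add("post_sigh_apnea", end[psa], sched$gap_after[psa])
  annotation_table(ev_kind, ev_on, ev_dur)
}

# Render the airflow waveform for a breath schedule: half-sine inspiration
# of amplitude vt*pi/(2*ti); exponential expiration with time constant
# tau = -te / (2 log r) so the noise-free E2/E1 equals r (constant flow for
# r = 1), amplitude normalized so expired volume equals VT.
render_flow <- function(sched, cfg) {
  fs <- cfg$fs_flow
  n <- round(cfg$duration * fs)
  x <- if (cfg$noise_sd_flow > 0) stats::rnorm(n, 0, cfg$noise_sd_flow)
       else numeric(n)
  r <- cfg$e2e1_target
  for (b in seq_len(nrow(sched))) {
    on <- sched$onset[b]; ti <- sched$ti[b]; te <- sched$te[b]
    vtb <- sched$vt[b]
    a <- vtb * pi / (2 * ti)
    i0 <- floor(on * fs) + 1L
    i1 <- min(floor((on + ti) * fs) + 1L, n)
    if (i1 > i0) {
      tt <- ((i0:i1) - 1L) / fs - on
      seg <- a * sin(pi * tt / ti)
      seg[tt < 0 | tt > ti] <- 0
      x[i0:i1] <- x[i0:i1] + seg
    }
    j0 <- i1 + 1L
    j1 <- min(floor((on + ti + te) * fs) + 1L, n)
    if (j1 >= j0) {
      tt <- ((j0:j1) - 1L) / fs - (on + ti)
      if (abs(r - 1) < 1e-12) {
        seg <- rep(vtb / te, length(tt))
      } else {
        tau <- -te / (2 * log(r))
        bamp <- vtb / (tau * (1 - exp(-te / tau)))
        seg <- bamp * exp(-tt / tau)
      }
      seg[tt < 0 | tt > te] <- 0
      x[j0:j1] <- x[j0:j1] - seg
    }
  }
  signal_trace(x, fs, "mL/s", label = "flow")
}

#' Generate a synthetic airflow recording with ground-truth annotations
#'
#' @param config a [synth_config()]
#' @return list with `flow` (a [signal_trace()] in mL/s), `truth` (an
#'   [annotation_table()] of every inserted event with exact onset and
#'   duration) and `breaths` (the per-breath ground-truth schedule)
#' @examples
#' rec <- generate_breathing(synth_config(duration = 60, seed = 7))
#' rec$flow
#' @export
generate_breathing <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "breathing"))
  sched <- schedule_breaths(config)
  truth <- schedule_truth(sched)
  list(flow = render_flow(sched, config), truth = truth, breaths = sched)
}

# Heart-period sequence: 60/hr plus LF sinusoid, respiration-locked HF
# sinusoid and white noise, all in seconds.
simulate_beat_times <- function(cfg, duration) {
  mean_rr <- 60 / cfg$hr
  n_est <- ceiling(duration / mean_rr) + 20L
  e <- if (cfg$rr_noise_sd > 0) stats::rnorm(n_est, 0, cfg$rr_noise_sd / 1000)
       else numeric(n_est)
  f_hf <- cfg$rf / 60
  times <- numeric(n_est)
  t <- 0; k <- 0L
  while (t < duration && k < n_est) {
    k <- k + 1L
    times[k] <- t
    rr <- mean_rr +
      (cfg$lf_mod$depth / 1000) * sin(2 * pi * cfg$lf_mod$freq * t) +
      (cfg$hf_mod$depth / 1000) * sin(2 * pi * f_hf * t) + e[k]
    t <- t + max(rr, 0.2 * mean_rr)
  }
  times[seq_len(k)]
}

#' Generate a synthetic arterial-pressure recording
#'
#' Periodic pulse waveform between `dbp` and `sbp` at 500 Hz (default); the
#' heart period carries LF and respiration-locked HF modulation, and when
#' `coupling_gain > 0` each beat's systolic level is offset by
#' `coupling_gain` times the breath-by-breath tidal-volume deviation.
#'
#' @param config a [synth_config()]
#' @param breaths optional per-breath schedule (from [generate_breathing()])
#'   supplying VT deviations for the coupling; required if
#'   `config$coupling_gain > 0`
#' @param duration recording length (s); defaults to `config$duration`
#' @return list with `pressure` (a [signal_trace()] in mmHg) and `beats`
#'   (ground-truth data frame: `time` (s), `rr` (ms), `sbp` (mmHg))
#' @export
generate_pressure <- function(config, breaths = NULL, duration = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$coupling_gain > 0 && is.null(breaths))
    stopf("coupling_gain > 0 requires the breathing schedule")
  duration <- duration %||% config$duration
  set.seed(substream_seed(config$seed, "pressure"))
  bt <- simulate_beat_times(config, duration)
  nb <- length(bt)
  sbp_b <- rep(config$sbp, nb)
  if (config$coupling_gain > 0) {
    vt_dev <- breaths$vt - mean(breaths$vt)
    idx <- findInterval(bt, breaths$onset)
    idx[idx < 1L] <- 1L
    sbp_b <- sbp_b + config$coupling_gain * vt_dev[idx]
  }
  fs <- config$fs_pressure
  n <- round(duration * fs)
  t <- (0:(n - 1L)) / fs
  bi <- findInterval(t, bt)
  bi[bi < 1L] <- 1L
  rr_b <- c(diff(bt), 60 / config$hr)
  u <- (t - bt[bi]) / rr_b[bi]
  u <- pmin(pmax(u, 0), 1)
  pulse <- ifelse(u < 0.25, 0.5 - 0.5 * cos(4 * pi * u),
                  0.5 + 0.5 * cos(pi * (u - 0.25) / 0.75))
  p <- config$dbp + (sbp_b[bi] - config$dbp) * pulse
  if (config$noise_sd_pressure > 0)
    p <- p + stats::rnorm(n, 0, config$noise_sd_pressure)
  list(pressure = signal_trace(p, fs, "mmHg", label = "pressure"),
       beats = data.frame(time = bt, rr = c(NA, diff(bt)) * 1000, sbp = sbp_b))
}

#' Generate a gas-challenge session with a first-order ventilatory response
#'
#' Minute ventilation tracks, with time constant `tau_resp`, the target
#' `baseline + hcvr_gain * FICO2 + hvr_gain * max(0, 21 - FIO2)`; the
#' response is realized by scaling respiratory frequency and tidal volume
#' equally (each by the square root of the ventilation scale).
#'
#' @param config a [synth_config()]
#' @param protocol a [gas_protocol()]; its last segment end sets the duration
#' @return list with `bundle` (a [recording_bundle()]), `truth` (events),
#'   and `breaths` (per-breath schedule including the realized minute
#'   ventilation `ve` in mL·100 g^-1·min^-1)
#' @export
generate_chemo_session <- function(config, protocol) {
  stopifnot(inherits(config, "synth_config"))
  if (!inherits(protocol, "gas_protocol") || nrow(protocol) == 0L)
    stopf("protocol empty")
  set.seed(substream_seed(config$seed, "chemo"))
  dur <- max(protocol$end)
  T0 <- 60 / config$rf
  n_est <- ceiling(3 * dur / T0) + 30L
  jit <- ar1_jitter(n_est, config$interval_jitter_sd, config$interval_ar1)
  vtn <- vt_noise(n_est, config$vt_cv / 100)
  u_ev <- stats::runif(n_est)
  ve_base <- config$vt * config$rf
  gas0 <- protocol_at(protocol, 0)
  target_at <- function(tt) {
    g <- protocol_at(protocol, tt)
    ve_base + config$hcvr_gain * g$fico2 + config$hvr_gain * pmax(0, 21 - g$fio2)
  }
  ve <- target_at(0)
  p_ev <- (config$apnea_rate + config$hypopnea_rate + config$sigh_rate) / 3600
  w_ap <- if (p_ev > 0) config$apnea_rate / (p_ev * 3600) else 0
  w_hy <- if (p_ev > 0) config$hypopnea_rate / (p_ev * 3600) else 0
  onset <- ti <- te <- dvt <- gapv <- numeric(n_est)
  kindv <- character(n_est); psav <- logical(n_est); vev <- numeric(n_est)
  t <- 0; k <- 0L; last_ev <- -1e9; prev_T <- T0
  vt_ml <- config$vt * config$body_mass / 100
  while (t < dur && k < n_est) {
    k <- k + 1L
    tgt <- target_at(t)
    ve <- tgt + (ve - tgt) * exp(-prev_T / config$tau_resp)
    s <- ve / ve_base
    Tk <- max(60 / (config$rf * sqrt(s)) + jit[k], 0.3 * T0)
    onset[k] <- t; ti[k] <- config$ti_frac * Tk; te[k] <- (1 - config$ti_frac) * Tk
    dvt[k] <- vt_ml * sqrt(s) * vtn[k]
    kindv[k] <- "normal"; vev[k] <- ve
    gapk <- 0
    if (u_ev[k] < p_ev * Tk && (k - last_ev) > 18L && t > 30) {
      u2 <- u_ev[k] / (p_ev * Tk)
      if (u2 < w_ap) {
        gapk <- stats::runif(1, 3.3, 5.5) * Tk
      } else if (u2 < w_ap + w_hy) {
        kindv[k] <- "hypopnea"; dvt[k] <- dvt[k] * 0.4
      } else {
        kindv[k] <- "sigh"; dvt[k] <- dvt[k] * 1.9
        if (stats::runif(1) < config$post_sigh_apnea_prob) {
          gapk <- stats::runif(1, 5.5, 7.0) * Tk
          psav[k] <- TRUE
        }
      }
      last_ev <- k
    }
    gapv[k] <- gapk
    prev_T <- Tk + gapk
    t <- t + prev_T
  }
  keep <- seq_len(k)
  keep <- keep[onset[keep] + ti[keep] + te[keep] <= dur]
  sched <- data.frame(onset = onset[keep], dur = ti[keep] + te[keep],
                      ti = ti[keep], te = te[keep], vt = dvt[keep],
                      kind = kindv[keep], gap_after = gapv[keep],
                      post_sigh = psav[keep], ve = vev[keep],
                      stringsAsFactors = FALSE)
  cfg2 <- config
  cfg2$duration <- dur
  flow <- render_flow(sched, cfg2)
  list(bundle = recording_bundle(flow, protocol = protocol,
                                 body_mass = config$body_mass),
       truth = schedule_truth(sched), breaths = sched)
}

#' Simulate an AR(1) breath-interval series
#'
#' Convenience generator for variability studies: a stationary AR(1) series
#' with marginal SD `sd_ms` and lag-1 coefficient `ar1`, for which the
#' population Poincare indices are `SD1 = sd_ms * sqrt(1 - ar1)` and
#' `SD2 = sd_ms * sqrt(1 + ar1)`.
#'
#' @param n number of intervals
#' @param mean_ms mean interval (ms)
#' @param sd_ms marginal SD (ms)
#' @param ar1 lag-1 coefficient in [0, 1)
#' @param seed integer seed
#' @return numeric vector of intervals (ms)
#' @export
simulate_intervals <- function(n, mean_ms, sd_ms, ar1 = 0, seed = 1L) {
  set.seed(substream_seed(seed, "breathing"))
  mean_ms + 1000 * ar1_jitter(n, sd_ms, ar1)
}
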