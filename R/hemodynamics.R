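# Arterial-pressure beat detection via dP/dt, Kalman-smoothed heart rate,
# and Teichholz echocardiographic derivations.

#' Construct a beat series
#'
#' @param beats data frame with columns `time` (s, strictly increasing),
#'   `rr` (ms; NA for the first beat), `sbp`, `dbp`, `map`, `pp` (mmHg)
#' @return an object of class `beat_series`
#' @export
beat_series <- function(beats) {
  need <- c("time", "rr", "sbp", "dbp", "map", "pp")
  if (!all(need %in% names(beats)))
    stopf("beats must have columns: %s", paste(need, collapse = ", "))
  if (is.unsorted(beats$time, strictly = TRUE))
    stopf("beat times must be strictly increasing")
  rr <- beats$rr[-1L]
  if (any(!is.finite(rr)) || any(rr <= 0)) stopf("rr must be positive")
  if (max(abs(beats$pp - (beats$sbp - beats$dbp))) > 1e-6)
    stopf("pp must equal sbp - dbp")
  rownames(beats) <- NULL
  structure(list(beats = beats), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  b <- x$beats
  cat(sprintf("<beat_series> %d beats, mean HR %.1f beats/min\n",
              nrow(b), 60000 / mean(b$rr, na.rm = TRUE)))
  invisible(x)
}

#' Detect beats from an arterial-pressure waveform
#'
#' Beats are located at maxima of dP/dt (central differences after a 20-Hz
#' low-pass) exceeding `peak_frac` of the running 95th percentile of dP/dt,
#' with a refractory period.  Per-beat pressures are taken over the cycle
#' from one beat to the next: SBP = maximum, DBP = minimum, MAP = time
#' average of the waveform (set `map_rule = "third"` for DBP + PP/3),
#' PP = SBP - DBP.  RR intervals come from successive beat times; the first
#' beat's RR is NA.
#'
#' @param pressure a [signal_trace()] in mmHg sampled at >= 100 Hz
#' @param lowpass_hz low-pass cutoff before differentiation (Hz)
#' @param peak_frac dP/dt threshold as a fraction of its running 95th
#'   percentile
#' @param refractory_s minimum separation between beats (s)
#' @param map_rule `"waveform"` (time average, default) or `"third"`
#' @return a [beat_series()]
#' @export
detect_beats <- function(pressure, lowpass_hz = 20, peak_frac = 0.3,
                         refractory_s = 0.08,
                         map_rule = c("waveform", "third")) {
  stopifnot(inherits(pressure, "signal_trace"))
  map_rule <- match.arg(map_rule)
  fs <- pressure$rate
  if (fs < 100) stopf("pressure sampling rate too low (< 100 Hz)")
  x <- pressure$samples
  n <- length(x)
  xf <- fir_lowpass(x, fs, lowpass_hz)
  dpdt <- c(0, (xf[-(1:2)] - xf[1:(n - 2L)]) * fs / 2, 0)
  # running 95th percentile over 10-s chunks
  chunk <- max(1L, round(10 * fs))
  ci <- ceiling(seq_len(n) / chunk)
  p95 <- stats::ave(dpdt, ci, FUN = function(v)
    stats::quantile(v, 0.95, names = FALSE))
  thr <- peak_frac * p95
  is_peak <- c(FALSE, dpdt[2:(n - 1L)] > dpdt[1:(n - 2L)] &
                      dpdt[2:(n - 1L)] >= dpdt[3:n], FALSE) & dpdt > thr
  pk <- which(is_peak)
  if (!length(pk)) stopf("no beats found")
  refr <- round(refractory_s * fs)
  keep <- pk[1L]
  last <- pk[1L]
  for (p in pk[-1L]) {
    if (p - last >= refr) { keep <- c(keep, p); last <- p }
  }
  if (length(keep) < 2L) stopf("no beats found")
  bt <- pressure$start_time + (keep - 1L) / fs
  nb <- length(keep)
  bounds <- c(keep, n + 1L)
  sbp <- dbp <- mp <- numeric(nb)
  for (b in seq_len(nb)) {
    seg <- x[bounds[b]:(bounds[b + 1L] - 1L)]
    sbp[b] <- max(seg); dbp[b] <- min(seg); mp[b] <- mean(seg)
  }
  if (map_rule == "third") mp <- dbp + (sbp - dbp) / 3
  beat_series(data.frame(time = bt, rr = c(NA, diff(bt)) * 1000,
                         sbp = sbp, dbp = dbp, map = mp, pp = sbp - dbp))
}

# Local-level (random-walk) Kalman filter + RTS fixed-interval smoother.
# q = process (level) variance, r = observation variance, per time step.
kalman_level_smooth <- function(y, q, r) {
  n <- length(y)
  a_f <- p_f <- a_p <- p_p <- numeric(n)
  a <- y[1L]; p <- 1e12 * (r + q)    # diffuse initial level
  for (t in seq_len(n)) {
    a_p[t] <- a; p_p[t] <- p
    k <- p / (p + r)
    a <- a + k * (y[t] - a)
    p <- (1 - k) * p
    a_f[t] <- a; p_f[t] <- p
    p <- p + q
  }
  a_s <- a_f
  for (t in (n - 1L):1L) {
    g <- p_f[t] / (p_f[t] + q)
    a_s[t] <- a_f[t] + g * (a_s[t + 1L] - a_p[t + 1L])
  }
  a_s
}

#' Kalman-smooth the RR series of a beat series
#'
#' The RR intervals are modelled as a local-level (random-walk) state-space
#' model and smoothed by fixed-interval (RTS) smoothing.  By default the
#' process/observation variances are estimated by maximum likelihood via
#' [stats::StructTS()]; pass `variances = c(level, observation)` to fix
#' them.  Beat count is preserved; only `rr` is replaced.
#'
#' @param beats a [beat_series()] with at least 10 beats
#' @param variances optional `c(level, observation)` variance pair (ms^2)
#' @return a [beat_series()] with smoothed `rr`
#' @export
smooth_hr <- function(beats, variances = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$beats$rr
  ok <- which(is.finite(rr))
  if (length(ok) < 10L) stopf("need at least 10 beats")
  y <- rr[ok]
  if (stats::sd(y) < 1e-12) return(beats)
  if (is.null(variances)) {
    fit <- stats::StructTS(y, type = "level")
    sm <- as.numeric(stats::tsSmooth(fit)[, 1L])
  } else {
    sm <- if (variances[2L] <= 0) y
          else kalman_level_smooth(y, max(variances[1L], 0), variances[2L])
  }
  out <- beats$beats
  out$rr[ok] <- sm
  structure(list(beats = out), class = "beat_series")
}

#' Teichholz left-ventricular volumes and derived indices
#'
#' Uses the canonical Teichholz cubed-diameter formula
#' `V(D) = 7.0 / (2.4 + D) * D^3` (V in mL for D in cm; reported in uL):
#' end-diastolic and end-systolic volumes from the two M-mode cavity
#' diameters, stroke volume `SV = LVEDV - LVESV`, ejection fraction
#' `EF = 100 * SV / LVEDV` and fractional shortening
#' `FS = 100 * (LVEDd - LVESd) / LVEDd`.  When a `reference` is supplied the
#' volume-overload criterion is evaluated: EF >= 50 % with LVEDV and SV at
#' least 1.5-fold the reference values.
#'
#' @param lvedd left-ventricular end-diastolic diameter (cm)
#' @param lvesd left-ventricular end-systolic diameter (cm, <= lvedd)
#' @param reference optional list with `lvedv` and `sv` (uL) of the control
#'   group
#' @return list of class `echo_summary`: `lvedv`, `lvesv`, `sv` (uL), `ef`,
#'   `fs` (%), and `hf_criterion` (logical or NA)
#' @export
teichholz <- function(lvedd, lvesd, reference = NULL) {
  if (!is_scalar_number(lvedd) || !is_scalar_number(lvesd) ||
      lvedd <= 0 || lvesd <= 0)
    stopf("diameters must be positive")
  if (lvesd > lvedd) stopf("lvesd must not exceed lvedd")
  vol <- function(d) 7.0 / (2.4 + d) * d^3 * 1000   # uL
  lvedv <- vol(lvedd); lvesv <- vol(lvesd)
  sv <- lvedv - lvesv
  ef <- 100 * sv / lvedv
  fs <- 100 * (lvedd - lvesd) / lvedd
  crit <- NA
  if (!is.null(reference))
    crit <- ef >= 50 && lvedv >= 1.5 * reference$lvedv && sv >= 1.5 * reference$sv
  structure(list(lvedv = lvedv, lvesv = lvesv, sv = sv, ef = ef, fs = fs,
                 hf_criterion = crit),
            class = "echo_summary")
}
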