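# Respiratory-cardiovascular coupling: magnitude-squared coherence between
# tidal-volume oscillations (input) and beat-to-beat systolic pressure
# (output), averaged over a 0.1-Hz band centered at the VT spectral peak in
# the low-frequency domain.

resample_point_series <- function(times, values, resample_rate) {
  grid <- seq(times[1L], times[length(times)], by = 1 / resample_rate)
  y <- stats::spline(times, values, xout = grid, method = "natural")$y
  signal_trace(y - mean(y), resample_rate, "dimensionless",
               start_time = grid[1L])
}

#' Per-breath parameter series on a uniform grid
#'
#' Per-breath values (VT or interval) placed at breath onsets are
#' cubic-interpolated onto a uniform grid and mean-removed.
#'
#' @param series a [breath_series()] with at least 30 breaths
#' @param parameter `"vt"` or `"interval"`
#' @param resample_rate grid rate (Hz, default 4)
#' @return a zero-mean [signal_trace()]
#' @export
breath_parameter_series <- function(series, parameter = c("vt", "interval"),
                                    resample_rate = 4) {
  stopifnot(inherits(series, "breath_series"))
  parameter <- match.arg(parameter)
  b <- series$breaths
  ok <- if (parameter == "interval") which(is.finite(b$interval))
        else seq_len(nrow(b))
  if (length(ok) < 30L) stopf("too few breaths (need >= 30)")
  out <- resample_point_series(b$onset[ok], b[[parameter]][ok], resample_rate)
  out$label <- paste0("breath_", parameter)
  out
}

#' Per-beat parameter series on a uniform grid
#'
#' @param beats a [beat_series()] with at least 30 beats
#' @param parameter one of `"sbp"`, `"dbp"`, `"map"`, `"pp"`, `"rr"`
#' @param resample_rate grid rate (Hz, default 4)
#' @return a zero-mean [signal_trace()]
#' @export
beat_parameter_series <- function(beats, parameter = "sbp",
                                  resample_rate = 4) {
  stopifnot(inherits(beats, "beat_series"))
  parameter <- match.arg(parameter, c("sbp", "dbp", "map", "pp", "rr"))
  b <- beats$beats
  ok <- which(is.finite(b[[parameter]]))
  if (length(ok) < 30L) stopf("too few beats (need >= 30)")
  out <- resample_point_series(b$time[ok], b[[parameter]][ok], resample_rate)
  out$label <- paste0("beat_", parameter)
  out
}

# Welch auto-/cross-spectra with Hann taper and 50% overlap.
welch_spectra <- function(x, y, rate, segment_s, overlap) {
  m <- round(segment_s * rate)
  n <- length(x)
  if (m > n) stopf("record too short for the segment length")
  hop <- max(1L, round(m * (1 - overlap)))
  starts <- seq(1L, n - m + 1L, by = hop)
  w <- hann(m)
  nf <- m %/% 2L + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + m - 1L)]; ys <- y[s:(s + m - 1L)]
    xs <- (xs - mean(xs)) * w; ys <- (ys - mean(ys)) * w
    fx <- stats::fft(xs)[seq_len(nf)]
    fy <- stats::fft(ys)[seq_len(nf)]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  list(freqs = (seq_len(nf) - 1L) * rate / m, sxx = sxx, syy = syy,
       sxy = sxy, n_segments = length(starts))
}

#' Mean-squared coherence between VT and SBP oscillations
#'
#' Welch overlapped-segment averaging (Hann taper, `segment_s`-second
#' segments, 50% overlap) yields auto- and cross-spectra over the first
#' `record_s` seconds; the magnitude-squared coherence is
#' `C(f) = |Pxy|^2 / (Pxx * Pyy)`.  The VT autospectrum peak within the
#' low-frequency domain defines the band center; `mean_coherence` is the
#' mean of C over a band of `2 * band_halfwidth` (0.1 Hz by default) around
#' it.  The analytic zero-coupling significance level
#' `1 - alpha^(1/(L-1))` for L segments is reported alongside.
#'
#' @param vt_series,sbp_series zero-mean [signal_trace()]s on a common grid
#'   (see [breath_parameter_series()] / [beat_parameter_series()])
#' @param record_s record length analyzed (s, default 600)
#' @param segment_s Welch segment length (s, default 120)
#' @param overlap fractional overlap (default 0.5)
#' @param lf_range frequency range searched for the VT peak (Hz)
#' @param band_halfwidth half-width of the coherence band (Hz, default 0.05)
#' @param alpha significance level for the zero-coherence threshold
#' @return list of class `coupling_result`: `peak_freq`, `band`,
#'   `mean_coherence`, `significance_level`, `n_segments`, plus the full
#'   `freqs` / `coherence` spectrum
#' @export
coherence_vt_sbp <- function(vt_series, sbp_series, record_s = 600,
                             segment_s = 120, overlap = 0.5,
                             lf_range = c(0.01, 0.6), band_halfwidth = 0.05,
                             alpha = 0.05) {
  stopifnot(inherits(vt_series, "signal_trace"),
            inherits(sbp_series, "signal_trace"))
  if (abs(vt_series$rate - sbp_series$rate) > 1e-9)
    stopf("mismatched sampling rates")
  rate <- vt_series$rate
  n <- round(record_s * rate)
  if (length(vt_series$samples) < n || length(sbp_series$samples) < n)
    stopf("record too short: need %g s on both channels", record_s)
  x <- vt_series$samples[seq_len(n)]
  y <- sbp_series$samples[seq_len(n)]
  sp <- welch_spectra(x, y, rate, segment_s, overlap)
  denom <- sp$sxx * sp$syy
  coh <- ifelse(denom > 0, Mod(sp$sxy)^2 / denom, 0)
  coh <- pmin(coh, 1)
  in_lf <- which(sp$freqs >= lf_range[1L] & sp$freqs <= lf_range[2L])
  if (!length(in_lf)) stopf("no frequency bins in the low-frequency domain")
  peak <- sp$freqs[in_lf[which.max(sp$sxx[in_lf])]]
  band <- c(max(peak - band_halfwidth, 0), peak + band_halfwidth)
  in_band <- sp$freqs >= band[1L] & sp$freqs <= band[2L]
  lvl <- if (sp$n_segments > 1L) 1 - alpha^(1 / (sp$n_segments - 1L)) else 1
  structure(list(peak_freq = peak, band = band,
                 mean_coherence = mean(coh[in_band]),
                 significance_level = lvl, n_segments = sp$n_segments,
                 freqs = sp$freqs, coherence = coh),
            class = "coupling_result")
}
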