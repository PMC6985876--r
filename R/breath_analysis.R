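# Breath segmentation, ventilation summaries, disordered-breathing event
# scoring and Poincare breath-interval variability.

#' Construct a breath series
#'
#' @param breaths data frame with columns `onset` (inspiratory onset, s),
#'   `exp_onset` (expiratory onset, s), `end` (expiratory offset, s),
#'   `vt` (mL), `ti`, `te` (s) and `interval` (onset-to-onset, s; NA for
#'   the last breath)
#' @param body_mass body mass (g)
#' @return an object of class `breath_series`
#' @export
breath_series <- function(breaths, body_mass) {
  need <- c("onset", "exp_onset", "end", "vt", "ti", "te", "interval")
  if (!all(need %in% names(breaths)))
    stopf("breaths must have columns: %s", paste(need, collapse = ", "))
  if (!is_scalar_number(body_mass) || body_mass <= 0)
    stopf("body_mass must be > 0")
  if (is.unsorted(breaths$onset, strictly = TRUE))
    stopf("breaths must be strictly time-ordered")
  if (any(breaths$exp_onset <= breaths$onset) ||
      any(breaths$end <= breaths$exp_onset))
    stopf("each breath needs onset < exp_onset < end")
  rownames(breaths) <- NULL
  structure(list(breaths = breaths, body_mass = body_mass),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths over %.1f s, body mass %g g\n",
              nrow(x$breaths), diff(range(x$breaths$onset)), x$body_mass))
  invisible(x)
}

#' Build a breath series from an interval sequence
#'
#' Used for variability analyses where only breath-to-breath intervals are
#' observed or simulated; breath timing fields are filled in nominally.
#'
#' @param intervals_ms onset-to-onset intervals (ms)
#' @param vt per-breath tidal volumes (mL); recycled
#' @param body_mass body mass (g)
#' @return a [breath_series()] with `length(intervals_ms) + 1` breaths
#' @export
breath_series_from_intervals <- function(intervals_ms, vt = 1, body_mass = 250) {
  iv <- as.numeric(intervals_ms) / 1000
  if (any(iv <= 0)) stopf("intervals must be positive")
  onset <- cumsum(c(0, iv))
  dur <- c(iv, mean(iv))
  breath_series(data.frame(onset = onset, exp_onset = onset + 0.4 * dur,
                           end = onset + dur, vt = rep_len(vt, length(onset)),
                           ti = 0.4 * dur, te = 0.6 * dur,
                           interval = c(iv, NA)),
                body_mass)
}

#' Segment breaths from a calibrated airflow trace
#'
#' Inspiration is positive flow by convention.  Breath onsets are upward
#' crossings of a hysteresis threshold (5 % of the 95th percentile of
#' absolute flow by default); a new onset is accepted only after the flow
#' has visited the negative threshold (a completed expiration), which makes
#' the detector robust to noise riding on the inspiratory peak.  Tidal
#' volume is the trapezoidal integral of inspiratory flow.  Candidate
#' breaths shorter than `min_duration` or with VT below `vt_floor_frac`
#' times the running median VT are discarded rather than emitted.
#'
#' @param flow a [signal_trace()] in mL/s
#' @param body_mass body mass (g)
#' @param hysteresis_frac threshold as a fraction of the 95th percentile of
#'   absolute flow
#' @param min_duration minimum breath duration (s)
#' @param vt_floor_frac minimum VT as a fraction of the running median
#' @return a [breath_series()]
#' @export
segment_breaths <- function(flow, body_mass, hysteresis_frac = 0.05,
                            min_duration = 0.1, vt_floor_frac = 0.1) {
  stopifnot(inherits(flow, "signal_trace"))
  x <- flow$samples
  fs <- flow$rate
  n <- length(x)
  th <- hysteresis_frac * stats::quantile(abs(x), 0.95, names = FALSE)
  if (th <= 0) stopf("no breaths: flat signal")
  up <- which(x[-1L] > th & x[-n] <= th) + 1L
  if (length(up) < 2L) stopf("no breaths: fewer than two threshold crossings")
  neg <- x < -th
  csneg <- cumsum(neg)
  acc <- up[1L]
  last <- up[1L]
  for (c in up[-1L]) {
    if (csneg[c] - csneg[last] > 0L) { acc <- c(acc, c); last <- c }
  }
  if (length(acc) < 2L) stopf("no breaths: no completed expirations")
  pos <- x > 0
  run_start <- which(diff(c(FALSE, pos)) == 1L)
  run_end <- which(diff(c(pos, FALSE)) == -1L)
  ri <- findInterval(acc, run_start)
  onset_i <- run_start[ri]
  expon_i <- pmin(run_end[ri] + 1L, n)
  # expiratory offset: end of the contiguous below-(-th) run that follows
  # the expiratory onset.  Runs separated by < 50 ms are merged so noise
  # riding on the decay does not truncate the expiration; isolated noise
  # dips during an apnea stay separate and cannot shorten the gap.
  nb <- length(acc)
  bs <- which(diff(c(FALSE, neg)) == 1L)
  be <- which(diff(c(neg, FALSE)) == -1L)
  if (length(bs) > 1L) {
    brk <- (bs[-1L] - be[-length(be)]) > 0.05 * fs
    bs <- bs[c(TRUE, brk)]
    be <- be[c(brk, TRUE)]
  }
  bs <- as.double(bs); be <- as.double(be)
  lims <- c(onset_i[-1L] - 1L, n)
  k <- findInterval(expon_i - 1L, be) + 1L   # first run ending >= expon
  valid_run <- length(be) > 0L & k <= length(be) & bs[pmax(k, 1L)] < lims
  k <- pmax(pmin(k, max(length(be), 1L)), 1L)
  end_i <- as.integer(ifelse(valid_run,
                             pmin(be[k], lims), pmin(expon_i + 1L, lims)))
  # the tail of expiration between -th and zero still belongs to the
  # breath: extend the offset to the end of the enclosing negative run
  nz <- x < 0
  zs <- as.double(which(diff(c(FALSE, nz)) == 1L))
  ze <- as.double(which(diff(c(nz, FALSE)) == -1L))
  if (length(ze)) {
    jz <- pmax(findInterval(end_i, zs), 1L)
    end_i <- as.integer(ifelse(valid_run & ze[jz] >= end_i,
                               pmin(ze[jz], lims), end_i))
  }
  # drop a trailing breath whose expiration runs into the end of the trace
  if (end_i[nb] >= n - 1L && nb > 1L) {
    onset_i <- onset_i[-nb]; expon_i <- expon_i[-nb]; end_i <- end_i[-nb]
    nb <- nb - 1L
  }
  vt <- vapply(seq_len(nb), function(b)
    trapz(pmax(x[onset_i[b]:expon_i[b]], 0), 1 / fs), 0)
  t0 <- flow$start_time
  onset <- t0 + (onset_i - 1L) / fs
  # sub-sample refinement of the expiratory onset: linear zero crossing
  # between the last positive and first non-positive sample
  prev <- pmax(expon_i - 1L, 1L)
  dx <- x[prev] - x[expon_i]
  frac <- ifelse(dx > 0, x[prev] / dx, 1)
  expon <- t0 + (prev - 1L + pmin(pmax(frac, 0), 1)) / fs
  # symmetric sub-sample refinement of the expiratory offset
  nxt <- pmin(end_i + 1L, n)
  dxe <- x[nxt] - x[end_i]
  frace <- ifelse(dxe > 0 & x[end_i] < 0, -x[end_i] / dxe, 0)
  endt <- t0 + (end_i - 1L + pmin(pmax(frace, 0), 1)) / fs
  dur <- endt - onset
  med <- stats::runmed(vt, k = min(21L, 2L * (nb %/% 2L) - 1L))
  keep <- dur >= min_duration & vt >= vt_floor_frac * med & vt > 0
  if (!any(keep)) stopf("no breaths after validity filtering")
  onset <- onset[keep]; expon <- expon[keep]; endt <- endt[keep]; vt <- vt[keep]
  breath_series(data.frame(onset = onset, exp_onset = expon, end = endt,
                           vt = vt, ti = expon - onset, te = endt - expon,
                           interval = c(diff(onset), NA)),
                body_mass)
}

#' Ventilation summary over a time window
#'
#' VT is normalized per 100 g body mass, Rf is the breath count scaled to
#' breaths/min, and minute ventilation is their product (exact by
#' construction).  When `ten_second_rule = TRUE` the window is flagged
#' invalid unless it holds 10 +/- 2 complete cycles, mirroring the
#' "ten-second segments of stable ventilation" convention.
#'
#' @param series a [breath_series()]
#' @param window numeric `c(t0, t1)`, half-open, seconds
#' @param ten_second_rule apply the 10 +/- 2 valid-cycle check
#' @return list of class `ventilation_summary` with fields `vt_per100g`
#'   (mL/100 g), `rf` (breaths/min), `ve` (mL·100 g^-1·min^-1), `window`,
#'   `n_valid_cycles`, `valid`
#' @export
ventilation_summary <- function(series, window, ten_second_rule = FALSE) {
  stopifnot(inherits(series, "breath_series"), length(window) == 2L)
  t0 <- window[1L]; t1 <- window[2L]
  if (t1 <= t0) stopf("empty window")
  b <- series$breaths
  sel <- b$onset >= t0 & b$onset < t1
  nb <- sum(sel)
  if (nb < 1L) stopf("window contains no complete breath")
  vt100 <- mean(b$vt[sel]) * 100 / series$body_mass
  rf <- 60 * nb / (t1 - t0)
  valid <- if (ten_second_rule) nb >= 8L && nb <= 12L else TRUE
  structure(list(vt_per100g = vt100, rf = rf, ve = vt100 * rf,
                 window = c(t0, t1), n_valid_cycles = nb, valid = valid),
            class = "ventilation_summary")
}

#' Score apneas, hypopneas, sighs and post-sigh apneas
#'
#' Definitions: one breathing cycle is the mean onset-to-onset interval of
#' the 10 preceding normal breaths; an apnea is an inter-breath gap (from
#' the last expiratory offset to the next inspiratory onset) of at least
#' `apnea_cycles` cycles; a hypopnea is a breath with VT at or below
#' `hypopnea_frac` of the mean VT of the 3 most recent normal breaths; a
#' sigh is a breath with VT at or above `sigh_frac` of that same reference;
#' an apnea whose onset falls within one cycle of a sigh offset is scored
#' as a post-sigh apnea (not double-counted as spontaneous).  "Normal"
#' excludes sighs, hypopneas and the two breaths flanking an apnea.
#'
#' @param series a [breath_series()] with at least 10 breaths
#' @param flow optional airflow [signal_trace()]; accepted for interface
#'   symmetry (all scoring operates on the segmented breaths)
#' @param apnea_cycles gap threshold in cycles (default 3)
#' @param hypopnea_frac,sigh_frac VT thresholds relative to the reference
#' @return an [annotation_table()]; the per-breath labels are attached as
#'   attribute `"labels"`
#' @export
detect_events <- function(series, flow = NULL, apnea_cycles = 3,
                          hypopnea_frac = 0.5, sigh_frac = 1.5) {
  stopifnot(inherits(series, "breath_series"))
  b <- series$breaths
  n <- nrow(b)
  if (n < 10L) stopf("need at least 10 breaths for baseline estimation")
  label <- rep("normal", n)
  adjacent <- logical(n)
  norm_vt <- numeric(0)      # VT of recent normal breaths (most recent last)
  norm_iv <- numeric(0)      # onset-to-onset intervals of recent normals
  ev_kind <- character(0); ev_on <- numeric(0); ev_dur <- numeric(0)
  last_sigh_end <- -Inf
  for (i in seq_len(n)) {
    if (!adjacent[i] && length(norm_vt) >= 3L) {
      ref <- mean(utils::tail(norm_vt, 3L))
      if (b$vt[i] <= hypopnea_frac * ref) {
        label[i] <- "hypopnea"
        ev_kind <- c(ev_kind, "hypopnea"); ev_on <- c(ev_on, b$onset[i])
        ev_dur <- c(ev_dur, b$end[i] - b$onset[i])
      } else if (b$vt[i] >= sigh_frac * ref) {
        label[i] <- "sigh"
        ev_kind <- c(ev_kind, "sigh"); ev_on <- c(ev_on, b$onset[i])
        ev_dur <- c(ev_dur, b$end[i] - b$onset[i])
        last_sigh_end <- b$end[i]
      }
    }
    if (i < n && length(norm_iv) >= 10L) {
      cycle <- mean(utils::tail(norm_iv, 10L))
      gap <- b$onset[i + 1L] - b$end[i]
      if (gap >= apnea_cycles * cycle) {
        kind <- if (b$end[i] - last_sigh_end <= cycle) "post_sigh_apnea"
                else "apnea"
        ev_kind <- c(ev_kind, kind); ev_on <- c(ev_on, b$end[i])
        ev_dur <- c(ev_dur, gap)
        adjacent[i] <- TRUE
        adjacent[i + 1L] <- TRUE
      }
    }
    if (label[i] == "normal" && !adjacent[i]) {
      norm_vt <- c(utils::tail(norm_vt, 9L), b$vt[i])
      if (is.finite(b$interval[i]) && !(i < n && adjacent[i + 1L]))
        norm_iv <- c(utils::tail(norm_iv, 19L), b$interval[i])
    }
  }
  out <- annotation_table(ev_kind, ev_on, ev_dur)
  attr(out, "labels") <- label
  out
}

#' Event rates and mean durations per hour of recording
#'
#' @param events an [annotation_table()]
#' @param duration recording duration (s, > 0)
#' @return list of class `event_summary`: per-kind rates (events/h), the
#'   apnea-hypopnea index `ahi = apnea_rate + hypopnea_rate`, and mean
#'   durations per kind (NA for absent kinds)
#' @export
event_summary <- function(events, duration) {
  stopifnot(inherits(events, "annotation_table"))
  if (!is_scalar_number(duration) || duration <= 0)
    stopf("duration must be > 0")
  rate_of <- function(kind) sum(events$kind == kind) * 3600 / duration
  dur_of <- function(kind) {
    d <- events$duration[events$kind == kind]
    if (length(d)) mean(d) else NA_real_
  }
  ap <- rate_of("apnea"); hy <- rate_of("hypopnea")
  structure(list(apnea_rate = ap, hypopnea_rate = hy, ahi = ap + hy,
                 sigh_rate = rate_of("sigh"),
                 post_sigh_apnea_rate = rate_of("post_sigh_apnea"),
                 mean_durations = c(apnea = dur_of("apnea"),
                                    hypopnea = dur_of("hypopnea"),
                                    sigh = dur_of("sigh"),
                                    post_sigh_apnea = dur_of("post_sigh_apnea"))),
            class = "event_summary")
}

#' Poincare variability of the breath-to-breath interval
#'
#' Over the first `n` consecutive intervals the lag-1 scatter (x_i,
#' x_(i+1)) is projected onto the axes perpendicular to and along the
#' identity line: `SD1 = popSD((x2 - x1)/sqrt(2))` (short-term) and
#' `SD2 = popSD((x2 + x1)/sqrt(2))` (long-term), with population (1/n)
#' variances.  Equivalently `SD1^2 = Var(diff(x))/2` and `SD1^2 + SD2^2 =
#' Var(x1) + Var(x2)`.  `cv_vt` is the coefficient of variation of VT over
#' the same breaths.
#'
#' @param series a [breath_series()] with at least `n` finite intervals
#' @param n number of consecutive intervals (default 300)
#' @return list of class `variability_stats`: `sd1`, `sd2` (ms), `cv_vt`
#'   (%), `n_breaths`
#' @export
poincare_stats <- function(series, n = 300L) {
  stopifnot(inherits(series, "breath_series"))
  iv <- series$breaths$interval
  iv <- iv[is.finite(iv)]
  if (length(iv) < n) stopf("need at least %d intervals, have %d", n, length(iv))
  x <- iv[seq_len(n)] * 1000
  x1 <- x[-n]; x2 <- x[-1L]
  sd1 <- sqrt(pop_var((x2 - x1) / sqrt(2)))
  sd2 <- sqrt(pop_var((x2 + x1) / sqrt(2)))
  vt <- series$breaths$vt[seq_len(n)]
  structure(list(sd1 = sd1, sd2 = sd2,
                 cv_vt = 100 * stats::sd(vt) / mean(vt), n_breaths = n),
            class = "variability_stats")
}
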