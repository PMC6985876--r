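# Active expiration: the late/early expiratory area ratio E2/E1 on randomly
# sampled eupneic cycle segments.

#' Quantify active expiration via the E2/E1 area ratio
#'
#' Mirrors the blind-operator procedure: `n_segments` non-overlapping runs
#' of `cycles_per_segment` consecutive eupneic cycles (no scored events
#' inside, operationalized through [detect_events()]) are chosen at random,
#' reproducibly from `seed`.  For each cycle the expiration is split at half
#' the expiratory time: E1 is the area under the absolute expiratory flow
#' over the first half, E2 over the second half (trapezoidal integration on
#' the native grid, with interpolated endpoints so the split point does not
#' need to fall on a sample).  An E2/E1 ratio above ~1 indicates forced,
#' late-expiratory flow, i.e. recruitment of active expiration.
#'
#' @param series a [breath_series()]
#' @param flow the airflow [signal_trace()] the series was segmented from
#' @param n_segments number of segments (default 3)
#' @param cycles_per_segment consecutive cycles per segment (default 20)
#' @param seed integer seed for the random segment choice
#' @return list of class `expiration_stats`: `e1`, `e2` (mL, means over all
#'   sampled cycles), `ratio = e2/e1`, `te` (mean expiratory time, s),
#'   `n_cycles`, `segment_starts` (s)
#' @export
active_expiration <- function(series, flow, n_segments = 3L,
                              cycles_per_segment = 20L, seed = 1L) {
  stopifnot(inherits(series, "breath_series"), inherits(flow, "signal_trace"))
  b <- series$breaths
  n <- nrow(b)
  if (n < cycles_per_segment * n_segments)
    stopf("insufficient eupneic cycles: %d breaths for %d x %d cycles",
          n, n_segments, cycles_per_segment)
  events <- detect_events(series)
  label <- attr(events, "labels")
  gap_after <- c(b$onset[-1L] - b$end[-n], 0)
  cycle <- stats::median(b$interval, na.rm = TRUE)
  clean <- label == "normal" & gap_after < cycle
  # candidate run starts: every breath beginning a clean run of the needed length
  run_ok <- vapply(seq_len(n - cycles_per_segment + 1L), function(i)
    all(clean[i:(i + cycles_per_segment - 1L)]), TRUE)
  cand <- which(run_ok)
  if (length(cand) < 1L) stopf("insufficient eupneic cycles")
  set.seed(substream_seed(seed, "segments"))
  draw_starts <- function() {
    starts <- integer(0)
    pool <- cand
    for (k in seq_len(n_segments)) {
      if (!length(pool)) return(NULL)
      s <- pool[sample.int(length(pool), 1L)]
      starts <- c(starts, s)
      pool <- pool[abs(pool - s) >= cycles_per_segment]
    }
    starts
  }
  starts <- NULL
  for (try in 1:100) {
    starts <- draw_starts()
    if (!is.null(starts)) break
  }
  if (is.null(starts)) {
    # deterministic fallback: earliest feasible non-overlapping placement
    starts <- integer(0)
    pool <- cand
    while (length(pool) && length(starts) < n_segments) {
      starts <- c(starts, pool[1L])
      pool <- pool[abs(pool - pool[1L]) >= cycles_per_segment]
    }
    if (length(starts) < n_segments)
      stopf("insufficient eupneic cycles for %d segments", n_segments)
  }
  idx <- unlist(lapply(starts, function(s) s:(s + cycles_per_segment - 1L)))
  absflow <- signal_trace(abs(flow$samples), flow$rate, flow$units,
                          flow$start_time, flow$label)
  e1 <- e2 <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    t0 <- b$exp_onset[i]; t1 <- b$end[i]
    tm <- (t0 + t1) / 2
    e1[k] <- trapz_window(absflow$samples, absflow$rate, absflow$start_time,
                          t0, tm)
    e2[k] <- trapz_window(absflow$samples, absflow$rate, absflow$start_time,
                          tm, t1)
  }
  m1 <- mean(e1); m2 <- mean(e2)
  structure(list(e1 = m1, e2 = m2,
                 ratio = if (m1 > 0) m2 / m1 else NA_real_,
                 te = mean(b$te[idx]), n_cycles = length(idx),
                 segment_starts = b$onset[starts]),
            class = "expiration_stats")
}
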