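# Domain types and plain-text readers/writers.
#
# Conventions used throughout the package: time is in seconds from the start
# of the recording, rates in Hz, windows are half-open [t0, t1), samples are
# 0-indexed in time (sample k sits at start_time + k/rate).  Tidal volume is
# carried in mL on raw traces and normalized per 100 g body mass only at
# summary time.

SIGNAL_UNITS <- c("mL/s", "mmHg", "ms", "dimensionless")
EVENT_KINDS  <- c("apnea", "hypopnea", "sigh", "post_sigh_apnea")

#' Construct a uniformly sampled physiological signal
#'
#' A `signal_trace` carries the samples of one channel (respiratory airflow,
#' arterial pressure, an RR tachogram, ...) together with its sampling rate,
#' units and start time.
#'
#' @param samples numeric vector of samples, all finite, length >= 2
#' @param rate sampling rate in Hz (> 0)
#' @param units one of `"mL/s"`, `"mmHg"`, `"ms"`, `"dimensionless"`
#' @param start_time time of the first sample in seconds (default 0)
#' @param label free-text channel label
#' @return an object of class `signal_trace`
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1.4 * seq(0, 10, by = 1e-3)), 1000, "mL/s")
#' trace_duration(tr)
#' @export
signal_trace <- function(samples, rate, units, start_time = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stopf("signal_trace needs at least 2 samples")
  if (!all(is.finite(samples))) stopf("non-finite samples in signal trace")
  if (!is_scalar_number(rate) || rate <= 0) stopf("sampling rate must be > 0")
  units <- match.arg(units, SIGNAL_UNITS)
  structure(list(samples = samples, rate = rate, units = units,
                 start_time = start_time, label = as.character(label)[1L]),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples @ %g Hz [%s], t = [%g, %g) s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$rate, x$units,
              x$start_time, x$start_time + length(x$samples) / x$rate))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a [signal_trace()]
#' @return numeric vector of times (s)
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Duration of a trace in seconds (n/rate, half-open span)
#' @param trace a [signal_trace()]
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

#' Extract the sub-trace on the half-open window [t0, t1)
#'
#' @param trace a [signal_trace()]
#' @param t0,t1 window bounds in seconds, relative to the recording clock;
#'   must satisfy `t0 < t1` and lie within the trace span
#' @return a [signal_trace()] with updated `start_time`
#' @export
slice_trace <- function(trace, t0, t1) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!is_scalar_number(t0) || !is_scalar_number(t1) || t0 >= t1)
    stopf("invalid window: need t0 < t1")
  span0 <- trace$start_time
  span1 <- trace$start_time + trace_duration(trace)
  eps <- 1e-9 / trace$rate
  if (t0 < span0 - eps || t1 > span1 + eps)
    stopf("window [%g, %g) out of trace range [%g, %g)", t0, t1, span0, span1)
  i0 <- ceiling((t0 - span0) * trace$rate - 1e-9) + 1L
  i1 <- ceiling((t1 - span0) * trace$rate - 1e-9)   # exclusive end
  i1 <- min(i1, length(trace$samples))
  if (i1 < i0 + 1L) stopf("window too short: fewer than 2 samples")
  signal_trace(trace$samples[i0:i1], trace$rate, trace$units,
               start_time = span0 + (i0 - 1L) / trace$rate, label = trace$label)
}

#' Construct a typed event table
#'
#' Houses scored breathing events (and, for synthetic recordings, the ground
#' truth).  Events are sorted by onset on construction.
#'
#' @param kind character vector from `apnea`, `hypopnea`, `sigh`,
#'   `post_sigh_apnea`
#' @param onset event onsets (s)
#' @param duration event durations (s, >= 0)
#' @param attributes optional character vector of JSON-encoded extras
#' @return a data frame of class `annotation_table`
#' @export
annotation_table <- function(kind = character(), onset = numeric(),
                             duration = numeric(), attributes = NULL) {
  kind <- as.character(kind)
  if (length(kind) && !all(kind %in% EVENT_KINDS))
    stopf("unknown event kind(s): %s",
          paste(setdiff(unique(kind), EVENT_KINDS), collapse = ", "))
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  if (any(duration < 0)) stopf("event durations must be >= 0")
  if (is.null(attributes)) attributes <- rep("{}", length(kind))
  df <- data.frame(kind = kind, onset = onset, duration = duration,
                   attributes = as.character(attributes),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Construct a gas-protocol schedule
#'
#' Ordered, contiguous, non-overlapping segments of inspired gas fractions.
#'
#' @param start,end segment bounds (s); segments must tile `[start[1], end[n]]`
#' @param fio2 inspired O2 fraction, percent in (0, 100]
#' @param fico2 inspired CO2 fraction, percent in [0, 100]
#' @return a data frame of class `gas_protocol`
#' @export
gas_protocol <- function(start, end, fio2, fico2) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   fio2 = as.numeric(fio2), fico2 = as.numeric(fico2))
  if (nrow(df) == 0L) stopf("empty protocol")
  if (any(df$end <= df$start)) stopf("protocol segments must have end > start")
  if (nrow(df) > 1L && any(abs(df$start[-1L] - df$end[-nrow(df)]) > 1e-9))
    stopf("protocol segments must be contiguous and non-overlapping")
  if (any(df$fio2 <= 0 | df$fio2 > 100)) stopf("fio2 out of (0, 100]")
  if (any(df$fico2 < 0 | df$fico2 > 100)) stopf("fico2 out of [0, 100]")
  class(df) <- c("gas_protocol", "data.frame")
  df
}

#' Look up inspired fractions at given times
#' @param protocol a [gas_protocol()]
#' @param t times (s); times outside the schedule take the nearest segment
#' @return data frame with columns `fio2`, `fico2`
#' @export
protocol_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "gas_protocol"))
  i <- findInterval(t, protocol$start, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i > nrow(protocol)] <- nrow(protocol)
  data.frame(fio2 = protocol$fio2[i], fico2 = protocol$fico2[i])
}

#' Bundle the channels of one recording session
#'
#' @param flow airflow [signal_trace()] in mL/s
#' @param pressure optional arterial-pressure [signal_trace()] in mmHg
#' @param protocol optional [gas_protocol()]
#' @param body_mass body mass in grams (> 0)
#' @param subject_id free-text identifier
#' @return an object of class `recording_bundle`
#' @export
recording_bundle <- function(flow, pressure = NULL, protocol = NULL,
                             body_mass, subject_id = "") {
  stopifnot(inherits(flow, "signal_trace"))
  if (!is_scalar_number(body_mass) || body_mass <= 0)
    stopf("body_mass must be > 0")
  if (!is.null(pressure)) {
    stopifnot(inherits(pressure, "signal_trace"))
    f0 <- flow$start_time; f1 <- f0 + trace_duration(flow)
    p0 <- pressure$start_time; p1 <- p0 + trace_duration(pressure)
    if (min(f1, p1) <= max(f0, p0))
      stopf("flow and pressure time ranges do not overlap")
  }
  structure(list(flow = flow, pressure = pressure, protocol = protocol,
                 body_mass = body_mass, subject_id = subject_id),
            class = "recording_bundle")
}

# ---- file formats ----------------------------------------------------------
# Signals: CSV with '#'-prefixed header lines (label, units, sampling_rate,
# start_time) and one 'value' column.  Annotations: CSV with columns
# kind,onset,duration,attributes (attributes JSON-encoded).  Protocols: YAML.

#' Write a signal trace to a delimited text file
#'
#' The header carries label, units, sampling rate and start time; values are
#' written with 17 significant digits, so write/read round-trips are exact to
#' double precision.
#'
#' @param trace a [signal_trace()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_signal <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", trace$label),
               sprintf("# units: %s", trace$units),
               sprintf("# sampling_rate: %.17g", trace$rate),
               sprintf("# start_time: %.17g", trace$start_time),
               "value"), con)
  writeLines(sprintf("%.17g", trace$samples), con)
  invisible(path)
}

#' Read a signal trace written by [write_signal()]
#'
#' Alternatively accepts a two-column `time,value` CSV without header
#' metadata, in which case the sampling rate is inferred from the time grid
#' and time stamps with more than 1\% jitter are rejected.
#'
#' @param path input file path
#' @return a [signal_trace()]
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, n = 10L)
  meta <- grep("^#", lines, value = TRUE)
  if (length(meta)) {
    get <- function(key) {
      hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
      if (!length(hit)) return(NULL)
      sub(sprintf("^# %s:\\s*", key), "", hit[1L])
    }
    dat <- utils::read.csv(path, comment.char = "#")
    samples <- dat[[1L]]
    if (!all(is.finite(samples))) stopf("non-finite values in %s", path)
    return(signal_trace(samples,
                        rate = as.numeric(get("sampling_rate")),
                        units = get("units") %||% "dimensionless",
                        start_time = as.numeric(get("start_time") %||% "0"),
                        label = get("label") %||% ""))
  }
  dat <- utils::read.csv(path)
  if (ncol(dat) < 2L) stopf("no header metadata and no time column in %s", path)
  tm <- dat[[1L]]; val <- dat[[2L]]
  if (!all(is.finite(val)) || !all(is.finite(tm)))
    stopf("non-finite values in %s", path)
  dts <- diff(tm)
  if (any(dts <= 0)) stopf("time column must be strictly increasing")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 0.01 * dt)
    stopf("non-uniform sampling (> 1%% jitter) in %s", path)
  signal_trace(val, rate = 1 / dt, units = "dimensionless",
               start_time = tm[1L], label = names(dat)[2L])
}

#' Write an annotation table to CSV
#' @param table an [annotation_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_annotations <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  df <- as.data.frame(table)
  df$onset <- sprintf("%.17g", df$onset)
  df$duration <- sprintf("%.17g", df$duration)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an annotation table (sorted on read)
#' @param path input file path
#' @return an [annotation_table()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_table(df$kind, as.numeric(df$onset), as.numeric(df$duration),
                   if ("attributes" %in% names(df)) df$attributes else NULL)
}

#' Write / read a gas protocol as YAML
#' @param protocol a [gas_protocol()]
#' @param path file path
#' @return `path` invisibly (write) or a [gas_protocol()] (read)
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "gas_protocol"))
  segs <- lapply(seq_len(nrow(protocol)), function(i)
    list(start = protocol$start[i], end = protocol$end[i],
         fio2 = protocol$fio2[i], fico2 = protocol$fico2[i]))
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  y <- yaml::read_yaml(path)
  segs <- y$segments
  gas_protocol(vapply(segs, `[[`, 0, "start"), vapply(segs, `[[`, 0, "end"),
               vapply(segs, `[[`, 0, "fio2"), vapply(segs, `[[`, 0, "fico2"))
}
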