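# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of samples on a uniform grid
#' @param y numeric samples
#' @param dt grid spacing (s)
#' @return integral (units of y * s)
#' @keywords internal
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

# Integral of a piecewise-linear signal between arbitrary times t0 < t1.
# `start` is the time of samples[1]; exact for the trapezoid interpolant,
# so half-cycle splits that fall between samples do not bias E1/E2 areas.
trapz_window <- function(samples, rate, start, t0, t1) {
  if (t1 <= t0) return(0)
  n <- length(samples)
  span_end <- start + (n - 1L) / rate
  t0 <- max(t0, start)
  t1 <- min(t1, span_end)
  if (t1 <= t0) return(0)
  f <- stats::approxfun((0:(n - 1L)) / rate + start, samples)
  i0 <- ceiling((t0 - start) * rate) + 1L
  i1 <- floor((t1 - start) * rate) + 1L
  total <- 0
  if (i1 >= i0) {
    inner <- samples[i0:i1]
    total <- trapz(inner, 1 / rate)
    ta <- start + (i0 - 1L) / rate
    tb <- start + (i1 - 1L) / rate
    if (t0 < ta) total <- total + (ta - t0) * (f(t0) + samples[i0]) / 2
    if (t1 > tb) total <- total + (t1 - tb) * (samples[i1] + f(t1)) / 2
  } else {
    total <- (t1 - t0) * (f(t0) + f(t1)) / 2
  }
  total
}

# Hann taper of length n (periodic form is irrelevant at these lengths;
# symmetric window used throughout).
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

# Zero-phase FIR low-pass by windowed-sinc convolution.  Edges (half a
# kernel) are left as the raw signal; callers only use interior structure.
fir_lowpass <- function(x, rate, cutoff_hz, ntaps = NULL) {
  if (cutoff_hz >= rate / 2) return(x)
  if (is.null(ntaps)) ntaps <- min(length(x), 2L * floor(rate / cutoff_hz) + 1L)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  k <- (-m):m
  h <- 2 * cutoff_hz / rate * sinc(2 * cutoff_hz / rate * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))   # Hamming taper
  h <- h / sum(h)
  y <- stats::filter(x, h, method = "convolution", sides = 2)
  y <- as.numeric(y)
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Population (1/n) variance, as used by the Poincare ellipse decomposition.
pop_var <- function(x) mean((x - mean(x))^2)

# Derive a reproducible per-channel substream seed from one global seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, channel) {
  offsets <- c(breathing = 101L, events = 211L, pressure = 307L,
               beats = 401L, chemo = 503L, noise = 601L, segments = 701L)
  off <- offsets[[channel]] %||% 997L
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
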