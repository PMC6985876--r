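# Chemoreflex gains (HVR, HCVR), the episodic hypercapnic stimulation
# schedule, and post-stimulation ventilatory-plasticity deltas.

#' Episodic hypercapnic stimulation (EHS) schedule
#'
#' Alternating hypercapnic and normoxic-rest segments, starting with a
#' stimulation segment.  Defaults follow the standard paradigm: 10 cycles
#' of 5-min 7% CO2 / 21% O2 (balance N2) spaced by 5-min normoxic periods,
#' spanning 100 min in total.
#'
#' @param n_cycles number of stimulation cycles (default 10)
#' @param stim_s,rest_s segment durations (s, default 300 each)
#' @param fico2 stimulation CO2 fraction (%, default 7)
#' @param fio2 O2 fraction throughout (%, default 21)
#' @param rest_fico2 CO2 fraction at rest (%, default room-air 0.03)
#' @param start schedule start time (s)
#' @return a [gas_protocol()] with `2 * n_cycles` segments
#' @export
ehs_schedule <- function(n_cycles = 10L, stim_s = 300, rest_s = 300,
                         fico2 = 7, fio2 = 21, rest_fico2 = 0.03, start = 0) {
  if (!is_scalar_number(n_cycles) || n_cycles < 1L) stopf("need >= 1 cycle")
  if (stim_s <= 0 || rest_s <= 0) stopf("segment durations must be positive")
  durs <- rep(c(stim_s, rest_s), n_cycles)
  ends <- start + cumsum(durs)
  starts <- c(start, ends[-length(ends)])
  gas_protocol(starts, ends, fio2 = rep(fio2, length(durs)),
               fico2 = rep(c(fico2, rest_fico2), n_cycles))
}

#' Chemoreflex gain from two-level exposures
#'
#' HCVR is the slope of minute ventilation between FICO2 0.03% and 7%;
#' HVR is the slope between FIO2 21% and 10%, reported per % FIO2 decrease
#' so a normal (ventilation-increasing) response is positive.  The raw
#' signed slope is returned alongside.
#'
#' @param ve_by_level named list or numeric vector mapping the gas level
#'   (%, as names) to minute ventilation — either numbers in
#'   mL·100 g^-1·min^-1 or [ventilation_summary()] objects
#' @param mode `"hcvr"` (levels 0.03 and 7) or `"hvr"` (levels 21 and 10)
#' @return list of class `chemoreflex_gain` with `gain`, `raw_slope`,
#'   `mode`, `levels`
#' @export
chemoreflex_gain <- function(ve_by_level, mode = c("hcvr", "hvr")) {
  mode <- match.arg(mode)
  want <- if (mode == "hcvr") c(0.03, 7) else c(21, 10)
  lv <- as.numeric(names(ve_by_level))
  if (length(ve_by_level) != 2L || anyNA(lv))
    stopf("need exactly two named levels")
  get_ve <- function(x) if (inherits(x, "ventilation_summary")) x$ve
                        else as.numeric(x)
  ve <- vapply(ve_by_level, get_ve, 0)
  ord <- match(want, lv)
  if (anyNA(ord)) {
    # tolerate approximate level labels (e.g. "0.03" vs 0.03)
    ord <- vapply(want, function(wv) {
      i <- which(abs(lv - wv) < 1e-6)
      if (length(i) != 1L) NA_integer_ else i
    }, 1L)
  }
  if (anyNA(ord))
    stopf("%s needs levels %s", toupper(mode), paste(want, collapse = " and "))
  ve <- unname(ve[ord]); lv <- unname(lv[ord])
  raw <- (ve[2L] - ve[1L]) / (lv[2L] - lv[1L])
  gain <- if (mode == "hvr") -raw else raw   # per % FIO2 *decrease*
  structure(list(gain = gain, raw_slope = raw, mode = mode, levels = lv),
            class = "chemoreflex_gain")
}

#' Post-EHS ventilatory-plasticity deltas
#'
#' Per requested timepoint, the change (post minus pre) in VT, Rf and
#' minute ventilation relative to the pre-stimulation baseline; ventilatory
#' long-term depression therefore appears as a negative delta-VE.
#'
#' @param pre baseline [ventilation_summary()]
#' @param post_series list of `list(minutes = , summary = )` entries, the
#'   post-stimulation timepoints (0-90 min)
#' @return data frame with columns `minutes`, `delta_vt` (mL/100 g),
#'   `delta_rf` (breaths/min), `delta_ve` (mL·100 g^-1·min^-1)
#' @export
post_ehs_deltas <- function(pre, post_series) {
  if (!inherits(pre, "ventilation_summary")) stopf("missing baseline summary")
  rows <- lapply(post_series, function(p) {
    s <- p$summary
    stopifnot(inherits(s, "ventilation_summary"))
    data.frame(minutes = p$minutes,
               delta_vt = s$vt_per100g - pre$vt_per100g,
               delta_rf = s$rf - pre$rf,
               delta_ve = s$ve - pre$ve)
  })
  do.call(rbind, rows)
}

#' Measure chemoreflex gain on a synthetic (or recorded) gas session
#'
#' Segments the flow, summarizes ventilation over stable windows in the
#' final `plateau_s` seconds of each exposure level, and computes the
#' two-level slope.
#'
#' @param bundle a [recording_bundle()] with flow and a two-level protocol
#' @param mode `"hcvr"` or `"hvr"`
#' @param plateau_s plateau window at the end of each segment (s)
#' @return a [chemoreflex_gain()]
#' @export
measure_chemoreflex <- function(bundle, mode = c("hcvr", "hvr"),
                                plateau_s = 300) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "recording_bundle"),
            inherits(bundle$protocol, "gas_protocol"))
  series <- segment_breaths(bundle$flow, bundle$body_mass)
  key <- if (mode == "hcvr") "fico2" else "fio2"
  prot <- bundle$protocol
  ve_by_level <- list()
  for (lev in unique(prot[[key]])) {
    seg <- prot[prot[[key]] == lev, ][1L, ]
    t1 <- seg$end
    t0 <- max(seg$start, t1 - plateau_s)
    ve_by_level[[as.character(lev)]] <-
      ventilation_summary(series, c(t0, t1))
  }
  chemoreflex_gain(ve_by_level, mode)
}
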