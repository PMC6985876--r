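# End-to-end orchestration: simulate (or load) a recording, run the
# analysis stages in dependency order, and emit a reproducible report.

ALL_STAGES <- c("breaths", "events", "variability", "expiration",
                "hemodynamics", "hrv", "coupling", "chemoreflex")

#' Build a validated pipeline run configuration
#'
#' Unknown argument names are rejected.  The defaults describe a 10-min
#' resting recording analyzed with scaled-down spectral windows so a full
#' simulate-then-analyze run stays interactive; all module parameters are
#' exposed.
#'
#' @param synth a [synth_config()] driving the simulation (default: 600-s
#'   resting recording)
#' @param stages character vector of stages to run (subset of
#'   breaths, events, variability, expiration, hemodynamics, hrv, coupling,
#'   chemoreflex)
#' @param flow_path,pressure_path optional CSV inputs replacing simulation
#' @param out_dir optional output directory for per-stage CSV/JSON files
#' @param poincare_n breaths for the Poincare window
#' @param expiration_segments,expiration_cycles active-expiration sampling
#' @param hrv_window_s,hrv_subwindow_s,hrv_ar_order AR spectral settings
#' @param coupling_record_s,coupling_segment_s coherence settings
#' @param chemo_exposure_s exposure length for the gain challenges (s)
#' @param seed seed override (defaults to `synth$seed`)
#' @return list of class `run_config`
#' @export
run_config <- function(synth = synth_config(duration = 600),
                       stages = ALL_STAGES,
                       flow_path = NULL, pressure_path = NULL,
                       out_dir = NULL,
                       poincare_n = 300L,
                       expiration_segments = 3L, expiration_cycles = 20L,
                       hrv_window_s = 240, hrv_subwindow_s = 60,
                       hrv_ar_order = 16L,
                       coupling_record_s = 300, coupling_segment_s = 60,
                       chemo_exposure_s = 600,
                       seed = NULL) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$stages, ALL_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stopifnot(inherits(cfg$synth, "synth_config"))
  if (!is.null(seed)) cfg$synth$seed <- seed
  cfg$seed <- cfg$synth$seed
  class(cfg) <- "run_config"
  cfg
}

mean_stable_ventilation <- function(series, t0, t1, window_s = 10) {
  starts <- seq(t0, t1 - window_s, by = window_s)
  sums <- lapply(starts, function(s) {
    tryCatch(ventilation_summary(series, c(s, s + window_s)),
             error = function(e) NULL)
  })
  sums <- Filter(Negate(is.null), sums)
  if (!length(sums)) {
    # fall back to a single whole-range summary on sparse records
    return(ventilation_summary(series, c(t0, t1)))
  }
  vt <- mean(vapply(sums, `[[`, 0, "vt_per100g"))
  rf <- mean(vapply(sums, `[[`, 0, "rf"))
  structure(list(vt_per100g = vt, rf = rf, ve = vt * rf,
                 window = c(t0, t1), n_valid_cycles = NA_integer_,
                 valid = TRUE),
            class = "ventilation_summary")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated (or
#' loaded) recording and returns a flat summary of the headline quantities:
#' VT, Rf, VE, SD1/SD2/CV-VT, event rates and durations, AHI, E2/E1 and Te,
#' SBP/DBP/MABP/PP/HR, LF/HF (normalized units and ratio), VT-SBP
#' coherence, and the chemoreflex gains HVR and HCVR.  Identical
#' configurations produce byte-identical reports.
#'
#' @param config a [run_config()]
#' @return list of class `pipeline_report` with elements `summary` (named
#'   numeric list), `tables` (per-stage data frames) and `config_seed`
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$synth
  summary <- list(seed = cfg$seed)
  tables <- list()

  if (!is.null(config$flow_path)) {
    flow <- read_signal(config$flow_path)
    breaths_truth <- NULL
  } else {
    rec <- generate_breathing(cfg)
    flow <- rec$flow
    breaths_truth <- rec$breaths
    tables$truth <- as.data.frame(rec$truth)
  }
  pressure <- NULL
  need_pressure <- any(c("hemodynamics", "hrv", "coupling") %in% config$stages)
  if (!is.null(config$pressure_path)) {
    pressure <- read_signal(config$pressure_path)
  } else if (need_pressure) {
    pressure <- generate_pressure(cfg, breaths_truth)$pressure
  }

  series <- NULL
  if ("breaths" %in% config$stages) {
    series <- segment_breaths(flow, cfg$body_mass)
    vs <- mean_stable_ventilation(series, flow$start_time,
                                  flow$start_time + trace_duration(flow))
    summary$vt_per100g <- vs$vt_per100g
    summary$rf <- vs$rf
    summary$ve <- vs$ve
    tables$breaths <- series$breaths
  }
  events <- NULL
  if ("events" %in% config$stages) {
    if (is.null(series)) stopf("stage 'events' requires stage 'breaths'")
    events <- detect_events(series)
    es <- event_summary(events, trace_duration(flow))
    summary$apnea_rate <- es$apnea_rate
    summary$hypopnea_rate <- es$hypopnea_rate
    summary$ahi <- es$ahi
    summary$sigh_rate <- es$sigh_rate
    summary$post_sigh_apnea_rate <- es$post_sigh_apnea_rate
    summary$apnea_duration <- es$mean_durations[["apnea"]]
    summary$hypopnea_duration <- es$mean_durations[["hypopnea"]]
    summary$post_sigh_apnea_duration <- es$mean_durations[["post_sigh_apnea"]]
    tables$events <- as.data.frame(events)
  }
  if ("variability" %in% config$stages) {
    if (is.null(series)) stopf("stage 'variability' requires stage 'breaths'")
    ps <- poincare_stats(series, config$poincare_n)
    summary$sd1 <- ps$sd1
    summary$sd2 <- ps$sd2
    summary$cv_vt <- ps$cv_vt
  }
  if ("expiration" %in% config$stages) {
    if (is.null(series)) stopf("stage 'expiration' requires stage 'breaths'")
    ex <- active_expiration(series, flow, config$expiration_segments,
                            config$expiration_cycles, seed = cfg$seed)
    summary$e2_e1 <- ex$ratio
    summary$te <- ex$te
  }
  beats <- NULL
  if ("hemodynamics" %in% config$stages) {
    if (is.null(pressure)) stopf("stage 'hemodynamics' requires pressure")
    beats <- detect_beats(pressure)
    b <- beats$beats
    summary$sbp <- mean(b$sbp)
    summary$dbp <- mean(b$dbp)
    summary$mabp <- mean(b$map)
    summary$pp <- mean(b$pp)
    summary$hr <- 60000 / mean(b$rr, na.rm = TRUE)
    tables$beats <- b
  }
  if ("hrv" %in% config$stages) {
    if (is.null(beats)) stopf("stage 'hrv' requires stage 'hemodynamics'")
    # Kalman smoothing is a time-domain QC step; spectra are computed on the
    # raw tachogram (ML level-smoothing would strip the HF band).
    tach <- build_tachogram(beats)
    bp <- band_powers(psd_ar(tach, config$hrv_window_s,
                             config$hrv_subwindow_s, config$hrv_ar_order))
    summary$lf_nu <- bp$lf_nu
    summary$hf_nu <- bp$hf_nu
    summary$lf_hf <- bp$lf_hf
  }
  if ("coupling" %in% config$stages) {
    if (is.null(series) || is.null(beats))
      stopf("stage 'coupling' requires stages 'breaths' and 'hemodynamics'")
    vt_s <- breath_parameter_series(series, "vt")
    sbp_s <- beat_parameter_series(beats, "sbp")
    cr <- coherence_vt_sbp(vt_s, sbp_s, config$coupling_record_s,
                           config$coupling_segment_s)
    summary$coherence <- cr$mean_coherence
    summary$coherence_peak_freq <- cr$peak_freq
    summary$coherence_significance <- cr$significance_level
  }
  if ("chemoreflex" %in% config$stages) {
    ex_s <- config$chemo_exposure_s
    hc_prot <- gas_protocol(c(0, ex_s), c(ex_s, 2 * ex_s),
                            fio2 = c(21, 21), fico2 = c(0.03, 7))
    hv_prot <- gas_protocol(c(0, ex_s), c(ex_s, 2 * ex_s),
                            fio2 = c(21, 10), fico2 = c(0.03, 0.03))
    hc <- measure_chemoreflex(generate_chemo_session(cfg, hc_prot)$bundle,
                              "hcvr", plateau_s = ex_s / 2)
    hv <- measure_chemoreflex(generate_chemo_session(cfg, hv_prot)$bundle,
                              "hvr", plateau_s = ex_s / 2)
    summary$hcvr <- hc$gain
    summary$hvr <- hv$gain
  }

  report <- structure(list(summary = summary, tables = tables,
                           config_seed = cfg$seed),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Serialize a pipeline report
#'
#' Writes `summary.json` (fixed 10-digit formatting, so identical runs are
#' byte-identical) and one CSV per stage table.
#'
#' @param report a [run_pipeline()] result
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")
  for (nm in names(report$tables)) {
    df <- report$tables[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Two-arm demo study: resting ("Sham-like") vs disease-like generators
#'
#' Runs paired seeded simulations of a resting-parameter arm against an arm
#' with elevated event rates, larger LF heart-period modulation and a
#' positive VT-to-SBP coupling gain, and recovers AHI, LF/HF and coherence
#' for each seed.  One-sided paired sign tests (disease > resting) are
#' reported per metric.
#'
#' @param seeds integer vector of seeds (default 1:20)
#' @param breathing_s breathing-recording length per seed (s)
#' @param pressure_s pressure-recording length per seed (s)
#' @return list with `results` (data frame: seed, arm, ahi, lf_hf,
#'   coherence) and `p_values` (named vector of sign-test p-values)
#' @export
demo_study <- function(seeds = 1:20, breathing_s = 2700, pressure_s = 600) {
  arm_cfg <- function(seed, arm) {
    if (arm == "resting") {
      synth_config(duration = breathing_s, seed = seed)
    } else {
      synth_config(duration = breathing_s, seed = seed,
                   apnea_rate = 7.8, hypopnea_rate = 5.8, sigh_rate = 16.8,
                   post_sigh_apnea_prob = 0.79,
                   interval_jitter_sd = 60,
                   lf_mod = list(freq = 0.3, depth = 4.5),
                   coupling_gain = 20, e2e1_target = 0.89)
    }
  }
  rows <- list()
  for (seed in seeds) {
    for (arm in c("resting", "disease")) {
      cfg <- arm_cfg(seed, arm)
      rec <- generate_breathing(cfg)
      series <- segment_breaths(rec$flow, cfg$body_mass)
      es <- event_summary(detect_events(series), trace_duration(rec$flow))
      pr <- generate_pressure(cfg, rec$breaths, duration = pressure_s)
      beats <- detect_beats(pr$pressure)
      bp <- band_powers(psd_ar(build_tachogram(beats), window_s = 240,
                               subwindow_s = 60))
      sub <- breath_series(series$breaths[series$breaths$onset <
                                            pressure_s - 2, , drop = FALSE],
                           series$body_mass)
      cr <- coherence_vt_sbp(breath_parameter_series(sub, "vt"),
                             beat_parameter_series(beats, "sbp"),
                             record_s = 300, segment_s = 60)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, arm = arm, ahi = es$ahi, lf_hf = bp$lf_hf,
                   coherence = cr$mean_coherence)
    }
  }
  res <- do.call(rbind, rows)
  sign_p <- function(metric) {
    d <- res[[metric]][res$arm == "disease"] -
         res[[metric]][res$arm == "resting"]
    d <- d[d != 0]
    stats::binom.test(sum(d > 0), length(d), alternative = "greater")$p.value
  }
  list(results = res,
       p_values = c(ahi = sign_p("ahi"), lf_hf = sign_p("lf_hf"),
                    coherence = sign_p("coherence")))
}
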