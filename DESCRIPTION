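Package: cardioresp
Title: Cardiorespiratory Signal Analysis for Rodent Plethysmography and
    Blood-Pressure Telemetry
Version: 0.1.0
Authors@R:
    person("cardioresp", "developers", email = "cardioresp@example.org",
           role = c("aut", "cre"))
Description: Analysis of conscious-rodent cardiorespiratory recordings:
    breath segmentation and disordered-breathing event scoring
    (apneas, hypopneas, sighs, post-sigh apneas) from whole-body
    plethysmography airflow, Poincare breath-interval variability,
    active-expiration (E2/E1) quantification, arterial-pressure beat
    detection with Kalman-smoothed heart rate, autoregressive heart-rate
    variability spectra with rodent LF/HF bands, tidal-volume to
    systolic-pressure coherence coupling, and chemoreflex gain (HVR,
    HCVR) under episodic hypercapnic stimulation protocols.  Includes a
    synthetic recording generator with programmable event rates,
    variability, expiratory shape, autonomic spectra, coupling gain and
    chemoreflex gains that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
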