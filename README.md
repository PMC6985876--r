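# cardioresp

Cardiorespiratory signal analysis for conscious-rodent physiology: breath
scoring and ventilatory variability from whole-body plethysmography
airflow, autonomic indices from blood-pressure telemetry, and the coupling
between the two.

## Who this is for

Labs recording unrestrained rats (or mice) in a plethysmography chamber
with radiotelemetric arterial pressure, who need the standard derived
quantities of the field computed reproducibly from raw traces:

* **Breath pattern** — breath segmentation from calibrated airflow; tidal
  volume (VT, mL/100 g), respiratory frequency (Rf), minute ventilation
  (VE = VT × Rf); scoring of apneas (gap ≥ 3 breathing cycles), hypopneas
  (VT ≤ 50 % of the 3 preceding normal breaths), sighs (VT ≥ 150 %) and
  post-sigh apneas; the apnea–hypopnea index (AHI, events/h).
* **Ventilatory variability** — Poincaré SD1/SD2 of the breath-to-breath
  interval over 300 consecutive breaths
  (SD1 = popSD((xᵢ₊₁−xᵢ)/√2), SD2 = popSD((xᵢ₊₁+xᵢ)/√2)) and the VT
  coefficient of variation.
* **Active expiration** — the E2/E1 ratio of late- to early-expiratory
  area under the flow curve, on randomly sampled eupneic segments
  (3 × 20 cycles).
* **Hemodynamics & HRV** — beat detection from dP/dt maxima; per-beat
  SBP/DBP/MAP/PP; Kalman-smoothed heart rate; Burg autoregressive RR
  spectra with rodent bands (LF 0.04–0.6 Hz, HF 0.6–2.4 Hz), normalized
  units and the LF/HF sympathovagal balance index.
* **Cardiorespiratory coupling** — Welch magnitude-squared coherence
  between VT oscillations and systolic pressure, averaged over a 0.1-Hz
  band at the VT spectral peak, with an analytic significance level.
* **Chemoreflex** — hypercapnic and hypoxic ventilatory response slopes
  (HCVR: FICO2 0.03 % → 7 %; HVR: FIO2 21 % → 10 %), episodic hypercapnic
  stimulation (EHS) schedules, and post-EHS ventilatory-plasticity deltas.
* **Echocardiography** — Teichholz volumes V(D) = 7.0/(2.4+D)·D³, stroke
  volume, ejection fraction, fractional shortening, and the
  volume-overload screening criterion.

Because raw animal recordings are rarely shareable, the package ships a
**synthetic recording generator** (`synth_config()`, `generate_breathing()`,
`generate_pressure()`, `generate_chemo_session()`) that emulates all of the
above with programmable event rates, variability, expiratory shape,
autonomic spectra, coupling gain and chemoreflex gains — and emits exact
ground-truth annotations, so every analysis stage is testable end to end.
See the methods vignette (`vignettes/methods.Rmd`) for the models and
design choices.

## Worked example

Simulate a 10-min recording with elevated event rates and VT→SBP coupling,
then run the full pipeline:

```r
library(cardioresp)
cfg <- synth_config(duration = 600, seed = 42, coupling_gain = 10,
                    apnea_rate = 12, hypopnea_rate = 6)
rep <- run_pipeline(run_config(synth = cfg))
str(rep$summary[c("vt_per100g", "rf", "ve", "ahi", "sd2", "cv_vt",
                  "e2_e1", "hr", "lf_hf", "coherence", "hcvr")])
```

which prints (numbers produced by this exact code):

```
vt_per100g   0.311      # mL/100 g        (programmed 0.31)
rf           81.6       # breaths/min     (programmed 85)
ve           25.367     # mL/100g/min
ahi          42         # events/h: 7 events in 10 min -> coarse per-hour rate
sd2          215.463    # ms; inflated by apnea gaps inside the 300-breath window
cv_vt        12.295     # %
e2_e1        0.68       # programmed 0.68
hr           298.064    # beats/min       (programmed 298)
lf_hf        1.299      # programmed ~1.1
coherence    0.936      # VT-SBP band coherence; coupling_gain 10 is strong
hcvr         4.191      # mL/100g/min per %FICO2 (programmed 4.1)
```

Reading these: VT, Rf, HR, E2/E1 and HCVR recover their programmed values;
the AHI of a 10-min record is granular (one event = 6/h); SD2 over a raw
300-breath window includes apnea gaps — score events first if you want
eupneic-only variability. Re-running with the same seed reproduces the
report byte-for-byte.

A command-line front end with `simulate`, `breaths`, `events`,
`expiration`, `beats`, `hrv`, `coupling`, `chemoreflex`, `report` and
`demo` subcommands is installed at `inst/cli/cardioresp.R`:

```sh
Rscript inst/cli/cardioresp.R simulate --seed 3 --duration 600 --out out/
Rscript inst/cli/cardioresp.R events --flow out/flow.csv --out out/
```

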