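---
title: "Methods: breath scoring, variability, autonomic spectra and coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath scoring, variability, autonomic spectra and coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioresp)
```

`cardioresp` analyzes cardiorespiratory recordings from conscious,
unrestrained rodents: calibrated airflow from whole-body plethysmography
(mL/s) and arterial pressure from radiotelemetry (mmHg, nominally 500 Hz).
This vignette is the package's account of its methods: the models and
conventions behind each stage, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Conventions

Time is in seconds from recording start; all rates are in Hz; analysis
windows are half-open `[t0, t1)`. Tidal volume (VT) is carried in mL on raw
traces and normalized per 100 g body mass only in summaries, so minute
ventilation is reported in mL·100 g^-1^·min^-1^. Inspiration is positive
flow by convention. The airflow sampling rate is configurable; 1 kHz is the
default (the pressure channel's 500 Hz is the only rate fixed by the
recording hardware convention).

## Breath segmentation

Breath onsets are upward crossings of a hysteresis threshold set to 5 % of
the 95th percentile of |flow|; a new onset is accepted only after the flow
has visited the negative threshold, i.e. after a completed expiration. This
two-threshold scheme is robust to noise riding on the inspiratory peak and
to the near-zero flow of apneic pauses. The expiratory offset is the end of
the contiguous below-threshold expiratory excursion — runs separated by
less than 50 ms are merged so noise on the decaying flow cannot truncate an
expiration, while isolated noise dips inside an apnea stay separate and
cannot shorten the measured gap. Both the expiratory onset (zero crossing)
and offset are refined to sub-sample precision by linear interpolation;
this matters for the E2/E1 areas below, where a one-sample bias at 1 kHz is
already visible at the third decimal. VT is the trapezoidal integral of
inspiratory flow. Candidate breaths shorter than 100 ms or with VT below
10 % of the running median are discarded as artifacts. All thresholds are
arguments of `segment_breaths()`.

## Event scoring

Definitions follow the standard rodent plethysmography criteria:

* **apnea** — an inter-breath gap (last expiratory offset to next
  inspiratory onset) of at least 3 local breathing cycles;
* **hypopnea** — a breath with VT at or below 50 % of the mean VT of the 3
  most recent *normal* breaths;
* **sigh** — a breath with VT at or above 150 % of that same reference;
* **post-sigh apnea** — an apnea whose onset falls within one cycle of a
  sigh offset (not double-counted as spontaneous).

Two quantities in these rules are not self-defining and were fixed as
package design choices: "one breathing cycle" is the mean onset-to-onset
interval of the 10 preceding normal breaths (10 balances adaptivity against
stability), and "normal" excludes sighs, hypopneas and the two breaths
flanking an apnea, so the reference cannot be contaminated by the events it
serves to detect. The apnea-hypopnea index (AHI) is the sum of the apnea
and hypopnea rates; post-sigh apneas are tabulated separately. Apnea
duration is measured from the last expiratory offset (the alternative —
from expected next-breath time — can be derived from the emitted onsets).

`ventilation_summary()` implements the 10-s stable-segment convention with
a `10 ± 2` valid-cycle flag. Note that at the rat's eupneic 85 breaths/min
a 10-s window holds ~14 cycles, so that flag is useful mainly at lower
respiratory rates; the pipeline's summary averaging therefore uses plain
10-s windows.

## Breath-interval variability

`poincare_stats()` projects the lag-1 interval scatter onto the axes
perpendicular to and along the identity line, over the first 300
consecutive intervals (in ms):

$$SD1 = \mathrm{popSD}\!\left(\tfrac{x_{i+1}-x_i}{\sqrt2}\right),\qquad
  SD2 = \mathrm{popSD}\!\left(\tfrac{x_{i+1}+x_i}{\sqrt2}\right),$$

with population (1/n) variances, matching the geometric ellipse definition
(documented to avoid n−1 ambiguity). Consequently
$SD1^2 + SD2^2 = \mathrm{Var}(x_1) + \mathrm{Var}(x_2)$ exactly, which the
tests assert against a brute-force rotation oracle. The VT coefficient of
variation is computed over the same breaths with the sample SD; sighs are
included in that pool by default (a config flag excludes them), since the
scoring convention does not say otherwise.

## Active expiration (E2/E1)

Three non-overlapping segments of 20 consecutive eupneic cycles — no scored
event inside, gaps below one cycle — are chosen reproducibly from a seed,
standing in for the blind operator's random choice. For each cycle the
expiration is split at half the expiratory time; E1 and E2 are the areas
under |flow| over the early and late halves (trapezoidal integration with
interpolated endpoints so the split need not fall on a sample; areas of
magnitude rather than signed flow, as expiratory flow is single-signed in
eupnea). The ratio reported is `mean(E2)/mean(E1)`, so `e1`, `e2` and
`ratio` are mutually consistent.

## Beat detection and heart-rate smoothing

Beats are located at maxima of dP/dt — central differences after a 20-Hz
windowed-sinc low-pass — exceeding 30 % of the running (10-s chunk) 95th
percentile, with an 80-ms refractory period. dP/dt maxima rather than
pressure maxima define beat times because the pressure upstroke is the
sharpest, most shape-robust landmark. Per-beat SBP/DBP are the cycle
max/min; MAP is the waveform time-average by default (the full waveform is
available; `map_rule = "third"` selects DBP + PP/3); PP = SBP − DBP.

RR smoothing uses a local-level (random-walk) state-space model with
fixed-interval smoothing. The noise variances are not prescribed by any
convention we know of, so they are estimated by maximum likelihood
(`stats::StructTS`), with a fixed-variance override exposed. Smoothing is a
*time-domain* quality-control step: because a maximum-likelihood
local-level smoother acts as a low-pass on the RR series, applying it
before spectral analysis would strip most high-frequency band power, so
the spectral pipeline below always consumes the unsmoothed tachogram.

## HRV spectra

The RR tachogram is built by cubic interpolation of RR (placed at the beat
closing each interval) onto a uniform 10-Hz grid — Nyquist 5 Hz comfortably
covers the rodent HF band edge at 2.4 Hz. Spectra use rodent band
conventions: LF 0.04–0.6 Hz, HF 0.6–2.4 Hz; normalized units divide by
LF+HF (with these bands this coincides with dividing by total-minus-VLF
when no power lies below 0.04 Hz); LF/HF indexes sympathovagal balance.

The estimator reading adopted for "autoregressive after Hann windowing with
50 % overlap" is Welch-style: the 10-min window is split into 60-s
subwindows with 50 % overlap, each mean-removed and Hann-tapered (taper
normalized to unit mean-square so power is preserved), a Burg AR model of
order 16 is fit per subwindow, and the AR spectra are averaged. This is the
most literal reading that keeps both phrases meaningful; setting
`subwindow_s = window_s` recovers a single-window AR estimate. Burg is the
standard numerically stable AR estimator; order 16 is config-exposed and
the order sensitivity is mild for the two-peak spectra involved. One
numerical point deserves emphasis: near-noiseless AR poles produce spectral
peaks far narrower than any casual frequency grid, and integrating such a
peak on a coarse grid silently loses most of its power — the default grid
is therefore 8193 points (≈0.0006 Hz), at which the Parseval check
(spectral integral vs tapered-series variance) holds within 5 %.

## Cardiorespiratory coupling

Per-breath VT (input) and per-beat SBP (output) are cubic-interpolated onto
a common 4-Hz grid (the oscillations of interest are well below 2 Hz) and
mean-removed. Welch auto- and cross-spectra over a 10-min artifact-free
record — Hann taper, 120-s segments, 50 % overlap, hence 9 segments — give
the magnitude-squared coherence $C(f) = |P_{xy}|^2/(P_{xx}P_{yy})$. The
segment length is a compromise: 120 s resolves ≈0.008 Hz, enough to
resolve a 0.1-Hz band, while retaining enough segments for the estimate to
be meaningful (the coherence of a single segment is identically 1). The
reported `mean_coherence` averages C over a 0.1-Hz band centered on the VT
autospectrum peak within the low-frequency domain, taken as 0.01–0.6 Hz
(upper edge matching the LF band; lower edge avoiding DC leakage). The
analytic zero-coupling threshold $1-\alpha^{1/(L-1)}$ for L segments is
reported alongside.

## Chemoreflex gains and ventilatory plasticity

HCVR is the slope of minute ventilation between FICO2 0.03 % and 7 %; HVR
the slope between FIO2 21 % and 10 %, reported per % FIO2 *decrease* so a
normal response is positive (the raw signed slope is also emitted). Gains
are measured on 10-min exposures, summarizing ventilation over the plateau
(final half) of each level. `ehs_schedule()` builds the episodic
hypercapnic stimulation protocol — 10 cycles of 5-min 7 % CO~2~ separated
by 5-min normoxia, 100 min in total — and `post_ehs_deltas()` reports
post-minus-pre changes in VT, Rf and VE, so ventilatory long-term
depression appears as a negative ΔVE.

## The synthetic generator: what it emulates

The generator is the package's ground truth and is itself first-class,
tested code. Its defaults are the resting values of the healthy conscious
rat: 85 breaths/min, VT 0.31 mL/100 g at 250 g body mass, breath-interval
SD 45 ms with AR(1) coefficient 0.4 (giving long-term variability SD2
≈ 53 ms through $SD2 = \sigma\sqrt{1+\phi}$), VT CV 8.7 %, apneas 3.4/h,
hypopneas 1.2/h, sighs 12.8/h with post-sigh-apnea probability 0.94, E2/E1
0.68, HR 298 beats/min with SBP/DBP 124/88 mmHg, LF/HF ≈ 1.1, zero
VT→SBP coupling, HCVR 4.1 and HVR 1.0 mL·100 g^-1^·min^-1^ per percent
(the HVR default is our choice of a physiologically plausible magnitude;
no group value is printed for it).

Mechanics, chosen for analytic control rather than biophysical realism:

* **Breath waveform** — half-sine inspiration (amplitude $VT\pi/2T_i$) and
  exponential expiration with $\tau = -T_e / (2\ln r)$, which makes the
  noise-free E2/E1 equal exactly the target $r$ (constant flow at $r=1$;
  the same formula covers $r>1$, i.e. active expiration).
* **Interval variability** — stationary AR(1) jitter; the coefficient maps
  monotonically onto SD2/SD1 asymmetry via $SD1 = \sigma\sqrt{1-\phi}$,
  $SD2 = \sigma\sqrt{1+\phi}$.
* **Events** — homogeneous Poisson counts, the simplest null consistent
  with events/h reporting, placed on breaths at least 18 cycles apart so
  the detection references stay clean. Apnea durations are drawn uniformly
  on 3.3–5.5 cycles (spontaneous) and 5.5–7.0 cycles (post-sigh), matching
  the reported mean durations (~3.1 s and ~4.4 s at the eupneic cycle).
  Sighs scale VT by 1.9 and hypopneas by 0.4 — chosen a priori so that
  programmed events clear the 1.5×/0.5× detection thresholds by more than
  two SDs of the lognormal VT noise at the default CV.
* **Pressure** — a smooth dbp→sbp→dbp pulse at 500 Hz; the heart period
  carries an LF sinusoid, an HF sinusoid locked to the respiratory rate,
  and white noise; the per-beat systolic level is offset by
  `coupling_gain` × the VT deviation of the current breath.
* **Gas challenges** — minute ventilation follows a first-order response
  (τ = 30 s) toward baseline + `hcvr_gain`·FICO2 + `hvr_gain`·max(0,
  21−FIO2), realized by scaling Rf and VT equally ($\sqrt{s}$ each).

A single global seed drives independent substreams per channel, so the
flow and pressure channels can be regenerated independently and all
outputs are bit-reproducible.

What the generator does **not** emulate: hemodynamic waveform realism (no
Windkessel), CO~2~ washout physiology, behavioral artifacts (sniffing,
movement), drifting baselines, or genuine post-stimulation ventilatory
plasticity (its ventilation returns to target once the stimulus ends). A
green recovery test therefore establishes that the analysis chain is
unbiased and consistent *under the stated statistical structure* — not
that it is robust to every artifact of real chamber recordings.

## Numerical choices and degenerate inputs

Trapezoidal integration is used throughout (flows are smooth at the stated
rates); band and area integrals interpolate their endpoints. Flat signals,
windows without breaths, series shorter than the Poincare window, zero HF
power, protocols that do not tile time, and event loads that would occupy
more than half the recording all raise errors rather than returning
degenerate numbers. Write/read round-trips are exact to double precision
(17 significant digits); reports are serialized with fixed 10-digit
formatting so identical runs are byte-identical.

## Known limitations

The event scorer assumes the generator's convention that breath amplitude
and timing carry the events; obstructive-vs-central apnea classification
is out of scope. Echocardiographic inputs are accepted as cavity diameters
only (the canonical cubed-diameter volume formula, documented in
`teichholz()`, is the package's choice — the source convention names the
method without printing a formula). Group-level statistics across animals
are deliberately not provided.
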