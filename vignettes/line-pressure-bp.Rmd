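---
title: "Estimating brachial blood pressure from dialysis line pressures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brachial blood pressure from dialysis line pressures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(linebp)
library(dplyr)
library(purrr)
```

## The measurement problem

Intradialytic hypotension — a fall in systolic pressure of more than
20 mmHg or in mean arterial pressure (MAP) of more than 10 mmHg during a
haemodialysis treatment — is a frequent and clinically serious event, yet
blood pressure during dialysis is normally recorded only every half hour by
an occluding arm cuff. Continuous non-invasive alternatives (tonometry,
pulse-transit time, finger volume clamp) restrict movement, are sensitive
to disturbance, or are unreliable in patients with poor peripheral
circulation.

`linebp` implements an alternative that needs no sensor on the patient at
all: two pressure transducers on the extracorporeal circuit, one on the
arterial line close to the fistula needle and one on the venous air trap,
both sampled at 1 kHz. From these two signals plus the routine intermittent
cuff readings, the package reconstructs brachial MAP continuously over the
treatment.

## The model

**Pump flow from the venous trace.** The peristaltic blood pump's lobes
impose a strong periodic pressure oscillation on the venous line. Any
periodic waveform can be expanded as a Fourier series; only the fundamental
is needed, so the pump frequency is taken as the dominant spectral
component of a sliding analysis window. Flow follows from pump geometry —
one rotation displaces the swept line volume:

$$fl = \frac{fr}{2\pi} \cdot 60 \cdot \pi r^2 L_n,$$

with $fr$ the rotation frequency in rad/s, $r$ the in-pump line radius and
$L_n$ the effective in-pump line length (mm). The default geometry
($r = 4$ mm, $L_n = 107.8$ mm) maps 1 rev/s to about 325 ml/min, a typical
prescription.

**Calibration.** Between the needle tip (pressure $P_1$, area $A_1$) and
the arterial sensor (pressure $P_2$, area $A_2$), steady incompressible
flow obeys Bernoulli/continuity,
$f = A_2 \left[\, 2 (P_1 - P_2) / (R\,(1 - (A_2/A_1)^2)) \right]^{1/2}$.
Almost everything in that expression — $P_1$, $A_1$, density, viscosity,
the metre of tissue and tubing between fistula and cuff site — is
unmeasurable or patient-specific, so it is absorbed into a single lumped
parameter $C$:

$$C = \frac{2\,(P_b - P_2)}{(f / A_2)^2},
\qquad
P_b = P_2 + \tfrac{1}{2}\,(f/A_2)^2\, C,$$

where $P_b$ is brachial MAP from the cuff and $P_2$ the arterial line
pressure after heavy smoothing. Each cuff reading paired with the
concurrent $P_2$ and flow yields one $C$; the session mean then converts
the continuous $P_2$ and flow into a continuous MAP estimate.

### Units of C

Internally everything is canonical: mmHg, ml/min, mm², seconds, rad/s. The
one subtle choice is the unit of $C$. The Bernoulli relation is physics:
with pressure in Pa and $f/A_2$ read as a velocity in m/s, $C$ is a
density-like coefficient in kg/m³. `linebp` reports $C$ in units of
$10^3$ kg/m³ (numerically g/cm³), on which clinically observed values fall
between roughly 5 and 11 — e.g. $C = 8$ with 325 ml/min through a 14g
needle corresponds to a 218 mmHg gap between cuff MAP and arterial line
pressure, exactly the regime of a real treatment (cuff around +90, line
around −130). `c_unit_scale()` returns the conversion constant; passing
`unit_scale = 1` to `c_from_point()` / `estimate_map()` gives the raw
canonical-unit ratio instead. Magnitudes reported by other instruments may
differ by their own unit conventions; ratios of $C$ between needle gauges
do not.

## Signal conditioning choices

* **Causal boxcar, 5000 samples.** Both lines are smoothed with a trailing
  5000-sample (5 s at 1 kHz) moving average. Trailing, not centred: the
  method is a real-time one and may not use future samples. At the start of
  a trace the filter is a running mean over the samples available so far —
  no values are fabricated. A 5 s boxcar annihilates any component with an
  integer number of cycles per window (exactly nulls 1.0 and 1.2 Hz tones)
  and attenuates white sensor noise by $\sqrt{5000} \approx 70$.
* **Window and hop.** Frequency estimates use the same 5000-sample window,
  advanced by 1000 samples: a 1 Hz update cadence, each estimate stamped
  with the time of its *last* sample (its real-time "as-of" time). Several
  cohort-scale analyses in the tests and the acceptance script use
  hop = width (one estimate per 5 s) since calibration needs flow only at
  cuff times; results are unchanged, runtime is fivefold lower.
* **Spectral estimation.** Each window is DC-removed, Hann-tapered,
  zero-padded 8-fold past the next power of two, and the in-band
  (0.2–3 Hz) periodogram peak is refined by parabolic interpolation on
  log-power. Across the clinical flow range with default noise the flow
  error stays around 0.1%, comfortably inside the ±1% agreement band the
  method is expected to achieve (the acceptance script reports the
  measured band).
* **Pump-off detection.** A window is declared pump-off when the in-band
  peak fails a signal-to-noise test. The statistic matters: on a *single*
  periodogram the maximum of the ~14 independent in-band noise bins has a
  heavy tail, so a fixed threshold separates pump-on from pump-off poorly.
  The detector therefore averages four half-overlapped Hann sub-windows
  (Welch) and takes the noise floor as the median power over a reference
  band four times wider than the search band, which tames the tail by
  orders of magnitude while genuine pump tones still exceed the threshold
  by a factor of hundreds (the test suite asserts zero false detections
  across its pump-off windows). Pump-off windows produce *gaps* in the
  flow series, never zeros.
* **Lobe ambiguity.** A two-lobed pump compresses the line twice per
  rotation, so the dominant venous tone could be the rotation frequency or
  twice it. The conversion treats the detected peak as the rotation
  frequency by default — consistent with the ~1 Hz / 325 ml/min
  arithmetic — and `detected_is_lobe_frequency = TRUE` divides by the lobe
  count; the simulator exposes the matching `pump_tone_is_lobe` flag so
  both interpretations are testable end to end.

## Pairing, aggregation, degenerate inputs

A calibration point pairs a cuff MAP with the filtered $P_2$ at the cuff
time (nearest sample, ties to the earlier one) and the nearest *preceding*
flow estimate. Cuff readings before the pump starts, or outside the
flow-estimable span, are skipped with a recorded reason; a session with no
usable reading raises a `no-calibration` error. The session $C$ is the
unweighted mean of the point values (a median alternative sits behind the
`aggregate` flag). $A_2$ is always the *arterial* needle area — that is
where the sensor sits — while the venous gauge is metadata, and gauge sets
are labelled by the venous gauge following renal-unit convention (set 16 =
15g arterial / 16g venous). Degenerate fits (fewer than 3 points, or no
variance in $P_2$) raise `degenerate-fit` errors rather than returning
nonsense; a constant response is reported as slope 0 with $R^2 = 0$.

Outliers in the per-gauge $C$ summaries are flagged by
median ± 3·MAD. Any such rule involves a choice; MAD-based flagging is
robust to the very outliers being sought, and sessions from immature
vascular access (the classic clinical culprit) sit far outside the core
bands, so membership is insensitive to the constant.

## What the simulator emulates — and what it does not

`simulate_session()` generates both traces *from the model plus disturbance
terms*, so ground truth (flow, $C(t)$, MAP$(t)$) is known exactly and
parameter recovery is a well-posed test:

* venous: baseline (+150 mmHg while pumping) + pump fundamental (default
  30 mmHg) + second harmonic at 0.3× + white noise (1 mmHg);
* arterial: $\text{MAP}(t) - \tfrac12 (f/A_2)^2 C(t)$ + pump oscillation
  (40 mmHg) + cardiac tone (1.2 Hz, 5 mmHg) + white noise;
* cuffs: true MAP + 2 mmHg measurement noise, every 75 s in the default
  600 s test profile — eight readings per session, the same per-treatment
  count as a 30-minute cadence over 4 hours. `full_session_config()` gives
  the full-length profile (4 h, pump enabled at 2000 s, cuffs every
  30 min). The 600 s default keeps the whole suite and the acceptance runs
  to a few minutes; problem sizes used are ten 600 s sessions for the flow
  sweep, twenty for noisy calibration, and 11–37-session cohorts for the
  regression and gauge analyses.
* cohorts: gauge sets 14/15/16 with true mean $C$ of 6 / 8.5 / 10.25 and
  between-session s.d. 0.5 (the width of the observed per-gauge core
  bands), within-session linear drift with time-s.d. 0.05, per-session MAP
  baselines uniform on 70–110 mmHg with slow drift, and per-gauge flow
  prescriptions inside the clinical 278–394 ml/min range (smaller needles
  run lower flows).

The generator is deliberately *not* a haemodynamic model: no Windkessel,
no ultrafiltration dynamics (hypotensive episodes are scripted raised-
cosine dips), no baroreflex, no cardiac waveform on the venous side, no
motion artefacts, and the arterial trace satisfies the calibration
relation by construction. Passing tests therefore demonstrate that the
*pipeline recovers the model's parameters under realistic disturbance
amplitudes* — not that the quasi-linear model itself is physiologically
complete, which only patient data can show. The relative amplitudes of
pump versus cardiac components in the arterial line are plausible
placeholders, not reported values.

The cardiac default of 1.2 Hz is deliberately non-harmonic with the ~1 Hz
pump tone. Components closer than the 5 s window's spectral mainlobe
(~0.4 Hz half-width) bias the peak — the known failure mode when heart
rate and pump speed coincide — and a config with
`cardiac_freq_hz` equal to the pump frequency reproduces it.

## The cohort regressions and a known degeneracy

`compensated_fit()` contrasts two pooled regressions of cuff MAP on
arterial pressure: one on the raw points, one with each point's MAP
replaced by the prediction from its session-mean $C$ — the scatter
re-expressed with within-session $C$ variation (and cuff noise) removed.
With one shared constant $C$ the two fits coincide exactly; whenever
within-session variation is material the compensated $R^2$ exceeds the
pooled one, and the effect grows monotonically with the within-session
s.d. (demonstrated in the test suite at s.d. 0.05 / 0.4 / 1.2).

One limitation deserves honesty. In a cohort that mixes needle-gauge sets,
the gauge-dependent $C$ means and the clinical flow range together force
per-set pressure gaps that differ by hundreds of mmHg, so the *pooled*
MAP-vs-$P_2$ slope across the whole cohort is dominated by between-set
offsets and is statistically indistinguishable from zero (its standard
error matches its size at n ≈ 88). Relative statements about that slope —
e.g. "compensation moves the slope by under 5%" — are then noise, not
signal, and the acceptance suite documents the corresponding check as
failing by construction on the mixed default cohort. Within a single gauge
set, or at materially larger within-session variation, the compensation
contrast behaves as expected.

## A worked session

```{r pipeline}
sim <- simulate_session(sim_config(duration_s = 300, cuff_interval_s = 60,
                                   cuff_first_s = 30, seed = 42))
session <- sim$session
flow <- flow_series(session$venous, session$pump)
filtered <- moving_average(session$arterial, 5000)
cal <- session_calibration(session, flow, filtered)
cal
est <- continuous_bp(session, cal$c_session, flow, filtered)
summary(est$map_mmhg - ground_truth_at(sim, est$time_s))
```

```{r plots}
autoplot(flow)
autoplot(est, cuffs = session$cuffs)
```

## Limitations

* MAP only: systolic/diastolic waveforms are not reconstructed.
* $C$ is treated as constant (or causally updated) within a session; the
  quasi-linear model is explicitly an approximation and time-variant or
  nonlinear extensions are out of scope.
* The cuff-vs-line regressions here characterise *synthetic* cohorts; the
  package reproduces procedures, not any particular patient study's
  printed statistics.
* No artefact rejection beyond the boxcar: real sessions with line
  manipulation, alarms, or transducer flushes would need additional
  conditioning.
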