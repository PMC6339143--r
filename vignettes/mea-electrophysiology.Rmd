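---
title: "Modelling and analysing population-level extracellular recordings on large-area MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing population-level extracellular recordings on large-area MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meawave)
```

## The measurement problem

Cancer cell lines such as PC-3 are not classically excitable, yet
populations of them generate picoampere-scale extracellular currents.
Recording those currents is feasible with large-area (mm^2) planar gold
electrodes: the large area lowers the electrode impedance and sums the
contributions of thousands of coupled cells, trading spatial resolution
for signal-to-noise. meawave packages the quantitative side of such an
experiment: a circuit model of the recording chain, a synthetic generator
of the reported activity regimes, spike detection and classification, and
the derived physiological quantities (wave speed, inhibition response,
growth and viability summaries).

## The equivalent-circuit measurement model

The electrode-electrolyte interface is modelled as a charge-transfer
resistance $R_D$ in parallel with the double-layer capacitance $C_D$, in
series with the spreading resistance $R_c$. A cell-generated voltage
$v_s(t)$ drives a displacement current through $C_D$,

$$ i_s(t) = \frac{dv_s}{dt}\, C_D \left(1 - e^{-(t-t_0)/\tau}\right), $$

which a transimpedance stage converts to the recorded voltage
$v_o(t) = -R_F\, i_s(t)$. For the time constant we use the charging time
of $C_D$ through the parallel resistor pair,
$\tau = C_D\, R_c R_D/(R_c+R_D)$: this is the form consistent with the
stated topology and has the right dimensions. The $(1-e^{-t/\tau})$
charging factor is referenced to the start of the supplied trace, the
only defined origin for a sampled recording.

Numerics: the derivative uses central differences in the interior
(second-order accurate, no phase lag) and one-sided differences at the
ends. For $t > 10\tau$ the model output converges to $C_D\, dv_s/dt$
within 1% on an analytic ramp, which the test suite asserts. Defaults
($R_D$ = 10 MOhm, $C_D$ = 1 uF, $R_c$ = 10 kOhm, $R_F$ = 1 GOhm) describe
a mm^2-scale gold electrode; no measured values are available for the
specific chip, so all are configurable. The seal impedance $Z_{seal}$
enters no equation; it is carried only to warn when a configuration
violates the high-seal assumption ($Z_{seal} < 10\max(R_D, R_c)$).

## What the synthetic generator emulates

Raw recordings for this experimental system are not publicly deposited,
so the package ships a generator whose defaults encode the reported
study conditions, and every analysis is validated against its ground
truth log:

* **Baseline**: medium-only recordings show fluctuations below 1 pA. The
  generator draws white Gaussian noise scaled so the theoretical
  0.01–99.99 percentile span equals `baseline_noise_pp` and bounds
  samples at half the span, so the configured peak-to-peak is a hard
  guarantee. The default span is 0.8 pA, keeping simulated baselines
  strictly under the 1 pA level. Peak-to-peak of an unbounded Gaussian is
  otherwise undefined, hence the quantile calibration.
* **Asynchronous-sporadic regime**: uncorrelated single-cell activity as
  Poisson-timed unipolar Gaussian lobes, amplitude ~ N(100, 30) pA,
  mostly negative (70%), widths log-uniform on 20–220 ms so that ~80% of
  draws fall in the reported 30–200 ms band. The event rate default,
  0.1 events/s, is set so that the detected-count disparity between the
  two regimes lands at the reported ~10x (no rate is reported directly).
* **Quasi-periodic biphasic regime**: cooperative activity as
  charge-balanced pairs of +150/−150 pA Gaussian lobes, lobe widths
  log-uniform on 50–300 ms, lobe-peak separation 0.3 s (or electrode
  diameter over wave speed when a wave geometry is supplied), and onsets
  advancing by ISIs from N(2, 1) s truncated to [1, 10] s. Note the
  truncation raises the effective mean ISI to about 2.29 s, so the
  realised event rate is about 0.44 events/s rather than exactly 0.5;
  this is a property of the stated interval distribution, not a free
  parameter.
* **Inhibition protocol**: synchronous activity, then a block phase in
  which spiking collapses to sparse sub-threshold residual fluctuations
  (default bound 4 pA, strictly inside the reported sub-5 pA level), then
  recovered activity drawn from the same distributions as the first
  phase. Default phase lengths are 600/1200/600 s, matching a ~20-minute
  inhibitor application flanked by ten-minute observation windows.

Spike lobes are Gaussian because the reported waveforms are smooth but no
functional form is given. The width parameter is defined as the full
width at the 50 pA analysis threshold (falling back to FWHM for lobes
too small to cross it), so detector-measured widths are directly
comparable to ground-truth widths. Overlapping events superpose
linearly — the recorded signal is explicitly the sum of all cell
contributions — and overlaps are counted, never dropped.

What the generator does **not** emulate: spatially resolved wave
propagation (lobe separation is imposed, not simulated), multi-channel
geometry, electrode drift and thermal artifacts, and 1/f or
line-frequency noise. Passing tests therefore demonstrate that the
analysis recovers the statistical structure the generator encodes; they
do not certify performance on real recordings with drift or
non-Gaussian noise (for drift there is an optional sliding-median
baseline correction, off by default since drift minimisation was a
hardware matter in the reference system).

## Detection and classification conventions

Detection is symmetric threshold crossing at ±50 pA by default, the only
analysis level the source experiment names. Each contiguous excursion
beyond the threshold yields one event; the peak is the extremum sample
(earliest wins ties), and the width is the time between the two
threshold crossings, linearly interpolated between samples — "width" has
no reported definition, so the package defines it at the detection
threshold. Same-polarity peaks within a 50 ms refractory gap merge,
keeping the larger. On traces up to 10^4 samples the implementation is
asserted to agree exactly with a naive per-sample oracle.

Biphasic classification is a greedy left-to-right rule: adjacent
opposite-polarity events whose peaks lie within the pairing window
(default 2 s, covering the reported 0.3–2 s separations) form one pair;
everything else is unipolar. Greediness keeps the rule order-independent
and guarantees each event joins at most one pair.

## Regime segmentation and statistics

The source experiment distinguishes the regimes by eye; the package
needs an algorithm. A sliding 30 s window is labelled synchronous when
the event-onset rate reaches 0.2 events/s **and** the inter-onset
interval coefficient of variation is at most 0.6 — quasi-periodic
activity is both frequent and regular, sporadic activity is neither.
Biphasic pairs count once (their first lobe) for rates and ISIs, since
the reported inter-spike intervals are distances between successive
biphasic spikes. Cutoffs sit mid-way between the two regimes' expected
statistics (~0.44 events/s at CV ≈ 0.4 versus ≤0.1 events/s), so the
margin is wide on both sides. Histograms use 50 pA amplitude bins from
50 to 350 pA plus underflow/overflow, 50 ms width bins to 0.5 s, and
1 s ISI bins, matching the granularity of the published statistics.

Wave speed: each biphasic pair converts to electrode diameter divided by
lobe separation. The diameter of the 1 mm^2 circular electrode is taken
as $2\sqrt{A/\pi}$ = 1.128 mm; the looser "1 mm" convention is available
by passing the diameter directly.

## Inhibition calls

"Activity almost disappears" and "counts are close" are operationalised
as: block when the during-phase count is at most 10% of the before-phase
count and the during-phase fluctuation magnitude is at most 5 pA;
recovery when the after-phase count is within ±50% of the before-phase
count. The fluctuation magnitude is the 99.5th percentile of the
absolute median-subtracted current — a robust peak measure a single
stray sample cannot defeat, invariant to offsets. Phases are half-open
intervals `[start, end)`, so a boundary event belongs to the phase that
starts there.

## Growth and viability arithmetic

Cell-count tables (electrodes x days) summarise to per-day mean and
S.E.M (sample sd over sqrt(n)); both rows are normalised by the
final-day average, making the final normalised average exactly 1. The
published table's day-4 normalised value is inconsistent with its own
average row (285.0000/1193.6250 = 0.2388, printed 0.2089), and its
normalised-S.E.M row follows no stated formula; the package documents
and uses the self-consistent definitions, which reproduce days 1–3 to
four decimals. MTT percent viability is the condition mean over the
negative-control mean (control treated as fixed for the S.E.M
propagation); hypothesis testing on the plate is left to standard tools.
Dilution arithmetic is exact: 3 uL of 1 mM stock into 280 uL of medium
gives 1000·3/283 ≈ 10.6 uM.

## Problem sizes and determinism

Simulation-based checks use 60 s baselines, 600 s single-regime and
1200 s two-regime recordings, and 2400 s inhibition experiments at
1 kHz — long enough that regime statistics stabilise (hundreds of events
per regime) while keeping the full suite inside a few minutes. All
randomness flows through the config seed; identical config and seed give
bit-identical traces, ground truth and reports.

## Known limitations

* Single channel only: no cross-electrode synchrony, so "synchronous" is
  inferred from temporal regularity, not spatial coincidence.
* The circuit model is lumped and first-order; no impedance
  spectroscopy, no amplifier noise physics beyond the additive baseline
  term.
* The segmentation cutoffs are tuned to the two reported regimes; exotic
  intermediate regimes would need re-tuning.
* HDF5 containers are not read by this build; recordings interchange as
  CSV (`time_s,current_pA`).
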