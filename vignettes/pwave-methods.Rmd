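---
title: "Measuring P-wave indices on simulated 12-lead ECGs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring P-wave indices on simulated 12-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwavekit)
```

## The measurement problem

Atrial depolarization writes a small, slow deflection — the P wave — into
every lead of the surface ECG. Four scalar indices of that wave are widely
used as markers of atrial conduction and left-atrial (LA) remodeling:

* **PWD** (P-wave duration, ms): time from P onset to P offset; prolonged
  conduction reflects atrial conduction delay.
* **PWV** (P-wave voltage, mV): distance from the isoelectric line to the
  P peak. This package reports, by default, the 12-lead *sum* of per-lead
  peak amplitudes, which puts the index at the conventional 1.2–1.3 mV
  magnitude (12 leads at roughly 0.1 mV each); `max` and `mean` rules are
  selectable.
* **PWDisp** (P-wave dispersion, ms): the maximum difference between
  per-lead P-wave durations, a heterogeneity marker.
* **PTFV1** (P-wave terminal force in V1): in lead V1 the P wave is
  typically biphasic; PTFV1 is the product of the deepest amplitude of its
  terminal negative phase and the duration of that phase, reported as a
  non-positive number. The package computes depth(mV) × duration(ms); the
  printed magnitudes of roughly −3 "mm·s" in the clinical literature this
  emulates correspond to that convention (the classical mm·s display unit,
  ×10 mm/mV × 10⁻³ s/ms, is available via `compute_ptfv1(unit = "mm.s")`).

Around these indices the package implements the full measurement chain used
in pre/post ablation studies — acquisition-matched filtering, beat
detection, 20-beat P-wave template averaging, geometric delineation — plus
a calibrated synthetic cohort generator with closed-form ground truth and a
two-arm statistical layer, so that the whole chain can be validated end to
end against known truth.

## The synthetic beat model

No public dataset accompanies the kind of pre/post repeat-ablation cohort
this pipeline targets, so the generator *is* the reference world. One beat
is parameterised per lead (`pwave_morphology()`):

* **P and T waves** are truncated, baseline-shifted Gaussian lobes. A lobe
  of amplitude $a$, center $c$ and support width $w$ is
  $a\,(e^{-(t-c)^2/2\sigma^2} - e^{-2})/(1 - e^{-2})$ with $\sigma = w/4$,
  and exactly zero outside $[c - w/2,\, c + w/2]$.
* **QRS** is a triangle whose corners are rounded with a 16 ms Hann kernel.
* **V1** carries a biphasic P: a positive lobe whose support is directly
  followed by a negative lobe of depth $d$ and width $w_{neg}$.

Two modelling decisions deserve justification because a plain Gaussian
would have been simpler:

1. **Compact support.** With infinite Gaussian tails, "onset" and "offset"
   are not well defined and any finite convention (e.g. ±3σ) disagrees
   systematically with a geometric delineator. Truncation makes the
   analytic fiducials exact: per-lead PWD equals the support width, the V1
   negative-phase duration equals $w_{neg}$, and analytic
   PTFV1 $= -d \cdot w_{neg}$.
2. **Non-zero corner slope.** The truncated lobe meets the baseline with a
   finite slope ($\approx 0.31\,a/\sigma$), so the onset/offset corners
   survive band-limited acquisition as identifiable curvature maxima. The
   QRS corners are rounded *in the generator* because a hard corner rings
   under the 50 Hz low-pass and the resulting pre-QRS undershoot would
   contaminate the P-offset search — physiological QRS feet are not
   discontinuous either.

Beat timing: QRS onset is fixed at 250 ms into the beat; the T wave peaks
at QRS onset + 0.43·RR (a rate-adaptive QT surrogate, which guarantees the
preceding T peak always falls inside the averaging window); each P-wave
support ends 30 ms before QRS onset. The RR interval is fixed within a
record: the measurement averages consecutive beats, so heart-rate
variability would not change the measurands, only complicate alignment.

`make_patient_template()` returns the sampled beat *and* this closed-form
ground truth; `generate_record()` tiles beats and adds white noise,
sinusoidal baseline wander and mains interference (`noise_config()`,
defaults 15 µV, 100 µV at 0.25 Hz, 30 µV at 50 Hz — ordinary clinical
acquisition conditions), reproducibly from a seed.

## Filtering

The acquisition contract is a 1–50 Hz band-pass with a mains notch over a
±5 mV, 16-bit range. No IIR-filter package is available in this
environment, so the package applies the filters in the frequency domain:
the signal is reflect-padded and multiplied by the *squared* magnitude
response of a 4th-order Butterworth band-pass (and an analog notch with
Q = 30) — exactly the zero-phase gain a forward–backward (filtfilt)
application realises. Zero phase matters: duration measurements cannot
tolerate group delay. The trade-offs of this choice are documented
behaviour: the heart-rate fundamental (≈1.2 Hz) sits near the 1 Hz edge, so
a small beat-periodic low-frequency residual ("sag") survives filtering;
the delineator is designed to be insensitive to it (below).

## Beat detection and template averaging

R peaks are found by thresholding a 60 ms moving average of the squared
first difference on lead II and refining each region to the raw-amplitude
extremum; QRS onset is the last pre-peak sample within 6% of the local
baseline-to-R excursion. Twenty consecutive beats — after excluding beats
whose preceding RR deviates more than 20% from the record median (ectopy
guard) — are aligned on their R peaks and averaged per lead over a window
spanning the last 60% of the median RR before QRS onset. The window
therefore contains the preceding T peak, the TP baseline, the P wave and
the PQ segment, and its last sample is QRS onset. Averaging suppresses
uncorrelated noise by $1/\sqrt{20}$, which the test suite verifies
empirically.

## Delineation

Fiducials are located per lead by chord geometry:

* **P peak**: the extremum of the widest deflection whose width at
  half-prominence is at least 15 ms — narrower spikes are rejected.
  Candidates must exceed 30% of the window's dominant deflection and be
  narrower than 60% of the window (this rejects the broad shallow humps
  the low-frequency sag produces). In V1 a qualifying *positive* lobe is
  preferred: in a biphasic P the peak anchor is the initial positive
  deflection even when the terminal negative phase is wider.
* **Onset** is located with the chord-distance (knee) rule: the interior
  sample at maximal perpendicular distance from the chord joining the
  T peak to the P peak. Taken literally in one pass, that knee lands on the
  *T-end* corner whenever the T wave is taller than the P wave, so the rule
  is applied in two stages: the first knee (the T end) becomes the chord
  anchor and the knee is recomputed. The second knee is accepted when the
  first lay before any plausible P onset, or when the segment between the
  two knees is flat relative to the P upstroke — a slope ratio that is
  insensitive to the residual sag. A literal "minimum" perpendicular
  distance would be attained at the chord's endpoints and cannot define an
  onset; the knee (maximum-distance) reading is the standard one.
* **Offset** mirrors the rule on the chord from the P peak to QRS onset,
  with two refinements: the chord is anchored at QRS onset *at the
  isoelectric (late-PQ) level* rather than at the sampled amplitude (which
  sits on the filter-smoothed QRS foot and would tilt the chord), and the
  15 ms immediately before QRS onset are excluded from the search. If the
  knee turns out to be a sub-baseline trough (a terminal negative phase, as
  in V1), the chord is re-anchored at the trough and recomputed, so the
  offset lands at the return to baseline after the negative phase.
* **Numerical de-biasing.** Band-limited acquisition smears the support
  corners over the filter's transition width, which biases a strict argmax
  knee outward by several ms. Two documented constants compensate: knee
  distances within a small tolerance of the maximum (1 µV on the onset
  chords, 3 µV on the offset chords — the template's effective amplitude
  resolution) are treated as ties and broken toward the later sample, and
  the onset is refined to the maximal-curvature sample within ±6 ms. With
  these, noiseless end-to-end recovery of per-lead PWD is within 5 ms and
  global PWD is unbiased to a fraction of a ms across the tested morphology
  range. The tie window also means exact mirror symmetry of a symmetric
  lobe holds to the tie-window width (a few samples), not to one sample.
* **V1 negative phase**: the contiguous sub-baseline run between the P peak
  and the offset (the whole wave when the P is entirely negative), relative
  to a two-anchor linear baseline interpolated from the TP window before
  onset to the PQ window after offset. The linear baseline (rather than a
  constant TP median) removes the first-order effect of the sag on trough
  depth, which would otherwise bias PTFV1 by up to ~10%. Runs shallower
  than 10 µV are reported as "no negative phase" (PTFV1 = 0), a valid
  outcome rather than an error.
* Leads whose delineated duration falls outside 30–220 ms are flagged
  unmeasurable; a record must retain at least 9 of 12 measurable leads to
  emit global parameters. Manual corrections enter through the
  annotation-override API (`delineate_template(overrides = ...)`): any
  override satisfying onset < peak < offset is honored verbatim.

All indices inside templates are 1-based R sample indices; exported
fiducials and durations are in ms, so nothing downstream depends on the
indexing convention.

## Cohort calibration

`calibration_config()` (backed by the plain-text fixture in
`inst/extdata/calibration_cohort.txt`) encodes a two-arm pre/post world:
43 patients whose repeat pulmonary-vein isolation succeeds and 29 whose
arrhythmia recurs. Population analytic means are set to the arm-level
values the package is designed to reproduce — success arm PWD
136.7 → 123.5 ms and PTFV1 −3.1 → −4.4 mV·ms; failed arm 135.4 → 125.3 ms
and −2.9 → −2.7 mV·ms; PWV ≈ 1.2–1.3 mV; PWDisp ≈ 28–30 ms — and the
morphology mapping is linear, so the calibration is solved in closed form:
the longest-lead width equals the PWD target, a fixed per-lead width
ranking spans the PWDisp target, amplitudes are rescaled to the PWV sum,
and the V1 negative lobe is depth = |PTFV1|/45 ms over a 45 ms support.

Between-patient SDs are back-solved from the reported significance of the
paired pre/post comparisons: a paired t-statistic $t = \bar\Delta /
(SD_\Delta/\sqrt{n})$ at the printed p-value fixes $SD_\Delta$, which is
split equally between independent pre and post draws
($SD_{phase} = SD_\Delta/\sqrt2$). This yields phase SDs of 23 ms (success)
and 13.4 ms (fail) for PWD, and 2.0 / 0.94 mV·ms for PTFV1. PTFV1 draws are
clipped at zero — a patient whose draw is non-negative simply has a
monophasic V1 P wave, which both truncates realistically and keeps the
analytic arm mean within ~2% of the target. Heart rate is 72 ± 5 bpm;
per-lead width jitter is 1.5 ms.

Two statistical consequences are worth stating plainly:

* A single cohort draw at n = 43/29 has arm-mean sampling SEMs of ~0.3
  mV·ms (PTFV1) and ~2.5–3.5 ms (PWD); recovery of the calibration targets
  is therefore asserted *within 2 SEM*, not exactly.
* With effect sizes faithful to the printed p-values, the per-seed
  probability of the full qualitative significance pattern (success arm
  significant, failed arm not, arms differing) is only ≈0.6–0.85. The
  acceptance check of that pattern is therefore made on the *median*
  p-values across seeds 1–5 — the modal study outcome — rather than
  demanding every seed reproduce it, which the stated effect sizes cannot
  guarantee.

## Statistical layer

Summary statistics are mean ± SEM (SD/√n). Pre/post comparisons within an
arm use a paired t-test on the differences when the D'Agostino–Pearson
omnibus test (K² = Z₁² + Z₂², χ² with 2 df; implemented from the published
skewness and kurtosis transformations and verified against an independent
re-derivation and reference values) does not reject normality at 0.05;
otherwise the Wilcoxon signed-rank test. Between-arm comparisons are run on
per-patient change scores with Welch's t (the safer unequal-variance
default; Student's t selectable) or the rank-sum fallback. The gate
requires n ≥ 8 (the K² approximation's validity floor); smaller samples
take the parametric path. Every result records which test ran. Two-sided
p-values throughout; no multiple-testing correction, matching the
single-outcome reporting style it emulates.

The intraobserver protocol (`run_intraobserver()`) re-measures 22 synthetic
12-lead ECGs with seeded annotation jitter (default SD 2 ms on onset,
offset and the V1 trough) emulating a human's second pass, and reports raw
(mean |Δ| ± SEM) and percentage variability, the percentage denominator
being the mean absolute parameter value across both runs. 22 ECGs × 12
leads × 20 beats = 5280 P waves per pass.

## What a green test does and does not establish

The generator emulates: sinus rhythm at fixed RR, lobe-shaped P/T waves,
biphasic V1, lead-specific amplitudes and durations, additive white noise,
baseline wander and mains. It does not emulate: atrial-fibrillation
episodes or ectopy (the ectopy guard is exercised only trivially),
respiration modulation, electrode-motion artifacts, notched/bifid P waves,
or inter-lead timing dispersion of onsets (per-lead durations vary; onsets
are aligned to a common offset gap). Green tests therefore establish that
the measurement chain is correct and well-calibrated *for clean
sinus-rhythm morphology of this family*, not that it is robust to every
clinical artifact.

## Numerical choices (summary table)

| Constant | Value | Where | Why |
|---|---|---|---|
| Lobe σ | width/4 | generator | support = ±2σ, finite corner slope |
| QRS corner kernel | 16 ms Hann | generator | suppress >50 Hz ringing |
| T-peak position | QRS onset + 0.43 RR | generator | stays inside averaging window for any RR |
| Averaging window | 60% of RR before QRS onset | `average_pwave` | covers T peak → PQ |
| RR ectopy guard | ±20% of median | `average_pwave` | excludes irregular beats |
| Peak width floor | 15 ms at half-prominence | `detect_p_peak` | spike rejection |
| Peak amplitude floor | max(15 µV, 30% of window max) | `detect_p_peak` | noise/sag rejection |
| Knee tie window | 1 µV (onset) / 3 µV (offset) | `chord_knee` | de-bias band-limited corners |
| Onset curvature refinement | ±6 ms, h = 5 ms | `refine_corner` | narrow-lobe corner recovery |
| Pre-QRS exclusion | 15 ms | offset search | QRS foot |
| Negative-phase depth floor | 10 µV | `locate_v1_negative_phase` | below noise resolution |
| Plausible per-lead PWD | 30–220 ms | `delineate_template` | physiological bound |
| Measurable-lead quorum | ≥ 9 of 12 | `measure_record` | quality guard |

## Known limitations

* The knee de-biasing constants are tuned for the 1–50 Hz acquisition
  band; a different passband would shift the corner smear and merit
  re-examination.
* PWDisp inherits the V1 duration, the hardest lead (narrowest positive
  lobe); its recovery bias (−1 to −2 ms) is larger than global PWD's.
* The generator's pre and post draws are independent within a patient — no
  within-patient correlation — so paired tests gain no precision from
  pairing beyond what the SD split implies.
* The D'Agostino–Pearson gate at n = 8–15 is itself noisy; the rank
  fallback triggers in ~15% of null cohorts at n = 10, making the
  whole-pipeline type-I error mildly conservative (verified ≈0.05 ± 0.02).
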