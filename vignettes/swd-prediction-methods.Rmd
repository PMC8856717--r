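---
title: "Predicting spike-and-wave discharges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spike-and-wave discharges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdpredict)
```

## The problem

Spike-and-wave discharges (SWDs) are the electrographic signature of absence
seizures: generalized, rhythmic spike-wave complexes that in the two classic
genetic rat models run at 5–7 Hz (GAERS) or 8–10 Hz (WAG/Rij), last seconds
to half a minute, and recur many times per hour with a pronounced diurnal
rhythm. They arise from the cortico-thalamic loop, with converging evidence
for an initiation network in the deep layers (IV–VI) of the primary
somatosensory cortex (S1). Shortly before onset — a few hundred
milliseconds — a transient 5–10 Hz oscillation (the *precursor*) appears in
these deep S1 layers, and this is the signal a closed-loop
prediction-prevention system would have to catch.

`swdpredict` implements the complete prediction pipeline: sliding-window
wavelet band energies and their cross-channel products, a three-criterion
precursor detector with threshold and recording-site sweeps, onset marking
and true/false-positive labeling, a random-forest stage that filters false
alarms, permutation surrogate statistics, and a synthetic LFP generator so
that every stage is testable end to end without animal recordings.

## The detection statistic

For each recording channel \(c\) and time \(t\), the pipeline computes the
mean wavelet energy \(W_{b,c}(t)\) in three frequency bands \(b\): 5–10 Hz
(precursor), 3–5 Hz (light slow-wave sleep) and 7–20 Hz (sleep spindles),
averaged over a 500-ms window ending at \(t\). Synchronous cortico-thalamic
activation is measured by the per-band product over the \(K \in \{2,3\}\)
channels of a recording-site combination,

\[
P_b(t) \;=\; \prod_{c=1}^{K} W_{b,c}(t),
\]

and a precursor is declared at \(t\) when three criteria hold
simultaneously:

1. \(P_{5\text{–}10}(t)\) exceeds a detection threshold;
2. \(P_{5\text{–}10}(t) > P_{3\text{–}5}(t)\) (not slow-wave sleep);
3. \(P_{5\text{–}10}(t) > P_{7\text{–}20}(t)\) (not a sleep spindle).

Maximal super-threshold runs closer than a 1-s refractory period are merged
into one detection event, time-stamped at the run start. A detection within
the 1-s preictal window before an SWD onset is a true positive (TP); inside
the SWD it is discarded (neither TP nor FP); anywhere else it is a false
positive (FP). Sensitivity is the percentage of SWDs with at least one TP
in their window; the false-alarm rate is FPs per recording hour.

## Numerical choices in the spectral stage

**Morlet parameter.** The wavelet is a complex Morlet with centre frequency
\(\omega_0 = 2\pi\), evaluated on a 0.5-Hz grid within each band. Both are
exposed (`morlet_param`, `freq_step`). `wavelet_spectrum()` is scaled to be
power-preserving: a unit tone contributes band-integrated power 1/2 when
the band resolves the wavelet bandwidth \(f/\omega_0\).

**Causality.** `band_energy_series()` uses the *past-only half* of the
Morlet kernel (renormalised to unit tone response). An online prediction
device only ever sees samples up to \(t\); with the usual symmetric kernel
the enormous ictal energy smears ~0.3 s backwards in time, so every channel
set — including ones with no precursor at all — would "predict" the seizure
from its own onset, and the contrast between recording sites collapses.
The causal kernel removes this leak exactly; its cost is a slightly slower
response (the kernel spans \(5\,\omega_0/2\pi f\) seconds into the past).
`wavelet_spectrum()` keeps the standard symmetric kernel, which is the
right tool for offline time-frequency maps and for cross-checks against
periodogram oracles.

**Normalisation.** The band energies are dimensionless:
\(W_{b,c}\) is divided by `norm_scale` (default 2.5) times the channel's
whole-recording median windowed band energy. The median tolerates the
ictal fraction of a recording (up to ~15 % of samples), where an upper
quantile would not. The scale factor is set once, from the structure of
the published fixed threshold grids: with interictal \(W \approx 0.4\),
three-channel interictal products (~0.06) lie just below the 14-point grid
on [0.1, 0.75], while two-channel products (~0.16) saturate above the
16-point grid on [0.005, 0.04] — reproducing the stated property that the
outer grid values correspond to saturated sensitivity or false-alarm
levels. Plain median normalisation (typical value 1) is available as
`normalization = "median"`.

**Edges and strides.** Two seconds of reflection padding precede the FFTs;
no output is produced for \(t\) earlier than one window length. The stride
defaults to one sample; coarser strides give bit-identical values at shared
time stamps (the normalisation reference is always computed at full
resolution). Pipeline runs use a 10–20 ms stride for tractability.

## Threshold sweeps and calibration

`sweep_thresholds()` evaluates the published fixed grids (14 thresholds on
[0.1, 0.75] for triples, 16 on [0.005, 0.04] for pairs; linear spacing, the
counts and ranges being given but not the spacing). Detection episodes are
found once at the grid minimum and scored by their peak precursor product;
an episode counts at threshold \(\theta\) iff its score exceeds \(\theta\).
This is how a ROC curve is built, and it makes sensitivity and false-alarm
counts non-increasing in the threshold *by construction*. Re-detecting at
every threshold independently can split one elevated episode into several
as the threshold rises, producing spurious false-alarm increments that
violate the monotonicity every user expects of a threshold sweep.

Two details of the score: samples inside an SWD are excluded (an episode
that starts preictally and runs into the seizure is scored by its preictal
evidence, not by ictal energy), and the exclusion starts 0.1 s *before* the
annotated onset and extends 2 s past the offset. The onset is by
convention the peak of the first spike, so that spike's rising edge — and,
because the analysis is causal, a post-offset tail of about one kernel
plus one window length — is seizure signal, not precursor evidence.

`calibrate_threshold()` performs bisection for the largest threshold whose
sensitivity still reaches the target (ties resolve upward, so the 60 %
threshold is never below the 90 % one); unreachable targets return the
grid floor with a flag and a warning.

## The synthetic generator

The generator encodes the study conditions rather than a biophysical
model; each piece is an explicit, tunable convention:

* **Background**: \(1/f^{\alpha}\) Gaussian noise (\(\alpha = 1\)),
  SD 135.9 µV — chosen so that twice the 99th percentile of the absolute
  background equals the 700 µV cortical spike amplitude, making the
  onset-marking rule exactly satisfiable.
* **SWD trains**: per cycle a narrow Gaussian spike (12 ms SD) plus an
  opposite-signed half-sine wave; frequency 5–7 Hz (GAERS preset) or
  8–10 Hz (WAG/Rij), durations 10–30 s / ~7 s, rates 17/h / 10/h with a
  24-h sinusoidal rate modulation for GAERS (relative amplitude 0.5 —
  the diurnal variation is documented but unquantified, so the depth is a
  convention). Thalamic channels get 500/700 of the cortical amplitude,
  reversed polarity, and a 4-ms lag; per-event amplitude jitter is drawn
  upward-only, U(1.0, 1.15), so the first spike always reaches twice the
  background in at least one cortical channel.
* **Precursors**: a tone burst ending at onset, lead time 0.3–0.9 s,
  frequency 5–9 Hz (the range reported to precede SWDs in GAERS; tones
  above ~8 Hz increasingly energize the spindle band and are vetoed by
  criterion 3, which is faithful behaviour), amplitude 1.0 × background SD
  in `precursor_strong` channels (deep S1), 0.3 × in `precursor_weak`,
  absent otherwise. The LFP amplitude of the real precursor is not
  quantified anywhere; these SNR conventions were fixed once, and the
  1.0 × value was kept after checking that a stronger precursor actually
  *weakens* the cortical-vs-thalamic sensitivity ordering (mixed
  combinations saturate toward the capture ceiling).
* **Confounders**: sleep spindles (30/h, 0.5–1 s, 8–16 Hz) and slow-wave
  epochs (4/h, 30 s, 3–5 Hz), both at 1 × background SD, injected away
  from seizures and identically across channels — they are the designed
  source of cross-channel synchronous false alarms.

What the generator does **not** emulate: real electrode artifacts,
behaviourally structured sleep architecture, inter-animal variability of
SWD morphology, and volume-conduction correlations of the background
noise. Passing tests therefore demonstrate that the pipeline recovers the
structure it assumes — not that it would reach the same sensitivities on
rat recordings.

## Classifier and surrogate stages

Detected events carry 6 or 9 features: \(W_{b,c}\) at the detection time
for each band and channel. Training uses the first 70 % of the recording
(a chronological, pseudo-prospective split; the published split fraction is
given but not its mechanism, and a random split would leak future context
into training). Classes are balanced by undersampling (all TPs plus an
equal FP draw) or moderate oversampling (TP set replicated 4×, matched FP
draw; factor from the admissible 2–7 range). 100 forests of 1000 trees are
trained, each with a fresh FP draw, and the forest whose held-out balanced
accuracy is closest to the ensemble mean is kept — reported performance is
that of a representative single forest, not the best one. Majority voting
decides; ties classify as FP, which conservatively suppresses the alarm.

The surrogate test retrains the same architecture on label-permuted
training tables (class sizes preserved, fresh seeds) and compares the
observed balanced accuracy with the 95th linear-interpolation quantile of
the null; the p value uses the add-one convention \((1 + \#\{null \ge
obs\})/(1+n)\). Note that a *single* permuted forest is not pinned to
50 %: majority voting amplifies whatever label imbalance the permutation
leaves in a feature-space neighbourhood, so single-permutation accuracies
scatter by ±10 % even though their mean sits at chance. This is why the
null needs hundreds of permutations and why chance-level calibration is a
statement about the distribution, not about one retrained forest.

## Degenerate inputs and tie-breaks

* Zero or constant signals have no usable normalisation reference; the
  band-energy stage raises a degenerate-signal error rather than emitting
  infinities.
* Events whose spikes never reach twice the background are dropped from
  the annotation with a warning; their time span still counts as
  contaminated when the next event's background window is placed.
* A detection exactly at the onset is a TP (prediction latency zero); the
  first sample after the onset is ictal.
* Calibration ties go to the larger threshold; representative-forest ties
  to the lower seed index; majority-vote ties to FP.

## Problem sizes used in the tests

The suite exercises the full pipeline at reduced but honest scales: 5-min
records for the monotonicity property (20 seeds), 2-h six-channel records
for the site-ordering contrast (10 seeds), a 24-h three-channel GAERS-like
record for the false-alarm-filtering trade-off, 99–200 permutations for
surrogate calibration, and 20–200-tree forests where the tree count is not
itself under test. These sizes were chosen so the whole suite runs on a
laptop-class single core; all of them are parameters, and the defaults of
the exported functions remain at the published values (1000 trees, 100
forests, 1000 randomizations).

## Known limitations

* The absolute scale of the published detection thresholds is not
  reproducible because the original energy normalisation is unstated; the
  scaled-median normalisation makes the grids discriminative on synthetic
  data but individual thresholds should be calibrated per recording
  (`calibrate_threshold`), as the original algorithm also did.
* Group summaries are descriptive (mean ± SEM); the original inferential
  ANOVA/ANCOVA machinery is out of scope, and the per-row sweep tables are
  written to CSV precisely so any statistics package can consume them.
* The EDF codec writes plain EDF (not EDF+); annotations travel in sidecar
  CSV files.
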