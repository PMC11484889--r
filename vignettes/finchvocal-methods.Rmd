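---
title: "Methods: vocal interaction and HVC playback-response analysis"
author: "finchvocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal interaction and HVC playback-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchvocal)
```

## Scope

finchvocal implements the analysis chain used to study how female zebra
finch calls during a juvenile's song practice relate to tutor-song
imitation, and how those calls drive responses in HVC projection neurons.
It covers four layers:

1. **Vocal segmentation** — envelope-based syllable detection, song-bout
   assembly, and attribution of female calls to song windows.
2. **Interaction statistics** — the call ratio, its developmental trend,
   and good/poor learner classification from externally supplied song
   similarity scores.
3. **Electrophysiology** — intracellular playback statistics (firing rate,
   permutation spiking precision, spike clipping, zero-lag subthreshold
   correlation, perturbation deltas) and extracellular unit QC with
   population summaries.
4. **Synthetic data** — generators for every input with known ground
   truth, so each stage can be validated without animal recordings.

Song-similarity scoring itself (SAP-style feature similarity) and neural
network segmentation are out of scope; their outputs are inputs here.

## Conventions

Times are seconds from recording start (float64); sample indices are
0-based; all event intervals are half-open `[onset, offset)`, which ensures
a call on a shared boundary is counted exactly once. Converting seconds to
samples floors onsets and ceils offsets, so a segment is never off by more
than one sample. Event tables are written as CSV with 6-decimal times
(1 µs, well below one sample at the 40 kHz recording rate); membrane
potential sweeps are stored as a plain-text archive (JSON metadata plus one
CSV per sweep at 0.1 µV precision).

## Vocal segmentation

The envelope is a centred moving RMS of the waveform, 5 ms window by
default. Syllables are maximal runs with envelope at or above a threshold,
merged across sub-threshold gaps shorter than 5 ms and discarded below
10 ms. The threshold is adaptive: 6× the 5th-percentile envelope (a noise
floor proxy), floored at 5 % of the envelope peak so that noiseless clips
still segment. These constants are free parameters of the approach — the
method is defined by envelope thresholding, not by specific values — and
can be overridden per channel (female calls on the backpack channel use
the same segmenter with a 20–300 ms duration filter).

Song bouts follow two rules: a silent gap of **at least 350 ms** ends a
bout (closed boundary: a gap of exactly 350 ms breaks the chain), and a
chain is kept as song only when its span — first-syllable onset to
last-syllable offset — is **at least 400 ms** (span of exactly 400 ms is
kept). A female call is song-practice-related iff its *onset* falls inside
a bout window; its offset may extend past the bout.

The syllable rate is the number of syllables divided by the summed
syllable durations, excluding gaps. On the synthetic ABAB tutor playback
(185/155 ms syllables, 119/124 ms gaps) this gives 4/0.680 ≈ 5.88
syllables/s, mean syllable duration 170 ms and mean internal gap
(119 + 124 + 119)/3 ≈ 121 ms. Gap statistics use the three internal gaps
of the ABAB motif.

An optional introductory-note rule can drop up to three leading syllables
shorter than 100 ms and under 0.6× the chain's median syllable duration.
It is **off by default**: there is no standard operational definition of
introductory notes, and the default pipeline stays literal and
reproducible.

Segmentation quality is scored by greedy one-to-one onset matching within
10 ms; the package reuses the precision ≥ 0.80 / recall ≥ 0.68 gate that
the original workflow applied to its neural-network segmenter as its own
quality bar on synthetic sessions.

## Interaction statistics

The call ratio is the number of call onsets inside song-bout windows per
second of summed bout-window duration. The denominator sums bout windows
(first onset to last offset, gaps included): the alternative reading —
vocalisation time excluding gaps — is not used, because the attribution
rule counts calls that fall in intra-bout gaps, and a denominator that
excludes those gaps would mix incompatible supports.

Developmental trends are ordinary least squares of call ratio on age
(days post-hatch), reporting slope, R², the regression F and the two-sided
slope p value. The learner threshold is the upper 95 % bound of the
untutored birds' mean similarity, `mean + 1.96 × SE`, reported to one
decimal (40.7 % for the published 32.023 ± 4.44 %). A z-based rather than
t-based bound reproduces the published threshold. Classification is
strict: similarity must *exceed* the threshold to count as a good learner,
because the threshold is an upper confidence bound on "no learning".

Post-call snippets are 300 ms of song directly after a call, anchored at
the call **offset** by default (`anchor = "onset"` is available; the
source description does not fix the anchor). Controls take the same
within-bout offsets in the nearest unperturbed bout of the same session
that is long enough, with seeded random tie-breaks.

## Intracellular statistics

Spikes are detected at an upward crossing of baseline + 15 mV,
timestamped at the crossing sample, with a 1 ms refractory merge (the
spike-time anchor is otherwise undefined by the method description).
Analysis windows run from call onset to offset + 50 ms; the matched
silence window has the same length and ends 50 ms before call onset, so
the two cannot overlap.

**Spiking precision.** The observed statistic is the mean absolute latency
difference over all pairs of spikes from *distinct* trials inside the
window (within-trial pairs are excluded; including them would dilute the
cross-trial locking signal). The null shuffles spikes across trials 1000
times while preserving the distribution of their occurrence. A plain
reassignment of trial labels that keeps absolute spike times cannot
destroy time-locking, so the default null applies an independent uniform
*circular shift* to each trial's spike train within the window: per-trial
counts and inter-spike structure are preserved, stimulus alignment is
destroyed. An ISI-resampling null is available behind
`nullMethod = "isi"`; neither is asserted to be the historical
construction. The precision score is the z-score
`(mean(null) − D_obs)/sd(null)` — near 0 under the null, positive for
locked spiking, matching the magnitudes the silence baseline should show —
and the responsive criterion is one-sided by default (more precise than
95 % of the null), with a two-sided option. Cells with spikes in fewer
than two trials yield an absent result, never a zero.

**Subthreshold analysis.** Spike removal cuts each detected spike from the
last sample below the detection level before the crossing to the first
sample below it after, replacing the segment by linear interpolation
between those anchors; overlapping cuts merge, and cuts touching a trace
edge are flagged. Stereotypy is the mean zero-lag Pearson correlation over
all unordered trial pairs within the window (zero-variance pairs are
skipped and counted); the same function serves across song-motif
renditions. The delta subthreshold is the per-trial difference of mean Vm
between analysis and silence windows, averaged over trials.

**Perturbation responsiveness.** For motif renditions with a female call,
the instance delta is the spike count in the call epoch (call + 50 ms)
minus the mean count in the same epoch over unperturbed renditions. The
control distribution is built leave-one-out over unperturbed renditions —
the method description says only that control deltas come from unperturbed
renditions, and leave-one-out is the construction that uses them all
without double-counting — and the confidence interval is control mean
± 1.96 control SD. Stereotyped "adult-like" activity yields delta 0 ± 0
and no flags. Subthreshold perturbation flags compare |ΔVm| against the
maximum observed in the adult reference dataset; that bound is not
derivable here and must be supplied explicitly, so the function errors
without it rather than guessing.

## Extracellular units

QC keeps units with ISI-violation index ≤ 0.25, amplitude cutoff < 0.3 and
presence ratio > 0.90. The violation-index criterion is stated in the
source with the opposite inequality; excluding high-violation units is the
only reading that yields well-isolated units, so it is the default, and
the literal reading is available behind `literalIsi = TRUE` with a
warning. Units missing a metric are excluded with reason
`missing_metric`. QC-passing units with spontaneous rate ≤ 2 Hz (measured
over inter-stimulus silence with analysis windows excised) are projection
neurons; above 2 Hz, interneurons — the boundary itself is inclusive for
projections. PSTHs conserve counts exactly. Population summaries pair
each unit's analysis-window firing rate and precision with the matched
silence statistics across the schedule (default: playback every 1.5 s,
60 trials).

## Group statistics

Rank-sum and t comparisons, one-sample t tests and Fisher's exact test are
delegated to the standard R implementations; the package owns the
contracts (exact rank-sum enumeration for pooled n ≤ 20 without ties,
midranks + continuity correction otherwise; constant pooled input returns
p = 1 with a warning; degenerate one-sample input is flagged, not
errored). The nested comparison design
`response ~ 1 + condition + (1 | outer) + (1 | outer:inner)` is fitted by
maximum likelihood via lme4 with a hand-computed two-sided Wald p for the
condition effect; when the nesting is degenerate (one inner group per
observation) the model falls back to outer-only intercepts with a
warning. No multiple-testing correction is applied anywhere, matching the
reporting style the pipeline mirrors.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the analyses assume,
not the acoustics or biophysics of real recordings:

- **Sessions** place song bouts by a Poisson process (default 4–6 bouts
  per minute, ~1.2 s bouts of ≥ 3 syllables, 120 ms syllables, 80 ms gaps
  — typical juvenile zebra finch practice values), and female call onsets
  by an inhomogeneous Poisson process whose in-song rate follows a linear
  age trend floored at zero. Syllables render as band-limited noise
  bursts and calls as harmonic stacks, all with 5 ms cosine ramps to
  avoid clicks; the backpack channel carries juvenile sounds at −20 dB,
  emulating a female-borne microphone. Spectral realism is deliberately
  absent — envelope segmentation does not use it.
- **Intracellular trials** are baseline + a shared stimulus-locked
  waveform + private Ornstein–Uhlenbeck noise (10 ms correlation time, a
  standard smooth-Vm surrogate) + spikes of ≥ 30 mV so the 15 mV detector
  finds every one. The shared waveform is one fixed smooth realization
  per seed, standardized inside the stimulus window, so the expected
  zero-lag pairwise correlation equals the configured variance fraction
  ρ exactly. Locked spikes fire at template latencies with Gaussian
  jitter; the default is a **single** template latency — one
  stimulus-evoked event per presentation, as in call-evoked responses —
  because the mean-pairwise-latency statistic measures dispersion around
  locked events, and spreading locked spikes over several latencies
  within a trial dilutes exactly the contrast the test is built to
  detect. `nTemplateLatencies` exposes the choice.
- **Singing renditions** share a stereotyped motif Vm pattern; perturbed
  renditions add a configurable deflection and/or an exact number of
  extra locked spikes in the call epoch.
- **Populations** draw projection-class units at ≤ 2 Hz and interneurons
  above, with an optional multiplicative call-locked rate increase and
  configurable QC pass/fail.

Every generator is deterministic under its seed. Passing tests on these
inputs demonstrates that the *statistics* behave as specified under their
own assumptions (Poisson counts, OU noise, linear trends); they do not
certify performance on real audio with cage noise, overlapping
vocalisations or non-stationary baselines.

## Numerical choices and problem sizes

Validation suites use sizes chosen to make Monte-Carlo bounds sharp while
staying desk-scale: 200 null cells and 100 powered cells at 1000
permutations for the precision test (type-I within [0.02, 0.10], power
≥ 0.9); 64 trials (2016 pairs) for shared-variance recovery within ±0.05
of ρ = 0.5; 100 replicate birds (16 ages, 2-minute sessions) for ≥ 90 %
slope-CI coverage; 200 sessions for call-ratio unbiasedness at 3 SE; 1000
simulated datasets (4 outer × 5 inner groups × 10 observations) for mixed-
model calibration (type-I in [0.03, 0.08]) and 200 for effect recovery.
Statistical assertions use fixed seeds and 3-SE bands.

## Known limitations

- The envelope segmenter has no spectral model; broadband cage noise at
  amplitudes near the syllable level will break the adaptive threshold.
- The precision-test null is one of several defensible shuffle
  constructions; both provided variants preserve per-trial counts, but
  neither is claimed to replicate the historical implementation exactly.
- The learner threshold uses a z-based bound; a t-quantile with n = 7
  would be wider.
- The adult |Δ subthreshold| reference is an external input; analyses that
  need it fail loudly rather than defaulting.
- Sweep archives store traces at 0.1 µV resolution, ample for mV-scale
  signals but not bit-exact against float32 hardware captures.
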