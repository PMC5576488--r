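---
title: "Separating movement- and immobility-associated sharp-wave ripple content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating movement- and immobility-associated sharp-wave ripple content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplecontent)
```

## The scientific problem

During active navigation, hippocampal CA1 place cells represent the
animal's position continuously. When the animal pauses, a distinct set of
CA1 cells with immobility fields at reward sites stays active, and the
local field potential (LFP) intermittently shows sharp-wave ripples
(SWRs): 150–250 Hz transients during which stored activity patterns are
reactivated. This package implements a complete, testable pipeline that
asks, for each detected SWR, whether the reactivated content involves
movement-associated place cells (MAPs), immobility-associated place cells
(IAPs), or both, and whether simultaneously recorded prefrontal (PFC)
units are modulated differently depending on that content.

The pipeline has six analysis stages — behavior segmentation, SWR
detection, CA1 unit classification, SWR content statistics, PFC
modulation, and spike-train correlation measures — plus a synthetic
session generator that produces recordings with known ground truth so
every stage can be validated end to end without proprietary recordings.

## Behavioral state

Speed is estimated from the tracked position by central differences with
Gaussian temporal smoothing (sigma = 0.25 s). The smoothing constant is a
design choice: raw frame-to-frame differences at 30 Hz flicker across any
threshold; 0.25 s is short relative to the ~6.6 s bouts yet long enough to
suppress tracking jitter. Movement is speed > 4 cm/s, immobility the
complement; a single threshold with no hysteresis and no minimum interval,
so the segmentation is a pure function of the speed trace. Well occupancy
combines recorded beam-break entry/exit intervals (authoritative where
present) with a 10 cm radius rule.

## SWR detection

Each LFP channel is band-passed at 150–250 Hz with a symmetric FIR filter
(Hamming design, transition bands within 25 Hz of the band edges, about
53 dB stopband) applied once with exact group-delay compensation — for a
linear-phase filter this is exactly zero-phase and considerably faster
than forward–backward filtering on multi-million-sample recordings. The
envelope is the magnitude of the analytic signal (computed by FFT),
smoothed with a 4 ms Gaussian; the consensus envelope is the pointwise
median across at least three channels, then normalized to zero mean and
unit SD over immobility samples.

The detection threshold is not a fixed SD multiple. The immobility
envelope distribution is taken as a mixture of a symmetric noise component
and a high-amplitude signal tail; the noise component is estimated by
histogramming the immobility envelope (200 equal-width bins spanning the
data up to the 99.9th percentile — the envelope is normalized and can be
negative, so the histogram spans from the sample minimum rather than
zero), locating the mode, and mirroring the mass below the mode around it.
The threshold is the 99.99th percentile of that mirrored distribution. On
Gaussian noise with mean mu and SD sigma this is mu + 3.719 sigma in
closed form, which the tests verify within 5%; because everything above
the mode is ignored, up to a few percent of high-amplitude contamination
moves the threshold only marginally.

Events are runs above threshold lasting at least 20 ms, extended backward
and forward to the nearest crossing of the immobility mean (zero on the
normalized scale); overlapping extended events are merged (the merge is a
design choice — two threshold crossings inside one mean-crossing envelope
hump are one physiological event), events starting during movement are
discarded, and events extended across a movement boundary are truncated
there. Treating the smoothed envelope magnitude (rather than its square)
as "envelope power" is a second design choice; the mode-mirroring
construction is monotone in scale, so the detected event set is virtually
identical either way.

Event-aligned spectral power uses a sliding periodogram (100 ms windows,
10 ms steps) of the channel-averaged LFP, z-normalized over all windows in
the session; each event reports the mean 150–250 Hz z-power of the first
100 ms after onset.

## CA1 unit classification

Units with spike width < 0.4 ms or session mean rate >= 10 Hz are putative
interneurons and excluded. For pyramidal units with more than 200 spikes,
the immobility firing rate at each reward well is computed with SWR spikes
and SWR time excluded; a maximum well rate >= 3 Hz makes the unit an IAP,
otherwise a MAP. The session mean rate for the interneuron rule includes
SWR spikes (the source analysis is silent on this; including them is the
simpler convention and the margin between pyramidal and fast-spiking rates
is wide).

Well specificity maps the per-well rates, normalized to their maximum,
onto unit vectors at equally spaced angles and reports the resultant
length divided by the summed weights. The division is a deliberate
normalization: the bare resultant length of max-normalized rates can
exceed 1 for multi-well cells, while the resultant-length form is bounded
in [0, 1] and reproduces both analytic anchors (1 for a single active
well, 0 for equal activity at all wells). Spatial coverage — not given a
formula in the source analysis — is defined here as the fraction of
occupied bins (>= 0.1 s) whose smoothed rate reaches 20% of the map peak;
the threshold is configurable. Rate maps divide Gaussian-smoothed spike
counts by Gaussian-smoothed occupancy (sigma = 2 cm, 12 cm extent) on a
2 cm grid, with never-visited bins undefined rather than zero.

## SWR content statistics

An event's participants are the classified units with at least one spike
inside the half-open event window; the event is MAP-only, IAP-only, joint,
or neither (neither-class events are excluded from the counts — the
published totals comprise only the three content classes). The number of
joint events expected under independence is
(n_map + n_joint)(n_iap + n_joint)/n_total, tested against the observed
joint/non-joint split with a 1-d.f. goodness-of-fit chi-square; the
expectation is rounded to an integer for reporting but kept exact for the
test. From the published counts (12881, 5009, 1311) this reproduces the
printed expectation of 4671 (24%).

Pairwise coactivity binarizes participation per event and compares the
observed joint-participation fraction against a null built by permuting
each unit's participation vector independently across events (5000
permutations), reported as a z-score. The per-pair permutation seed is
derived from the global seed and the sorted unit ids, making
z(a, b) = z(b, a) exactly. Pairs enter the group comparison when their
cross-correlogram peak lag lies within 3.3 s (half a typical bout) and
they have more than 100 coincident events; the correlogram for this rule
is computed over a ±10 s window so the criterion can actually bind.

## PFC modulation

For each selected PFC unit (mean rate > 1 Hz during movement or
immobility) and each SWR class with at least 10 events, the modulation
index is I = (r_SWR − r_1s)/r_1s, with r_SWR the mean rate over
[start, start + meanDur) across events (meanDur the class mean duration)
and r_1s the mean rate in the 1 s window centered on the events (here:
on the event midpoint start + meanDur/2; the index is insensitive to this
choice because the event lies inside the window either way).

Significance comes from a circular permutation test: the PETH of the unit
in a ±0.5 s window around event starts (10 ms bins) is compared with 1000
control PETHs in which each event's window spikes are circularly shifted
by an independent uniform offset. The squared deviation of the observed
PETH from the mean control PETH, summed over the bins spanning the mean
event duration, is compared with the same deviation of each control; the
p-value is the exceedance fraction, floored at 1/1000 (the smallest
resolvable value). Both observed and control PETHs are smoothed with a
20 ms Gaussian before the comparison: the statistic then compares mean
firing-rate curves rather than raw counts, which matters for inhibition —
with the ~50 events per class a 30-minute session yields, the unsmoothed
statistic has almost no power to detect a rate decrease, while smoothing
leaves the observed/control exchangeability (and hence the type-I error,
verified by simulation in the tests) untouched. Direction is the sign of
the index when the test is significant.

Significantly modulated units map to four groups — excited only during
IAP-SWRs, excited only during MAP-SWRs, inhibited during either or both,
excited during both — covering the 8 significance combinations other than
doubly non-significant. Expected counts under a uniform distribution over
combinations are round(combos × n/8) (half away from zero, so 2×70/8
gives 18 and 1×70/8 gives 9), tested with one-sided exact binomial tails
toward the observed deviation. Duration-matched controls resample events
within pooled duration deciles; label-permutation controls shuffle class
labels across events; the joint-class regression is ordinary least squares
of the joint index on the two single-class indices.

## The synthetic session generator

The generator embodies the study conditions the analysis assumes, with
ground truth recorded for every latent variable.

* **Behavior**: four wells on a circle (70 cm apart for adjacent wells in
  a 1 m arena), alternating immobility and movement bouts with gamma
  durations (mean 6.6 s, CV ≈ 0.32, the transition cadence reported for
  the task; the resulting time split is close to 50/50). Movement follows
  straight paths with a trapezoidal speed profile (0.25 s ramps, plateau
  ≈ 10–13 cm/s); immobility adds slow sub-centimetre tracking jitter.
  The sharp ramps ensure the 4 cm/s threshold is crossed within ~0.2 s of
  each schedule boundary, so speed-based segmentation can agree with the
  schedule on well over 95% of samples.
* **CA1 units**: 20 MAPs with 2-D Gaussian place fields (sigma 12 cm,
  peak 20 Hz) on randomly chosen path segments, theta-modulated at 8 Hz
  (depth 0.5) and gated to movement, generated by Poisson thinning; 10
  IAPs firing at 5 Hz during immobility at a round-robin home well. The
  5 Hz home rate sits well above the 3 Hz criterion and the 20 Hz field
  peak yields several hundred spikes per MAP in 30 minutes, so
  classification is well-posed under the stated thresholds.
* **LFP and SWRs**: four channels of pink (1/f) noise at 1.5 kHz — pink
  rather than white so the band-pass stage is exercised against a
  realistic spectrum. Events arrive as a Poisson process (0.22 Hz) inside
  immobility bouts with lognormal durations (median 80 ms), a 200 Hz
  carrier under a raised-cosine envelope, and peak envelope equal to
  ripple_snr × √2 × the channel's ripple-band noise SD (SNR defined
  against the RMS envelope of band-limited noise). Each event draws a
  content class with probabilities (0.67, 0.26, 0.07) — the published
  class shares, which inherently embed the below-independence joint
  deficit — and participants per unit by independent Bernoulli draws
  (p = 0.3, at least one per required class), with spike times uniform in
  the event and an optional early-latency offset for IAPs.
  Background CA1 spikes inside the event window plus a 75 ms guard margin
  are removed before content spikes are added: detected event boundaries
  extend to the envelope mean crossing, i.e. beyond the injected window,
  and without the guard the resident well's IAPs would leak background
  spikes into detected windows and the recorded truth class would not
  describe what a boundary-extending detector measures.
* **PFC units**: 16 units with baseline 4 Hz, behavior-locked profiles
  (movement-tuned ×2, immobility-onset with 2 s decay after well entry,
  or flat) and per-class multiplicative SWR gains: 3 for excited classes,
  0.15 for inhibited, with the joint-class gain the geometric mean of the
  single-class gains. The group plan cycles IAP-excited, MAP-excited,
  inhibited, both-excited and flat units.

What the generator does **not** emulate: theta sequences and phase
precession, ordered replay trajectories within events, biophysical LFP
structure (sharp waves, slow gamma), inter-regional conduction delays,
non-Poisson spike statistics (bursting, refractoriness), and electrode
drift. Passing tests therefore demonstrate that the pipeline recovers the
statistical structure it is designed to measure — event times, content
classes, rate modulations — not that it is robust to every artifact of
real recordings.

## Numerical choices and degenerate inputs

All times are seconds from session start and all intervals half-open
[start, end), so boundary spikes are counted exactly once. Every
stochastic operation takes an explicit seed, with stage seeds derived
deterministically from it; identical seeds give bit-identical results,
and sessions round-trip exactly through the plain-text on-disk format
(numerics serialized as %.17g). Degenerate cases are explicit: units
participating in no or every event give an undefined coactivity z with a
flag; constant PETHs are skipped in correlations; wells with no eligible
immobility time report NA rates; a constant envelope raises a degeneracy
error rather than a threshold.

## Problem sizes used in validation

The validation suite runs the full pipeline on a 30-minute session
(~200 injected events, 30 CA1 and 16 PFC units), calibrates the
coactivity null on 1000 independent pairs of 500 events (1000
permutations each), and the circular permutation test on 200 null units —
sizes chosen so each check has enough statistical resolution for its
stated tolerance while the whole suite stays comfortably runnable on a
laptop core.

## Known limitations

The noise-threshold construction assumes the envelope noise mode is
interior to the distribution; heavily contaminated recordings (a large
fraction of samples inside events) would bias the immobility
normalization. Classification pools a single session rather than all
sessions of a day, so the >200-spike criterion binds more tightly than in
multi-session use (a pooling switch is the natural extension). The
coincidence and similarity indices assume stationary behavior-locked
firing across the session. None of the empirical figures quoted in this
vignette are asserted anywhere except where the test suite or the
acceptance script computes them.
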