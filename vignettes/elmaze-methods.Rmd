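---
title: "Methods: single-unit analysis of anxiogenic maze exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-unit analysis of anxiogenic maze exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmaze)
```

## The problem

Ventral hippocampal (vH) neurons change their spatial firing when a
familiar environment acquires an anxiogenic feature. The paradigm elmaze
analyses is an elevated linear maze (ELM): a 120 x 8 cm track with reward
zones at both ends, explored under a fully walled configuration (CC),
then with the sidewalls removed from one half (CO), which exposes the
animal to height and creates an anxiogenic open half. Control
configurations change the texture and visual cues instead (CT, preceded
by its own closed epoch CC2). A companion elevated plus maze (EPM) with
two open and two closed arms is supported at the analysis level.

The package implements the complete analysis chain from tracking and
spike times to: occupancy-normalised rate maps, per-neuron spatial
statistics, directional place-field similarity, peak-location remapping
tests, speed-controlled activity, sharp-wave-ripple (SWR) exclusion, and
a linear-SVM decoder that predicts from pre-entry activity how far into
the open half the upcoming run will go.

## Linearisation, trials, and zones

Tracking (nominally 50 frames/s) is projected onto the track's principal
axis and clipped to `[0, 120]` cm, with 0 at the never-changing reward
end. Running direction uses a 5-sample smoothed position derivative with
2.5 cm hysteresis: the direction flips only after the animal has
retraced 2.5 cm from its running extreme, which suppresses jitter flips
at turning points. Both choices are package conventions — the underlying
papers in this tradition rarely state them — and both are arguments of
`linearize_elm()`.

A trial is the trajectory from a reward-zone exit that crosses the track
middle. End-to-end runs are single rewarded trials; cross-and-return
runs count as two unrewarded directional trials split at the turning
point (the outbound trial is taken to start at the reward-zone exit);
runs that never reach the middle are discarded. Reward zones default to
10 cm from each end (the reward location is defined at the endpoints;
the zone extent is a package convention).

The centre band used for zone occupancy is 11.5 cm *total* width centred
on the middle. The phrase "11.5 cm around the centre" is ambiguous
between total and half width; we default to total width and expose
`centre_zone_is_halfwidth` in `maze_spec()` for the other reading.

On the EPM, each 2D point P on an arm is linearised by projecting onto
that arm's directional vector D: `(P . D)/||D||`. Trajectories are
demarcated from the furthest point reached on one (closed) arm to the
furthest point reached on the next visited arm. Because paths through
the centre vary, centre activity is divided into five fixed time bins
spanning the crossing instead of spatial bins.

## Rate maps and smoothing

Linear maps use 2.5 cm bins (48 on the default track), EPM arm maps
5 cm bins, 2D maps 10 x 10 cm bins. The raw rate in a bin is the spike
count divided by the occupancy in seconds. Two conventions make the
count/occupancy identity exact: each tracking sample contributes its
following inter-sample interval (capped at 0.5 s across dropouts), and a
spike is assigned to the bin of the last tracking sample at or before it
(zero-order hold). Consequently `sum(rate_i * occupancy_i)` equals the
in-epoch spike count exactly, which the tests assert as an integer
identity.

Smoothing is a Gaussian kernel truncated at 3 SD and renormalised over
the visited-bin mask, so unvisited bins and map edges do not leak zeros
into their neighbours. The kernel SD defaults to 1 bin (2.5 cm linear,
10 cm in 2D); published analyses in this field rarely state their kernel width, so
every downstream metric records whether it used raw or smoothed rates,
and the SD is a configuration argument. Bins with under 0.1 s occupancy
are masked as unvisited. No minimum-speed filter is applied during map
construction by default.

## Spatial statistics

For occupancy probabilities `p_i`, bin rates `lambda_i` and overall rate
`lambda = sum(p_i * lambda_i)`:

* **Spatial information** (bits/spike):
  `sum_i p_i (lambda_i/lambda) log2(lambda_i/lambda)`, with
  `0 log 0 := 0`. Zero for uniform firing.
* **Sparsity** (coverage): `lambda^2 / sum(p_i lambda_i^2)` — the
  standard Skaggs form; 1 exactly when firing is uniform over visited
  bins.
* **Coherence**: `Z = 0.5 ln((1+R)/(1-R))`, the Fisher z-transform of
  the correlation `R` between raw and smoothed rates over visited bins.
  `R` is Pearson by default (the tradition's "correlation" is typically
  unspecified); Spearman and a first-neighbour-average variant
  (`neighbour = TRUE`, the Muller-Kubie reading) are selectable. `R` is
  clipped to `1 - 1e-12` in magnitude before the transform.

A silent map returns `NA` statistics with an `undefined` flag rather
than an error; coherence requires at least three visited bins.

**Place-field similarity (PFS)** is the Spearman correlation (average
ranks on ties) between a neuron's z-scored linear maps for the two
running directions, computed over bins visited in both directions (the
bin-intersection rule is a package decision). High PFS means
direction-homogenised firing; the CO manipulation raises the PFS
distribution in sessions simulated with homogenisation, which the tests
verify.

**Rate remapping** between two epochs is scored as
`|m_a - m_b| / (m_a + m_b)` on occupancy-weighted mean rates. There is
no single agreed rate-remapping score in the literature, so this
normalised rate difference is the package's own definition: it
reproduces the expected qualitative contrasts on synthetic data and is
labelled as such in the output.

**Peak density** per bin divides the number of neurons peaking in that
bin by the number of neurons with any activity there (20 peaks among
100 active neurons: 0.2). Its null reassigns each neuron's peak
uniformly over that neuron's own visited bins, 1000 times by default; a
bin is significant when the observed density exceeds the null's 95th
percentile, one-tailed, per bin, with no multiplicity correction
(the field's convention; the number of tests run is reported).
Because the null is a discrete count distribution, the strict `>` rule
is conservative in sparsely populated bins; the calibration test
therefore checks the ~5% flag rate in a well-populated regime (hundreds
of neurons per bin), where discreteness is negligible.

## Unit processing

**Cell classes** from waveform summaries: putative pyramidal cells have
trough-to-peak latency above 0.3 ms and mean rate below 20 Hz; putative
interneurons latency below 0.3 ms and rate of at least 10 Hz; everything
else (including exactly 0.3 ms) is unclassified but kept in unsplit
analyses.

**SWR detection**: band-pass 130-230 Hz (4th-order Butterworth applied
forward and backward for zero phase), RMS in 10 ms sliding windows with
one-sample step, threshold at mean + 5 SD of the whole RMS trace,
boundaries extended to the mean + 1 SD crossings. Manual artefact
curation is replaced by two automated rules: events closer than 20 ms
merge, events shorter than 15 ms are dropped. All thresholds are
SD-relative, so amplitude rescaling cannot change the events. Under
these settings pure Gaussian noise still yields on the order of one
spurious excursion per minute; the detector is meant to be followed by
the ripple-spike excision stage, not used as a rate estimator on silent
traces. `exclude_swr_spikes()` removes every spike inside a detected
event (boundaries inclusive).

**Speed model**: spike counts in 20 ms bins (one video frame, aligning
"the number of spikes at a given time" with the tracking rate) are
regressed on the instantaneous speed interpolated to bin centres, by
ordinary least squares. The residuals are the speed-controlled activity;
residualised rate maps can be negative per bin, which does not affect
z-scored analyses. Significance of the slope is a two-sided t-test at
alpha = 0.05 — the field states no standard criterion, so this default is
flagged in reports and configurable.

## Decoding the extent of open-half exploration

Toward-open trials are labelled **proximal** or **distal** by a
per-session threshold at the middle of the explored range:
`nearest + (furthest - nearest)/2` in spatial bins. The printed formula
`(Furthest - Nearest)/2` admits a literal half-range reading, which is
selectable (`threshold_rule = "half_range"`); the midpoint reading
matches the accompanying description of "the middle of the exploration".
Boundary trials count as distal.

Features are pre-entry firing rates: spikes from the trial start (the
moment the animal heads toward the open arm after leaving the reward
zone) until the linear position first reaches the spatial bin before the
centre, divided by that window's duration. A linear-kernel SVM (cost 1 —
only the kernel and feature scaling are dictated by the tradition; cost
is our default) is evaluated by leave-one-out cross-validation. A
wrapper search scores all `C(n, 2)` unit pairs exhaustively and keeps
the best, breaking ties toward the lexicographically first pair.
Because proximal/distal counts are imbalanced, significance comes from
permuting trial labels (preserving the imbalance exactly) and re-running
the same pair's LOOCV; a session is "successfully predicted" when the
observed performance exceeds the null's 95th percentile. Sessions with
fewer than three units are excluded, a standard exclusion for underpopulated recordings.
Inside permutation loops the linear SVM's prediction is computed
directly from the decision value `w . x - rho`; the tests assert exact
agreement with the reference predict method on a thousand random
problems.

## The synthetic-session generator

The generator exists so that every stage is testable without recordings;
it emulates the statistical structure the analyses assume, not the
biophysics.

* **Behaviour**: bout-based shuttling. Each leg runs end to end at a
  speed drawn from `N(25, 5)` cm/s; the animal dwells 1.5 s at reward
  ends. In CO it pauses an extra 2 s at the closed-side boundary of the
  centre band before entering the open half (hesitation), and each entry
  retreats with probability `retreat_prob`, turning back at a shallow
  point drawn around a quarter of the open half's depth (hesitant
  entries venture only a short way past the boundary; SD
  `retreat_depth_sd = 10` cm). None of these magnitudes are estimates of
  real rats — no quantitative behavioural model exists for this
  paradigm — they are free parameters chosen to produce the
  characteristic occupancy asymmetries (avoidance of the open half,
  inflated centre dwell) at desk scale.
* **Spiking**: inhomogeneous Poisson with rate
  `baseline + peak * Gaussian(position | centre_direction, width) +
  speed_gain * speed`, thinned per 20 ms frame with uniform jitter
  within the frame. Gaussian bumps and the additive speed term are
  standard modelling choices; the additive form matches the linear speed
  model used in the analysis.
* **Population structure**: baseline field centres are uniform over the
  track interior; the two directional centres coincide with probability
  `direction_similarity`. In CO a fraction `remap_to_open_prob` of
  neurons relocate into the open half and directional tuning is
  re-homogenised with probability `co_direction_similarity`. Waveform
  summaries span both cell classes (85% pyramidal-like by default).
* **LFP**: Gaussian background plus Hanning-enveloped ripple-frequency
  bursts (130-230 Hz, default 150 Hz, 60 ms, 8 background-SD peak
  amplitude) with non-overlapping supports; the envelope supports are
  the ground-truth intervals.
* **Decoding signal**: optionally, informative units add a fixed rate
  during the closed-half approach of each open entry, differing between
  entries that will complete and entries that will retreat.
* **Seeding**: one master seed expands into per-component child seeds by
  a fixed affine rule (`child_seed()`), so adding a neuron or toggling
  the LFP does not reshuffle other components. Identical seeds give
  byte-identical sessions.

What the generator does **not** emulate: EPM trajectories (EPM analyses
are tested on hand-built paths), theta/phase structure, bursting,
ripple-locked spiking, non-Poisson variability, and tracking noise
beyond lateral jitter. Passing recovery tests therefore show that the
analysis code measures what it claims on data satisfying its
assumptions, not that those assumptions hold in any recording.

## Numerical and design choices

* Bins are half-open `[lo, hi)` with the final bin closed; peak ties
  break to the lowest bin index; positions are clipped to the track.
* Tracking dropouts are excluded sample-wise; excursions containing gaps
  over 0.5 s are discarded from trial segmentation.
* The problem sizes used by the verification suite — e.g. 200
  populations of 800 neurons for the bootstrap calibration, 200
  no-signal sessions of 12 trials with 100-permutation nulls for the
  decoder calibration, 500 units for the speed-model type-I check, and
  a 12-session batch of 8-shuttle sessions with 10 units for the
  determinism check — are the package's desk-scale study conditions,
  chosen so each check is statistically meaningful (well-populated bins,
  central-limit regime) while remaining runnable on one CPU.
* Epoch ordering (CO before or after CT) is configuration-driven; no
  canonical order is asserted.
* All file formats are plain text: CSV for tracking/spikes/units/LFP
  samples, YAML for session metadata, JSON for truth records and
  reports. Numeric columns are written at 17 significant digits so
  round trips are exact.

## Known limitations

* The rate-remapping score is the package's own definition (see above).
* SVM results are solver-dependent in the last decimal: other
  implementations of the same linear-kernel formulation may differ on
  near-tied folds, so equivalence claims are behavioural (calibration
  and recovery), not bit-exact.
* The peak-density significance rule is per-bin with no multiplicity
  correction, faithful to the tradition but anticonservative across many
  bins; the report carries the number of tests run.
* The speed model is linear and Gaussian-error by construction; for
  strongly bursty units the t-test on the slope is only approximately
  calibrated (the type-I check uses Poisson spiking).
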