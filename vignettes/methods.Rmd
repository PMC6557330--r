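---
title: "Models and methods behind zfhunt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zfhunt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfhunt)
```

# Scope

zfhunt implements the analysis pipeline of a larval-zebrafish prey-capture
assay: video tracking of a freely swimming larva and its prey, kinematic
segmentation of hunting routines from ocular vergence, bout-level pursuit
metrics and outcome ethograms, loom-contrast psychometrics, and
trial-based calcium statistics for the isthmic (nucleus isthmi) imaging
experiment. Because no raw recordings are bundled, every stage is validated
against a synthetic-data generator that produces ground-truthed sessions
with the statistical structure the analyses assume. This vignette documents
the models, the tunable constants and the design decisions.

# Behavioral model and the synthetic generator

Larval zebrafish swim in discrete bouts. The generator
(`simulate_session()`) places a single larva in a 35 mm dish imaged at
24.8 px/mm, with kinematics at 700 Hz and full-frame prey video at
17.5 Hz — the standard acquisition geometry of this assay. Locomotion is a
sequence of displacement-plus-turn events with raised-cosine displacement
profiles (~150 ms); the sharp-onset tail-beat envelope (20 ms Tukey ramps,
22 Hz oscillation, ~3000 deg/s peak cumulative angular velocity) gives
unambiguous ground-truth bout onsets for detector validation, and peak
velocities in the range observed in real swim bouts.

Ocular vergence (left minus right eye angle) is drawn from two modes:
baseline (default 16 ± 3°) and hunting (52 ± 4°), with 15 ms convergent
saccades and ~80 ms relaxation. The generator logs a routine's onset as the
time the noiseless saccade crosses its own hunting threshold (mean of the
high mode minus one SD), which makes onset agreement between detector and
log a well-posed comparison: both reference the same threshold-crossing
event rather than an arbitrary point on the ramp.

Prey motion is an Ornstein–Uhlenbeck velocity process (default speed
1 mm/s, correlation time 1 s) with reflecting dish walls; the assay's
literature does not constrain a prey model, so these defaults are exposed
in the configuration. Hunting routines are scheduled as a Poisson process
(default 3/min); each routine selects a target location inside the
reactive perceptive field (range 2.5–5.5 mm, |azimuth| 25–95°), smoothly
translates one prey path through that point, and constructs bouts whose
distance- and orientation-gains are drawn positive (0.2–0.5 and
0.25–0.6) so that the target criterion holds by construction.
Outcomes follow configurable branch probabilities (default
P(abort) = 0.6, the abort rate typical of this assay); aborted and attempt
routines receive a final negative-gain bout with probabilities 0.37 and
0.09 respectively, the rates at which pursuit-abandoning bouts occur in aborted and completed routines in this assay.

What the generator does *not* emulate: occlusions and imaging artifacts,
prey depth (everything is planar), biomechanics and hydrodynamics,
inter-fish variability beyond configuration, and manual-annotation noise.
Tests passing on synthetic data therefore demonstrate correctness of the
estimators under the assumed structure, not robustness to every nuisance
of real video.

# Rendering and video tracking

Frames are rendered dark-on-light (IR contrast polarity) with sub-pixel
anti-aliasing. The body is a tapered capsule whose binary-mask centroid
coincides exactly with the nominal body centroid and whose mass taper
yields a negative third central moment along the heading — the property
the tracker uses to resolve the 180° orientation ambiguity of the
second-moment axis. Eyes are rotated ellipses rendered with 6x6
supersampling; prey are Gaussian spots with analytically exact centers.
Coordinates follow image convention: origin top-left, x rightward, y
downward, angles clockwise-positive, heading 0° along +x.

`detect_fish()` thresholds the background-subtracted frame twice (body
0.235, eyes 0.65 on a [0, 1] intensity scale; both configurable), takes
the largest in-range blob's binary moments for centroid and heading, and
each eye blob's intensity-weighted moments for the eye angles (weights are
the above-threshold excess, which de-emphasizes quantized edge pixels).
`trace_tail()` performs 8 annular scans (first radius 20 px to clear the
body, then 9 px steps, ±60° forward sector) locating the dark tail line by
the weighted centroid of the arc's intensity dip; the frame is pre-smoothed
with a 0.8 px Gaussian as an anti-alias filter, without which worst-case
per-segment errors roughly double. Typical accuracy on rendered frames:
centroid < 0.15 px, heading < 1°, eye angles ~1° (median), per-segment
tail angles within ~10% at a 12°/segment bend.

`detect_prey()` follows the assay's standard recipe: Gaussian smoothing at
sigma = 7 px (24.8 px/mm) of the inverted background-subtracted image,
local maxima above a minimum prominence, and separable quadratic sub-pixel
refinement. The blur is implemented as two banded-matrix products with
edge renormalization, which is an order of magnitude faster than generic
2-D filtering at the 868 px arena frame size. `link_tracks()` solves each
frame-pair assignment with the Hungarian algorithm (implemented in the
package; no assignment solver is available among the dependencies) under a
maximum link distance, with tracks closed after `gap_frames` missed frames
(default 2).

# Kinematic segmentation

The per-fish vergence threshold is one SD below the mean of the
higher-angle component of a two-Gaussian mixture fit. The mixture is fit
by EM via mclust (model "V", G = 2); degenerate fits (component weight
below 2%, or mode separation under 8°) raise an error signalling a
unimodal distribution rather than returning a meaningless threshold.
Hunting epochs are maximal above-threshold runs with a 70 ms merge gap and
100 ms minimum duration; bouts are supra-500 deg/s runs of the
Savitzky–Golay-smoothed (cubic, 21 samples at 700 Hz) cumulative tail
angle derivative, with a 30 ms merge gap and 20 ms minimum duration.
Escapes are single events per supra-75 mm/s run of the frame-to-frame
centroid speed at the 17.5 Hz full-frame rate, unsmoothed — a genuine
escape displaces several millimetres per low-rate frame, so a single-step
threshold is unambiguous. All constants are config-exposed.

Epoch offsets are taken at the threshold down-crossing with no
baseline-return extrapolation; vergence relaxes to baseline within a few
hundred milliseconds of the final bout in aborted routines, so the two
conventions differ by less than the epoch merge gap.

# Hunting analysis

Bout gains are fractions eliminated: `gain = (pre - post) / pre`, with
distance measured from the midpoint of the eye centroids to the target and
azimuth the signed angle (positive to the fish's right) between the
eyes-center-to-target vector and the heading; only |azimuth| enters the
gain and the ±120° field criterion. Prey positions are linearly
interpolated from the 17.5 Hz tracks to the 700 Hz bout boundaries.

Target assignment follows the assay's two-part criterion — candidate
within 6 mm and ±120° at routine onset, and positive distance- and
orientation-gain on the first two bouts. With ~80 prey in the dish,
several prey routinely satisfy both conditions because anything inside the
pursuit cone is co-approached; resolving ties by the largest summed
first-two-bout gains recovered only ~82% of generator-intended targets in
simulation. The package therefore resolves ties by (1) the number of
positive-gain bouts across the whole routine and (2) the smallest
fish–target distance after the final bout, reflecting that a pursued
target is homed in on over the entire sequence; this recovers ~97% and is
flagged `ambiguous` whenever more than one candidate passed. Routines with
fewer than two bouts get no target and are excluded from gain summaries.

Capture type (ram vs suction) and ingestion are consumed as annotations
(ground-truth flags from the generator, or a CSV of scored events) and
never inferred from kinematics — no kinematic classifier is specified for
the assay. A routine is an abort iff no capture event falls inside its
epoch; an ingestion without a capture event is an annotation error.
Ethograms report branch probabilities per fish and pooled, with per-fish
medians and a Wilcoxon rank-sum convenience for group contrasts.

# Stimuli and psychometrics

The looming stimulus follows the constant-approach model
θ(t) = 2·atan[(L/V) / (t_c − t)], clipped to the start/end angles; the
closed-form inversion is exact to numerical precision. The dimming control
is a fixed disc at the loom's final size whose contrast deficit tracks the
loom's solid-angle-weighted luminance change at every instant. Contrast is
handled as the nominal fraction (0.2–1.0); measured lux values are
metadata only, since the grayscale-to-lux mapping is projector-specific.

Escape probability versus contrast is fit by maximum-likelihood logistic
regression with the lower asymptote fixed at zero and the lapse rate fixed
at zero by default (a `free_lapse` flag re-parameterizes it on (0, 0.2)).
The slope is optimized on a log scale, which enforces β > 0. Goodness of
fit and CIs come from a parametric bootstrap (default 1000 resamples).
All-zero and all-one response sets are rejected as non-identifiable.

# Calcium statistics

Traces are z-scored per ROI over the whole recording; traces with SD below
1e-6 map to zero and are flagged. VRVs concatenate per-stimulus trial
averages on a fixed epoch-relative grid (linear interpolation, since epoch
onsets are asynchronous to the 3.6 Hz frame clock) in a fixed stimulus
order.

Clustering is the two-stage correlation-distance procedure: average-linkage
agglomerative clustering cut at distance 0.1 (r = 0.9); single-pass pruning
of members beyond 0.5 of their cluster centroid; surviving clusters with at
least 5 members (configurable) define archetypes; a second cut at 0.3
(r = 0.7) re-forms lenient clusters whose members are all assigned de novo
to the nearest archetype within 0.5, or left unassigned. Assignments are
invariant to ROI order up to archetype relabeling (ties broken by first
minimum).

The convergence modulation index compares, for each GO event, the mean
z-scored activity in a 4 s window centered on the convergent saccade with
the means over the identical epoch-relative window in NO-GO trials of the
same stimulus type: d_i = (X_GOi − μ_NOGO)/σ_NOGO with the sample (n−1)
SD and a 1e-6 degenerate-SD guard; the CMI is the mean of d_i over GO
events, computed separately for left- and right-dominant convergences, and
CMI > 3 flags a cell CMI+. Windows truncated below 50% at recording edges
are dropped, and events with fewer than 3 matching NO-GO epochs are
skipped. Sp-CMI applies the same computation to spontaneous convergences,
referenced against up to 20 stimulus-free windows with no convergence
within ±4 s. The chance level comes from recomputing the CMI under
uniformly random circular shifts of each ROI's trace (default 1000).

The calcium generator's cell classes (whole-field, spot-CW/CCW,
loom-phasic, loom-sustained, dimming-nonselective, convergence-modulated,
silent) place events per class — stimulus-locked for visual classes,
convergence-locked and GO-only for convergence cells, with an ipsilateral
side preference — and convolve them with a single-exponential kernel
(τ = 3 s, a nuclear indicator's time scale) implemented as an exact AR(1)
recursion, sampled at 3.6 Hz plus Gaussian noise. Two defaults deviate
deliberately from the tethered assay's empirical rates: 20 repetitions per
stimulus with a 10 s inter-stimulus interval and a GO fraction of 0.4
(versus ~6% GO and 30 s intervals in vivo). At the in-vivo rates a
desk-scale session leaves almost no GO events or NO-GO reference windows,
making the CMI estimator statistically starved; the chosen defaults keep
roughly 6–10 GO events and ≥ 12 reference epochs per side, at which the
separation between modulated and noise cells is the estimator's property
rather than a sampling accident.

# Numerical choices and degenerate inputs

* Mixture-fit degeneracy: weight floor 2%, separation floor 8°.
* Hungarian costs must be finite; forbidden links carry a large finite
  penalty and are rejected after assignment if they exceed the link
  radius.
* Sub-pixel refinements (prey peaks, tail dip) fall back to the grid
  optimum when the local quadratic/dip is flat.
* An invalid pose (no in-range body blob, fewer than two eye candidates)
  is a value, not an exception; tail tracing an invalid pose is an error.
* All simulations fan a single seed out to per-subsystem streams, so each
  subsystem can be re-simulated independently and every pipeline output is
  byte-reproducible given the seed.

# Problem sizes used in the validation suite

The bundled tests validate threshold recovery over 50 randomized sessions,
bout/epoch detection over 10 sessions of 60 s at 700 Hz, tracker accuracy
over 1000 rendered frames, target assignment over 500 routines, ethogram
recovery at 784 routines with a 100-replicate power check of the 0.60 vs
0.80 abort contrast, CMI separation at 500 cells with a 200-shuffle null,
and clustering recovery at 100 noisy template copies. These sizes were
chosen to give the binomial or Monte-Carlo margins the assertions need.

# Known limitations

* The tail tracer's per-segment angles degrade beyond ~25°/segment bends
  (the forward sector and ring geometry assume moderate curvature).
* Prey detection merges particles closer than roughly the smoothing
  kernel width, as the sigma = 7 px smoothing implies; the linker then sees a
  single detection.
* The ram/suction distinction and ingestion are annotation inputs;
  outcome statistics are only as good as the annotations.
* The "visually responsive" denominator used in region summaries is a
  repository convention (maximum |epoch-mean response| above twice the
  baseline SD); the assay itself never defines one, so fractions built on
  it are not comparable across conventions.
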