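---
title: "Margin-of-stability analysis of perturbed treadmill walking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-of-stability analysis of perturbed treadmill walking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridestab)
```

## The problem

When a treadmill briefly decelerates one belt ("stick"), accelerates it
("slip"), or shifts the whole platform a centimetre sideways at the stance
phase of every stride, a walker's balance is challenged stride by stride.
The standard way to quantify the challenge and the walker's reaction is the
margin of stability and its components,

$$\mathrm{MOS} = \mathrm{BOS} - \mathrm{XCOM}, \qquad
  \mathrm{XCOM} = \mathrm{COM} +
  \frac{V_{\mathrm{COM}} - V_{\mathrm{treadmill}}}{\sqrt{g/l}},$$

evaluated at left heel strike (reactive control) and left toe off
(anticipatory control). BOS is the base-of-support boundary — the leading
toe marker in the anterior-posterior (AP) direction, the leading ankle
(lateral malleolus) in the medial-lateral (ML) direction — measured
relative to the corresponding trailing-foot marker. The XCOM is the COM
advanced by its velocity *relative to the moving surface* (belt velocity on
the AP axis, platform velocity on the ML axis), scaled by the
inverted-pendulum eigenfrequency $\sqrt{g/l}$ with $g = 9.81$ m/s² and $l$
the distance from the leading ankle to the COM at the event. A positive MOS
means the XCOM lies inside the support boundary.

This package implements the full analysis chain for such protocols —
filtering, kinematic event detection, the mid-stance trigger, the
stability metrics, protocol phase labelling with catch strides, and the
repeated-measures statistics — together with a synthetic trial generator,
because no raw motion-capture data are publicly deposited for this
paradigm. Every downstream stage is therefore testable by parameter
recovery against generator ground truth.

## The synthetic walker

The generator is a *kinematic template*, not a dynamic simulation: the
pelvis follows sinusoids (ML sway at stride frequency, AP and vertical
oscillation at step frequency), and each foot alternates belt-locked stance
(60% duty factor, double support 10% of the cycle) with a smooth quintic
swing to the next planned landing. Timing is fixed — right heel strike at
0 T, left toe off at 0.1 T, left heel strike at 0.5 T, right toe off at
0.6 T — so ground-truth events are exact and cheap, at the price that
perturbations cannot alter step *timing*, only placement and pelvis
trajectory.

Two design choices matter for event detection. The heel's vertical
trajectory ends in a *landing cushion*: a cosine-squared acceleration
impulse (half-width 40 ms, peak 25 m/s²) symmetric about the ground-truth
contact instant, preceded by a squared-quintic rise whose near-ground
acceleration is negligible. The toe carries the mirrored *push-off*
impulse (18 m/s²) centred on toe off. Because the impulses are symmetric
in time, zero-phase filtering does not displace their acceleration maxima,
and the detected events land on the ground-truth frames; the asymmetric
alternatives we tried first (sharp one-sided curvature at contact) biased
detection by 5–7 frames after filtering.

Default gait parameters are ordinary values for treadmill walking at
1.0 m/s: step length 0.55 m (cadence 0.909 strides/s follows from the
treadmill constraint $v = 2 \cdot \text{step length} \cdot \text{cadence}$),
step width 0.12 m, pelvis height 0.95 m, marker noise 0–1 mm, all series on
a single 240 Hz clock. (The original hardware samples the treadmill at
300 Hz; we unify the clocks to avoid resampling.)

Perturbations follow the protocol constants: belt ramps at 12.5 m/s² to
0.6/0.8/1.2/1.4 m/s and back within 400 ms; platform shifts are bang-bang
moves at 3.6 m/s² to ±1 cm with a dwell, returning to neutral at 400 ms.
Onset is the first frame of right stance at which the trigger fires: COM
(mean of the four pelvis markers) between right heel and right toe in AP,
and the left heel at least 5 cm above the right toe. One catch stride is
drawn uniformly in every complete five-stride batch of the perturbation
block; an incomplete final batch is all perturbed, so the one-in-five rule
holds exactly for complete batches.

## The response model

Reactions are injected, not emergent. Deltas are expressed directly in the
metric frame: `bos_*` deltas displace the landing of the foot that leads at
the named event (left at lhs; right at lto — an anticipatory adjustment,
since that foot lands before perturbation onset), and `xcom_*` deltas move
the pelvis through a cosine-squared bump (half-width T/4) centred on the
event, so exactly the stated offset appears in the XCOM there (the bump's
velocity is zero at its peak). Catch strides have their own delta set. A
delta on the stride k strides after the first perturbed stride is scaled by
$e^{-k/\tau}$, modelling exponential adaptation back toward baseline.

Two couplings are worth knowing. First, a foot-placement delta moves the
leading ankle and therefore changes the pendulum length, so the margin
changes by slightly more or less than the BOS delta; recovery tests compare
against ground truth computed from the noise-free template rather than
against the raw injected number. Second, the template's COM has no inertia:
the forward surge a real body experiences when its stance belt slows is not
produced mechanically and must be emulated through `xcom_*` deltas (the
`analysis/` drivers do exactly that). Under belt conditions the surface
coupling also means that fully decayed responses leave the *measured*
metrics at the mechanically perturbed level, not at the pre level.

## Pipeline choices

* **Filtering.** 4th-order Butterworth, 12 Hz cutoff, applied forward and
  backward (zero phase, effective 8th-order magnitude). Phase fidelity is
  essential because events are timed off acceleration maxima. Series are
  extended by odd reflection at both ends and the edge value is subtracted
  before each pass, which removes start-up transients exactly for constant
  input.
* **Heel strikes** are strict local maxima of vertical acceleration within
  a near-ground band — at or below 3 cm above the trial's 5th-percentile
  heel height ("near zero" made operational; configurable). Candidates
  closer than half the nominal cycle time are reduced to the largest, and
  peaks below 20% of the strongest candidate are discarded as doubles.
* **Toe offs** maximise the transitioning foot's vertical toe acceleration
  between consecutive heel strikes. Boundary strides and strides with
  missing or mis-ordered events are dropped.
* **Trigger.** The AP "between heel and toe" test is inclusive at both
  markers; ties fire. The detector latches the first firing frame per
  stride.
* **Metric signs.** The belt surface moves at minus the belt speed along
  +AP, so $V_{\mathrm{COM}} - V_{\mathrm{treadmill}}$ is approximately the
  walking speed in steady gait; the instantaneous right-belt speed at the
  event frame is used (a perturbation need not have finished by left heel
  strike). The ML frame is signed positive from the trailing toward the
  leading foot, so BOS_ml is positive in normal gait and negative on
  crossover steps (signed rather than absolute distance; none occur at
  these magnitudes).
* **Phases.** Pre excludes the first 11 strides (belt spin-up). Early
  perturbed is the first three perturbed strides — for lto metrics,
  perturbed strides 2–4, because the first left toe off precedes the first
  onset. Late perturbed is the last three perturbed strides; early/late
  catch the first/last two catch strides; early/late post the first/last
  three post strides. Overlapping definitions (too-short blocks) raise an
  error rather than silently sharing strides.
* **Outliers.** Values strictly beyond 3 SD are excluded, with mean and SD
  computed from the *remaining* values of the data set: with the value
  included, |z| cannot exceed $(n-1)/\sqrt{n} \approx 2.85$ in a
  ten-subject sample, so the rule could never fire at group level. The
  screen is single-pass and is applied per metric × phase × condition
  across subjects before the ANOVA (subjects with a removed cell are
  dropped listwise).
* **Statistics.** The one- and two-way within-subject ANOVA decompositions
  are written out longhand (each effect tested against its own
  effect-by-subject interaction) and verified against `aov(...,
  Error(subject/...))` to six significant digits. Partial eta squared is
  SS_effect / (SS_effect + SS_error-term). Tukey HSD p values use the
  studentized range with the full family size even though only the a
  priori pairs are reported (conservative). Paired Cohen's d defaults to
  d_z = mean(diff)/sd(diff); `"dav"` is available by flag. No sphericity
  correction is applied by default — Mauchly's test is reported, not acted
  on — matching the reporting style of the protocol. Shapiro–Wilk (on
  within-subject residuals) and Levene (centred on the mean) are likewise
  reported, not gates. Follow-ups after a significant two-way interaction
  are paired t tests at the Bonferroni-corrected α = 0.025.

## What the tests do and do not show

The test suite validates the pipeline at the study's operating conditions:
event detection within ±1 frame of ground truth on noiseless full-protocol
trials (±2 frames at 1 mm marker noise); exact MOS = BOS − XCOM identity on
every emitted row; recovery of injected placement deltas within 5% at 1 mm
noise (per seed for BOS channels; pooled over ten seeds for XCOM channels,
whose late-phase deltas of a few millimetres sit at the noise floor of
differentiated marker noise); type-I error of the whole
simulate-filter-detect-aggregate-test chain within 0.05 ± 0.02 over 1,000
null replicates (four subjects per replicate, 42-stride trials — sizes
chosen to keep the suite fast; the calibration does not depend on them);
and uniformity of the catch schedule over 10,000 batches.

Passing these says the *machinery* is correct. It does not make the
synthetic cohort a substitute for human data: the walker has no trunk
inertia, no temporal adaptation, no step-timing variability, no
kinematic variability beyond additive marker noise, and its response
magnitudes are chosen, not measured. Group results produced by the
`analysis/` drivers illustrate the protocol's statistical pathway on a
cohort whose effect directions emulate the published pattern; their
magnitudes are properties of the chosen emulation parameters.

## Numerical notes

Profiles are exactly feasible by construction: belt ramps occupy
$2|\Delta v|/a \le 400$ ms and the out-and-back platform move needs
$4\sqrt{d/a} \approx 211$ ms, leaving a dwell at the peak. Degenerate
inputs fail loudly: coincident ankle and COM (zero pendulum), zero-variance
paired differences, incomplete ANOVA cells, too-short filter inputs, and
phase definitions that cannot be satisfied all raise errors naming the
offending quantity. All randomness in a trial flows from one integer seed;
identical seeds give byte-identical CSV exports.
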