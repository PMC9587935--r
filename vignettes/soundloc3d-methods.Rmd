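---
title: "Methods: analysing 3D sound localization under static and active listening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing 3D sound localization under static and active listening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundloc3d)
```

## The experimental paradigm

The package analyses a class of spatial-hearing experiments in which a real
loudspeaker is guided, trial by trial, to one of twelve predetermined
positions defined in *head-centered* coordinates — four azimuths
($\pm 30^\circ$, $\pm 150^\circ$) crossed with three depths (35, 55, 75 cm)
at ear-level elevation — while the listener's head, gaze and hand are
tracked. The sound (a 3 s amplitude-modulated broadband burst) is delivered
only when three gating criteria hold concurrently: the speaker sits inside a
2.5 cm tolerance sphere around its predetermined position, and head and eyes
face straight ahead. Listeners then point with a hand-held tracker to the
perceived 3D sound position. The factor of interest is the listening
posture: *static* (head must stay still during the sound) versus *active*
(spontaneous head movements are allowed during the sound).

The pipeline reproduces the full offline analysis: re-referencing to the
head center, locating the delivery onset, kinematic segmentation of head and
hand movements, compliance-based trial rejection, localization-error
statistics per dimension and in 3D, and the repeated-measures statistical
battery.

## Coordinate conventions

All internal computation uses meters and radians; every reported quantity is
in centimeters, degrees, or milliseconds.

The head frame is right-handed with $x$ = right, $y$ = forward (the aligned
straight-ahead direction), $z$ = up. Azimuth is $\mathrm{atan2}(x, y)$ in
degrees, *positive rightward*, in $(-180, 180]$; elevation is the angle
above the horizontal plane; depth is the Euclidean distance from the head
center in cm. The sign convention for azimuth is a package choice — the
paradigm itself only fixes the unsigned target layout — and is stated here
rather than attributed to any external source. Front space is
$|azimuth| < 90^\circ$.

The head center is calibrated as the exact midpoint of the two ear
positions. The tracked rigid body sits on the head-mounted display, a fixed
lever arm in front of the head center; `head_center_offset` (default
$(0, -0.10, 0)$ m in body coordinates, i.e. a 10 cm pivot) maps marker to
head center. The reference pose for re-referencing each trial is the head
pose at the delivery onset, when the head is aligned; `to_head_frame()` and
`from_head_frame()` compose to the identity to within $10^{-9}$ m.

Degenerate zero-depth points are flagged rather than raised as errors, so a
single pathological response cannot abort a cohort-level analysis.

## Delivery gating

`check_delivery()` re-implements the controller's gate offline: placement
passes iff $\|\mathrm{speaker}-\mathrm{target}\| \le 2.5$ cm (closed ball —
"within a sphere" reads as boundary-inclusive), and head/eye pass iff their
angular deviation from the straight-ahead reference is at most the
configured tolerance. The angular tolerances are **not** fixed by the
paradigm; the defaults (5° for both) are typical of crosshair-alignment
tasks and are explicit configuration (`gating_criteria()`). The trigger
fires on the *first* sample at which all three criteria pass
(`find_delivery_onset()`); whether the original controller required the
criteria to hold for a sustained period is unknown, so no hold period is
imposed. Slower tracks (the 60 Hz gaze stream) are aligned to the head grid
by sample-and-hold interpolation, which is what a real-time controller
polling the most recent sample would see.

## Kinematics

Position signals are low-pass filtered with a linear-phase windowed
(Hamming) FIR applied forward–backward (zero net phase, unit DC gain
enforced exactly). The nominal cutoff is 50 Hz; with head data sampled at
100 Hz that cutoff sits exactly at Nyquist, where the filter would be a near
no-op, so cutoffs at or above Nyquist are clamped to $0.45 f_s$ with a
warning. Edge transients of the forward–backward pass are suppressed by
odd-reflection padding.

Speed is the norm of the two-point central difference of the filtered
position, $v_i = \|p_{i+1}-p_{i-1}\|/(2\Delta t)$, in mm/s; endpoints use
one-sided differences and are flagged non-central so the series keeps its
length. The central difference is exact for linear and quadratic motion,
which the tests exploit as an oracle.

Movements are maximal runs of samples with speed $\ge 80$ mm/s
(`segment_movements()`); onset and offset are the first and last sample of
the run, with no back-extrapolation. A minimum segment duration of 50 ms
(configurable) suppresses single-sample noise crossings; this guard is
standard kinematic practice and not part of the original description. The
movement count is the number of surviving runs. The speed that is
thresholded is the translational speed of the tracked head rigid body — the
marker rides a ~10 cm lever arm, so a head rotation of 15° or more reliably
clears the threshold, while postural jitter does not.

Head movements are counted only if their onset falls inside the 3 s sound
window; the first movement's end direction is the head facing azimuth
(relative to the delivery-onset pose) at its offset. Trials are rejected for
a head movement during the sound in the static condition, or an anticipatory
hand movement (onset before sound offset) in any condition; when both occur
the static head movement takes precedence in the label. Participants who
barely move in the active condition are flagged by the $1.5\times$IQR rule
on the per-participant percentage of moving trials (type-7 linear-interpolated
quartiles; the convention only affects borderline cases).

## Error metrics

Azimuth errors are circular differences wrapped to $(-180, 180]$; elevation
errors are against the common ear-level 0°; depth errors are in cm. The
*absolute* (constant) error averages $|$signed error$|$ over trials; the
*variable* (random) error is the SD of responses at each position, averaged
with equal weight across positions; positions with fewer than two accepted
trials are skipped with a warning. For azimuth the dispersion is computed on
deviations from the circular mean, so back-space responses straddling the
$\pm 180^\circ$ seam are not artificially inflated.

The composite 3D error per participant and condition combines accuracy and
precision:
$$\text{error}_{3D} \;=\; \sqrt{\bar{C}^2 + \bar{s}^2},$$
where $C_i$ is the 3D distance (cm) between the response and the *actual*
speaker position at delivery, $\bar C$ its mean over all accepted trials
irrespective of position, and $\bar s$ a per-position dispersion of the 3D
responses averaged across positions. Whether the random term should be a 3D
RMS dispersion $\sqrt{\sigma_x^2+\sigma_y^2+\sigma_z^2}$ or the mean of the
three per-axis SDs is genuinely open; both are implemented
(`dispersion = "rms3d"` — the default, as the natural 3D extension of "SD of
the responses" — or `"axis_mean"`). The index always dominates its parts:
$\text{error}_{3D} \ge \max(\bar C, \bar s)$.

The front/back sector of a trial is always the *target's* nominal sector,
never the response's, matching the ANOVA factor definition.

## Statistics

`rm_anova()` fits balanced fully-within designs (up to three crossed
factors) on per-participant cell means, using the classical univariate
error-stratum partition. Greenhouse–Geisser epsilon is computed from the
covariance of the cells projected onto orthonormal effect contrasts and
applied only to effects involving a factor with more than two levels —
two-level factors are sphericity-trivial, which is why corrected
(fractional) degrees of freedom appear only for the three-level distance
factor. Effect sizes are generalized eta squared with the observed-variance
denominator,
$\eta_g^2 = SS_\text{effect} / (SS_\text{effect} + \sum SS_\text{error})$,
summing every subject-related error stratum.

Planned condition contrasts are paired t tests on per-participant values,
Holm-adjusted within the family of within-sector comparisons for a given
dependent variable. The exact multiple-comparison family is a configuration
choice (the `by` argument), not a fact of the paradigm. Degenerate families
are reported explicitly: identically-zero differences give $t=0, p=1$;
constant non-zero differences are flagged rather than silently passed to a
t test. Kendall's tau-b (tie-corrected) relates head-movement propensity to
the localization benefit of active listening.

Aggregation always runs trial → participant mean → group mean ± SE; trials
are never pooled across participants.

## The synthetic experiment generator

`generate_experiment()` draws complete cohorts with the study design: 4
ABBA-counterbalanced blocks of 48 randomized trials, 8 trials per position
per condition. Its defaults *are* the study conditions the package targets;
they were fixed once by calibration and are not tuned per run:

* **Placement noise.** Direction from an anisotropic Gaussian
  ($\sigma = (0.8, 1.2, 0.9)$ cm), radius $2.5\,\mathrm{cm}\times
  \mathrm{Beta}(6, 1.58)$. The boundary-hugging radial law models an
  experimenter who stops guiding the speaker as soon as it *enters* the
  tolerance sphere; a mean 3D placement error near 2 cm with per-axis means
  around 0.9–1.2 cm cannot arise from a center-concentrated law (a uniform
  ball would cap the mean norm at 1.875 cm).
* **Responses.** Spherical errors around the actual speaker position with
  condition × sector biases and SDs (azimuth/elevation in degrees, depth in
  cm). The angular bias/SD table was obtained by folded-normal inversion of
  the target group-level absolute errors and an additive decomposition of
  the variable errors; depth biases are distance-dependent (overshoot near,
  undershoot far) and condition-independent. Angular errors scale inversely
  with target depth (normalized to mean 1 over the three depths), emulating
  pointing noise that is approximately constant in Cartesian space.
  Participant-level offsets (`tau_*`) add realistic between-subject
  heterogeneity.
* **Head movements.** Per-participant movement propensity
  $\sim\mathrm{Beta}$ (mean 0.736, SD 0.24); moving trials carry
  $1+\mathrm{Poisson}(0.22)$ minimum-jerk yaw reorientations with onset
  latency $\sim 1077 \pm 250/150$ ms (between/within participants),
  truncated to the sound window. Front-target movements aim at the target
  (gain 0.85); back-target movements mix full turns (65%) with partial
  turns into the front quadrant of the target's side. Reorientations are
  converted to marker translation through the 10 cm pivot, so the 80 mm/s
  detector sees realistic bell-shaped speed profiles.
* **Benefit coupling.** A participant's active-condition improvement
  interpolates between the static and active parameter sets by
  $g = p_\text{move}/0.736$ plus jitter (SD 0.3), so cohorts exhibit a
  positive rank correlation between movement rate and localization benefit
  mechanistically rather than by construction of the summary statistics.
* **Compliance.** Anticipatory hand responses at 5.6% (static) / 6.6%
  (active) plus 0.5% static head movements, giving ~6% rejection per
  condition. Compliant hand responses start $3.65 \pm 0.3$ s after sound
  onset.

With `track_mode = "full"` the generator also synthesizes 100 Hz world-frame
head/hand/speaker tracks and a 60 Hz gaze track per trial: postural jitter
is a sum of slow (< 0.45 Hz) sinusoids that stays far below the movement
threshold; the gaze aligns exactly at $t=0$ (a saccade onto the fixation
cross), so the delivery gate opens at a known instant and kinematic labels
can be checked for exact recovery. With `track_mode = "none"` the trial
table carries the equivalent kinematic annotations directly, which keeps
large-cohort statistical simulations fast.

All draws flow from a single seed; the caller's RNG state is untouched.

### What the generator does and does not emulate

It reproduces the design structure, placement statistics, error biases and
dispersions, movement propensities/latencies/directions, and rejection
rates of the paradigm. It does **not** model auditory cues (ILD/ITD/HRTF),
eye movements beyond compliant fixation, trunk–head decomposition,
elevation components of head reorientation, or trial-to-trial learning.
Passing tests therefore validate the *analysis machinery* — geometry,
gating, segmentation, error algebra, statistics — on data with the right
structure; they are not evidence about any particular human dataset.

One known tension is documented rather than hidden: group-level angular
errors of the calibrated magnitude, mapped to centimeters at 35–75 cm
depths, force a composite 3D error in the high 30s of cm for static
listening. A smaller 3D error alongside such angular errors would require
error correlations across dimensions that the generator does not model, so
the emergent 3D error of synthetic cohorts runs some 25% above the angular
calibration's implied lower bound. The condition *contrast* (active better
than static, mostly in front space) is unaffected.

## Numerical choices

* FIR order 24 (reduced on short series), Hamming window, coefficients
  renormalized to exactly unit DC gain; forward–backward application with
  odd-reflection padding.
* Quartiles for the IQR rule: `stats::quantile` type 7.
* A numerically null ANOVA effect (SS $\approx 0$, as when condition means
  are identical per participant) reports $F = 0$, $p = 1$ even when its
  error stratum is also degenerate.
* Greenhouse–Geisser epsilon is clamped to $[1/\mathrm{df}, 1]$.
* Ties between movements and window edges: a movement counts if its onset
  is at or before 3.000 s; the static-condition head check uses the open
  interval $(0, 3)$.
* Zero-depth spherical coordinates return azimuth = elevation = 0 with a
  degenerate flag.

## Problem sizes used in the shipped tests

The test-suite cohorts are deliberately compact — up to 20 virtual
participants at 8 trials/cell for parameter-recovery checks (the full
study-sized design), 2–6 participants elsewhere, 2000 replicates for the
null-calibration of the contrast pipeline, and small full-track cohorts
(3 participants × 24 trials) for exact kinematic label recovery. These
sizes give Monte-Carlo error well inside the asserted tolerances while
keeping the default test run fast.

## Limitations

* The analysis assumes yaw-dominant head reorientation when reporting
  movement end *azimuth*; pitch/roll components are carried by the
  quaternion track but not summarized.
* Real deposited datasets come in heterogeneous layouts; `load_trials()`
  defines this package's documented long-format schema, and mapping an
  external deposit onto it requires a thin adapter written against that
  deposit's actual layout.
* The RM-ANOVA machinery requires balanced complete designs (by design —
  that is the analysis it reproduces); unbalanced data should go to a
  mixed-effects framework instead.
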