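---
title: "Evaluating a video eye tracker with a simulated robotic eye: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a video eye tracker with a simulated robotic eye: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roboteye)
```

## The problem

Whether ambient brightness changes measured saccadic peak velocity is hard
to settle with human observers, because brightness also changes the pupil,
and pupil-based video trackers estimate gaze *from* the pupil. A
stepper-driven artificial eye cuts the knot: its pupil is rigid, its
motion is scripted, and any brightness effect that survives must be an
artifact of the tracking technique. `roboteye` implements both halves of
that experiment in software — a digital twin of the two-axis gimbal that
generates tracker-like gaze recordings, and the analysis chain (saccade
detection, accuracy/precision metrology, main-sequence regression,
repeated-measures inference) that is run on them. Because the generator is
an explicit null model — brightness never alters the motion — the
analysis chain can be validated against known ground truth: detectors
should find every scripted saccade, metrology should recover injected
errors, and the brightness ANOVA should reject at exactly its nominal
rate.

## The gimbal model

Two stepper motors (1.8° full step, 16× microstepping, hence
`r microstep_resolution(1.8, 16)`° per microstep) drive orthogonal axes
whose rotations superpose independently. Moves follow a trapezoidal
velocity profile: constant acceleration $a$ = 9000°/s² (80,000 pulses/s²)
toward the ceiling $v_{max}$ = 360°/s (3200 pulses/s), with symmetric
deceleration. A move of amplitude $d < v_{max}^2/a$ = 14.4° never reaches
the ceiling and peaks at $\sqrt{a\,d}$ — 300°/s for a 10° move. The
profile is sampled on the 1 kHz tracker clock
(`motor_move_profile()`), so all closed forms are testable to one
sample-interval of discretization error.

Two quantizations are distinguished deliberately. The *commanded* target
is snapped to the microstep lattice (at most half a microstep,
0.056°), so the integral of any profile's velocity equals its command to
within one microstep. The *executed* target additionally carries the
drive chain's positioning error — potentiometer, ADC and driver — which
is bounded by ±2 microsteps (±0.225°). The simulator draws this error per
move and axis, uniformly over the lattice points within the bound, so
repeated trials scatter around the planned coordinates exactly as the
bound allows and the accuracy tables can be checked against it.

The physical rig's measured peak velocity at 10° exceeded the triangular
closed form (drive and superposition details the twin does not model), so
absolute peak-velocity levels are not a target of this package; the
*structure* of the main sequence and its invariance across conditions
are.

## The measurement model

Gaze angles map to screen pixels through the display geometry: a
531.36 mm × 298.89 mm, 1920 × 1080 panel (square 0.27675 mm pixels)
viewed from 927 mm, with per-axis angles
$\theta = \arctan(\text{offset}/D)$ about the screen-centre normal.
`render_stream()` adds i.i.d. Gaussian position noise per axis; the
default SD of 0.02° was chosen as the static-target sample noise typical
of a well-focused video tracker at 1000 Hz (sub-pixel to a few pixels),
and is the level the precision tables should give back.

The pupil channel uses a Lambert-style foreshortening model: apparent
area = true area × cos γ, with γ the angle between gaze direction and
the eye-to-camera line. This reproduces the qualitative phenomenon —
the pupil images roundest when looking into the camera — with a single
free parameter, the camera position. The published setup gives only
"slightly left and down" plus the 530 mm working distance, so the camera
offset default had to be fixed here: we use (−80, +130, +530) mm, the
smallest round left-and-down offset whose cosine model makes apparent
pupil area *monotone* across the grid's ±14.2° horizontal extremes
(largest left, smallest right) and across its vertical extremes (largest
down), matching the observed ordering. A camera only 3°–4° off-axis
would instead peak near the centre coordinate and break the ordering.
The default true area, 2888.94 tracker units, is declared equivalent to
the 5 mm artificial pupil; that single declaration fixes the a.u.→mm
scale used when percent deviations are converted to millimetres
(`pupil_deviation_range_mm()`). Pupil measurement noise defaults to
2 a.u. (≈0.07% of the mean) — enough to make the direction ANOVAs
honest tests rather than divisions by zero, small enough to keep their
effect sizes near 1, as observed with a rigid pupil.

## What the generator does and does not emulate

Emulated: 1000 Hz sampling; 300 ms fixations between jumps; random
saccade plans uniform in direction with amplitudes uniform in
4.5–14.1° inside a 10% screen margin, reused across the three brightness
conditions per participant; flagged repositioning (transition) moves
between participants; microstep quantization and the ±2-microstep
positioning error; condition-wise independent measurement noise over a
shared motion (the null model — sharing the noise seed instead makes the
three condition streams bit-identical).

Not emulated: hinge backlash (a dead-band hook exists but defaults to
zero, the effect being acknowledged but unquantified for the rig),
tracking loss near screen corners and the resulting split saccades (the
fragment flag exists so the exclusion rule is exercised, but losses are
not injected), post-saccadic oscillation (meaningless for a rigid eye),
camera image formation, and display photometry. Passing tests therefore
certify the *analysis chain* against an idealized rig; they do not
certify tracker firmware or optics.

## Saccade detection

Velocity is the first derivative of position in degrees, from a 3rd-order
Savitzky–Golay filter over seven samples (`sg_velocity()`), which
differentiates polynomials up to its order exactly. Saccades are runs of
at least six consecutive samples whose combined speed
$\sqrt{v_x^2+v_y^2}$ exceeds $\eta = \lambda\sigma$, λ = 3
(`detect_saccades()`); onset and offset are the first and last run
samples, with no sub-threshold refinement. The combination rule
$\eta = 3\max(\sigma_x,\sigma_y)$ is used because the per-axis noise
levels are estimated separately but one threshold must apply to the
combined speed.

The noise level σ is estimated adaptively: starting from 100°/s, σ is
the SD of samples below the threshold and the threshold is updated to
mean + 6σ, iterating to a 1°/s tolerance. One guard was added to the
published scheme: the update is accepted only while it *lowers* the
threshold. Scripted recordings have a much higher movement duty cycle
than human viewing, and the trapezoid spends equal time at every
velocity below its peak, so an increasing update sweeps movement samples
into σ and diverges to a mixture estimate several times the noise floor;
stopping at the first non-decreasing update keeps the estimate at the
noise level (within ~50% upward bias from ramp samples) while leaving
the pure-noise behavior unchanged. On noiseless input σ is floored at
10⁻⁶°/s so the threshold never collapses to zero.

Onset/offset clipping biases measured amplitudes low by
$\approx \eta^2/a$ (~0.1–0.3° at default noise), which together with the
positioning error explains why a fraction of a percent of saccades
planned at the 4.5° edge can cross the 4.0° exclusion bound; the
exclusion log accounts for every drop.

## Metrology

Accuracy is the signed deviation of the mean measured fixation position
from the planned coordinate τ, averaged over trials, reported in px, mm
and degrees (`accuracy_table()`). Fixation windows are the guarded
complement of the detected events (20 ms trimmed at each end — the
published analyses use unmargined "fixation periods", but transient
samples around onset/offset would otherwise leak into the means).

Precision is reported as the pooled SD of raw fixation samples about
their per-trial means, with $\sum_t (n_t - 1)$ degrees of freedom
(`precision_table()`). Two readings of "SD over all trials" were
possible; dispersion about the per-coordinate grand mean would be
dominated by the rig's trial-to-trial repositioning scatter (up to
±0.225°, an order of magnitude above the tracker's sample noise) and
could never recover an injected noise level, so the per-trial-centred
pooled estimate is the headline number and the between-trial SD of the
fixation means is emitted alongside.

The main sequence is fitted by OLS of peak velocity on amplitude over
the 4–14.6° window (the planned 4.5–14.1° range widened by the
tracker's 0.5° tolerance), where the relation is linear; the fitted
value at 10°, $v_{10}$, is the between-condition statistic. Grand fits
pool all saccades per condition and per-participant fits feed the ANOVA;
whether to pool or average was left open in the source analyses, so both
are computed.

## Repeated-measures inference

`rm_anova()` computes the one-way within-subject decomposition directly
from sums of squares — effect, subject, and subject × level error — so
that the F statistic, partial η² = SS_eff/(SS_eff+SS_err), Mauchly's W
(with Anderson's two-term chi-square approximation) and the
Greenhouse–Geisser/Huynh–Feldt epsilons are auditable in one place and
can be cross-checked against independent implementations in the test
suite rather than delegated to them. The Huynh–Feldt epsilon uses the
classic form $(n q \hat\varepsilon - 2)/(q(n - 1 - q\hat\varepsilon))$,
$q = k-1$, with n subjects, capped at 1 and floored at the
Greenhouse–Geisser value. With k = 2 levels sphericity is automatic
(W = 1, ε = 1) and F equals the squared paired t statistic.

Granularity follows the quantity: the v10 ANOVA uses participants as
subjects (a 198-subject design at full scale); the pupil-size ANOVA uses
individual fixations as subjects, matching the tens-of-thousands error
degrees of freedom of the published analysis — both granularities are
available from the same matrices.

The pupil-direction analysis takes the grid's outer-medial and centre
coordinates — (left, middle, right) on the horizontal midline and
(up, middle, down) on the vertical — and splits trials into random
halves, one half per axis, so no fixation enters both ANOVAs. The exact
split rule was unspecified in the source design; an even seeded random
split is used. Percent deviations of direction means from the grand mean
convert to millimetres under the 5 mm ≡ grand-mean declaration.

## Numerical choices and degenerate inputs

All randomness descends from one master seed through a deterministic
child-seed scheme (multiplicative hash, kept below 2³¹), so every
dataset, report and manifest regenerates bit-identically; manifests
record an MD5 of the canonical config JSON plus output checksums.
Degenerate cases are defined, not accidental: zero-length moves return
empty profiles; an all-identical ANOVA matrix returns F = 0 and η² = 0;
a singular contrast covariance returns W = 0 with p = 0; single-trial
precision and single-amplitude regressions are errors; a participant
cell with fewer than three retained saccades is excluded with a warning,
mirroring the handling of empty recordings at full scale.

## Problem sizes

The package's own validation runs use 100 trials of the 13-point grid
for metrology and pupil-direction analyses, and 100 replicate
experiments of 20 participants × 50 saccades × 3 conditions for the
null-model calibration (type-I rate checked against 0.05 ± 0.04 at that
replicate count, and the p-value distribution against uniformity). These
sizes were chosen as the smallest at which the chi-square, binomial and
Kolmogorov–Smirnov checks are informative; the full published scale
(200 × 200 × 3) runs through the same code path via `run_config()`.

## Known limitations

The twin's peak velocities follow the ideal trapezoid, so absolute
main-sequence levels sit below a physical rig whose drive overshoots the
closed form. The foreshortening model is a single cosine — no corneal
refraction, iris thickness or centroid-estimation geometry — so its
percent deviations are indicative, not calibrated; only their ordering
and sign structure are claimed. The laser-projection helper follows the
doubled-tangent convention of the printed arithmetic
(`2 D \tan\theta`); exact specular reflection (`D \tan 2\theta`) is
available as an alternate model and differs by ~2 cm at the outermost
pattern coordinate — the discrepancy is surfaced rather than silently
resolved.
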