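---
title: "Models and methods behind povar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind povar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povar)
```

povar measures the mouse vestibulo-ocular reflex (VOR) from video-oculography
on a dual-axis turntable and simulates the central circuitry believed to
generate it. This vignette states the models, the algorithms, the tunable
parameters with their units and defaults, what the synthetic data do and do
not emulate, and the design choices that were genuinely open.

## Stimulus kinematics

During constant main-axis rotation at angular velocity $\omega$ (rad/s) on an
arm of radius $r$ (m), gravity $g$ and the centrifugal acceleration
$\omega^2 r$ sum to a gravito-inertial acceleration (GIA) tilted from Earth
vertical by $\theta = \arctan(\omega^2 r / g)$. This is the *equivalent tilt
angle*: the tilt a conventional OVAR test would need for the same otolith
stimulus. `equivalent_tilt_angle()` exposes the exact closed form;
`nominal_tilt_angle()` rounds to the nearest 10° because stimulus grids label
conditions that way (186 °/s at 17 cm is "10°" although the exact angle is
10.35°; the labels are robust to using $g = 9.8$ vs $9.81$ m/s²). We use
standard gravity 9.80665 m/s² and the tangent of the force ratio (the
direction of the resultant force), which is the quantity the otoliths sense;
the residual 1–2% discrepancy between the printed velocity grid and the exact
angles is a property of the labels, not of the physics.

The eccentric axis sets how often the tilted GIA sweeps around the head:
$f = |V_E|/360$ Hz. `gia_timecourse()` returns the head-frame GIA with axes
$x$ naso-occipital (+nose), $y$ interaural (+left), $z$ dorso-ventral (+up).
Sign conventions, fixed once and used everywhere: positive angular velocities
are clockwise (CW) viewed from above; internally angles are radians and
rotations right-handed about $+z$ (so the public CW yaw is the negated
internal $z$ component); degrees at every public boundary.

## Synthetic recordings and their ground truth

No recordings ship with the package; `generate_trace()` builds them with the
statistical structure the analysis assumes, returning the exact ground truth
alongside. The horizontal channel is

$$h(t) = b\,t + A_h \sin(2\pi f t) + Q(t) + \varepsilon(t),$$

a slow-phase drift at the bias velocity $b$, a small horizontal modulation,
the cumulative quick-phase displacement $Q(t)$, and white Gaussian position
noise (default SD 0.1°). The vertical channel is the otolith modulation
$A_v \cos(2\pi f t)$ plus noise. Defaults: $A_v = 3°$, $A_h = 1°$,
$b = -8$ deg/s for CW rotation (mirrored for CCW; with CW positive, the bias
is negative), sampling 60 Hz — typical for the cameras used in mouse
video-oculography and enough to resolve 40 ms quick phases.

Quick phases are triggered two ways, both logged in the ground truth:

- a Poisson process (default rate 1 Hz) with a refractory gap of the
  quick-phase duration + 20 ms;
- a deterministic reset whenever the eye exceeds the orbital limit
  (default 30°, roughly the mouse oculomotor range), which returns the eye
  fully to center.

Poisson amplitudes are drawn from a normal distribution (mean 10°, SD 2°)
but **capped** so a reset never carries the eye more than ~2° past primary
position, and **floored** at 3°. Both rules are deliberate: uncapped draws
would out-run the slow drift and rail the eye against the opposite orbital
limit, firing wrong-direction resets no real mouse shows; and resets smaller
than ~3° are below what 60 Hz video-oculography resolves, so they are not
part of the phenomenon being emulated. The waveform is a half-cosine
displacement step over 40 ms — smooth, differentiable, with a realistic
peak-velocity-to-amplitude ratio. The generator's Poisson counts therefore
follow the dead-time-corrected rate $\lambda/(1+\lambda d)$, which is what
the test suite checks.

Lesion scenarios set parameters, not code paths: `canal_null` keeps the SMC
but removes bias and quick phases; `otolith_null` removes everything at
steady state; `uvl_left`/`uvl_right` multiply the quick-phase rate by the
asymmetry ratio (default 0.6) when the rotation direction matches the
lesioned side's preferred direction (CCW for a left lesion); and
`storage_attenuated` halves bias and rate with the SMC untouched. TAV
(trapezoidal angular velocity) traces use a decaying slow-phase envelope
$v_0 e^{-t/\tau}$ with the same quick-phase machinery.

What the generator does **not** emulate: colored noise, blinks and eyelid
occlusion (artifacts enter only as quality flags), torsion, amplitude–gap
correlations beyond the capping rule, and any dependence of the SMC phase on
the animal. Passing tests on synthetic data therefore demonstrate that the
estimators recover what they claim to recover under the stated noise model —
not that real recordings satisfy that model.

Synthetic video frames (`generate_frames()`) are a bright field with a dark
filled ellipse, an optional specular highlight, and optional pixel noise; the
commanded centers are returned verbatim. The pixel-to-degree calibration is a
fixed linear scale (default 0.2 deg/px): geometric eyeball-rotation
calibration is out of scope, and the mirror optics of real rigs make the
horizontal sign per-camera, so it is a configuration flag (`sign_flip`),
never inferred.

## Pupil detection

`detect_pupil()` binarizes the frame (Otsu threshold by default, or a fixed
value; dark-object polarity assumed), keeps the largest dark connected
component above a minimum area fraction (default 0.5% of the frame), fills
its holes — specular highlights puncture the pupil blob — and fits an
ellipse to the component boundary by the direct least-squares (conic with
ellipse constraint) method, solved on centered/scaled coordinates for
conditioning. Two or more dark components within 20% of each other's size
make the detection *ambiguous* and the frame fails loudly
(`multiple_ambiguous`) rather than guessing; no failure mode ever fabricates
a center. `track_frames()` calibrates centers to degrees (image $y$ grows
downward, so up is positive), bridges failed frames by linear interpolation
up to `max_gap` samples (default 3), and marks longer gaps as artifacts that
the segmentation later excludes.

## Fast/slow-phase separation

`smooth_and_differentiate()` applies a zero-phase (forward–backward)
Butterworth low-pass — zero-phase so event onsets are not lagged, since
onset timing feeds the direction-asymmetry analysis — then first- and
second-order central differences. `segment_phases()` then:

1. marks samples with $|a| >$ `acceleration_threshold` (default
   1000 deg/s²) as seeds and grows candidate events over contiguous runs
   with $|v| >$ `velocity_threshold` (default 30 deg/s);
2. splits a run at pronounced velocity dips between local maxima (a dip
   below 90% of both neighbouring peaks). A single quick phase has a
   unimodal velocity pulse — its two acceleration lobes straddle the
   velocity *maximum* — so a genuine single event never splits, while
   quick phases merged by filter smearing are recovered;
3. times each event by the crossing of 25% of its own peak velocity, which
   makes onset timing amplitude-invariant (large orbital resets smear more
   in absolute terms, but not relative to their peak);
4. absorbs ringing side lobes (neighbouring "events" under 10% of the
   adjacent peak within 0.2 s) and discards events shorter than
   `min_duration` (15 ms) and anything within 0.25 s of the record edges,
   where the zero-phase filter is still settling.

The thresholds are an order of magnitude above what the 0.1–0.4 Hz slow
phases can produce (a 5° modulation at 0.4 Hz peaks at ~13 deg/s and
~32 deg/s², versus ~400 deg/s and ~30,000 deg/s² for a 10° quick phase), so
the margin is wide; all are exposed in `analysis_config()`. The default
low-pass cutoff is 12 Hz: at 60 Hz sampling, a lower cutoff (e.g. 10 Hz)
smears 40 ms quick phases to over 100 ms and irrecoverably fuses events
closer than ~0.12 s, which selectively under-counts high-rate recordings and
biases the CW/CCW ratio; 12 Hz removes frame-rate jitter while keeping
adjacent events separable, and measured detection on the default synthetic
suite is >99% sensitive with no false discoveries. The default analysis
window starts 60 s after record start — platform spin-up and the initial
canal response are discarded — when the recording is at least 90 s long.
Events straddling the window boundary count if their onset is inside.

`bias_velocity()` averages slow-phase velocity after fit-and-subtract of the
stimulus-frequency sinusoid (the intercept of a constant + sinusoid
regression on slow samples), rather than desaccade-and-average alone, so SMC
leakage cannot bias short windows; it refuses to report
(`povar_unreliable_estimate`) when less than half the window is slow phase.
`fit_smc()` fits $dc + \text{drift}\cdot t + A\sin(2\pi f t + \varphi)$ at
the known stimulus frequency — the apparatus controls $f$, so fixing it makes
the fit linear — on slow samples only, with one intercept per inter-quick-
phase segment ("desaccade-and-stitch"): the sawtooth steps left by quick
phases then cannot leak into the sinusoid, which matters for the small
horizontal SMC under a strong FPN. The drift term keeps residual bias out of
the amplitude. The reported amplitude is the fitted peak amplitude (not
peak-to-peak, not a gain); `smc_gain()` divides it by the exact equivalent
tilt angle (pOVAR/OVAR) or the yaw oscillation amplitude (aVOR). Phase is
reported relative to the profile's `phase_reference` but plays no role in
any headline metric (absolute-phase hardware synchronization is out of
scope).

## Time constant

`slow_phase_envelope()` reduces each inter-quick-phase slow segment to its
median velocity (median for outlier robustness) at the segment midpoint;
segments shorter than 8 samples or within 0.1 s of a quick phase are dropped
— the low-pass smears quick-phase velocity into its neighbourhood, and short
fragments sit exactly in those smear zones. `fit_time_constant()` fits
$v_0 e^{-t/\tau}$ by Levenberg–Marquardt nonlinear least squares initialized
from a log-linear regression. The default fit window starts 0.5 s after the
step (platform transients) and stops at the first point below 10% of the
initial velocity or at the first sign flip, whichever comes first — beyond
that the envelope is noise and the log-linear step would blow up.

## The velocity-storage model

The simulator is an explicit dynamical-system formalization of the
velocity-storage circuitry; the schematic it implements names the parts but
not the equations, so the concrete ODEs below are this package's documented
choice — the minimal system consistent with every pathway and with the
behaviours it must reproduce. State: canal high-pass state $x_c$, internal
gravity estimate $\hat g$, storage $s$ (all 3-vectors, head frame), and eye
position. With head angular velocity $\Omega$ and sensed GIA:

$$\dot x_c = (\Omega - x_c)/T_c, \qquad c = \Omega - x_c$$
$$\dot{\hat g} = -\,\omega_{est} \times \hat g + k_G\,(GIA - \hat g)$$
$$\dot s = \big(k_S\,c^{*} + k_F\,\gamma\,(GIA \times \hat g) - s\big)/T_s,
\qquad \omega_{est} = c^{*} + s$$

where $c^{*}$ applies the side-specific canal gain to the yaw component (the
left lateral canal drives CCW estimates, the right CW), and the gate
$\gamma = \text{otolith\_gain} \times \text{canal gain of the driving
side}$. The gate is the model's core claim: the rotation feedback
$k_F(GIA \times \hat g)$ — which converts the rotating otolith vector into a
sustained angular-velocity estimate, because $\hat g$ tracks the rotating
GIA with a lag and the cross product of two vectors rotating together with a
fixed lag has a constant axial component — is only effective when canal
input maintains the rotational estimator. Cutting both canal gains silences
the fast phases while leaving the direct otolith pathway (the SMC) intact;
cutting the otolith gain removes both drive and modulation; halving $T_s$
and $k_F$ (pharmacological storage suppression) reduces the fast-phase rate
with the SMC nearly unchanged; and a one-sided canal gain suppresses only
the rotation direction that side drives. Slow-phase eye velocity is
$-\,\text{vor\_gain}\cdot\omega_{est,yaw}$ plus a small otolith-driven
horizontal modulation; quick phases are deterministic orbital resets (limit
15°, reset fraction 0.9, no Poisson term) so the simulator's fast-phase rate
is a reproducible function of its bias. The sign structure makes the bias
oppose head rotation and the quick phases beat with it, with CW rotation
producing a negative bias.

Defaults: $T_c = 4$ s, $T_s = 15$ s, $k_F = 0.7$ (deg/s)/(m²/s⁴),
$k_G = 2$ s⁻¹, $k_S = 0.9$, vor_gain 0.8, vertical SMC drive 0.5 deg per
m/s² of naso-occipital GIA. These were chosen once to put the control
phenotype in the physiological range for mice (bias ~9 deg/s and FPN
~0.7 Hz at tilt 30°, 0.2 Hz; V-SMC ~3°; TAV decay slower than the canal
alone); they are not fits to any figure, and no quantitative matching to
published group data is attempted. Integration is fixed-step RK4 at
$dt = 1$ ms — far below every time constant in the system and the
modulation period — with divergence guards on the state and a stability
check that $|\hat g|$ stays within [0.5, 1.5] × gravity. Head angular
velocity during pOVAR is the signed sum of both axis rates; the spin-up
transient this implies is discarded by the steady-state window (the last
half of the simulation), and steady-state claims require the simulated
duration to cover at least five storage time constants.

## Problem sizes and numerical choices

The test suite regenerates everything from code: 3-minute, 60 Hz recordings
for detection and asymmetry studies (50 and 20 seeds), 20 seeds per
time-constant condition ($\tau$ = 2, 5, 10 s), 90–150 s simulator runs, and
100-frame image stacks — sizes chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick to run.
Ties and degenerate inputs are handled explicitly: zero traces flag
$r^2$ as undefined instead of dividing by zero; a segmentation with no
events degrades the envelope to fixed 0.5 s bins; asymmetry ratios with a
zero denominator raise `povar_undefined_ratio` rather than returning
infinity; all stochastic code is driven by a single integer seed and
regenerates bit-identically.

## Known limitations

- The detector's resolution floor is set by the camera rate: at 60 Hz,
  quick phases closer than ~2 samples are one event to any method.
- The calibration is linear; true eyeball-rotation geometry (and hence
  amplitude compression at large eccentricities) is not modelled.
- The velocity-storage model is qualitative by design: it reproduces
  orderings and dissociations, not published effect sizes, and its
  leaky-integrator realization of the otolith-to-bias conversion is one of
  several dynamical systems consistent with the circuit.
- Torsional eye movements, binocular interactions and group-level
  statistics are out of scope.
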