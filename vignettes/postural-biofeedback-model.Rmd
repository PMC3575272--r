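---
title: "Modelling perturbed stance with vibrotactile biofeedback torques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perturbed stance with vibrotactile biofeedback torques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturefb)
```

## The model

`posturefb` simulates a standing human as a two-link inverted pendulum in
three dimensions: a legs link (knees locked) pinned to a movable platform at
the ankle, and a head–arms–trunk link articulated at the hip. Both joints are
ideal spherical joints reduced to two rotational degrees of freedom each
(pitch and roll; axial yaw carries no torque in the model and is locked), so
the plant state is eight-dimensional: four joint angles and their rates.
There is no passive joint stiffness or damping — the passive contribution to
stance torque is known to be small — so all stabilisation comes from active
torques.

Two independent delayed full-state-feedback controllers stabilise the
sagittal (anterior–posterior, AP) and coronal (medial–lateral, ML) planes:

$$ T_{PC}(t) = -K\,x(t - t_d), \qquad
   x = (\alpha_a, \alpha_h, \dot\alpha_a, \dot\alpha_h)^\top $$

with a 2×4 gain matrix per plane and a common sensorimotor delay $t_d$
(default 0.1 s, a typical physiological latency; the delay is rounded to an
integer number of integration steps). Plane independence reflects the
experimental observation that AP and ML balance are controlled separately;
the nonlinear plant still couples the planes away from the upright
symmetric configuration, and the simulation captures that coupling in full.

Vibrotactile biofeedback is modelled *after* the postural controller, as an
additional joint torque:

$$ T_J = T_{PC} + T_F, \qquad
   \tau_F \dot T_F + T_F = K_F, $$

a first-order lag (reaction time constant $\tau_F$) pulling the biofeedback
torque toward a target $K_F$ set by the tactor display. The display senses
torso tilt: inclination $\varphi$ plus half its rate, $m = \varphi +
\tfrac12\dot\varphi$, displayed through up to 16 tactor columns at 22.5°
around the waist (nearest-neighbour column selection, 1° dead zone) and up
to three rows coding magnitude stepwise. The torque target decomposes the
*displayed* column azimuth $\theta$ into cardinal components,

$$ K_F^S = k_r \cos\theta, \qquad K_F^C = k_r \sin\theta, $$

with per-row magnitude vectors $k_1 \le k_2 \le k_3$ (componentwise, ankle
and hip). Using the displayed azimuth rather than the raw tilt azimuth is a
deliberate modelling choice: it is the only reading under which display
resolution can influence the closed loop at all, which is precisely the
comparison of interest (3×4 vs 3×8 vs 3×16 vs 1×2 column layouts).

## Dynamics and numerics

The equations of motion are evaluated by an exact Kane/Newton–Euler
formulation (closed-form partial velocities; no finite differences, no
small-angle approximation) in compiled code. The platform enters as a
prescribed horizontal acceleration of the ankle point; perturbations are
trapezoidal velocity pulses — 100 ms constant acceleration, 200 ms constant
velocity, 100 ms deceleration, 50–70 mm of travel (default 60 mm, the
midpoint of the range) — aimed along an azimuth measured clockwise from the
navel: 180° moves the platform backward (sagittal response), 90° rightward
(coronal), 225° diagonally.

The closed loop is integrated with fixed-step classical Runge–Kutta (RK4)
at `dt = 1` ms on a single shared grid for plant, delay buffer and device,
which keeps the delayed-state lookup exact. Within a step the controller
torque is interpolated linearly between the two bracketing delayed samples
at the half-step stage, and the biofeedback lag is advanced by its exact
exponential solution, so constant targets reproduce the analytic step
response to machine precision. Halving `dt` changes the 3-s sway response
by well under $10^{-4}$ degrees RMS. Runs abort with a diagnostic if any
joint angle passes $\pi/2$ (a fall; far outside the model's intended
regime).

The centre of pressure (COP) is computed from the reaction wrench
transmitted at the ankle: the horizontal point about which the ground
reaction has no horizontal moment, with the vertical reaction including
link accelerations. For a held static lean this reduces to the textbook
moment balance `COP = T_ankle / (m g)`, and over long windows the mean COP
tracks the horizontal projection of the whole-body centre of mass. How the
original study computed its model COP is not documented; the reaction-wrench
definition is the standard reconstruction.

Two further routes are implemented for validation rather than simulation:
a closed-form linearization about upright (per-plane planar double-pendulum
mass and gravity-stiffness matrices), and — in the test suite — a fully
independent symbolic Euler–Lagrange derivation; the Kane implementation
agrees with it to machine precision on random states.

## Anthropometry

Body parameters derive from subject height and mass through a documented
fraction table: the legs link lumps both thighs, shanks and feet
(mass fraction 0.322, length 0.530 of height, centre of mass 0.56 of link
length above the ankle) and the torso link is the head–arms–trunk segment
(0.678, 0.470, 0.35). Inertia tensors use closed-form solids: a cylinder
for the legs, an ellipsoid for the trunk, with dimensions as fixed fractions
of link length. The original study cites external segment tables without
printing them, so these defaults are a stand-in assembled from standard
biomechanics segment data, fully overridable in the scenario configuration;
all parameter-recovery experiments treat the body as given rather than as a
reproduction target. The default subject (1.78 m, 86 kg) is the mean of the
study population the model was built for (individuals with bilateral
vestibular hypofunction).

## Default controller gains

Demonstration gains cannot come from plain LQR: with a 0.1 s delay the
LQR-optimal gains destabilise the loop (the fast hip mode's growth rate
times the delay is of order one, so the stable gain region is narrow).
The packaged defaults are instead designed against the delay explicitly:
the rightmost characteristic root of the delayed per-plane closed loop is
computed by Chebyshev spectral collocation of the delay system and
minimised over the eight gains with a deterministic Nelder–Mead search,
seeded from the LQR solution and from a literature-scale
proportional–derivative pattern; among stable candidates the better-damped
transient wins. For the default body this yields a well-damped response
with ~2° peak AP sway and peak ankle torques near 110 N·m for the 60 mm
backward perturbation — the same order as stance torques reported for
perturbed standing. These are illustrative values: fitting replaces them,
and the fitted gains, not the defaults, are the scientific object.

## The synthetic reference generator

The study's averaged human trajectories are not publicly deposited, so the
package generates its own reference data with known ground truth: the
default study fixture simulates the mean subject with the 3×4 display,
reaction constant $\tau_F = 0.3$ s, sagittal magnitudes
$k^S_{\text{ankle}} = (4, 6, 8)$ N·m and $k^S_{\text{hip}} = (0, 2, 3)$
N·m, and zero coronal magnitudes — mirroring the qualitative fitted
findings (no coronal biofeedback torque needed; the lowest row acts on the
ankle only; peak additional ankle/hip torques of order 8/3 N·m). References
are decimated to the experimental 100 Hz rate. Optional noise is smooth
(2nd-order Butterworth low-passed Gaussian, 2 Hz cutoff, scaled to a target
standard deviation) because the experimental references were across-subject
*averages*, which are smooth; white noise would mis-weight the fit. What
the fixture does **not** emulate: inter-subject variability, sensory noise,
nonlinear postural strategies for large perturbations, or cognitive load —
so passing recovery tests demonstrates the machinery, not clinical
validity.

## Fitting

The fitting criterion integrates the squared *sum* of the normalised
residual channels over a 3-s window from perturbation onset, exactly as the
printed criterion does (cross terms included); a `form = "sum_of_squares"`
switch provides the conventional alternative, since the printed form is
unusual. Channels are normalised by their peak reference values; AP sway is
excluded for 90° perturbations and ML sway for 180° (the model responds
strictly unidirectionally there — an exact symmetry of the implementation,
tested to $10^{-12}$°), and any channel whose reference peak is zero is
dropped because its normaliser would vanish.

Optimisation is two-stage: an exhaustive grid sweep, then a perpendicular
search from the sweep winner. The search probes a set of mutually
orthogonal directions with adaptive signed steps (success: accept and grow
×3; failure: reverse and halve) and, once every productive direction has
both succeeded and subsequently failed, re-orthogonalises the direction set
around the accumulated progress vector — Rosenbrock's rotating-coordinate
scheme. Plain axis-aligned probing with step halving was implemented first
and stalls badly in the long curved valleys this objective has (it needed
an order of magnitude more evaluations to reach a worse point); rotation is
the textbook remedy and remains a derivative-free perpendicular-direction
search. The biofeedback row-ordering constraint $k_1 \le k_2 \le k_3$ is
handled by projection; for fits over several rows at once it is better to
parameterise the rows by non-negative increments $(k_1, k_2-k_1, k_3-k_2)$
through the custom-objective hook, which removes the flat directions the
projection would otherwise create.

Two identifiability facts, established numerically and worth knowing before
fitting real data. First, without delay ($t_d = 0$) the sagittal gain
matrix is *not* identifiable from a single 180° transient — the smallest
singular value of the output sensitivity is ~0.002, and gain sets differing
by over 100% reproduce the trajectories to 0.01% — whereas with the 0.1 s
delay present the spectrum is well conditioned (smallest singular value
~1.1). Parameter-recovery experiments therefore run with the delay, which
is also the physiological condition. Second, the biofeedback objective is
multimodal: tactor switching creates nearby basins whose trajectories
differ by under a percent while the parameters differ by tens of percent,
and the true-parameter basin is only a few percent wide. Local searches,
box sweeps at tractable density, Nelder–Mead and Levenberg–Marquardt all
land in the spurious basins. The shipped biofeedback-recovery experiment
instead uses the structure the reference exposes: the display senses
exactly the sway the reference records, so the row/column activation
sequence can be reconstructed from the reference itself; given that
sequence and a candidate $\tau_F$, the biofeedback torque is an exactly
linear function of the magnitude increments. Sweeping $\tau_F$ over
0.1–0.7 s, injecting the lag-filtered basis staircases as exogenous
torques into the display-off loop, and solving a linear least-squares
problem per level lands within a few percent of the generating
parameters; the perpendicular search then polishes the best level.

## Validation metrics

Model fits are scored by two windowed metrics, both over 3 s from
perturbation onset (onset sample included) on the 100 Hz grid: the mean
absolute instantaneous difference ("average error", degrees for sway,
centimetres for COP) and the zero-lag normalised cross-correlation
$\sum e s / \sqrt{\sum e^2 \sum s^2}$. No mean subtraction is applied —
the channels are deviations from upright, where zero is meaningful — and no
lag search is performed by default (a `max_lag_s` option exists); with
values like 0.97–0.998 on transients the zero-lag coefficient already
indicates shape agreement. The printed validation table of the original
display-configuration study ships as a CSV resource
(`table1_values()`), and `table1_summary()` reproduces its block means —
0.24° and 0.39 cm average error, 0.97 cross-correlation for both sway and
COP — by plain arithmetic.

## Reproducibility and problem sizes

Everything is deterministic given a seed: the simulator itself uses no
randomness, and fixture noise flows from a single recorded seed. The test
suite and the acceptance script run closed-loop simulations of 4 s at 1–2 ms
steps (4 s covers the 0.5 s settling margin, the 0.4 s perturbation and the
3 s analysis window), recovery experiments with a few thousand objective
evaluations, and the dynamics cross-checks on 100 random states — sizes
chosen so the whole suite completes in minutes on a single core while still
exercising every code path at full precision.

## Known limitations

The model is valid for small discrete perturbations of quiet stance only:
no feet (COP is not saturated at a base of support), no knees, no arm or
stepping responses, no sensory noise or estimation, no torque saturation,
no habituation or cognitive-load effects, and deterministic dynamics — it
reproduces average trajectories, not trial-to-trial variability. The device
row thresholds beyond the 1° dead zone and the exact anthropometric tables
are reconstructions, configurable but not authoritative.
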