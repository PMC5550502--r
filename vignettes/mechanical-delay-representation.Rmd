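---
title: "Representing a visuomotor delay as an equivalent mechanical system"
author: "mechdelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing a visuomotor delay as an equivalent mechanical system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechdelay)
```

## The task and the two operators

In the tracking task this package models, a participant moves a handle to
drive a cursor after a sinusoidally moving target,
$x_{target}(t) = A_T \sin(\omega t)$ with $A_T = 6$ cm and
$f = 0.556$ Hz. Three cursor mappings are used:

* **Normal (N)** — the cursor equals the hand position.
* **Delay (D)** — the cursor lags the hand by $\tau = 0.25$ s:
  $x_{cursor}(t) = x_{hand}(t - \tau)$.
* **Mechanical (M)** — the cursor is the state of a virtual
  spring–mass–damper link driven by the hand,
  $x_{hand} = x_c + (B/K)\,\dot x_c + (M/K)\,\ddot x_c$.

The Mechanical condition is not arbitrary: truncating the Taylor expansion
of the delayed state after the second-order term,
$x(t+\tau) \approx x + \tau \dot x + \tfrac{\tau^2}{2}\ddot x$, and matching
coefficients gives $B/K = \tau$ and $M/K = \tau^2/2$
(`mechanical_from_delay()`). Any such system is underdamped with damping
ratio $1/\sqrt 2$ regardless of $\tau$. In the frequency domain the delay
operator is $e^{\tau s}$ (unit gain, temporal shift exactly $\tau$) while
the mechanical operator is $1 - \tfrac{\tau^2}{2}\omega^2 + j\tau\omega$,
with gain $\sqrt{1 + \tau^4\omega^4/4}$ and temporal shift
$\arctan\!\big(\tfrac{2\tau\omega}{2-\tau^2\omega^2}\big)/\omega$. At the
experiment's operating point these shifts are 0.25 s and 0.27 s, and the
mechanical gain is about 1.070 — to track perfectly through the mechanical
link the hand must move both earlier *and* larger (about 6.42 cm for a 6 cm
target).

Within a trial the manipulation follows a ramp–plateau–ramp profile
(`delay_schedule()`): 5 s aligned, a 10 s linear ramp to the full value, an
80 s plateau, a 10 s ramp down and 5 s aligned. All headline metrics are
computed on the plateau. The Mechanical condition ramps the *equivalent
delay*: at each instant the ratios are $(\tau(t), \tau(t)^2/2)$, keeping
both conditions parameterized by the same scalar profile.

## Competing internal representations

Two feed-forward models of how a participant might generate the hand
command are implemented (`representation_state()`):

* **Delayed-state** — an explicit delay estimate $\tilde\tau$ advances the
  target: $x_{hand}(t) = A_T \sin(\omega(t + \tilde\tau))$.
* **Mechanical** — estimated elements $\tilde K, \tilde B, \tilde M$ shape
  the command from the target and its closed-form derivatives:
  $x_{hand} = x_{des} + (\tilde B/\tilde K)\dot x_{des} +
  (\tilde M/\tilde K)\ddot x_{des}$.

Both representations can cancel *their own* condition at the tracking
frequency, but they fail differently on the other one: the delayed-state
command has unit gain, so it can never correct the mechanical operator's
amplitude inflation; the mechanical command is only a second-order
approximation of a true delay, so a third-order Taylor remainder survives
on Delay trials. This asymmetry is what catch trials probe.

Trial-by-trial adaptation is an exponential law
$value(i) = c_1 + c_2 e^{i/c_3}$ over the 16 manipulation trials
(`adaptation_schedule()`; familiarization trials do not enter it, and the
index is the manipulation-trial number). For the mechanical representation
the estimated spring $\tilde K(i)$ carries the trial dependence while
$\tilde B$ and $\tilde M$ stay constant, so "ratios near zero" early in
learning is realized by a large $\tilde K$ rather than a special case.
Values are clamped to physical ranges ($\tilde\tau \in [0, 0.5]$ s,
$\tilde K \in [1, 500]$ N/m) so a diverging exponential cannot leave the
model's domain.

## Simulating protocols and fitting schedules

`run_protocol()` simulates the 19-trial group designs (three Normal
familiarization trials, then 16 manipulation trials; groups 1–2 train on
one condition with catch trials of the other at manipulation trials 7, 11
and 15 by default; groups 3–4 run two 8-trial blocks). Each trial's
tracking error is the RMSE between target and cursor over the 80 s plateau.

`fit_schedule()` recovers the adaptation constants from an observed
per-trial RMSE series by least squares over the dominant-condition trials
only — catch trials are excluded from the loss, mirroring how the
experiment's learning curves are derived. Two numerical choices matter:

* The predicted plateau RMSE inside the loss is evaluated in closed form:
  the hand command is an exact sinusoid, the cursor its image under the
  condition's steady-state response, and the sampled-grid RMSE of two
  sinusoids has an exact expression via geometric sums
  (`sampled_sinusoid_rmse()`). For the Mechanical condition the steady
  state used is that of the *discrete* RK4 recursion, not the continuous
  transfer function, so the prediction matches the full simulation to the
  integrator's transient accuracy (~1e-8 m) and fits against simulated
  series recover schedules to better than 1e-6 m.
* The loss surface of exponential-plus-offset families has local minima,
  so the fit uses seeded multi-start (20 restarts by default,
  Nelder–Mead followed by a quasi-Newton polish), and is deterministic
  given its seed.
* The schedule is anchored to the un-adapted state before the first
  manipulation trial (`unadapted_start`): the representation is veridical
  during normal tracking ($\tilde\tau$ near 0, $\tilde K$ large), so
  fitted trajectories must start there. Without this anchor the clamped
  exponential family admits "overshooting" solutions (e.g. $\tilde\tau$
  starting at 0.5 s and descending) that fit a descending error series
  comparably well but are not physiologically interpretable, and whose
  catch-trial predictions differ qualitatively.

With schedules fitted this way, the catch-trial contrast
(`catch_trial_contrast()`: catch RMSE minus the mean of the neighbouring
dominant trials, averaged over catches) separates the representations:
the mechanical representation predicts worse performance on Delay catches
under mechanical training and no worsening on Mechanical catches under
delay training, while the delayed-state representation predicts the
reverse. The package's tests assert exactly these signs.

## Kinematic analysis

`plateau_rmse()`, `segment_signal()` (a 110 s trial gives exactly 22
five-second segments; non-multiple durations are an error rather than a
silent truncation), `trial_lag_profile()`, `after_effect()` (lag of
segment 19 minus lag of segment 22), `fit_learning_curve()` (double
exponential $p_1 e^{-i/p_2} + p_3 e^{-i/p_4} + p_5$ with positive time
constants, multi-start least squares, extrapolation to an arbitrary trial)
and `movement_amplitude()` (mean absolute displacement of reversal points)
implement the per-trial metrics.

Cross-correlation lags (`xcorr_lag()`) use these conventions: positive lag
means the first signal leads the second; the search window defaults to
±0.9 s — half the target period, the widest alias-free window for
near-sinusoidal signals; the correlation is Pearson-normalized on every
overlap so amplitude differences between conditions cannot bias the
argmax; ties are broken toward the smallest absolute lag. The
implementation computes all overlap correlations exactly via one FFT
cross-correlation plus prefix sums, and recovers on-grid shifts exactly
and off-grid shifts to within one sample.

## Grip-force analysis

The load force on the hand is inertial: handle mass times acceleration,
with acceleration from double central differences, low-pass filtered at
12 Hz with a fourth-order Butterworth applied forward and backward (zero
net phase; the effective order doubling is accepted as part of the
zero-phase procedure). The handle mass is not part of the task definition
and defaults to 0.1 kg; all phase metrics are mass-invariant because mass
scales the load uniformly, but the GF/LF ratio is not — ratios should be
compared across conditions, not read as absolute physical values.

Because the inertial load oscillates about zero while grip force is
strictly positive, the GF–LF phase correlates grip force against the
*rectified* load, and "mean LF" in the GF/LF ratio is the mean absolute
load. The rectified load has half the movement period (~0.9 s), so the
GF–LF search window defaults to ±0.4 s, below a quarter movement period,
to avoid rectification aliasing. Both metrics average segments 4–19, the
maximum-manipulation window.

The virtual spring force is $F = K (x_{hand} - x_{cursor})$ — the force
the spring of the mechanical model exerts given the instantaneous stretch;
adding it to the inertial load and recomputing phase and ratio
(`grip_metrics()`) tests whether grip force was programmed for the total
(real plus illusory) load. On synthetic trials whose grip force is coupled
to the total load with a constructed lead, the raw phase exceeds the lead,
correction with the generating $K$ restores it to within one sample, and
the corrected ratio drops — the direction the grip-force evidence takes in
the human data.

## The synthetic-subject generator

`subject_params()` + `generate_experiment()` produce whole experiments
with known ground truth, replacing the (unavailable) human recordings.
What it emulates, and what it does not:

* Hand trajectories follow the subject's internal representation with the
  within-trial ramp, plus band-limited noise (white noise low-passed at
  5 Hz, default SD 2 mm). Raw white noise would make the differentiated
  load force unbounded, unlike human kinematics; conversely, no attempt is
  made to match human noise spectra or variability distributions, so
  passing tests demonstrate pipeline correctness, not behavioural realism.
* The compensatory lead carries across trials: the head lead of a trial is
  0.8 times the previous trial's tail lead, and within a trial the lead
  morphs between the carried value and the representation's steady-state
  compensation following the ramp profile, with half the plateau lead
  surviving to the tail. This reproduces the observed pattern of cursor
  leads at trial starts and after-effects at trial ends, without claiming
  the carry-over dynamics are quantitatively human.
* Grip force is a gain times the rectified (total or inertial) load,
  shifted by a 50 ms anticipatory lead, plus a 1 N baseline and band-
  limited noise, floored at 0.1 N so grip never fully releases. The lead
  magnitude is a free default — the experiment only reports that grip
  force slightly led the load.
* The default ground-truth adaptation converges the estimated spring to
  the delay-equivalent parameters ($\tilde K \to 27$ N/m with
  $\tilde B/\tilde K \to \tau$, $\tilde M/\tilde K \to \tau^2/2$), i.e.
  the subject ends up representing the delay *as* its canonical mechanical
  image rather than as the tracking-error-optimal member of its parameter
  family. This is the package's modelling choice; it is what produces the
  catch-trial asymmetry as observed, and the starting value saturates the
  clamp so subjects begin effectively un-adapted.
* Every generator is a pure function of (parameters, seed, trial index).

## Numerical choices and degenerate inputs

* **Integration** — fixed-step 4th-order Runge–Kutta at the 400 Hz
  sampling rate with linear interpolation of the forcing between samples:
  deterministic and directly testable against closed forms. The linear
  forcing interpolation carries a relative amplitude bias of order
  $(\omega\,dt)^2/8 \approx 10^{-5}$; analyses that must match the
  integrator exactly use its discrete steady state rather than the
  continuous transfer function.
* **Ramping mechanical trials** — as $\tau(t) \to 0$ the link becomes
  stiffer than the step size can resolve; below an equivalent delay of
  5 ms the cursor is clamped to the hand (the rigid limit). At 400 Hz the
  stability margin of RK4 is reached near 1.3 ms, so the 5 ms threshold is
  conservative.
* **Delay implementation** — exact sample shift when $\tau/dt$ is an
  integer (0.25 s at 400 Hz is exactly 100 samples), linear interpolation
  otherwise; pre-history held at the first sample, which real trials never
  exercise because they start aligned.
* **Quadrant handling** — the mechanical phase uses the two-argument
  arctangent, so it grows continuously past $\pi/2$ when
  $\tau\omega \ge \sqrt 2$ turns the real part negative; at the
  experiment's operating point both conventions agree.
* **Initial conditions** — the cursor starts at the hand's position with
  zero velocity, as trials begin aligned.
* **Reversal detection** — a zigzag filter with a prominence threshold of
  10% of the signal half-range (configurable) rejects noise
  micro-reversals; boundary extrema are discarded.
* **Degenerate inputs** — zero-variance signals, non-multiple segment
  durations, negative delays or ratios, missing plateaus, zero load force
  and non-positive spring constants all raise errors rather than
  propagating silently.

## Problem sizes

The package's own validation uses full-scale trials (110 s at 400 Hz,
44 000 samples) throughout, with 30–40 s signals for steady-state
transfer-function checks, 19-trial protocols for the catch-trial
analysis, and 20-seed Monte-Carlo batches for the noisy-recovery checks
of the schedule fits; these sizes keep every check well-resolved while the
whole suite runs in a few minutes.

## Known limitations

* The simulator is feed-forward per trial: no within-trial feedback
  corrections or optimal-control model, so it cannot reproduce
  within-trial error dynamics, only steady-state plateau behaviour.
* Group-level inferential statistics on human data are out of scope; the
  pipeline exports descriptive per-trial metrics only.
* The mechanical-representation fit is intentionally over-parameterized
  ($\tilde B$, $\tilde M$ and the $\tilde K$ schedule trade off); only the
  predicted RMSE series is identified, not the individual constants.
* Absolute GF/LF ratios depend on the unknown handle mass; only their
  condition-wise ordering is meaningful.
* The hand mass of the physical setup never enters the implemented
  dynamics: the hand-side mass is flagged but deliberately left out, as
  only the hand-to-cursor map matters for the analyses.
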