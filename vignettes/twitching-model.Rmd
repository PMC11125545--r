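---
title: "The twitchsim model: kinetic Monte Carlo twitching motility and likelihood-free inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The twitchsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twitchsim)
```

## The physical model

`twitchsim` simulates surface ("twitching") motility of a rod-shaped
bacterium driven by type IV pili (TFP).  The cell body is a rigid
spherocylinder (radius $r$ = 0.5 µm, cylinder length $l$ = 3 µm, typical
*P. aeruginosa* dimensions) above the plane $z = 0$.  Each pole carries
one surface interaction site at the centre of its spherical cap; the
site potential is a stiff harmonic wall against penetration plus,
optionally, a bounded quadratic well of depth $\varepsilon$ and width
0.05 µm that represents short-range, pilus-independent adhesion.  The
well is what maintains the crawling orientation (both poles down): pili
pull on the leading pole and would otherwise torque the body upright
into the walking state.

TFP nucleate at rate $k_\mathrm{spawn}$ at anchor sites distributed
around the leading pole.  The anchor field follows a von Mises–Fisher
distribution with concentration $\kappa$ about the body axis, the
spherical analogue of a Gaussian: large $\kappa$ concentrates pili at
the pole tip, small $\kappa$ spreads them down the leading half of the
body.  Polar angles up to $\pi/4$ stay on the leading cap; angles in
$[\pi/4, \pi/2]$ are transported by a linear map onto the near half of
the cylindrical wall; back-hemisphere draws anchor at the mirrored
position but keep their (backward-pointing) growth direction, so a
small, $\kappa$-dependent fraction of pili extends backwards over the
body.  This backward fraction is what makes the deviation-angle
statistic a sharp readout of $\kappa$.

Free pili are discrete worm-like chains (segment length $\delta$ = 4 nm,
persistence length $L_p$): bend angles carry the harmonic bending
Boltzmann weight $\exp(-(L_p/2\delta)\theta^2)$ under the spherical
$\sin\theta$ measure, so the tangent correlation decays as
$\exp(-s/L_p)$.  Chain shapes are refreshed at rate $k_\mathrm{resample}$
by a Boltzmann generator; because the substrate is impenetrable, draws
that overlap the surface are rejected and redrawn (a chain that cannot
avoid the wall is trapped against it and binds).  Between refreshes a
chain is a frozen thermal shape tethered at its anchor: it follows the
anchor's translation but does not co-rotate with body spin.  Pili adhere
to the surface at their tips only: a chain binds the moment its tip
crosses $z = 0$ — by extension growth, by resampling, or because the
body moved.

Each pilus runs a motor state machine: extending
→ (motor off, $k_\mathrm{ext,off}$) passive → ($k_\mathrm{ret,on}$)
retracting → ($k_\mathrm{ret,off}$) passive → ($k_\mathrm{ext,on}$)
extending, with extension/retraction advancing in Poisson $\delta$-steps
at rates $v_\mathrm{ext}/\delta$ and $v_\mathrm{ret}/\delta$.  In the
surface-sensing limit used by default ($\tau_\mathrm{delay} = 0$) a
bound pilus retracts immediately and keeps the retraction motor when it
detaches, so most pili perform a single extension–retraction cycle;
setting `tau_delay > 0` inserts an exponential passive interval after
binding instead.  A bound pilus is a straight elastic filament: with
anchor–attachment distance $r_{ab}$ and rest contour length
$l_\mathrm{eq}$ it stores $u = (E/2)(r_{ab} - l_\mathrm{eq})^2 /
l_\mathrm{eq}$ when stretched and nothing when slack (pili cannot push).
Retraction shortens $l_\mathrm{eq}$ until the tension exceeds the stall
force $f_\mathrm{stall}$, at which point the motor stalls until the body
relaxes or another pilus lets go; an unrestrained bound pilus retracts
to zero length and dissolves.  Detachment (rate $1/\tau_\mathrm{dwell}$,
tension-independent) shrinks the pilus by one $\delta$ and re-shortens
it until the freed chain clears the surface.

## Body dynamics: overdamped creep and impulsive release

Events are scheduled by a kinetic Monte Carlo loop: waiting times are
exponential in the total rate and events are chosen proportionally to
their rates.  After every event that changes bound-pilus geometry the
rigid body is moved toward mechanical equilibrium of the pilus tensions
and surface forces, over the six rigid-body degrees of freedom
(translation plus axis–angle rotation).

The model contains no explicit friction or viscous force; dissipation
enters through the *loaded* retraction speed, which is what experiments
that watch pili drag cells actually measure.  Concretely the pose
follows an overdamped quasi-static descent of the total energy at speed
$\min(|F|/\gamma, v_\mathrm{ret})$, with the mobility calibrated so that
a stall-force load drags the body at the loaded retraction speed
($\gamma = f_\mathrm{stall}/v_\mathrm{ret}$).  Balanced multi-pilus
configurations therefore creep slowly, while a single taut pilus drags
the cell at $v_\mathrm{ret}$.  Losing an attachment is different: the
remaining stretched pili then snap the body to its new equilibrium on a
timescale far below the creep scale, so detachment relaxations are
performed as one uncapped, impulsive "slingshot" minimisation — the
rapid sub-second displacements that tracking studies of twitching
report.  The exported `relax_body()` keeps strict local minimisation
(monotone descent, damped Newton with a finite-difference Hessian of the
analytic gradient); the time-budgeted variant is internal to the
engine.  Relaxation is invoked only after events that change the
bound-pilus set or geometry, since free pili exert no force on the body.

## Trajectory statistics

Pole tracks are recorded at 10 frames per second.  Analysis follows the
tracking pipeline used for experimental data: tracks are linearised into
steps of fixed length $\delta_\mathrm{step}$ = 0.12 µm (greedy scan;
noise suppression), and a trajectory set is reduced to four pooled
statistics — the mean linearised speed $\langle u\rangle$, the variance
of the deviation angle between the surface-projected body axis and the
step velocity, and the persistence $\hat q$ and activity $\hat a$ of a
fitted persistent random walk $v_i = \hat q\, v_{i-1} + \hat a\, n_i$.
The deviation angle is taken as the *signed* planar bearing in
$(-\pi,\pi]$; its mean vanishes by left–right symmetry, so the variance
is the mean-square deviation from straight-ahead motion.  (The unsigned
angle folded onto $[0,\pi]$ cannot exceed a variance of about 0.6 for
any forward-concentrated distribution and would make the statistic
nearly independent of $\kappa$; the signed bearing's variance equals the
mean-square fan angle of the pili, which is exactly what makes it
informative about the anchor distribution.)  The top 1% of step speeds
(at least one step, so small pooled samples are protected too) is
discarded from $\hat q$ and $\hat a$ only — these estimators are the
statistics most sensitive to rare tracking glitches — while the mean
speed and deviation-angle variance use all steps.  The package also
provides the mean-squared-displacement scaling exponent (lag times
$\ge$ 2 s), the walking/crawling classifier based on the sliding-window
minimum of the projected aspect ratio (threshold 1.6, window 200
frames), and walking↔crawling transition timing from the trailing-pole
contact gap.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `tau_dwell` | 1.0 | s | mean surface dwell of a bound tip |
| `kappa` | 2.5 | – | anchor-fan concentration (no measured value exists; the default is the value used throughout the simulated validation studies) |
| `k_spawn` | 5.0 | 1/s | pilus creation rate (validation value; single-cell estimates vary widely) |
| `k_resample` | 1.0 | 1/s | chain shape refresh rate |
| `v_ret`, `v_ext` | 0.09, 0.28 | µm/s | loaded retraction / extension speeds |
| `k_ext_off`, `k_ret_off` | 1/1.6, 1/9.1 | 1/s | motor unbinding rates |
| `k_ext_on`, `k_ret_on` | 1/2.4, 1/0.40 | 1/s | motor binding rates (free pili) |
| `L_p` | 5 | µm | pilus persistence length |
| `E` | 2000 | pN/µm | elastic modulus of the TFP machine |
| `f_stall` | 100 | pN | retraction stall force |
| `epsilon` | 50 | pN·µm | pole–surface well depth (crawling) |

Two documented ambiguities are resolved as follows.  The motor-rate
tables in the source literature list $1/k_\mathrm{ext,on}$ = 2.4 s while
a later passage quotes 0.4 s (the retraction-motor value); the tabulated
2.4 s is used.  The sensitivity bounds for $v_\mathrm{ret}$ (2.5–250)
are interpreted in nm/s — the only reading that brackets the measured
0.09 µm/s — and every parameter box row carries an explicit unit tag.

## Sensitivity analysis and inference

`run_sensitivity()` estimates Sobol total-effect indices of the four
statistics over an 11-parameter box with the Saltelli design
($n_\mathrm{base}(d+2)$ rows; the blocks come from a randomised Halton
sequence, chosen because no Sobol'-sequence generator is available among
the package's dependencies) and the Jansen estimator, clipped to
$[0,1]$, with bootstrap confidence intervals.  At the full published
scale ($n_\mathrm{base}$ = 2048, i.e. 26 624 trajectories of 2000 s)
the run takes hours; the package's tests use $n_\mathrm{base}$ = 128
with 300 s trajectories, which preserves the rank structure of the
indices (ranks are far more stable than values).

At desk scale the per-row trajectory length, not the design size, is the
binding constraint: 100 s rows leave a third of the box immotile and the
activity statistic heavy-tailed, which saturates the Jansen estimator.
The index ranking for the deviation-angle variance (dominated by the
anchor concentration) survives this; the activity ranking and the
absolute "weak parameter" levels require full-length rows.  For users
`run_sensitivity()` offers an optional rank transformation of the
outputs, a standard robustification for heavy-tailed responses.

`rejection_abc()` implements plain rejection ABC over
$(\tau_\mathrm{dwell}, \kappa, v_\mathrm{ret}, k_\mathrm{spawn})$ with
the uniform prior box, standardised Euclidean distance, and
Epanechnikov weights of width equal to the acceptance threshold.
Posterior marginals are weighted Gaussian KDEs with least-squares
cross-validated bandwidths (Silverman fallback); the mode is reported as
the maximum-likelihood estimate and the central 90% mass as the
interval — central rather than highest-density, for determinism.  The
per-sample budget follows the validation protocol (up to 10 trajectories,
stopping at 1000 pooled linear steps); the test suite scales this to
$n$ = 300 samples, 200 s trajectories and 80 pooled steps, keeping the
acceptance fraction at about 0.5%.  Raw experimental tracks for the
published inferences are not distributed, so the pipeline accepts a
four-number reference-statistics file and is validated on simulated
references, where the generating parameters are known.

## What the synthetic fixtures do and do not emulate

`make_fixtures()` produces 10 fps, µm-scale leading/trailing-pole tables
with isotropic Gaussian localisation noise: straight tracks (known
speed), persistent-random-walk tracks generated at the step level (known
$\hat q$, $\hat a$), and simulator-backed crawler/walker tracks.  They
emulate the *format* and noise scale of tracking output, not its
biology: there is no segmentation error, no wavelet smoothing, no
population heterogeneity, and no flagellar or division behaviour, so
passing fixture-based tests demonstrates correctness of the analysis
chain, not fidelity to any particular experiment.

## Numerical choices

Rigid-body relaxation uses damped Newton steps on preconditioned
coordinates (rotations scaled by $l/2$), a central-difference Hessian of
the analytic gradient, Levenberg damping, a 0.2 µm trust region, and —
near the minimum, where energy differences fall below floating-point
resolution — acceptance on gradient decrease, which lets the gradient
norm converge to tolerances ($10^{-8}$–$10^{-5}$ pN) that energy
comparisons alone cannot certify.  Stall checks use the current tension;
a bound pilus one step from zero dissolves when it retracts.  Frames are
recorded by last-state sampling (the state is piecewise constant between
events).  Inside the engine, worm-like chains are drawn with tangent
steps coarsened to at most $\min(L_p/25,\,10\delta)$, laying
$\delta$-spaced nodes along straight sub-blocks — exact aggregation of
the harmonic bending walk, an order of magnitude cheaper on long
chains.  Chains whose anchor sits higher than their contour length
cannot reach the surface, so their (unobservable) shapes are not
refreshed.  The quadratic surface well has a force discontinuity at its
outer edge; it is irrelevant in practice because crawling poses sit at
the well floor.  Body roll about the long axis is a free (gauge-like)
mode for the surface potential but moves anchors physically and is kept.

## Known limitations

* The absolute scale of the well depth $\varepsilon$ is not comparable
  to published transition curves — only the direction of the
  transition-rate trends (with $\varepsilon$, $\kappa$ and
  $k_\mathrm{spawn}$) is, because the functional form of the adhesion
  potential is a design choice and published units for $\varepsilon$ are
  unstated.  With the quadratic well of width 0.05 µm, crawling
  destabilises below $\varepsilon \approx 0.5$ pN·µm.
* At the validation parameter set the simulator reproduces the
  deviation-angle variance and persistence of the reference statistics
  closely, while the pooled mean speed runs high and the activity low
  (see the acceptance tests); the residual gap sits in the duty cycle of
  drag versus pause phases, which depends on relaxation-scheme details
  that are not published.
* Pili do not interact with each other, cannot push, bind only at their
  tips, and detach independently of tension; Brownian motion, explicit
  friction, cell growth and cell–cell interactions are out of scope.

## Problem sizes used by the packaged studies

The acceptance script pools six 2000 s crawling trajectories; the test
suite uses five.  The ABC validation uses 300 samples with two
acceptances; the sensitivity study uses $n_\mathrm{base}$ = 128 (1664
trajectories of 100 s); transition-rate checks use 10–20 replicates of
150–200 s.  The simulated-validation, transition and contact-fraction
studies are stable across seeds at these sizes; the limits of the
sensitivity study at short row length are discussed above.

## A worked example

```{r example, eval = FALSE}
params <- sim_params(mode = "crawling", tau_dwell = 2.0, kappa = 2.5,
                     v_ret = 0.09, k_spawn = 5.0)
sim <- simulate_twitching(params, duration = 2000, seed = 1)
steps <- linearise(sim, delta_step = 0.12)
summary_stats(steps)
tfp_diagnostics(sim)
```
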