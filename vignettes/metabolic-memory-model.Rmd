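---
title: "Modeling glucose-driven oxidative stress and metabolic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glucose-driven oxidative stress and metabolic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosmm)
```

## The model

`rosmm` implements a semi-mechanistic model of oxidative stress in
endothelial cells exposed to high glucose. Three coupled state variables
evolve in time (hours):

* **ROS** — a normalized "ROS production potential", expressed as fold of
  the normoglycemic control. It is a slow proxy for measured reactive
  oxygen species, not the fast radical concentration itself: the species
  turn over in seconds, but the production machinery that assays pick up
  integrates over hours.
* **MM** — metabolic memory: persistent, ROS-driven cell alterations
  (mitochondrial and epigenetic damage) that keep ROS production elevated
  after glucose has been normalized.
* **AD** — a lumped cellular adaptation (antioxidant-response programs)
  triggered by glucose excess, which inhibits ROS synthesis through a
  Hill-type negative feedback.

With the positive-part excess functions
`GLU_excess = max(GLU - GLU_basal, 0)` and
`ROS_excess = max(ROS - ROS_basal, 0)`, the dynamics are

$$
\begin{aligned}
dMM/dt &= ktu_{MM}\,(a_{rosmm}\,ROS_{excess} - MM)\\
dAD/dt &= ktu_{AD}\,(GLU_{excess} - AD)\\
dROS/dt &= ktu_{ROS}\,\bigl(1 + (a_{gluros}\,GLU_{excess} + MM)\,AD_{ef} - ROS\bigr)\\
AD_{ef} &= 1 - \frac{F\!max_{ad}\,AD^{Nh_{ad}}}{AD^{Nh_{ad}} + EC50_{ad}^{Nh_{ad}}}
\end{aligned}
$$

ROS excess feeds MM (positive feedback, gain `a_rosmm`); glucose excess
feeds both ROS directly (gain `a_gluros`) and the protective AD pool,
whose effect `AD_ef` scales the whole ROS drive down by at most
`Fmax_ad`. The two feedback loops of opposite sign are what generate the
characteristic phenomenology: bell-shaped ROS time courses under constant
high glucose (adaptation eventually wins), persistent ROS elevation after
normalization (memory), and worse outcomes under oscillating than under
constant glucose (oscillations keep resetting the adaptation below its
activation threshold while memory keeps accruing).

`ros_params()` carries the calibrated population values. `GLU_basal = 9`
mM is the highest glucose level that drives nothing; `ROS_basal = 1` is
the control-normalized baseline; `ktu_MM = 0.007`/h derives from a 4-day
mitochondrial protein half-life (`log(2)/96` rounded as printed);
`ktu_ROS` (alias `kel_ROS`) `= 0.0316`/h, `ktu_AD = 0.00714`/h,
`a_gluros = 0.364`/mM, `EC50_ad = 6.142`, `Fmax_ad = 0.8`, `Nh_ad = 5`,
`a_rosmm = 1`.

The memory gain `a_rosmm` deserves emphasis. For the post-normalization
steady state `ROS_ss` one finds `a_rosmm = (ROS_ss - 1)/(ROS_ss -
ROS_basal)` (`a_rosmm_from_target()`), which with `ROS_basal = 1` equals
1 for *every* admissible target: at `a_rosmm = 1` the normoglycemic
system has a whole one-parameter family of equilibria `(ROS, MM, AD) =
(1 + M, M, 0)`, and whatever memory was accumulated during exposure is
held indefinitely. `a_rosmm < 1` makes the family collapse to `(1, 0,
0)` (gradual recovery, the regime plausible in vivo where ROS is also
cleared by perfusion), and `a_rosmm > 1` is the runaway-amplification
regime. This knife-edge structure is why the long-horizon sensitivity
analysis is dominated by `a_rosmm`.

### Initial conditions

The healthy state fixes `ROS = 1` by the normalization convention.
`MM(0) = AD(0) = 0` is the package's reading of "healthy": a state that
has stimulated neither memory nor adaptation. `healthy_state()` returns
this triple; any other non-negative initial state may be supplied.

## Protocols and integration

Exposure designs are piecewise driving functions (`glucose_protocol()`):
constant segments (CG, NG) and square-wave segments (OG) that alternate
`high`/`low` every `half_period` hours. The square wave starts in its
HIGH phase — cells are moved *into* high glucose at experiment start —
and is right-continuous at flips; published oscillating-exposure
designs do not state the starting phase, so it is configurable by
building an explicit segment list with swapped `low`/`high` boundaries. Times are hours everywhere internally; config
files and the shorthand syntax (`"og:5-20mM:24h:14d+ng:5mM:70d"`) accept
days and convert on read.

The positive-part kinks and the square-wave jumps are deliberately *not*
smoothed: `integrate(protocol, ...)` reduces every protocol to
constant-glucose pieces and restarts the solver at each discontinuity
(`switch_times()`), so no step ever straddles a jump. Two engines solve
the identical right-hand side: `deSolve::lsoda` (the user-facing
default) and a compiled adaptive Dormand-Prince 5(4) (`engine =
"dp45"`) used in likelihood loops, where tens of thousands of short
solves make per-call overhead dominant. Both run at `rtol = 1e-8`,
`atol = 1e-10` by default; the test suite pins them against each other
and against the closed-form adaptation relaxation `AD(t) = GE + (AD0 -
GE) e^{-ktu_{AD} t}`, which is exact on any constant-glucose segment.

### Post-normalization steady states

`post_ng_steady_state()` extends the terminal NG segment until the
maximal component-wise change over a trailing 24-h window, relative with
a unit floor on the denominator, drops below `1e-6`, with a hard cap of
one extra simulated year. The unit floor matters: AD decays
exponentially forever on a 140-h time constant, so a purely relative
criterion would never trigger; with the floor, convergence is declared
once AD is numerically gone (~`1e-6`), which for the default parameters
happens around 12 simulated weeks. Non-convergence at the cap is a
warning and a `converged = FALSE` flag — distinct from a solver failure,
which is an error.

## The population layer

The calibration setting is a pooled collection of small in vitro
studies, with large systematic differences between laboratories.
`population_model()` describes it as a nonlinear mixed-effects model:
per-study parameters

$$ktu_{ROS,j} = ktu_{ROS}\,e^{\eta_{1j}}, \qquad
a_{gluros,j} = a_{gluros}\,e^{\eta_{2j}}, \qquad
\eta_{ij} \sim N(0, \Omega_i^2)$$

and proportional residual error `y = f (1 + b e)`, `e ~ N(0,1)`,
resampled in the generator on the (practically impossible at `b ≈ 0.1`)
event `y ≤ 0`. Two conventions are resolved explicitly rather than
silently: the random effects are taken *lognormal* (multiplicative
`exp(eta)`, the standard convention of NLME estimation software; the
source material does not state the distribution), and the printed
inter-study variability values `Ω = 1.145, 0.936` are read as *standard
deviations* of the log-scale effects, their printed rate/gain units
treated as a table artifact. `omega_scale = "var"` switches to the
variance reading if wanted.

### Likelihood and fitting

`loglik_population()` integrates the two random effects out per study:
Laplace approximation at the posterior mode of `eta` (`nodes = 1`), or
adaptive Gauss-Hermite quadrature on a mode-centred, curvature-scaled
tensor grid (`nodes > 1`). With `Ω` above 1 and only a handful of
observations per study the integrand is distinctly heavier-tailed than
Gaussian, so low-node AGH converges slowly; the suite verifies that the
value is stable to below 0.01 under node doubling at ~20 nodes per
dimension. With both omegas at zero the marginal collapses exactly to
the fixed-effects product density, which is tested against a
hand-computed closed form.

`ros_fit()` maximizes the marginal likelihood over the free fixed
effects `{ktu_ROS, ktu_AD, a_gluros, EC50_ad}` (the remaining structural
parameters stay at their fixed values, mirroring the calibration
layout), the two omegas and `b`, all log-transformed with box
constraints. Two numerical choices proved load-bearing:

* the outer objective must be a *deterministic* function of the
  parameters, so the inner mode search always starts from `eta = 0`
  rather than warm-starting from the previous evaluation — warm starts
  make the objective history-dependent and corrupt finite-difference
  gradients;
* the quasi-Newton first stage (`nlminb`) is followed by a
  derivative-free Nelder-Mead polish: the Laplace objective carries
  small-scale jaggedness where per-study posterior modes switch basins,
  which can stall gradient-based search a few log-units short of the
  optimum, and the simplex stage walks through it reliably.

Marginal-likelihood maximization is the contract; a stochastic-EM
(SAEM) implementation would be an equally admissible route to the same
estimates, and acceptance of the layer is by parameter recovery on
synthetic data, not by algorithm identity. `restarts > 0` adds seeded
random multistarts (log-scale Gaussian jitter, SD 0.5), mirroring the
many-random-inits practice used to argue identifiability. RSEs come
from the observed information at the optimum (`RSE% ≈ 100·SE(log
parameter)`), with a seeded nonparametric bootstrap over studies
(`rse_bootstrap()`) as the fallback when the Hessian is ill-conditioned.
Omega estimates within numerical reach of the lower box bound are
flagged as boundary estimates. `AIC = 2k - 2 logLik` with `k` the number
of free parameters.

`vpc()` provides the simulation-based diagnostic: percentile bands of
simulated observations (random effects plus residual error) under a
design, to be compared with data or with the deterministic population
prediction.

## The synthetic-data generator

The real pooled calibration set (43 points from 9 studies) was digitized
from published figures and is not redistributable; its per-study designs
are not recoverable. `default_designs()` therefore ships an explicitly
*synthetic* stand-in, frozen in
`extdata/calibration_designs_synthetic.json`: 9 designs, 43 observation
slots, spanning what the pooled setting reports — CG at 15/20/25 mM from
6 h to 14 d, OG 5↔20 and 5↔25 mM with the 24-h half-period, and
post-normalization sampling ≥ 7 days after return to 5 mM, one value per
(study, time point) since replicate structure is likewise unknown.
`generate_studies()` draws study parameters, integrates, samples the
error model; the generating per-study parameters are emitted in a
separate truth table so that recovery experiments cannot leak them
through the fitting interface.

What passing recovery tests on these data does show: the estimation
layer recovers the parameters of the data-generating process it assumes,
at the design sizes used. What it does not show: robustness to
assay-specific offsets (fluorescence vs 8-OHdG readouts), outlier
studies, replicate correlation, or model misspecification — none of
which the generator emulates.

## Sensitivity analysis

`tornado()` implements the local one-at-a-time analysis: each structural
parameter is varied multiplicatively in uniform steps to ±50% (default
five per side), the reference protocol — CG 20 mM or OG 5↔20 mM for two
weeks, then NG through week 12 — is re-simulated, and ROS is compared at
24 h, 2 weeks and 12 weeks. The ranking metric is the larger absolute
relative delta of the two ±50% endpoints, the usual tornado-plot
convention. Perturbations act on the fixed effects with random effects
off, since single predictions are being compared. The default
perturbable set is every structural parameter except `ROS_basal`, which
defines the observation scale itself; `Fmax_ad` at +50% would leave the
admissible region (`1.2 > 1`) and is clamped to 0.999 with a warning.
With the calibrated values the early (24 h) response ranks `a_gluros`
and `ktu_ROS` on top — though `GLU_basal` trails `ktu_ROS` only by a
thin margin, so that third place is not a robust separation — and the
12-week point is dominated by `a_rosmm` under both protocols,
reflecting the equilibrium-family structure described above.

## Problem sizes and numerical defaults

Deterministic checks (fixed-point invariance, oracle equivalence,
bell-shape and OG/CG orderings, steady-state sweeps) run at the
protocols' natural sizes. Stochastic checks use: 10^4 draws for sampler
and residual calibration; 200 single-design studies for the generator's
distributional check; a 50-study, 237-observation recovery fit (the 9
default designs recycled) with Laplace likelihood and one multistart;
and 5 replicate 12-study fits for the precision (RSE vs empirical SD)
comparison. Solver tolerances are `rtol 1e-8` / `atol 1e-10`
throughout; steady-state detection uses the trailing-24-h criterion at
`1e-6` with a 1-year cap; quadrature-stability checks use 21 vs 42
nodes per dimension.

## Known limitations

* The ROS variable is a production-potential proxy; sub-hour dynamics of
  actual radical species are out of scope by construction.
* Continuous glucose inputs (sinusoids, measured CGM traces) are not
  supported in this version; the protocol interface is piecewise
  constant by design and leaves room for them.
* The oscillation-amplitude sweep of the published contour analysis is
  ambiguous about which end of the wave is held fixed;
  `sweep_og(encoding = )` exposes both readings ("fixed_max",
  "fixed_min") rather than guessing.
* With `Ω ≈ 1` and ≤ 5 observations per study, the Laplace approximation
  sits measurably below the converged quadrature value; fixed-effect
  point estimates are affected far less than the omegas, but precision
  statements about the omegas at small study counts should not be
  over-read.
* Model-structure search (alternative error models, structural variants)
  is exposed as configuration, not automated; only the implemented
  model's AIC is reported.
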