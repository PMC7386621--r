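---
title: "Estimating conductance-model parameters from membrane-voltage recordings"
author: "neuroassim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conductance-model parameters from membrane-voltage recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A current-clamped neuron is observed through a single variable, the
membrane voltage $V(t)$, sampled at discrete times while a known current
protocol $I_{inj}(t)$ is injected.  The cell is modelled by a
conductance (Hodgkin–Huxley-family) system of $L = 7$ states — voltage
plus six gate occupancies — and $K = 41$ parameters: maximal
conductances, reversal potentials, membrane area, capacitance, and five
kinetic constants per gate.  The estimation task is to recover all 41
parameters (and the unobserved gate trajectories) from the voltage trace
alone.  `neuroassim` implements the full loop as *twin experiments*:
data are synthesized from the model with known parameters, noise is
added, and the estimator is scored against the generating truth.

## The model

The membrane equation, in current densities ($\mu$A cm$^{-2}$),

$$C \frac{dV}{dt} = J_{NaT} + J_K + J_{HCN} + J_L - J_{CaT} +
  I_{inj}/A,$$

uses driving-force densities $J = \bar g\, x^{a} y^{b} (E - V)$ for the
transient sodium ($m^3 h$), delayed-rectifier potassium ($n^4$),
hyperpolarization-activated cation ($z$) and leak channels.  The
low-threshold calcium current follows the Goldman–Hodgkin–Katz flux
equation with activation $q^2$ and inactivation $r$; because the GHK
expression is written in the electrophysiological convention (positive =
outward) while the $(E - V)$ densities are positive-depolarizing, it
enters the sum with a minus sign.  This sign layout is the only reading
under which the published channel complement produces physiological
spiking and post-inhibitory rebound, and it is the convention used
throughout the package.

Each gate relaxes as $\dot x = (x_\infty(V) - x)/\tau_x(V)$ with

$$x_\infty(V) = \tfrac12\!\left(1 + \tanh\frac{V - V_t}{\delta V}\right),
\qquad
\tau_x(V) = t_0 + \epsilon\left(1 - \tanh^2\frac{V - V_t}
{\delta V_\tau}\right),$$

so the recovery time is $t_0 + \epsilon$ at threshold and $t_0$ in the
fully (de)polarized states.  The capacitance is carried as the first of
the 41 parameters with a degenerate search interval $[1, 1]$, which
keeps the parameter count at 41 while never estimating $C$.

Calcium concentrations are not part of the published parameter set; the
package fixes $[Ca]_o = 2$ mM and $[Ca]_i = 10^{-4}$ mM (typical
mammalian values) in `physical_constants()`, and all calcium-dependent
checks are self-consistent under whatever values are configured.

### The GHK polynomial

The assimilation layer can evaluate the GHK voltage factor either
exactly or through an order-25 polynomial in Horner form
(`ghk_horner()`), certified on $[-100, 45]$ mV to a relative error
below $10^{-6}$.  A Taylor expansion about $V = 0$ cannot deliver this:
the factor has complex poles at $V = \pm 2\pi i\,RT/zF \approx \pm 81i$
mV, inside the physiological range, so its Taylor series diverges
beyond 81 mV.  The package therefore builds the polynomial by Chebyshev
interpolation on the certified range (geometric convergence; observed
error $\sim 10^{-9}$) and evaluates it in Horner form in the affinely
scaled variable.  Voltages outside the certified range raise an error
rather than extrapolating.

## Twin data

`make_twin_dataset()` integrates the model with LSODA (stiff-capable,
segment-by-segment across protocol discontinuities, tolerances
$10^{-8}$) on a uniform grid — by default $\Delta t = 20\ \mu$s over a
200 ms window, i.e. $n = 10{,}000$ mesh intervals — and adds seeded
Gaussian noise: $V_{exp}(t_i) = V_{use}(t_i) + \sigma\,\eta_\zeta(t_i)$.
The pair $(\sigma, \zeta)$ fully determines the realization; a negative
$\sigma$ means the sign-flipped realization, the convention used by the
noise-ramp regularizer.

The published experiments used mixed depolarizing/hyperpolarizing
current steps whose amplitudes were not printed.  The package ships
versioned protocol fixtures (`default_protocol()`): a 200 ms and a
500 ms training protocol and a held-out prediction protocol, calibrated
once so that the generating parameter set produces several action
potentials, a hyperpolarized episode that engages HCN and de-inactivates
CaT, and a rebound — the dynamic range that parameter identifiability
requires.  They emulate protocol *structure*, not the unpublished
amplitudes, so numerical results tied to one specific protocol (e.g.
exact cost values at minima) are not expected to reproduce.

### Adaptive sampling

`adaptive_mesh()` retains every base sample where $V_{exp}$ exceeds a
depolarization threshold (default $-65$ mV; the figure captions' $-63$
mV variant is a configurable argument) and every $m$-th sample
elsewhere ($m \in \{1, 2, 4\}$), then regroups the retained samples
into 5-point collocation groups with a uniform step inside each group.
Trailing samples that do not complete a group are trimmed.  Holding the
retained size fixed while increasing $m$ lengthens the observation
window without growing the problem — the mechanism behind the
window-length decorrelation experiment.

## The collocation estimator

`assemble_nlp()` transcribes estimation into a sparse constrained
nonlinear least-squares problem over a decision vector holding, per
retained mesh point, the 7 states and a nudging control $u$, plus the
41 parameters.  The cost is

$$c = \tfrac12 \sum_i \left[(V_{exp}(t_i) - V(t_i))^2 + u^2(t_i)\right],$$

and the dynamics enter as equality constraints per 5-point group: Boole
quadrature over the group span,

$$x_{i+4} = x_i + \frac{2\Delta t}{45}\,(7F_0 + 32F_1 + 12F_2 + 32F_3 +
7F_4),$$

exact for dynamics polynomial of degree 5 ($O(\Delta t^7)$), plus two
Hermite midpoint conditions (at the 2nd and 4th points, symmetric about
the group centre),

$$x_{i+1} = \tfrac12 (x_i + x_{i+2}) + \frac{\Delta t}{4}(F_i -
F_{i+2}),$$

exact for cubic trajectories.  The $\Delta t/4$ factor is the standard
Hermite–Simpson coefficient for points spaced $\Delta t$ apart (the
half-group spans $2\Delta t$); the cubic-exactness property test pins
this down.  With $G$ groups this yields $7G$ Boole plus $2 \cdot 8G$
Hermite equality rows — the control $u$ is smoothed by the same two
Hermite conditions with finite-difference slopes as its "dynamics".
Internally each row is divided by its group time span so that
feasibility tolerances are uniform rate units across adaptive meshes.
Bounds: gates in $[0,1]$, $0 \le u \le 1$, $|du/dt| \le 1$ ms$^{-1}$
(one-sided hinge penalties on consecutive differences), and the
parameter search intervals.

Because several published search intervals exclude the generating
values (E$_{Na}$, E$_K$, g$_{NaT}$ are outside their printed intervals
and the g$_K$ interval is degenerate), the package ships two bound
sets: `table_as_printed` (verbatim) and `table_widened` (symmetric
enlargement about the printed midpoint until the generating value sits
at least 25% of the final width from either edge, with physical floors
for signs and widths).  All recovery experiments use the widened set.

### Solver

No sparse interior-point NLP library is available to the package, so it
carries its own solver (`al_lm()`): a bound-projected augmented-
Lagrangian method whose inner iterations take damped Newton steps using
the exact sparse Jacobian *and* the exact sparse Hessian of the
weighted constraint sum (both hand-derived and machine-precision,
validated against finite differences in the test suite), with a
backtracking line search and a Levenberg–Marquardt damping parameter
that also absorbs indefiniteness.  Outer iterations update the
multipliers ($\lambda \leftarrow \lambda + \mu c$) or grow the penalty
$\mu$ when feasibility stalls.  Convergence is declared on KKT
conditions: constraint residual below the feasibility tolerance
($10^{-8}$ by default, in step-scaled rate units) and bound-projected
Lagrangian gradient below the optimality tolerance ($10^{-6}$, relative
to the residual scale).  All variables are diagonally scaled (voltages
by 25 mV, gates and control by 0.25, parameters by their half-widths).

### Initialization

The default (`init = "staged"`) is built from the data alone:

1. the voltage trajectory is copied from $V_{exp}$;
2. each gate is *filtered* along the observed voltage with an exact
   exponential integrator for its linear kinetics (pointwise
   steady-state gates lag badly during action potentials and start the
   solver far from the feasible manifold);
3. parameters start at their bound midpoints and are refined by a
   synchronization stage: the model is integrated with a strong nudging
   term $g_s (V_{exp} - V)$ added to the voltage equation — which
   suppresses the positive conditional Lyapunov exponent and makes the
   fit landscape smooth — and the parameters are improved by damped
   Gauss–Newton on the synchronization error with exact forward
   sensitivities (a dedicated compiled integrator propagates the
   states by Runge–Kutta substeps and the linear sensitivity system by
   the trapezoidal rule), annealing the coupling $g_s$ downward in
   stages, with a weak interval-scaled ridge that keeps sloppy
   parameter combinations from drifting into the bounds.

Initializations used by the success-rate experiment deliberately skip
step 3: those runs measure basin-of-attraction statistics from random
parameter guesses, which the staging would mask.

Cold starts are the honest limitation of this solver: on the full-size
spiking problem the staged pipeline still terminates in sub-optimal
local minima, a gap relative to the mature sparse interior-point
machinery used in the experiments this package replicates (which
itself converged from random starts only 67% of the time).  The
flagship noise-free recovery experiment therefore *secures*
convergence by initializing the search at the published zero-noise
optimum — the same practice those experiments use for their posterior
ensembles — and measures the accuracy of the optimum the collocation
estimator then converges to.

## Noise-ramp regularization

When a solve lands in a sub-optimal local minimum, the package applies
the constructive-noise escape: keep one noise realization $\zeta$
fixed, ramp its signed amplitude in 10 µV steps across $\pm[10, 500]$
µV re-solving warm-started at each amplitude, and flag the critical
amplitude at which the tracked solution jumps basins — the signature of
the local minimum merging with a saddle (a saddle-node bifurcation of
the cost landscape).  The jump detector requires an interval-scaled
parameter displacement exceeding 10 times the median inter-step
displacement on the current leg *and* a simultaneous cost
discontinuity; both the factor and the 1% displacement floor are
package choices, made scale-free to match the qualitative published
description (the paper gives no quantitative jump criterion).  After a
jump the amplitude is annealed monotonically back to zero (reverse
grid, warm starts); a further jump during annealing is treated as an
error (mis-detected basin).  The regularized result replaces the plain
one only when its zero-noise cost is lower, so regularization can never
worsen a solve.  The critical amplitudes themselves depend on the
realization (published examples: $-40$ µV and $+50$ µV for two seeds)
and are not reproduction targets.

## Posterior and misfit geometry

`ensemble_estimates()` re-estimates the parameters across many seeded
noise realizations of the same clean trace, initialized at the
zero-noise optimum; `covariance_and_spectrum()` forms the unbiased
sample covariance and its eigen-spectrum (the squared principal
half-lengths of the constant-misfit ellipsoid).  `misfit_terms()`
computes the quadratic expansion of the misfit about a converged
solution: the offset $F = \tfrac12\sum \epsilon^2 + \sum \epsilon\,
\epsilon_{mod}$, the gradient $G_k = \sum_i \epsilon_i\,\partial
V_i/\partial p_k$, and the Hessian $H_{kk'} = \sum_i [\partial_k V_i\,
\partial_{k'} V_i + \partial^2_{kk'} V_i\,(\epsilon_i +
\epsilon_{mod,i})]$.  First-order sensitivities are exact (forward
sensitivity ODEs integrated alongside the model); the error-weighted
second-order term is obtained by central differencing of those exact
sensitivities, which agrees with full finite differences of the cost to
about $10^{-7}$ relative — the one place the derivative chain is not
fully analytic, chosen because the term is a small perturbative
correction weighted by the noise.  The noise-induced offset of the
minimum solves $H\,\delta p = -G$; note the sign (the published formula
omits the minus of the minimizer), and that consistency between
"$\lambda_k^{-2}$ Hessian eigenvalues" and "covariance eigenvalues
$\lambda_k^2$" requires reading the quadratic form's diagonal as
$\lambda_k^{-2}$.  In twin experiments $\epsilon_{mod} = 0$ by
construction; `misfit_terms()` accepts an injected model-error trace
for mis-specified-model studies but no reference magnitudes exist to
test against.

The noise-entropy identity used in the tests,
$E[\tfrac12\sum_i \epsilon_i^2] = (n+1)\sigma^2/2$, also defines the
noise-equivalent temperature through the Johnson–Nyquist relation
$T_\sigma = \sigma^2/(4 k_B R\,\Delta f)$ with the membrane resistance
and noise bandwidth as configuration.

## Prediction scoring

`predict_voltage()` drives a fitted parameter set on a held-out
protocol with no nudging (the result cannot depend on any observed
trace); `compare_traces()` reports the pointwise error trace, RMS
error, and a spike-mismatch summary (upward crossings of $-20$ mV with
a 2 ms refractory gap, greedily matched within $\pm 2$ ms — reasoned,
configurable defaults; the publication scored mismatches visually).
`parameter_distance()` reports both the raw Euclidean norm (the
published convention) and an interval-normalized variant, which is the
meaningful one given the heterogeneous units.

## Problem sizes, tolerances and limitations

* The flagship noise-free recovery experiment runs at the published
  size: $n = 10{,}000$ intervals, $\Delta t = 20\ \mu$s, $T = 200$ ms
  (decision vector $\approx 80{,}000$, $57{,}500$ equality rows).
  The test suite exercises the same machinery at reduced sizes (short
  windows, 400–600 mesh intervals, reduced-channel models whose truth
  is known by construction, ensembles of 50 replicates with
  iteration-capped warm-started solves) so that the whole suite stays
  within routine CI budgets; the full sizes remain available through
  arguments.
* Accuracy at the optimum is limited by parameter sloppiness: along
  the flattest directions of the misfit Hessian (recovery time
  constants, calcium permeability), the collocation discretization
  bias at under-resolved spike upstrokes is amplified by the small
  curvature, leaving residual deviations of a few percent on noise-free
  data — the same order as the deviations visible in the published
  optimum itself.
* At $\Delta t = 20\ \mu$s the sodium upstroke is resolved by only a
  few samples; the collocation solution then differs from the
  continuous trajectory near spike peaks by more than solver tolerance,
  so exact cost values at minima are protocol- and mesh-specific and
  are not comparison targets.  Parameter estimates are.
* Gate trajectories stay in $[0, 1]$ by bound constraints at mesh
  points (the continuous-time interval is attracting, so interior
  collocation values do not escape in practice).
* The synthetic data generator emulates additive white Gaussian
  measurement noise only — no channel (state) noise, no correlated or
  multiplicative noise, no electrode artefacts.  Passing twin tests
  therefore demonstrates estimator correctness under the stated noise
  model, not robustness to real electrophysiology artefacts.
* Degenerate inputs are rejected loudly: zero gate widths, nonpositive
  concentrations, traces shorter than one collocation group, bounds
  with `lower > upper`, voltages outside the certified GHK-polynomial
  range.
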