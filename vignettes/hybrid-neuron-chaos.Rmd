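---
title: "Routes to chaos in a hybrid spiking neuron: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Routes to chaos in a hybrid spiking neuron: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridspike)
```

## The model and its assumptions

`hybridspike` analyses a planar hybrid neuron: the membrane potential $v$
and recovery variable $u$ follow the continuous flow

$$\dot v = v(a - v)(v - 1) - u + I, \qquad
  \dot u = \alpha\left(\frac{1}{1 + e^{-(v-\beta)/\varepsilon}} - u\right),$$

and a discontinuous after-spike rule is applied whenever $v$ reaches the
spike-detection threshold $v_{peak}$:

$$v \to v_r, \qquad u \to u + d.$$

The cubic $v$-nullcline is the classic excitable-membrane shape; replacing
the usual linear recovery equation by a *sigmoidal* $u$-nullcline lets the
resting state lose stability through **either** a saddle-node or a Hopf
bifurcation depending on the sigmoid midpoint $\beta$ — both transitions
occur in real neurons. All quantities are dimensionless; no unit
conversions are performed anywhere.

Two modelling assumptions matter for everything below:

* the continuous flow is planar and bounded, so **without the reset it
  cannot be chaotic** (a Poincaré–Bendixson consequence, and a test the
  package's Lyapunov machinery must reproduce numerically);
* the reset is instantaneous and state-dependent only through $u$, so the
  hybrid system is a piecewise-smooth flow whose variational dynamics need
  a correction — the saltation matrix — at every jump.

### Parameters

| name | meaning | default |
|------|---------|---------|
| `a` | cubic shape of the v-nullcline | 0.1 |
| `alpha` | recovery rate (1/time) | 0.1 |
| `beta` | sigmoid midpoint | 0.5 (`region1`) / 0.3 (`region2`) |
| `eps` | sigmoid slope width | 0.05 |
| `I` | applied current | 0.004 / 0.04 |
| `v_peak` | spike threshold | 0.4 / 0.225 |
| `v_r` | reset voltage (`v_r < v_peak`) | 0.33 / 0.14 |
| `d` | recovery increment (`d >= 0`) | 0.01 |

`v_peak` is chosen at the maximum of $v$ along the continuous model's
limit cycle, so that letting $v_r \to v_{peak}$ and $d \to 0$ recovers the
continuous dynamics — the *continuity limit* used repeatedly in the test
suite. The preset reset values place each region inside its chaotic
window.

## Numerical integration

Continuous segments are integrated with an explicit adaptive
Dormand–Prince 5(4) pair implemented in compiled code. The flow is
non-stiff (every Jacobian entry is $O(1)$ at the default parameters), so
an explicit pair with tight tolerances is both faster and simpler than an
implicit scheme. Design choices:

* default `rtol = atol = 1e-12`; going far below that buys nothing at
  double precision, and halving the tolerances moves the first twenty
  spike times by less than $10^{-6}$ (a test);
* the step is capped (`max_step = 0.02`) so a threshold crossing cannot
  be straddled by a single step — near $v_{peak}$ the flow is slow
  ($\dot v \to 0$ at the cycle's top), which is exactly where crossings
  must not be missed;
* each upward crossing of $v = v_{peak}$ is located by bisection on the
  step, to $|v - v_{peak}| \le 10^{-12}$; spikes fire on **upward**
  crossings only ($\dot v > 0$), and since $v_r < v_{peak}$ a re-trigger
  at the reset instant is impossible;
* a quiescence detector ends a run early (reason `"converged"`) once
  $\|(\dot v, \dot u)\|$ stays below $10^{-12}$ for a sustained window, so
  parameter sweeps over non-spiking cells do not burn the full horizon;
* dense output is stored at a configurable interval (default $10^{-2}$)
  by cubic Hermite interpolation, plus the exact event states.

The integrator is cross-checked in the test suite against
`deSolve::lsodar` (trajectories to $10^{-8}$, and spike times against an
independent root-finding/reset loop).

## Lyapunov spectra with saltation matrices

The perturbation matrix $\Lambda$ evolves by
$\dot\Lambda = J(v,u)\,\Lambda$ along the orbit (six coupled equations,
integrated jointly with the state). At a spike the perturbation is
corrected by the saltation matrix

$$S = \begin{pmatrix} \dot v^+/\dot v^- & 0 \\
 (\dot u^+ - \dot u^-)/\dot v^- & 1\end{pmatrix},$$

with the flows evaluated at the crossing state and at the post-reset
state; $S \to I$ in the continuity limit. Gram–Schmidt renormalisation is
applied every $\tau$ time units and the exponents are the time-averaged
log-norms of the orthogonalised columns.

Choices and rationale:

* **renormalisation interval** $\tau$: the default for
  `lyapunov_spectrum()` is $10^{-3}$ — very conservative, and cheap in
  compiled code. Heatmap sweeps use $\tau = 0.1$: in a planar system a
  column norm changes by at most a factor $e^{0.1\|J\|}$ per interval, so
  orthogonality degrades negligibly while the sweep runs two orders of
  magnitude faster. Both settings give the same exponents to within the
  convergence noise, and $\tau$ is a user-visible argument everywhere.
* **horizons**: the default `total_time = 1e4` with `transient = 1e3`
  stabilises the exponent *signs* and the $\approx 0$ neutral exponent
  well before the horizon; the convergence trace stored in every result
  lets users check this. Heatmaps default to 1500 per cell (300
  transient), which resolves sign classification after the refinement
  pass below.
* **chaos threshold**: a cell is chaotic when $\lambda_1 > 10^{-3}$ —
  above the numerical jitter of a neutral exponent at these horizons, far
  below the genuine positive exponents ($10^{-2}$–$10^{-1}$) seen on
  chaotic attractors here.
* **borderline refinement**: the finite-time estimate of a neutral
  exponent fluctuates at the few-$10^{-3}$ level over short runs, so
  heatmap cells whose first-pass $\lambda_1$ lies within `refine_band`
  ($5\times10^{-3}$) of the threshold are re-run 8 times longer. This
  removes essentially all misclassification at a fraction of the cost of
  running every cell long.
* **warm starts**: each heatmap cell starts from the final state of its
  left neighbour (first cell of a row from $(v_r, 0)$), keeping the sweep
  on the attractor branch.
* at a non-spiking equilibrium the exponents equal the real parts of the
  Jacobian eigenvalues — used as an oracle test.

## Poincaré maps and characteristic multipliers

The section $\Psi$ is the set of upward crossings of $v = v_{peak}$; map
samples are the recovery values $u_i$ there, and the post-reset values
$u_i + d$ are recorded separately for jump-sign diagnostics. The local
section at which the multiplier is evaluated is taken to coincide with
$\Psi$ itself — the multiplier must be evaluated where the return is
defined.

The multiplier of $\psi^l$ is assembled from the variational monodromy
$\Phi(t_l, t_0)$ (identity at the post-reset start, saltation-corrected at
the $l-1$ interior crossings) as

$$\mu^l = \left(-\dot u/\dot v,\;\; 1\right)\, \Phi(t_l,t_0)
 \begin{pmatrix}0\\1\end{pmatrix},$$

where the projection row is evaluated at the terminal crossing. The row
is the flow-aligned projection onto the section: a variation $\delta x$
arriving at the section at a shifted time contributes
$\delta u - (\dot u/\dot v)\,\delta v$ to the section coordinate. The
package derives this row analytically and verifies it against centred
finite differences of $\psi^l$ (relative error below $10^{-9}$ at a fixed
point; $10^{-3}$ is the acceptance bar across ten sampled orbits); in the
continuity limit the multiplier converges to the continuous cycle's
nontrivial Floquet multiplier computed independently with `deSolve`.

### Periodic orbits and continuation

`find_periodic_orbit()` solves $\psi^l(u) = u$ by damped Newton iteration
with the variational derivative $\mu^l - 1$, with a bisection fallback
when a sign-changing bracket appears. Two tie-breaks matter:

* **shorter-period collapse**: a period-1 orbit is also a fixed point of
  $\psi^2$. By default convergence onto an orbit whose actual period
  divides $l$ is an *error* (`strict_period = TRUE`), never a silent
  substitute. The switch exists because continuing the $\psi^2$ fixed
  point *through* a period-doubling collapse — where the doubled branch
  shrinks onto the period-1 orbit and $\mu^2 \to +1$ — is precisely how
  the lower boundary of the region-2 chaotic window is located.
* **continuation bracket**: `locate_map_bifurcation()` continues the
  orbit while it stays *stable* ($|\mu^l| < 1$) and bisects the stability
  boundary. At a period-doubling the multiplier crosses $-1$
  transversally and the same orbit persists (unstable) beyond; at a
  tangent point the orbit folds, $\mu \to +1$ with square-root steepness
  in the parameter, and beyond the fold Newton either fails or lands on a
  distinct unstable orbit embedded in the chaotic attractor. Treating
  "not found, not the same period, or not stable" uniformly as the far
  side of the bracket handles all three exits robustly; the recorded
  `mu_at_star` is the multiplier at the last located orbit, which near a
  fold can still sit visibly below $+1$ because of the square-root
  approach.

Initial guesses come from the simulated attractor (the last $l$ section
crossings after a transient of a few hundred crossings — chaotic regimes
settle slowly), tried phase by phase.

### What the sweeps found in the two regions

With $d = 0.01$, region 1's period-1 orbit period-doubles at
$v_r \approx 0.290$, period-2 at $\approx 0.318$, period-4 at
$\approx 0.322$, and the chaotic band terminates at a period-5 stability
boundary near $0.388$; the spike-to-burst threshold (first reset landing
on the depolarising side of the v-nullcline) is $\approx 0.308$. In
region 2 the chaotic window is bounded by the $\mu^2 = +1$ point near
$0.138$ below and the period-1 tangent at $\approx 0.141$ above; the
attractor there is near-period-2 chaos, and no stable true period-2 orbit
exists at these parameters — the reason for the `strict_period` design
above. All of these numbers are recomputed by `scripts/acceptance.R` and
asserted in `tests/testthat/test-acceptance.R`.

## Problem sizes

The defaults were chosen as the smallest runs at which each quantity's
convergence plateaus, and the test suite uses deliberately scaled-down
versions of the long-run settings: Lyapunov sign checks at
`total_time = 1e4` (signs stabilise by $\sim 3\times10^3$; doubling the
horizon moves exponents by under $5\times10^{-3}$, a tested invariant),
heatmaps at $20\times20$ cells with 1500 time units per cell plus
refinement, bifurcation continuations with 16–34 scan steps before
bisection to $10^{-5}$ brackets, and 200-crossing transients before any
attractor statistic.

## Known limitations

* No noise, synaptic input, or network coupling: the model is autonomous
  and deterministic, and the package contains no random number generation
  at all.
* Grazing events — crossings with $\dot v^- \to 0$, which occur at the
  edge of the return map's folding structure — make the saltation matrix
  ill-conditioned; the package raises a degenerate-crossing error below
  $|\dot v^-| = 10^{-12}$ rather than silently producing huge entries.
* The equilibrium continuation handles one parameter (I) and one branch;
  two-parameter continuation and normal-form coefficients (sub- vs
  supercritical Hopf classification) are out of scope.
* Fold-structure counting on return-map profiles is left to visual
  inspection of the exported profiles; no automated fold counter is
  provided.
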