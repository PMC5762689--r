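# hybridspike

Bifurcation and chaos analysis for a planar **hybrid spiking neuron
model**: a continuous FitzHugh–Nagumo-type flow with a sigmoidal recovery
nullcline, combined with a discontinuous after-spike resetting rule. The
package is for computational neuroscientists and nonlinear-dynamics
practitioners who want to quantify how a state-dependent jump turns a
perfectly tame planar oscillator into a chaotic burster.

## The model

Between spikes the state (v, u) — membrane potential and recovery
variable — follows

    dv/dt = v (a − v)(v − 1) − u + I
    du/dt = α ( σ((v − β)/ε) − u ),        σ(x) = 1/(1 + e^(−x))

and whenever v reaches the spike-detection threshold `v_peak` the state is
reset discontinuously:

    v → v_r,   u → u + d.

A planar continuous flow cannot be chaotic; all of the interesting
dynamics here is injected by the reset. Two parameter regions are built
in as presets: `region1` (β = 0.5, I = 0.004, v_peak = 0.4), where the
resting state disappears through a saddle-node bifurcation, and `region2`
(β = 0.3, I = 0.04, v_peak = 0.225), where it destabilises through a Hopf
bifurcation.

The toolkit provides:

* **event-located hybrid integration** (adaptive Dormand–Prince 5(4) with
  bisection of every upward threshold crossing),
* **equilibrium analysis** — nullcline intersections, Jacobian
  eigenvalues, saddle-node/Hopf location in the applied current I,
* **Lyapunov spectra** of the piecewise-smooth flow via the variational
  equation with **saltation matrices** at each reset and periodic
  Gram–Schmidt renormalisation, plus (v_r, d) heatmaps of λ₁,
* **Poincaré return maps** u_{i+l} = ψ^l(u_i) on the section v = v_peak,
  **characteristic multipliers** μ^l = dψ^l/du from the variational
  monodromy, periodic-orbit location by Newton iteration, and
  **continuation of period-doubling (μ = −1) and tangent (μ = +1)
  bifurcations** in the reset voltage v_r,
* bifurcation diagrams, interspike-interval return maps, a jump-sign
  (spike-to-burst) threshold finder, CSV/JSON/YAML I/O, `autoplot()`
  methods and a small command-line interface
  (`system.file("cli", "hybridspike", package = "hybridspike")`).

## Worked example

```r
library(hybridspike)

p <- neuron_preset("region1", I = 0)
find_equilibria(p)
#> # A tibble: 3 × 6
#>           v         u m1                     m2                  stable residual
#> 1 -0.000448 0.0000450 -0.10049+0.00947i     -0.10049-0.00947i    TRUE   3.4e-20
#> 2  0.104    0.000362   0.09242+0i           -0.09623+0i          FALSE  3.8e-19
#> 3  0.363    0.0609     0.10165+0.27142i      0.10165-0.27142i    FALSE  2.1e-17
```

Three nullcline intersections, one stable: the resting state. Raising the
current destroys it:

```r
locate_bifurcation_in_I(neuron_preset("region1"), c(-0.005, 0.005))
#>    I_star kind        bracket_width
#> 1 0.00250 saddle-node   0.00000079
```

With the reset switched on, the period-1 spiking orbit loses stability in
a period-doubling cascade as v_r grows:

```r
p <- neuron_preset("region1")   # v_r = 0.33, d = 0.01
locate_map_bifurcation(p, l = 1, c(0.27, 0.31), target_mu = -1)
#>   v_r_star     l kind            mu_at_star bracket_width
#> 1    0.290     1 period-doubling     -1.000    0.0000068
```

and the chaotic preset has a positive maximum Lyapunov exponent with the
neutral second exponent of a bounded attractor:

```r
lyapunov_spectrum(p, total_time = 1e4, transient = 1e3)
#> <lyapunov_result> lambda1 = 0.035936, lambda2 = -2.3e-05
#>   T = 10000 (transient 1000), tau = 0.001, 1035 spikes
```

Trajectories, heatmaps, bifurcation diagrams and return maps are tibbles;
`autoplot()` turns each into a ggplot, e.g.
`autoplot(integrate_hybrid(p, t_end = 500))` for the chaotic bursting
voltage trace.

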