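# cfgeom

Counterfactual geometry: information-geometric measures on distributions over
future outcomes, and adversarial dynamics that stabilize them.

## The problem

Adaptive biological systems — neural circuits under stimulation, immune
repertoires under antigenic challenge, regulatory networks under therapy —
can be characterized by the *distribution over futures* they keep
accessible, not just by their current state. That distribution can fail in
two opposite ways: **collapse** (probability mass concentrates on a single
future; diversity is lost and sensitivity to perturbation diverges at the
simplex boundary) or **runaway sensitivity** (weak constraint lets the
distribution swing violently between extremes). Between them lies **bounded
regulation**, where diversity and sensitivity both stay finite without the
dynamics ever converging. `cfgeom` provides, for researchers in systems
biology and network inference:

* the geometric primitives on a discrete future law
  `q = (q_1, ..., q_K)`: Shannon entropy `H(q) = −Σ q_i log q_i` (nats), KL
  divergence from a baseline, Fisher information (for binary laws,
  `I(p) = 1/[p(1−p)]`), minimal credible sets, and non-commuting intervention
  operators (projection, exponential tilting);
* a minimal two-player saddle-flow model — an Explorer adapting
  `q = (p, 1−p)` by replicator descent against a Verifier adapting
  feasibility costs `c = (c1, c2)` by gradient ascent on the shared payoff
  `L = E_q[c] − βH(q) − λ‖c‖²` — with presets realizing all three regimes,
  stationary-point and linear-stability analysis, and a single-objective
  gradient-flow baseline for contrast;
* trajectory diagnostics (entropy/KL/Fisher extrema, boundary time
  fraction) and a rule-based regime classifier;
* finite-sample proxies computable from perturbation–response data alone —
  effective sensitivity `Var(F(z))/Var(u)`, response diversity, recovery
  curves `R(τ)`, early-warning trend flags;
* a one-dimensional resource-gated generator/discriminator simulator whose
  endpoint samples reproduce the same three regimes from observable
  statistics only.

## Worked example

```r
library(cfgeom)

# geometry of a binary future law at p = 0.2
q <- future_law(c(0.2, 0.8))
shannon_entropy(q)                            # 0.5004024
kl_divergence(q, future_law(c(0.5, 0.5)))     # 0.1927448
fisher_binary(0.2)                            # 6.25
credible_set(future_law(c(0.7, 0.2, 0.1)), delta = 0.1)
#> <credible_set> delta = 0.1, |M| = 2, mass = 0.9

# integrate the bounded-regulation preset of the saddle flow and classify it
traj <- integrate_saddle(minimal_preset("bounded"))
summarize_trajectory(traj)
#> <regime_diagnostics>
#>   p in [0.20, 0.51], H in [0.50, 0.69] nats
#>   max KL = 0.19 nats, max I = 6.25, boundary fraction = 0.00 (band 0.05)
classify_regime(summarize_trajectory(traj))
#> <regime_call> bounded (terminal H = 0.693, boundary fraction = 0.00, max I = 6.25, reentries = 0)

# adversarial endpoint simulator, collapse preset: narrow, fully feasible
tr <- train_gan(gan_preset("collapse", seed = 1))
finite_sample_diagnostics(tr$state, n = 1000, seed = 2)
#> <sample_diagnostics> Var = 0.002839, H = -1.527, RMS/dz = 0.0525, residence = 0.000, cost = 0, recovery = NA
```

The bounded trajectory starts at `p0 = 0.2` and spirals into the interior
fixed point `p* = 1/2`, `c* = 1/(4λ)`: its entropy floor `H(0.2) ≈ 0.50`
nats, peak KL from uniform `≈ 0.19` nats, and peak Fisher information
`I(0.2) = 6.25` are all attained at the initial condition, and it never
enters the 0.05 boundary band. The collapse-preset generator concentrates
(`Var ≈ 0.003`, sensitivity amplification `≈ σ = 0.05`) entirely inside the
feasible interval: boundary residence and mean feasibility cost are exactly
zero.

A command-line wrapper over the same API lives at `inst/cli/cfgeom`
(subcommands `simulate-minimal`, `simulate-gan`, `diagnose`, `classify`,
`proxies`, `make-fixture`).

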