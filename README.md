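# impulseRAD

Numerical tools for threshold dynamics of stage-structured populations in
heterogeneous one-dimensional habitats.  The target system is a species
with two non-overlapping life stages — e.g. stream insects whose larvae
drift in the current while the winged adults disperse to lay eggs.  Within
a season of length τ the larval density follows a
reaction-advection-diffusion equation

    ∂u/∂t = D ∂²u/∂x² − q ∂u/∂x + f(x, u),   f(x, u) = −α(x)u − u²,

and between seasons an impulsive, non-local birth map redistributes the
offspring with a dispersal kernel K, so start-of-season densities obey the
generation map

    u_{n+1,0} = Q[u_{n,0}] = K * g(·, Φ_τ[u_{n,0}]),   g(x, u) = r(x)u/(1+u),

where Φ_τ is the within-season solution operator and the profiles α(x),
r(x) encode habitat quality (single favourable plateau or periodic patch
arrangements).  Persistence is governed by the asymptotic spectral radius
ρ_L of the linearised generation operator
L[φ] = K * (η · 𝕃_τ[φ; θ]) with θ = −α, η = r: the population persists
(unique, globally attractive positive fixed point) when ρ_L > 1 and goes
extinct when ρ_L < 1.  The package provides:

* exact-substep Strang-splitting season solver (closed-form Bernoulli
  reaction, advected heat-kernel convolution transport),
* the generation map, trajectory iteration and fixed-point search,
* dense assembly of the linearised operator, tent-cutoff truncations and
  the spectral sweep estimating ρ_L,
* scenario builders for the published plateau/periodic simulation grids,
  outcome classification and parameter sweeps,
* YAML configs, CSV/JSON outputs, seeded test fixtures and a thin CLI
  (`inst/cli/impulseRAD.R`).

## Worked example

Weak drift on the single-plateau habitat (mortality plateau m = 5,
reproduction plateau l = 10, Gaussian kernel sd 2, q = 0.1):

```r
library(impulseRAD)

sc  <- build_scenario("fig1", q = 0.1, half_width = 100, n_nodes = 2001)
rho <- scenario_rho_L(sc)
rho
#> <spectral_sweep> rho_L ~ 1.80299 (plateaued; 8 radii in [10, 90])

traj   <- run_scenario(sc, n_gens = 200)
report <- classify_outcome(traj)
report
#> <outcome_report> persistent (final sup 0.471327, tail slope -3.69985e-18)
```

ρ_L ≈ 1.80 > 1 predicts persistence, and the simulation agrees: the
trajectory settles on a positive steady state with peak density ≈ 0.471
concentrated over the favourable patch (sup-norms 1.0000 → 0.4713 → 0.4713
at generations 0/50/200; the flat tail slope is the fitted log-trend of
the last 100 generations).  Raising the drift to q = 10 drops ρ_L below
10⁻³ and the same pipeline reports extinction.

The same run from the command line:

```sh
Rscript inst/cli/impulseRAD.R simulate --figure fig1 --q 0.1 --out runs/
Rscript inst/cli/impulseRAD.R rho      --figure fig1 --q 0.1 --out runs/
```

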