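# fatecircuit

Deterministic and stochastic analysis of the two-gene circuit that drives
binary cell-fate decisions: two transcription factors that each activate
themselves and repress one another (the GATA1/PU.1 architecture). The
package is for modellers who want the complete, reproducible phase-plane
story of this motif — from elementary promoter-binding chemistry to
bifurcation diagrams and noisy attractor landscapes — as tidy tibbles.

## The model

Two elementary chemistries are implemented: **Model 1**, where activator
and repressor bind the promoter independently, and **Model 2**, where the
repressor forms a ternary complex on the activator-occupied promoter with
its own affinity. Under rapid binding equilibrium and promoter conservation
both reduce (Model 2 exactly when `K_xxy = K_yx`) to one generic system

    dx/dt = a x / ((1 + b x)(1 + c y)) − d x
    dy/dt = f y / ((1 + b y)(1 + c x)) − d y

with production scales `a`, `f`, self-saturation `b`, cross-repression `c`,
degradation `d`, and bifurcation parameter `q = c/b`. No molecular
cooperativity is assumed anywhere — the sigmoidal response and the
bistability emerge from the reduction itself. The system has four steady
states; at `q = 1` the interior (progenitor) state exchanges stability with
the two asymmetric (differentiated) states, and exactly at `b = c` the
interior equilibria degenerate into an attracting manifold
`(1 + b x)(1 + b y) = a/d` with one zero eigenvalue everywhere and a
minimum of the contracting eigenvalue at its symmetric point.

## Worked example

```r
library(fatecircuit)

p <- generic_params(a = 1, f = 1, b = 0.5, c = 1, d = 0.5)  # q = 2
steady_states(p)
#> # A tibble: 4 × 6
#>   label         x     y lambda      mu stability
#>   <chr>     <dbl> <dbl>  <dbl>   <dbl> <chr>
#> 1 trivial   0     0      0.5    0.5    unstable
#> 2 asym_x    2     0     -0.25  -0.167  stable
#> 3 asym_y    0     2     -0.25  -0.167  stable
#> 4 symmetric 0.562 0.562 -0.289  0.0702 saddle
```

Above the critical ratio the two differentiated states `(2, 0)` and
`(0, 2)` are stable and the progenitor state on the diagonal is a saddle.
The critical ratio itself:

```r
critical_q(generic_params(a = 1, f = 1, b = 0.5, c = 0.5, d = 0.5))
#> [1] 1
```

On the degenerate manifold (`b = c`), the most attracting point:

```r
pd <- generic_params(a = 1, f = 1, b = 0.5, c = 0.5, d = 0.5)
lambda_min(pd)
#> $x
#> [1] 0.8284271
#> $y
#> [1] 0.8284271
#> $lambda
#> [1] -0.2928932
```

Noisy attractor landscape (ensemble of trajectories pooled into one
stationary density; modes are the noisy attractors):

```r
tr <- simulate_ensemble(p, sigma = 0.05, n_steps = 2.5e5, seed = 1)
stationary_density(tr)$modes
#> # A tibble: 2 × 3
#>       x     y  height
#>   <dbl> <dbl>   <dbl>
#> 1 0.036 1.81  0.00824
#> 2 1.81  0.036 0.00774
```

Each result type has `tidy()`, `glance()` and `autoplot()` methods
(`bifurcation_sweep()` diagrams, `stationary_density()` grids,
`manifold_points()` samples). A command-line interface wraps the same
functions:

```sh
Rscript exec/fatecircuit bifurcate \
  --config inst/presets/bifurcation-sweep.yaml --out results/
```

with subcommands `steady-states`, `bifurcate`, `manifold`, `simulate` and
`reduce`, YAML/JSON configs (shipped presets under `inst/presets/`), CSV/JSON
outputs that echo version, parameters and seed.

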