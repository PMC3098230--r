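---
title: "Models and methods: bistability and the degenerate bifurcation in a two-gene fate-decision circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bistability and the degenerate bifurcation in a two-gene fate-decision circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatecircuit)
```

## The circuit

Binary cell-fate decisions — the classic example being the GATA1/PU.1 choice
of blood progenitors — are commonly modelled by a pair of transcription
factors $X$ and $Y$ that each activate their own gene and repress the
opposing one. The observed biology has three ingredients a model must
reproduce: a *progenitor* state with intermediate, similar levels of both
factors; two *differentiated* attractors with reciprocal expression; and a
parameter change that destabilizes the progenitor state and forces a choice.

`fatecircuit` implements two elementary promoter-binding chemistries of this
circuit, their reduction to one shared two-variable dynamical system, the
complete steady-state and bifurcation analysis of that system — including a
degenerate case in which the equilibria form a continuum — and stochastic
simulation of the noisy circuit.

## Two chemistries, one dynamical system

**Model 1 (independent binding).** Each factor binds its own promoter with
equilibrium constant $K_x$ (resp. $K_y$), and the production of protein
proceeds from the activator-bound promoter at rate $\alpha$. The opposing
factor binds the promoter as a repressor with constant $K_{yx}$ ($Y$ on the
$x$-promoter), *independently* of whether the activator is bound — so the
ternary promoter–activator–repressor complex exists, reached from either
side with unchanged affinities. Assuming the binding/release reactions are
fast compared with protein production and degradation (rapid equilibrium)
and using conservation of the promoter total $x_{tot}$, the occupancies can
be eliminated:

$$\frac{d[X]}{dt} = \frac{\alpha_x x_{tot} K_x [X]}
  {(1 + K_x[X])(1 + K_{yx}[Y])} - \delta_x [X].$$

Expanding the denominator produces a $K_x K_{yx}[X][Y]$ cross-term — an
effective heterodimer — although only independently acting monomers were
assumed. No molecular cooperativity (multimeric binding, Hill exponents)
enters anywhere; the sigmoidal ("functionally cooperative") response is an
emergent property of the reduction.

**Model 2 (in-situ ternary complex).** The repressor binds the
activator-occupied promoter with its *own* constant $K_{xxy}$, giving

$$\frac{d[X]}{dt} = \frac{\alpha_x x_{tot} K_x [X]}
  {1 + K_x[X] + K_{yx}[Y] + K_x K_{xxy}[X][Y]} - \delta_x [X].$$

The denominator factorizes into Model 1's product form exactly when
$K_{xxy} = K_{yx}$ — the no-cooperativity condition under which the two
chemistries are *identical* dynamical systems despite their different
molecular stories. `reduce_model2()` tests this factorization at $10^{-12}$
relative tolerance and reports near-misses rather than silently
factorizing, because an approximate factorization changes the phase
portrait qualitatively nowhere but quantitatively everywhere.

Both reductions map onto the generic system

$$\dot x = \frac{a\,x}{(1 + b x)(1 + c y)} - d\,x,
  \qquad
  \dot y = \frac{f\,y}{(1 + b y)(1 + c x)} - d\,y,$$

with $a = \alpha_x x_{tot} K_x$, $b = K_x$, $c = K_{yx}$, $d = \delta_x$
(mirrored for $y$). Here $b$ measures self-activation saturation (with
$a$), and $c$ cross-inhibition; the dimensionless ratio $q = c/b$ is the
bifurcation parameter. The package carries the gene-asymmetric system
($b_x, b_y, c_x, c_y, d_x, d_y$) everywhere; the symmetric system is a
constrained view, not a separate code path.

### The full network as a brute-force oracle

The rapid-equilibrium reduction is itself checked against the unreduced
mass-action network (ten species, all binding, production and degradation
reactions) integrated with a stiff solver (`deSolve::ode`, lsoda). The
binding/release pair behind each equilibrium constant $K$ is realized as
rates $(\text{rate\_scale}\cdot K,\ \text{rate\_scale})$, so $K$ is exact
and a single knob controls timescale separation.

Two subtleties determine what "convergence to the reduced model" can mean
here, and the tests are written accordingly:

* At *steady state* the promoter subnetwork satisfies detailed balance (the
  binding cycle has consistent equilibrium constants), so occupancies sit
  exactly at binding equilibrium for **any** rate_scale: full-network and
  reduced steady states agree to integrator accuracy at rate_scale 1 and
  1000 alike.
* In *transients* the reduction is genuinely approximate, and it also
  neglects sequestration of protein in promoter complexes. Finite-time
  trajectories of the full network therefore converge to reduced-model
  trajectories as rate_scale grows only when promoter totals are small
  relative to protein levels; the convergence tests use
  $x_{tot} = 0.02$ with $\alpha$ scaled up to keep $a = 1$.

## Steady states and stability

Setting $\dot x = \dot y = 0$ with symmetric parameters gives four isolated
states when $b \neq c$:

| label | coordinates | stability |
|---|---|---|
| trivial | $(0, 0)$ | always unstable (eigenvalues $a - d$, $f - d$ > 0) |
| asym_x | $((a-d)/(bd),\ 0)$ | stable iff $q > 1$ |
| asym_y | $(0,\ (f-d)/(bd))$ | stable iff $q > 1$ |
| symmetric | $(s, s)$, $(1+bs)(1+cs) = a/d$ | stable iff $q < 1$ |

All four have positive-coordinate existence exactly when $a > d$ and
$f > d$ (`check_positivity()`). The asymmetric coordinates do not involve
$c$ at all, which is why the differentiated branches of the bifurcation
diagram are horizontal lines. The Jacobian at the symmetric state commutes
with the coordinate swap, so its eigenvectors are the diagonal $(1,1)$ and
anti-diagonal $(1,-1)$; the anti-diagonal ("transversal") eigenvalue

$$\mu_\perp = \frac{d\,s\,(c - b)}{(1+bs)(1+cs)}$$

changes sign exactly at $c = b$, i.e. $q = 1$: the progenitor state is
stable below the critical ratio and a saddle above it, while the two fate
branches do the opposite. `critical_q()` locates the exchange by bisection
on that sign rather than trusting the closed form.

Numerical policy: every closed-form coordinate is polished by a damped
Newton iteration (relative tolerance $10^{-12}$) before classification —
this protects the downstream eigenvalue analysis from any transcription
slip in the closed forms; duplicates are collapsed at $10^{-8}$ in the max
norm; coordinates in $(-10^{-8}, 0)$ are snapped to $0$ because they are
concentrations; and the eigenvalue zero-tolerance for calling a state
degenerate is scale-aware, $10^{-9}\max(|\lambda|, |\mu|, d)$. For
asymmetric production ($a \neq f$) the diagonal ansatz fails and the
interior state is found by multi-start Newton from a $5\times5$ grid
instead.

```{r steady-states}
p <- generic_params(a = 1, f = 1, b = 0.5, c = 1, d = 0.5)  # q = 2
steady_states(p)
critical_q(generic_params(a = 1, f = 1, b = 0.5, c = 0.5, d = 0.5))
```

## The degenerate manifold at b = c

At the critical ratio itself (with $a = f$) the interior steady-state
equations lose uniqueness: every point of the curve

$$(1 + b x)(1 + b y) = a/d, \qquad 0 \le x \le x_{max} = \frac{a - d}{b d},$$

is an equilibrium, with endpoints at the two asymmetric states. The
Jacobian on the manifold is rank-deficient: one eigenvalue is exactly zero
(no force along the manifold — every point is indifferently stable
longitudinally) and the other,

$$\lambda(x) = -d\,b\left(\frac{x}{1+bx} + \frac{y}{1+by}\right) < 0,$$

attracts transversally. $\lambda$ has an interior minimum at the symmetric
point $x^* = (\sqrt{a/d} - 1)/b$; under noise this most-attracting point
marks the indeterminate progenitor state. `manifold_points()` samples the
continuum (200 points by default, parameterized by $x$ since $x_{max}$ is
known in closed form) and retains raw eigensolver values next to the
closed forms for diagnostics. The configuration is structurally unstable —
perturbing $c$ to $b(1 - 10^{-3})$ collapses the continuum to the single
stable symmetric state, and to $b(1 + 10^{-3})$ to the saddle plus the two
stable fates — which is exactly the biological reading: a small parameter
shift resolves the indeterminacy.

Two presets ship for this regime: $b = 0.5$ (manifold spanning
$x \in [0, 2]$) and $b = 1$ (spanning $[0, 1]$), since both
parameterizations are natural and differ only by scale.

```{r manifold}
pd <- generic_params(a = 1, f = 1, b = 0.5, c = 0.5, d = 0.5)
lambda_min(pd)
```

## Stochastic simulation

The noisy circuit adds independent additive Gaussian noise to each
coordinate, integrated by the Euler–Maruyama scheme:
$x \leftarrow x + \dot x\,dt + \sigma\sqrt{dt}\,\xi$, with each coordinate
clamped at zero from below after every step (concentrations cannot be
negative). Clamping was chosen over reflection or rejection because it is
the smallest intervention that preserves the Euler–Maruyama update
elsewhere. With $\sigma = 0$ the integrator *is* the deterministic Euler
scheme, bitwise — a property the tests assert. All randomness comes from
one explicitly seeded generator, and the seed is echoed into every output.

Defaults: $dt = 0.01$, $10^6$ steps (trajectory length $T = 10^4$),
$\sigma = 0.05$, burn-in fraction 0.1, $100\times100$ histogram bins over
$[0, 1.2\,x_{max}]^2$ smoothed with a one-bin Gaussian kernel, mode
threshold 0.1 of the global maximum, mode merge radius 0.5 state units.

**Why an ensemble.** At $\sigma = 0.05$ the two basins of the bistable
regime are separated by a barrier whose escape time grows like
$e^{\Delta U/\sigma^2}$ — astronomically longer than any feasible
trajectory. A single finite path therefore samples only the basin it first
enters, and its histogram shows one peak where the stationary landscape has
two. `simulate_ensemble()` estimates the landscape honestly by pooling
trajectories started from a $2\times2$ grid of initial conditions covering
both sides of the diagonal ($4 \times 2.5\cdot10^5$ steps by default,
burn-in applied per trajectory). Mode counts from the pooled density are
stable across seeds: one attractor for $q < 1$, two for $q > 1$.

Two further empirical notes, both visible in the tests rather than claimed
beyond them. First, the noisy attractors sit slightly *inside* the
deterministic fixed points (by roughly 0.15–0.2 state units at
$\sigma = 0.05$): at an attractor like $(2, 0)$ the repressor coordinate is
clamped at zero, fluctuates as a half-normal with strictly positive mean,
and that mean represses $x$ — a real property of the clamped process, not
an estimator artifact. Second, in the degenerate regime the trajectory
spreads *along* the manifold (the flat direction), giving strongly
anti-correlated $x$ and $y$ — the population-level signature of
inversely related factor levels in individual progenitor cells — while
`manifold_residence()` shows the process hugs the manifold (fraction
within 0.3 of it exceeds 0.9 at $\sigma = 0.05$).

```{r sde, eval = FALSE}
tr <- simulate_ensemble(set_circuit_q(pd, 2), sigma = 0.05,
                        n_steps = 2.5e5, seed = 1)
stationary_density(tr)$modes
```

## What the simulations do and do not show

The simulated trajectories emulate intrinsic expression noise as additive,
state-independent Gaussian fluctuations on a coarse-grained two-variable
system. Real single-cell noise is state-dependent (roughly Poissonian in
copy number), extrinsic factors correlate the two genes, and the molecular
layer (chromatin, bursting, mRNA) is integrated out entirely. Passing tests
therefore validate the *dynamical-systems* claims — attractor counts,
their rearrangement at $q = 1$, manifold residence — not quantitative
distributions of any real transcription factor pair.

Problem sizes used in the test suite are chosen to keep each property
cleanly resolved: $10^6$-step trajectories where the claim concerns
long-run landscapes, $5\cdot10^4$-step ensembles where only mode counts are
at stake, and 200-point manifold samples matching the default export.

## Known limitations

* No Gillespie/chemical-master-equation simulation at the elementary level;
  the stochastic treatment is the additive-noise SDE only.
* No continuation machinery: the bifurcation diagram is a parameter sweep
  plus bisection, which is complete for this two-variable system but would
  not scale to higher-codimension problems.
* No quasi-potential computation; the stationary density gives only the
  qualitative "relative depth" picture.
* SBML export covers the elementary networks; there is no SBML import.
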