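---
title: "Compositional epidemic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional epidemic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opetri)
```

# The modelling framework

`opetri` separates the *syntax* of a composite model — which subsystems
exist and which populations they share — from its *semantics* — the
concrete mathematics filling each subsystem. The syntax is an undirected
wiring diagram (UWD): boxes are slots for subsystems, ports are attachment
points on boxes, and junctions are shared variables to which ports are
wired. Three semantics are provided and can be mixed:

1. **Petri nets with mass action.** A whole-grain Petri net is four finite
   tables (species, transitions, input arcs, output arcs) with maps from
   arcs to their species and transition. Multiplicity matters: infection
   consumes one susceptible and one infected and produces two infected,
   so it has two input arcs and two output arcs. Mass action assigns each
   transition the flux `phi_t = beta_t * prod u_s^(m_st)` with `m_st` the
   input multiplicity, and species derivatives sum fluxes of producing
   transitions minus consuming ones, with multiplicity.
2. **Resource sharers.** A general open ODE: named states, exposed ports,
   a field `(t, u, params) -> du`. Composition along a UWD identifies
   states wired to a common junction and *sums the rates of change* of
   identified states. The two-compartment Ross–Macdonald model arises this
   way from host (`dIH = -r IH`), vector (`dIV = -g IV`) and bloodmeal
   (`dIH += a b IV/H (H - IH)`, `dIV += a c IH/H (V - IV)`) submodels.
3. **Delay sharers.** As above, plus a list of fixed positive delays; the
   field additionally receives the lagged states `u(t - tau_k)`. An ODE
   sharer is coerced into this world by `ode_to_dde()` (empty delay list,
   history ignored), which is how mixed ODE/DDE composites are formed.

Composition is an operad-algebra action: it is associative, the order of
boxes is irrelevant up to isomorphism, and a box may itself be filled by a
composite (`uwd_substitute()` flattens hierarchical specifications).
Mass-action interpretation commutes with composition — composing Petri
nets and then taking mass action equals taking mass action per component
and composing the sharers — and the tests assert this pointwise at random
states.

## Typing and stratification

A typed Petri net carries a morphism into a small type-system net. A
morphism maps the four tables coherently (sources and targets commute) and
*preserves arities*: over each transition the arc maps restrict to
bijections onto the arcs of the image transition. The package formalizes
arity preservation as this fibrewise bijectivity; without it a binary
interaction could be typed by a unary transition type and the type
discipline would collapse. This is a design decision recorded here because
the defining condition admits looser readings.

Two standard type systems ship as fixtures: `p_infectious` (one place
type; unary disease-status and strata-change types; one binary interaction
type) and `p_vector_borne` (host and vector place types; interactions only
between a host and a vector). Because every transition type in
`p_infectious` has equal input and output arity, any net typed by it
conserves total population under mass action — the tests verify both the
per-transition balance and numerical conservation along trajectories.

The *stratification* of a disease model by a stratification scheme (both
typed by the same system) is their pullback: species are pairs of
same-typed species, transitions pairs of same-typed transitions, and arcs
pairs of arcs over the same type arc, with endpoints computed
componentwise. Pair labels are joined with `"_"`, ordering is
lexicographic in (disease index, strata index), and both projections are
returned and checked to be morphisms. Pullback is commutative and
associative up to isomorphism, so the order of stratifying by quarantine,
age or location is immaterial; the suite checks this by explicit
isomorphism search.

### Scheme fixture conventions

The shipped stratification schemes (quarantine, age, flux and simple-trip
movement) each include a disease-status *self-loop* on every stratum
place. Without them no disease-status transition would survive
stratification in any stratum, while stratified models plainly retain
recovery in every stratum; the self-loops are the minimal convention with
the right behaviour. Similarly, the age scheme ships the (infector, infectee)
interaction in both directions, selectable via the `directions` argument,
and the simple-trip scheme on `n` patches uses places `P_ij` (currently in
patch `i`, resident in `j`), travel that preserves residence, and
interactions between all ordered pairs of places sharing a current patch.
These are fixture conventions, verified against an independent
pair-enumeration size oracle.

### Further fixture design choices

* The host/vector Petri decomposition shares only the infected
  populations `IH`, `IV` at junctions and keeps the susceptible places
  `SH`, `SV` inside the bloodmeal box; several placements are defensible,
  and this fixture is used for gluing tests only.
* The delayed bloodmeal is modelled as
  `dIV = a c IH(t - tau)/H * (V - IV(t - tau)) * exp(-g tau)` — new vector
  infections reflect host prevalence one incubation period ago, discounted
  by vector survival. It is exercised only in consistency and
  vanishing-delay tests, never as a source of reference numbers.
* The vaccination-model wiring diagram is modelled closed (no outer
  ports): nothing downstream needs to compose with the composite, and a
  closed diagram composes to a closed system.

# Parameters and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `beta_t` | mass-action rate constant of transition `t` | 1/time (× 1/concentration per extra input) | per fixture (SIR: 0.3, 0.1) |
| `a` | vector biting rate | bites/vector/day | 0.3 |
| `b`, `c` | infection efficacy vector→host, host→vector | — | 0.5, 0.5 |
| `r` | host recovery rate | 1/day | 0.05 |
| `g` | vector mortality | 1/day | 0.1 |
| `H`, `V` | host and vector population sizes | individuals | 1000, 10000 |
| `tau` | vector incubation delay | day | 10 |

The Ross–Macdonald reference evaluation in tests and the acceptance script
uses the point `(a, b, c, g, r, H, V) = (1, 1, 1, 1, 1, 10, 100)` at state
`(IH, IV) = (1, 5)`, where the composite field equals `(3.5, 4.5)` by hand
evaluation of the printed equations.

# Numerical choices

* **ODE integration**: adaptive Dormand–Prince (`deSolve::ode`, method
  `ode45`), `rtol = 1e-8`, `atol = 1e-10`. These tolerances leave the
  closed-form checks (exponential decay at `1e-6`, conservation at `1e-9`)
  comfortably integrator-limited.
* **DDE integration**: `deSolve::dede`; history lookups at or before the
  start time are routed to the user-supplied history function (a constant
  vector or a function of time on `[t0 - max tau, t0]`), later lookups
  interpolate the accumulated solution. Only constant, fixed delays are
  supported — the incubation delay the framework targets is a constant.
* **Stochastic simulation**: the Gillespie direct method with
  falling-factorial propensities `beta_t * prod n_s (n_s - 1)...`, the
  standard stochastic convention; the deterministic semantics uses plain
  powers as written. This divergence is deliberate and documented.
  Waiting times are inverse-transform exponentials from one stream seeded
  per call, so event lists are bit-reproducible.
* **No state clipping**: negative concentrations are a modelling
  diagnostic, not an error; the vector field is evaluated as written.
* **Morphism search**: backtracking over transitions in decreasing-arity
  order, binding species as arc bijections are chosen, tie-breaking by
  smallest codomain index; exhaustive and duplicate-free, exponential in
  the worst case but instant on the type systems and disease models in
  scope. Isomorphism adds injectivity constraints and stops at the first
  hit.
* **Gluing**: union–find with path compression over junctions and
  component species; junction classes come first in junction order with
  junction labels winning (the wiring diagram is the shared vocabulary),
  then unmerged species in (component, local) order, so serialization is
  deterministic. A junction wired to no port survives only when it is an
  outer junction — closed composites do not grow phantom places.
* **Composition interface**: every port exposes exactly one place
  (singleton feet). General finite-set feet are representable but refused
  by `oapply()` with a clear error, because no gluing rule for unequal
  foot cardinalities is defined in scope.
* **Sensitivity**: central differences with per-parameter step
  `h = 1e-4 * max(|beta_t|, 1)`; the tests cross-check against Richardson
  step-halving extrapolation at `1e-4` relative tolerance.
* **Fitting**: unweighted least squares on observed species at observation
  times; `n = 8` multi-start with seeded log-uniform draws inside the
  bounds, refined by `L-BFGS-B`. The inner loss integrates at exactly the
  observation times with `rtol = 1e-6`, looser than the reporting
  integrator — the loss only needs smoothness well below the residual
  scale. Initial values may be free parameters on the same footing as
  rates.

# What the synthetic data does and does not show

Parameter-recovery experiments use trajectories generated by the model
itself at 21 evenly spaced times over `[0, 20]` with the SIR ground truth
`beta = (0.3, 0.1)`, observed species `I` and `R`, optionally with 1%
multiplicative Gaussian noise. This emulates regular surveillance of
infection prevalence and cumulative recovery with small measurement error.
It deliberately does not emulate reporting delays, day-of-week effects,
underascertainment, overdispersed counts or model misspecification — so a
passing recovery test shows the estimator and its seeding are correct, not
that real surveillance data would identify the rates this well. Fitting
real surveillance data is out of scope by design: no external data ships
with the package.

Problem sizes throughout (nets of ≤ 16 transitions, stratifications up to
12 places × 18 transitions, 100-state random checks, 8-start fits on a
2-parameter SIR) were chosen so that every check is exact or
statistically decisive at desk scale.

# Known limitations

* Morphism enumeration and isomorphism checks are exponential in general;
  they are intended for type systems and small disease models, not for
  stratified products of many factors.
* Delays are constant and shared across the composite's delay list;
  state-dependent or distributed delays and event handling are out of
  scope, as are stochastic differential equations.
* Composition along transitions (rather than places), general colimit
  machinery, and SBML interchange are not provided.
* Parameter namespaces of sharers are merged by name; two components
  using the same name for different quantities must be renamed before
  composition (a collision with differing values is an error).
* The TOML configuration file mentioned in early CLI sketches is not
  implemented; all behaviour is reachable through flags.
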