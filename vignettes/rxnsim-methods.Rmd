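---
title: "rxnsim: model semantics, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rxnsim: model semantics, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnsim)
```

## The modelling problem

Large metabolic models reuse the same reactant in many reactions, often
with different stoichiometric coefficients, and are conventionally drawn
as several maps ("layers") coupled through shared species. `rxnsim`
represents this with three ideas:

* a **species symbol** is the single source of truth for a reactant: its
  display name (free-form, e.g. `"NAD+"`), initial concentration, and
  reactant type — `variable` (an ODE state) or `pool` (a boundary
  concentration held constant during integration);
* a **shortcut symbol** is an alias for a species, usable from any layer.
  Its name, concentration and type read through to the target — they are
  never stored on the shortcut, so an edit of the target is immediately
  visible through every alias — while its **stoichiometric coefficient is
  its own**. A reaction edge wired to a shortcut uses the shortcut's
  coefficient; an edge wired to the species directly uses the per-edge
  coefficient given on that edge;
* **layers** are unordered labels with no hierarchy. Flattening
  (`flatten_scheme()`) merges all layers and replaces every shortcut
  reference by a direct reference carrying the shortcut's coefficient.
  Flattening is idempotent, preserves the multiset of
  (reaction, species, role, coefficient) edges, and — by construction of
  the derivation below — never changes the mathematics. `connectors()`
  reports, for every pair of layers, the species used by both; that set
  is the biological coupling between the maps.

One reading had to be fixed here: whether a species carries one global
stoichiometric coefficient or one per reaction edge. We adopt **per-edge
coefficients** (each direct edge and each shortcut carries its own),
because it is the only reading under which the same reactant can enter
one step with coefficient 1 and another with coefficient 2 while staying
a single state variable — the motivating use case.

## From scheme to ODEs

`derive()` assigns a state index to every `variable` species that is not
the target of an assignment rule (pools and rule targets are outputs, not
states; state order is species declaration order grouped by layer). The
stoichiometry matrix entry for species $s$ and reaction $j$ is

$$\nu_{sj} = \sum_{\text{product edges}} c_e \;-\; \sum_{\text{substrate edges}} c_e,$$

with each edge contributing **its own** coefficient (the shortcut's for
shortcut edges, against the *target's* state index). The right-hand side
is $\dot x = N\,v(x, p, t)$ restricted to state rows.

Rate laws:

* `mass_action(k)`: $v = k \prod_i S_i^{c_i}$ — the substrate edge
  coefficient doubles as the kinetic order, so a coefficient-2 ATP edge
  yields an $\mathrm{ATP}^2$ term. This matches the rendered equations of
  diagrammatic simulators for such steps.
* `michaelis_menten(Vmax, Km)`: the single-substrate steady-state
  approximation $v = V_{max} S/(K_m + S)$. Enzymes can be attached as
  **modifiers** (rate-affecting participants without mass change); the
  modifier role exists because enzyme-kinetic steps need a place for the
  catalyst even though it never enters the balance.
* `rate_law(expr)`: any expression in the package's expression language;
  stoichiometry then only shapes the balance, never the rate.

Custom-law local parameters are addressed as `reaction.param`
(e.g. `"r1.k1"`) in the derived parameter vector, alongside global
parameters and pool concentrations; that vector is the estimation
interface.

`render_equations()` prints one `d[name]/dt = ...` line per state, terms
in reaction declaration order, `^` for exponentiation, coefficients of 1
omitted — deterministic, so the rendering is regression-testable.

## The expression language

Kinetic laws, rules and triggers share one grammar: numeric literals,
identifiers, `+ - * / ^` with `^` right-associative and binding tightest
(`2^3^2 = 512`, `-x^2 = -(x^2)`), unary minus, `exp`, `ln`, `log10`,
`sqrt`, `abs`, `pow`, `min`, `max`, single-condition
`piecewise(a, cond, b)`, comparisons `< <= > >= ==`, `and/or/not`,
parentheses, and the reserved time symbol `t`. Multi-condition
`piecewise` is deliberately rejected (it is outside the supported SBML
subset, and accepting it silently would change semantics on import).
`ln`/`log10`/`sqrt` raise domain errors on non-positive/negative
arguments rather than returning IEEE specials: a silent `NaN` inside a
rate law is much harder to diagnose than a named error. The function
list itself is a design choice — the formats we interoperate with do not
pin one down — chosen to cover the MathML operators the importer maps.

Parsing is a hand-written tokenizer plus recursive-descent parser;
`expr_render()` inverts it structurally (`parse(render(ast)) == ast`).
The test suite checks evaluation against base R's own parser/evaluator
on 1000 random expressions (tolerance 1e-12) — two independent routes
from the same abstract syntax.

## Numerical integration

`simulate_scheme()` integrates with the variable-order stiff **BDF**
family (`deSolve`, `method = "bdf"` — the Gear method), with a numerically
approximated Jacobian; no non-stiff fallback is offered, keeping one
well-characterised code path. Defaults: `max_step = 0.1` (the
conventional default for this class of simulator; it bounds event-miss
latency as well as step size), `rel_tol = 1e-6`, `abs_tol = 1e-9`, 201
output points. All concentrations and times are in arbitrary units;
nothing in the package assumes a unit system.

**Assignment rules** are evaluated inside the right-hand side (in
topological order; cyclic rule sets are rejected at validation) so rates
may depend on rule outputs, and again at every reported point for the
output table. **Pools** are carried in the parameter vector, so events
can reset them.

**Events** fire on a false→true transition of their trigger. Each
trigger is compiled to a signed margin (`a >= b` → `a - b`,
`and` → `min`, `or` → `max`, `not` → negation) that is non-negative
exactly when the trigger is true; the integrator root-finds the zero
crossing, stops, applies the assignments of every event whose boolean
state flipped (in declaration order), and restarts from the event time.
Equality triggers (`==`) get the margin `-|a - b|`, which only touches
zero: the crossing can in principle be skipped between steps, a
documented limitation. Triggers already true at `t0` do not fire at
`t0` (the usual initial-trigger convention of SBML Level 3, kept for
interchange compatibility). A guard aborts if events stall integration
at one time point (a trigger that refires endlessly).

Negative concentrations are **reported, never clamped** (with a warning
beyond `100 * abs_tol`): clamping would silently change the model.
Degenerate inputs are handled explicitly: schemes with no reactions
produce constant columns; schemes with no state variables short-circuit
the integrator and only scan time-triggers; an integrator failure
surfaces as a structured error carrying the last good time.

## Parameter estimation

The objective is the (optionally per-species weighted) sum of squared
errors between simulation and observation at the observation times;
simulation failure maps to `+Inf`, so every in-bounds point is
evaluable. Unweighted SSE is the default; weights exist because
multi-scale concentrations otherwise dominate the fit.

* `fit_powell()` — modified Powell conjugate directions: cyclic Brent
  line minimisations over the bound-feasible interval of each direction,
  the iteration's net displacement replacing the direction of largest
  decrease under the standard acceptance test, and a reset of the
  direction set to the identity once all directions have been replaced
  (guarding against degeneration). Deterministic given the start.
* `fit_rcga()` — real-coded GA: uniform initialisation within bounds,
  BLX-α crossover (α = 0.5), per-gene Gaussian mutation (rate 0.1,
  σ = 5% of the parameter range), binary tournament selection, elitism
  of one, bound clipping. Fully reproducible from its seed (the RNG
  state is restored afterwards). These operator choices are declared
  defaults, all overridable — reproducibility is worth more than
  fidelity to any particular published GA variant.
* `fit_hybrid()` — the GA's best individual handed to Powell; the result
  objective is never worse than the GA phase's by construction.

Because rules and events live inside the simulation, estimation works
unchanged for schemes containing them; the test suite recovers the decay
constants of the rule+event toy through its event discontinuity.

## SBML interchange

Export flattens first (the XML format cannot carry layers or shortcuts;
shortcut edges become plain `speciesReference` stoichiometries), maps
pools to boundary/constant species, preserves display names in `name`
and sanitized identifiers in `id`, and emits kinetic laws, rules,
triggers and event assignments as MathML. Every export is checked by a
structural validator (`check_sbml()`: unique resolvable ids, numeric
attributes, well-formed math); semantic fidelity is asserted by the
round-trip tests (export → import simulates identically to 1e-6 on all
fixtures). The reader/writer is implemented in-package on top of `xml2`.

Import places everything in one layer named after the model id;
`partition_scheme()` then re-layers it from an explicit user config
(element id → layer), creating shortcuts for every cross-layer
participation — no automatic inference of which occurrences "should" be
shortcuts is attempted, since that is a presentation decision.
Compartments are imported as **inert global parameters**: their sizes
appear in rate expressions exactly as written in the source math, and
their organisational role is different from (and orthogonal to) layers.
Reaction-local parameters are promoted to globals as
`reactionid__param` to avoid collisions. Unsupported constructs — fast
reactions, `csymbol` delay, dynamic stoichiometry, multi-piece
`piecewise`, rate/algebraic rules, event delays/priorities, function
definitions — abort the import with an error naming each feature;
silent skipping would corrupt models.

## Fixtures: what the generators emulate

The fixtures module makes every test input reproducible in code:

* `make_linear_chain(n, k = 0.1, x1_constant = 100)` — the pool-fed
  first-order chain: `X1` constant at 100, `X2..Xn` starting at 0, all
  rate constants 0.1. These values are the conventional benchmark
  configuration for this system. Whether the chain ends in a terminal
  outflow (n rate constants for n species) is genuinely ambiguous in
  diagrams of this benchmark; the fixture defaults to **with outflow**
  and exposes `terminal_outflow` so either reading is available. With
  outflow, `X2(t) = 100(1 - e^{-0.1t})` exactly; without,
  `X2` grows linearly at rate 10 — both closed forms are tested.
* `make_atp_toy()` — the aliasing example: coefficient 1 via direct
  symbols at step 1, coefficient 2 via shortcuts at step 3. The backbone
  species are named `S1..S4` (their identities are immaterial to the
  asserted structure); rate constants 0.1 and initial values are chosen
  to give visibly ATP-limited dynamics.
* `make_butanol()` — two layers (*E. coli* glycolysis-side, *C.
  acetobutylicum* reductive chain) connected through acetoacetyl-CoA,
  NAD+ and NADH, with the narrated redox balance: 2+2 NADH produced in
  the first layer, 1+1+1+1 consumed in the second, NAD+ mirrored, and
  the 2-vs-1 pair at the glyceraldehyde-3-phosphate oxidation /
  acetoacetyl-CoA reduction steps. Kinetics are placeholder unit-rate
  mass action: the fixture's asserted content is topology and
  stoichiometry only, and tests touch only those.
* `make_three_layer_toy()` — the canonical connector pattern: layers
  coupled through B, S, and {K, M, N}.
* `make_rule_event_toy()` — four decaying species, an assignment rule
  computing their total (the "total concentration" read-out pattern of
  cell-cycle models), and an event zeroing one decay constant at t = 5;
  every species has a piecewise closed form.
* `make_random_scheme(seed, ...)` — seeded random mass-action schemes
  (integer coefficients 1–3, optional pools and two-layer splits with
  shortcuts) for oracle-based property tests.

What the generators do **not** emulate: realistic enzyme saturation and
regulation, measured rate constants of any published pathway,
concentration units, or experimental noise structure beyond i.i.d.
Gaussian observation error in the estimation tests. Passing tests
therefore certify the machinery (derivation, integration, event
handling, estimation, interchange), not the biology of any particular
organism.

## Problem sizes and test design

The suite uses sizes chosen to make each property legible: chains of
n = 2–5 for closed forms and recovery, n = 100 over t ∈ [0, 1000] for
the large-scale integration check; 50 random schemes against a
brute-force edge-enumeration derivative oracle (tolerance 1e-12); 6
random first-order schemes against an exact matrix-exponential solution
(relative 1e-6, with integrator tolerances tightened to 1e-9/1e-12 for
that comparison); estimation with GA populations of 16–30 over 12–30
generations. The two-basin landscape used to demonstrate the hybrid's
global behaviour is constructed so that axis-parallel line searches from
the local basin cannot see the global one — pure Powell provably stalls
at the local minimum there, while the hybrid reaches the global basin
in at least 8 of 10 seeds.

## Known limitations

* Equality (`==`) event triggers can be missed between integrator steps
  (margin touches zero rather than crossing it).
* No compiled right-hand side: rates are evaluated in R (with an
  index-based fast path for pure mass-action schemes); very large custom-
  law models will be slower than code-generating simulators.
* SBML support is the Level 3 Version 1 Core subset described above;
  Levels 1–2 documents are not dialect-converted.
* No stochastic (SSA) simulation — the semantics here are purely
  deterministic ODEs.
* Identifiability is the user's problem: the estimators report the best
  SSE found, with no confidence intervals.
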