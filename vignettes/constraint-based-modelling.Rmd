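---
title: "Constraint-based modelling with fluxkit: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling with fluxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkit)
```

## The modelling framework

A constraint-based metabolic model consists of a stoichiometric matrix $S$
(metabolites $\times$ reactions), per-reaction flux bounds
$lb \le v \le ub$ (mmol gDW$^{-1}$ h$^{-1}$ by convention) and a linear
objective $c$. Under the steady-state assumption, internal metabolite
concentrations do not change, so every feasible flux distribution satisfies
$S v = 0$. Flux-balance analysis (FBA) maximises $c^\top v$ — typically the
flux through a biomass drain — over that polytope. Because the optimum is a
property of the constraint set, not of enzyme kinetics, FBA needs no kinetic
parameters, which is what makes genome-scale analyses tractable.

Several related methods refine or perturb this picture, and all of them are
formulated in `fluxkit` as optimisation problems over the same constraint
set:

* **mtf** (minimal total flux): among the FBA-optimal flux distributions,
  select one minimising $\sum_j |v_j|$, linearised with a split
  $v = p - q$, $p, q \ge 0$. The optimum is pinned by
  $c^\top v \ge z^\ast - \varepsilon$ with
  $\varepsilon = 10^{-6}\max(1, |z^\ast|)$ — an inequality with slack rather
  than an equality, because pinning an LP optimum exactly is numerically
  brittle. All mtf-derived quantities therefore carry a relative fuzz of
  order $10^{-6}$, which the test tolerances acknowledge.
* **MOMA** minimises $\lVert v - w \rVert_2^2$ against a wild-type
  reference $w$ — a quadratic program; the prediction is the Euclidean
  projection of $w$ onto the perturbed flux space.
* **linear MOMA** minimises the $L_1$ distance
  $\sum_j (d^+_j + d^-_j)$ with $v - w = d^+ - d^-$. No additional biomass
  constraint is imposed; which variant of the linear relaxation to adopt was
  genuinely open, and the plain $L_1$ form was chosen because it needs no
  extra parameter and nests naturally between FBA and MOMA.
* **ROOM** minimises the *number* of fluxes leaving the window
  $[\,w_j - \delta|w_j| - \epsilon,\; w_j + \delta|w_j| + \epsilon\,]$,
  a mixed-integer program with one binary indicator and two big-M rows per
  reaction. Defaults $\delta = 0.03$, $\epsilon = 0.001$ follow the original
  ROOM publication. A relaxed LP mode ($y \in [0,1]$) exists but must be
  requested explicitly, because its objective is only a lower bound on the
  change count.

The wild-type reference for the MOMA family defaults to the **mtf** flux
distribution rather than a raw FBA solution: FBA optima are massively
degenerate, and distances to an arbitrary vertex are not reproducible across
solvers, while the minimal-total-flux point is far more stable.

## Model representation

`MetabolicModel` objects are value-semantic: every manipulation
(`add_reaction()`, `change_bounds()`, `change_uptake()`, ...) returns a
modified copy, so batch analyses can never corrupt a shared model. Three
representation choices deserve a note:

* **Reversibility is derived**, not stored: a reaction is reversible exactly
  when its lower bound is negative. A stored flag can contradict the bounds;
  a derived one cannot.
* **Compartments are identifier suffixes** (`glc[e]`), matching the BiGG
  reaction-list convention; there is no separate compartment table, which
  keeps the TSV round trip lossless.
* **Exchange sign convention**: positive exchange flux is secretion,
  negative is uptake, so growth environments are set through exchange lower
  bounds. `change_uptake()` *closes every exchange it is not given*
  (`lb = 0`). This is a deliberate decision on a point the classic
  interfaces leave ambiguous: the resulting environment is exactly the one
  stated in the call, independent of the model's previous state.

Default open bounds are $\pm 1000$ for reversible and $[0, 1000]$ for
irreversible reactions — the common convention in curated models, large
enough to be non-binding wherever a biological capacity is not intended.

## The solver layer

Batch analyses — a genome-wide knockout screen, flux variability — solve
thousands of problems that differ only in a few bounds or in the objective.
`fluxkit` therefore separates the *description* of a problem
(`problem_spec()`) from a mutable *handle* (`build_problem()`): the problem
is transferred to the backend once, subsequent edits
(`set_var_bounds()`, `set_objective()`, `set_row_limits()`) touch only the
changed entries, and `solve_problem()` re-solves from the previous optimal
basis. The contract is strict: basis reuse and in-place editing must never
change a returned objective (beyond $10^{-9}$) relative to building a fresh
problem — speed is allowed to differ, results are not. The test suite
enforces this batch-vs-rebuild equivalence on full single- and double-gene
screens.

The backend interface is a name plus capability flags (`lp`, `qp`, `milp`),
so commercial kits can be plugged in behind the same contract. The shipped
reference backend is self-contained:

* **LP**: a bounded-variable two-phase primal simplex (dense linear
  algebra), returning row duals and the optimal basis for warm starts.
  Writing it in-package was a deliberate design decision: the backend must
  expose dual values (phase-plane shadow prices, duality diagnostics),
  in-place modification and basis reuse, which rules out one-shot
  `solve()`-style wrappers. Entering variables are chosen by largest
  reduced cost, with Bland's rule after an iteration threshold as the
  anti-cycling fallback; feasibility tolerance is $10^{-8}$, optimality
  $10^{-9}$, and all cross-implementation assertions in the tests use
  $10^{-6}$.
* **QP** (MOMA): an active-set quadratic-programming routine
  (`pracma::quadprog`) over the dense constraint form, preceded by an LP
  feasibility pre-check so that infeasible knockouts report `infeasible`
  rather than a numeric failure.
* **MILP** (ROOM): depth-first branch-and-bound on the LP relaxation with
  best-bound pruning and most-fractional branching; integrality tolerance
  $10^{-6}$.

The dense simplex is sized for the models this package targets in its tests
and examples (tens to a few hundred reactions). It is *not* tuned for
2000-reaction genome-scale reconstructions; for those, a sparse
factorising backend should be plugged in behind the same contract. That is
the main known limitation.

## High-level analyses

`gene_deletion()` enumerates gene sets lexicographically over sorted gene
identifiers (reproducible output files), maps each set through the GPR rules
to the reactions it disables, zeroes those columns on the shared handle,
solves, records and restores. Two policies are worth stating:

* **Lethality** is `biomass < 1%` of wild type (configurable), or an
  infeasible status. The literature rarely defines "lethal" numerically; 1%
  cleanly separates numerical zero from residual growth.
* **No lethal-subset pruning** by default: a pair containing a lethal
  single knockout is still solved, keeping exact parity with exhaustive
  enumeration (and with the rebuild-per-knockout oracle used in testing).

For `algorithm = "mtf"` the pinned optimum must be the *knockout's own* FBA
optimum — pinning the wild-type value would make every growth-reducing
knockout infeasible — so the screen keeps a companion FBA handle and
re-pins the optimum row before each mtf solve.

`flux_variability()` holds the model objective at
$\ge \gamma z^\ast - \varepsilon$ (default $\gamma = 1$) and
minimises/maximises each reaction flux on one handle. A $\ge$ constraint
with $\gamma$ defaulting to 1 was chosen over an equality row: it
degrades gracefully to the classic "fraction of optimum" analysis and
avoids equality-pinning brittleness.

`phenotypic_phase_plane()` pins two control fluxes via singleton constraint
rows and reads the two shadow prices from the row duals; grid points are
assigned to a phase by the dual pair rounded at $10^{-6}$ — shadow prices
are piecewise constant over the plane and change exactly at phase
boundaries. Fluxes below $10^{-9}$ in magnitude are reported as exact zeros
throughout, so downstream flux classifications are stable.

## Fixtures: what the generated models do and do not emulate

The package generates its own test models rather than shipping a curated
reconstruction:

* `make_chain_model()` — a linear uptake-to-biomass chain with an isoenzyme
  pair; FBA optimum equals the uptake bound, every optimal route is unique.
* `make_branched_model()` — a direct route vs a two-step bypass; mtf prefers
  the direct route (total flux 30 vs 40), and the `g1` knockout has
  closed-form MOMA (biomass 5, distance 200), linear-MOMA (30) and ROOM (3)
  responses.
* `make_two_substrate_model()` — two substrates with yields 1 and 2, giving
  analytically known phase-plane objectives and distinct shadow prices.
* `make_core_model()` — a deterministic, glycolysis-shaped network with
  exactly 30 genes (transporter complexes, isoenzymes, a bypass, an
  overflow branch secreting a by-product); wild-type optimum 10. This is the
  substrate for the full single+double knockout screens (465 sets).
* `make_random_model()` — seed-deterministic path networks with random
  capacities in $[1, 10]$ and random 1–2-gene rules; the first path is kept
  fully open so a strictly positive optimum is guaranteed by construction.
  Arbitrary random stoichiometries are avoided deliberately: they are
  usually infeasible or unbounded and would test nothing.

These fixtures exercise the machinery — alternative optima, reversible
exchanges, isoenzyme/complex logic, infeasible knockouts — but they do not
reproduce properties of real reconstructions: no cofactor and energy
coupling, no conserved moieties, no compartmental transport cycles, and
stoichiometric coefficients mostly $\pm 1$. Passing tests therefore
establish the correctness of the algorithms and of the solver plumbing, not
the biological accuracy of any particular reconstruction.

Validation in the test suite runs the implementation against independent
oracles on these generated models: a classic tableau simplex for LPs, an
alternating-projection (Dykstra) computation of the MOMA projection, and
exhaustive on/off-pattern enumeration for ROOM on models with at most eight
reactions (problem sizes: ~100 random models of up to 12 reactions for the
LP/QP routes, 25+ for ROOM, 465 knockout sets for the screen equivalence).

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| default open bounds | $\pm 1000$ / $[0,1000]$ | model construction, TSV reader |
| backend feasibility tolerance | $10^{-8}$ | simplex |
| optimality / pivot tolerance | $10^{-9}$ | simplex |
| optimum-pinning slack $\varepsilon$ | $10^{-6}\max(1,|z|)$ | mtf, FVA |
| flux zero-clipping | $10^{-9}$ | `optimize_problem()` |
| MILP integrality tolerance | $10^{-6}$ | branch and bound |
| lethality threshold | 1% of wild-type biomass | deletion analyses |
| ROOM thresholds | $\delta = 0.03$, $\epsilon = 0.001$ | `build_room()` |
| phase rounding | $10^{-6}$ | phase plane |
| cross-route assertions | $10^{-6}$–$10^{-7}$ | test suite |

Numbers in TSV output are written as the shortest decimal string that parses
back to the identical double, so round trips are bit-faithful and identical
analyses produce byte-identical report files.

## Known limitations

* The dense reference simplex targets fixture-scale models; genome-scale
  reconstructions need a sparse external backend behind the same contract.
* SBML input is intentionally out of scope (`read_sbml_model()` fails with
  a clear message); models enter through the tab-separated reaction-list
  dialect.
* Problem handles are single-owner: parallel screens must build one handle
  per worker.
* The QP path supports minimisation with a positive-semidefinite quadratic
  term only — exactly what MOMA needs, nothing more.
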