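---
title: "Growth-coupled target scanning: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled target scanning: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcscan)
```

## The problem

A genome-scale metabolic model (GEM) represents an organism's metabolism as
a stoichiometric matrix $S$ (metabolites $\times$ reactions) with flux
bounds $l \le v \le u$ in mmol gDW$^{-1}$ h$^{-1}$. Flux balance analysis
(FBA) finds a steady-state flux distribution by linear programming:

$$\max_{v}\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

usually with $c$ picking out the biomass pseudo-reaction. For metabolic
engineering of a product — here motivated by heme b overproduction in
*Pichia pastoris*, where heme supply limits leghemoglobin yield — the
question is which reactions to upregulate, downregulate or delete so that
product formation rises without killing growth. `gcscan` answers it with an
enforced-objective-flux scan: force the product flux upward in steps,
re-optimize growth at each step, and watch which reaction fluxes co-vary
with the product.

## The scan

1. **Initialization** (`initialize_scan`). Record the non-growth ATP
   maintenance floor (the maintenance reaction's lower bound — the ATP
   hydrolysis flux the cell must sustain at any growth rate), the minimal
   and maximal biomass flux under the applied constraints, and the maximal
   product flux $t_{\max}$ with biomass left free.
2. **Schedule** (`build_step_schedule`). The enforced values are
   $e_k = k \cdot \frac{f \, t_{\max}}{n}$ for $k = 1..n$, with $n = 5$
   steps and cap fraction $f = 0.9$ by default. The cap keeps the last
   step away from the theoretical maximum, where the whole flux budget
   goes to product and biomass collapses to zero — at that point
   growth-coupling can no longer be read out. With the last value anchored
   at $f\,t_{\max}$ and the axis divided into equal steps, the first step
   is one fifth of the capped maximum rather than zero; the zero point is
   still covered by the baseline FBA solution, which the suite checks the
   first step degenerates to when an enforced value of 0 is substituted.
3. **Per-step FBA** (`run_scan`). At each step the product sink's *lower*
   bound is raised to $e_k$ (the upper bound is kept, so the optimum may
   overshoot if that benefits growth), biomass is re-maximized, and every
   reaction's flux is recorded, giving one $n$-vector profile per
   reaction. An infeasible step is flagged, not fatal. The biomass
   trajectory must be non-increasing in $e_k$ — raising a lower bound
   only shrinks the feasible region — and `run_scan` asserts this on
   every run.
4. **Validity filter** (`filter_valid_profiles`). Only profiles with a
   value at all steps and a monotone (non-increasing or non-decreasing)
   absolute-flux sequence are kept; wobbling profiles are alternate-optima
   noise or non-steady behaviour.
5. **Classification** (`classify_reactions`). Comparing $|v_1|$ and
   $|v_n|$: flux-increasing reactions are upregulation candidates,
   flux-decreasing ones downregulation/deletion candidates, the rest
   unaffected. The four proportionality tables
   (`partition_proportionality`) combine the carried direction of the
   flux (positive = left-to-right in the written stoichiometry) with the
   trend (directly vs contra proportional to the enforced product flux).

## Deterministic solving

Plain FBA optima are degenerate: many flux vectors attain the same
objective, and which vertex a solver returns is arbitrary. A scan
classification built on arbitrary vertices would not be reproducible. By
default every solve therefore adds a parsimonious second stage: holding
the optimal objective value fixed, minimize the total absolute flux
$\sum_j |v_j|$ (linearized by splitting $v = v^+ - v^-$). The resulting
vector is unique in practice and byte-reproducible across runs; a
`deterministic = FALSE` flag restores raw single-stage vertices for users
who want to mimic plain-FBA behaviour, since the two modes can classify
borderline reactions differently.

The LP backend breaks pivot ties using R's random number stream; `gcscan`
pins and restores the RNG state around every solve, so results are
bit-for-bit reproducible and a user's random stream is never disturbed.

## Step-weighted factor

Candidates are ranked by how strongly their profile moves relative to its
mean. The default (`variant = "deviation"`) is the summed absolute percent
deviation from the profile mean,

$$\mathrm{SWF} = \sum_{k=1}^{n} \frac{|v_k - \bar v|}{|\bar v|} \times 100\,\%,$$

which is zero exactly for constant profiles, grows with coupling strength,
and is invariant under rescaling the profile. A `"literal"` variant that
sums the raw ratios $v_k / \bar v \times 100\,\%$ is retained behind a
flag; it evaluates to $100 n$ for *every* profile (ratios to the
arithmetic mean sum to $n$), a regression-tested identity documenting why
it cannot discriminate candidates — the deviation form is the reading
under which reported score ranges (e.g. 17.3 for amino-acid reactions vs
5–9 for dihydroxyacetone-cycle reactions) are attainable. Scores are used
ordinally: the ranking, not the magnitude, is the contract. Ties at
LP-noise resolution (scores equal after rounding to 9 decimals) break
lexicographically by reaction id.

## Essentiality screen

Downregulation/deletion candidates must leave the cell viable.
`screen_essentiality` deletes each candidate (bounds to $(0,0)$) and
re-maximizes biomass; a reaction is essential when post-deletion growth
falls below `essentiality_fraction` (default $10^{-3}$) of wild type.
The threshold separates numerically-zero growth from LP round-off
without crediting marginal growth as viability; it is configurable. Both
screening modes are exposed: only the ranked candidates (default) or
every reaction in the model (`screen_all`). Gene-level (GPR) deletion is
out of scope; gene-association strings are carried through the tables so
reaction-level hits can be mapped to genes downstream.

## Constraints and conventions

Within a model, uptake is a negative exchange flux and secretion positive
(the interoperability convention of published constraint-based models).
Measured uptake rates are reported as positive magnitudes, so a
`constraint_set` `uptake` entry of `c(2.17, 2.29)` mmol gDW$^{-1}$
h$^{-1}$ — an O$_2$ consumption range of the kind measured in glycerol
cultivations — becomes exchange bounds $(-2.29, -2.17)$. A measured
specific growth rate is applied as the biomass reaction's *upper* bound:
it caps growth at what was observed while leaving the scan free to trade
growth against product below it; pinning both bounds would make every
scan step infeasible the moment the enforced product flux costs any
growth. In models carrying one biomass composition per carbon source, the
`substrate` field selects the matching biomass reaction. The wet-to-dry
cell weight helper uses the empirical gravimetric factor DCW = 0.3 × WCW.

## Toy fixtures and the oracle

Testing needs models whose scan outcome is known by construction, because
the published *P. pastoris* model (iMT1026: 1708 metabolites, 2243
reactions, two biomass compositions) is not bundled with the package and
its headline candidate counts depend on the exact published file and
constraint values. Two generators stand in:

* `build_toy1()` — a fixed 7-reaction chain: substrate uptake (bound 10)
  feeds either biomass or the product sink, plus a never-profitable waste
  branch. Ground truth: biomass and product maxima are both 10, enforcing
  product flux $e$ forces biomass $10 - e$, the product branch is
  flux-increasing, biomass flux-decreasing, the saturated uptake
  unaffected, and exactly the chain reactions are essential.
* `build_random_toy(seed)` — seeded random branched networks (chain
  length, branch count and attachment points drawn from the seed; at most
  15 reactions). The topology is deliberately a **tree**: for any fixed
  enforced product flux the optimal flux distribution is then unique, so
  the oracle's flux-range midpoints coincide with the parsimonious vertex
  and any scan/oracle disagreement is a genuine defect rather than a
  tolerance case.

The oracle (`oracle_scan`) is an independent code path: a dense
bounded-variable formulation solved by the package's own two-phase
tableau simplex with Bland's anti-cycling rule, computing each reaction's
attainable flux range at the step optimum exhaustively and classifying on
range midpoints. The production path and the oracle share no solver code.

What the fixtures do not emulate: cofactor stoichiometry, compartments
beyond one, reversible internal cycles, alternate-optima degeneracy, and
genome-scale size. Passing the fixture matrix therefore demonstrates the
algorithm's correctness on networks with known coupling structure, not
numerical robustness at genome scale or agreement with any particular
published candidate list.

## Numerical choices

* LP backend feasibility is as provided by the dense simplex; reported
  comparisons in the suite use $10^{-6}$, and fluxes below $10^{-10}$ are
  zapped to zero for clean serialization.
* Monotonicity tolerance (validity filter): relative $10^{-4}$ of the
  profile's largest magnitude, absolute floor $10^{-9}$ — above LP noise,
  below any real trend.
* Change tolerance (affected vs unaffected): 1 % relative change between
  first and last step, same floor.
* Bounds of magnitude $\ge 10^5$ are treated as infinite and capped; an
  optimum driven to such a cap is reported `unbounded`.
* Degenerate inputs: a fully pinned model (every reaction with
  $l = u$) reduces to a residual feasibility check; an enforced value
  above the target's own upper bound marks the step infeasible; a
  zero-mean profile has no defined score and is excluded from ranking
  with a message.

## Problem sizes

The test suite and the acceptance script run the reference toy plus a
20-seed fixture matrix (≤ 15 reactions each) through the full scan and
oracle — about 3,000 small dense LPs — in well under a minute on one
core. These sizes were chosen so the brute-force oracle remains exact
and exhaustive; the scanning code itself has no hard-coded size limits,
but the dense simplex makes genome-scale runs slow, which is the main
known limitation (see below).

## Known limitations

* The LP layer is dense; models with thousands of reactions will solve,
  but slowly. The module boundary (`fba()`) is the place to swap in a
  sparse/industrial LP backend.
* Reaction-level only: GPR boolean evaluation, double deletions and
  synthetic lethality are not implemented.
* No flux-variability envelope per step beyond feasibility, no dynamic
  FBA, no thermodynamic or enzyme-constrained extensions.
* XLSX mirroring of the report tables is not available on installations
  without an XLSX writer; CSV is the canonical, diff-able output and the
  report layout (columns `Reactions_ID`, `Reactions_name`,
  `FBA_results_1..5`, `Subsystem`, `Var10` — the latter carrying the
  reaction stoichiometry text) mirrors the supplementary-table
  convention.
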