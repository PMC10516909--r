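# gcscan

Growth-coupled target scanning for constraint-based metabolic models.

## What it does, and for whom

Metabolic engineers working with a genome-scale metabolic model (GEM) —
for example *Pichia pastoris* engineered for heme b overproduction, where
intracellular heme supply limits leghemoglobin yield — need to know which
reactions to upregulate, downregulate or delete so that product formation
rises while the cell stays viable. `gcscan` implements an
enforced-objective-flux scan over a stoichiometric model:

1. apply measured exchange-flux constraints (substrate/O₂ uptake, CO₂
   evolution, growth rate) to the model;
2. find the maximal product flux t_max, divide the axis up to a capped
   maximum (default 0.9 · t_max) into n equal steps (default 5);
3. at each step force the product sink's lower bound to the enforced
   value, re-maximize biomass

       max cᵀv   s.t.  S·v = 0,  l ≤ v ≤ u,

   with a parsimonious (minimal total |v|) second stage so the flux
   vector is deterministic, and record every reaction's flux;
4. keep profiles that are complete and steadily changing, classify each
   reaction as **flux-increasing** (upregulation candidate),
   **flux-decreasing** (downregulation/deletion candidate) or
   **unaffected**, and partition the affected set into the four
   direction × proportionality tables;
5. rank candidates by the **step-weighted factor**

       SWF = Σₖ |vₖ − v̄| / |v̄| × 100 %,

   the summed absolute percent deviation of the profile from its mean;
6. screen deletion candidates by single-reaction-deletion essentiality
   and keep only the non-essential ones.

Models are read and written in SBML Level 3 (fbc) and COBRA-style JSON;
constraints come from YAML; reports are CSV tables in the
supplementary-style layout (`Reactions_ID`, `Reactions_name`,
`FBA_results_1..5`, `Subsystem`, `Var10`).

## Worked example

The bundled reference toy model routes a substrate (uptake bound 10)
either to biomass or to a product sink `EX_P`, with a never-used waste
branch:

```r
library(gcscan)
m <- build_toy1()
bundle <- run_full(list(model = m, biomass_id = "R2", target_id = "EX_P",
                        out_dir = "toy_report"))
#> loaded model TOY1: 4 metabolites, 7 reactions
#> init: biomass in [0, 10], target max 10, maintenance floor 0
#> schedule: 1.8 3.6 5.4 7.2 9
#> biomass per step: 8.2 6.4 4.6 2.8 1
#> 7 profiles retained after validity filter
#> classes: 2 increasing, 1 decreasing, 4 unaffected
#> excluded from scoring (zero-mean profile): R5, EX_W
#> 2 upregulation candidate(s); 0 non-essential downregulation candidate(s) of 1
```

Reading the log: the product can carry at most flux 10, so the five
enforced steps run 1.8 … 9.0 (steps of 0.9 · 10 / 5), and biomass falls
linearly from 8.2 to 1.0 — the model trades growth for product one for
one. The product branch is classified flux-increasing, the biomass drain
flux-decreasing, and the saturated uptake unaffected.

```r
bundle$upregulation[, c("Reactions_ID", "FBA_results_1", "FBA_results_5", "SWF_percent")]
#>   Reactions_ID FBA_results_1 FBA_results_5 SWF_percent
#> 1         EX_P           1.8             9         200
#> 2           R3           1.8             9         200

bundle$essentiality
#>   reaction_id growth_after_deletion wild_type_growth essential
#> 1          R2                     0               10      TRUE
```

Both product-pathway reactions score SWF = 200 % (their profiles double
their mean's worth of deviation over the scan) and tie; the only
flux-decreasing reaction is the biomass drain itself, which is essential,
so the non-essential deletion list is — correctly — empty.

For a real run, point `run_full()` (or the thin CLI in
`inst/cli/gcscan.R`) at an SBML model, name the biomass and target sink
reactions explicitly, and supply measured bounds:

```yaml
# constraints.yaml
substrate: methanol
measured_mu: 0.03
uptake:
  EX_o2_e: [2.17, 2.29]   # positive magnitudes; becomes bounds (-2.29, -2.17)
bounds:
  EX_co2_e: [1.61, 1.70]
```

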