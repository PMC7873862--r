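# gsmforge

Tools for building, curating, and validating genome-scale metabolic models
of non-model organisms — written around the workflow used for oleaginous
yeasts that grow on lignocellulosic carbon (glucose, pentoses, aromatic
acids) and accumulate storage lipid.

The package covers the full pipeline:

* **Draft reconstruction** — transfer reactions from donor models through
  an ortholog map (`transfer_reactions()`), rewrite GPR rules with
  isozyme (OR) semantics, and resolve donor genes without orthologs by
  the isozyme/complex rule (`resolve_unmapped()`): drop a complex branch
  missing a subunit if an isozyme remains, remove the reaction otherwise.
* **Curation audits** — duplicate metabolite/reaction detection by
  canonical keys and stoichiometric signatures (`find_duplicate_metabolites()`,
  `dedup_reactions()`), exact mass/charge balance (`check_balance()`),
  dead-end reporting, compartment reassignment.
* **Biomass with a lean/lipid-body split** — fit per-fatty-acid lines
  `y_k = m_k (x − x0) + b_k` against total fatty-acid content by
  segmented regression (`fit_segmented()`): intercepts give the lean-mass
  fatty-acid composition (into the biomass equation), slopes give the
  lipid-body composition (into lipid-droplet demand/sink reactions), so
  growth and lipid accumulation are simulated independently
  (`assemble_biomass()`).
* **Simulation** — FBA with shadow prices, flux variability, single and
  combined gene deletions through GPR logic, biomass-precursor diagnosis,
  and mixed-integer detection of energy-generating cycles with all
  exchanges closed (`fba()`, `delete_genes()`, `find_egc()`). The LP/MIP
  core is a self-contained bounded-variable simplex with duals.
* **Validation** — growth-phenotype arrays (Biolog-style substrate wells)
  and gene-fitness tables scored as confusion matrices with accuracy and
  Matthews correlation, including the always/never/conditionally
  essential gene partition (`simulate_phenotypes()`,
  `essentiality_concordance()`).
* **Synthetic data + demo fixture** — seed-deterministic generators with
  ground-truth ledgers (`make_universe()`, `make_fame()`,
  `make_phenotype_and_fitness()`), and a fully balanced ~115-reaction
  demo yeast model (`demo_model()`) with pentose and p-coumarate
  catabolism, respiratory chain with ubiquinone-9, and lipid-droplet
  wiring.

Models read and write a BiGG-style JSON dialect and an SBML Level 3 + FBC
subset (`read_model()`, `write_model()`); fixture JSON loads unchanged
into cobrapy.

## Worked example

```r
library(gsmforge)

model <- demo_model()
media <- demo_media()

fba(model, media$glucose)$objective
#> [1] 1.362055
fba(model, media$xylose)$objective
#> [1] 0.9540162

# D-ribulose kinase is required on pentoses but not on glucose:
delete_genes(model, "14368", media$xylose)$growth
#> [1] 0
delete_genes(model, "14368", media$glucose)$growth_ratio
#> [1] 1

# the lean/lipid-body split behind the biomass equation:
fit <- fit_segmented(demo_fame_data())
fit
#> <fame_fit> x0 = 5.000 wt% CDW, 3/3 fatty acids increasing, RSS = 0
#>       slope_m intercept_b increasing
#> C18_1     0.7           3       TRUE
#> C16_0     0.2           1       TRUE
#> C18_2     0.1           1       TRUE
```

The first two numbers are growth rates (h⁻¹) on glucose and D-xylose
minimal media at 10 mmol·gDW⁻¹·h⁻¹ carbon uptake. The deletion shows the
fixture's pentose route running through D-ribulose kinase (protein 14368):
knocking it out abolishes growth on xylose and leaves glucose untouched.
The fit recovers the packaged fatty-acid panel's lean contents
(b, wt% CDW), lipid-body composition (m, mass fractions) and lean total
(x0 = sum(b)).

See the vignette in `vignettes/gsmforge-methods.Rmd` for the model,
assumptions, parameter meanings and design decisions.

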