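---
title: "Reconstruction, biomass decomposition and validation with gsmforge"
author: "gsmforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction, biomass decomposition and validation with gsmforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmforge)
```

gsmforge implements the workflow by which a genome-scale metabolic model of
a non-model organism — here an oleaginous yeast that assimilates the
hexoses, pentoses and aromatic acids of lignocellulosic hydrolyzate — is
assembled from donor models via orthology, audited and curated, given a
biomass objective whose lipid term is split into lean cell mass and a lipid
body, simulated by flux balance analysis, and finally scored against
growth-phenotype arrays and transposon-fitness data. This vignette is the
package's account of the underlying methods, the modeling decisions they
required, and what the packaged synthetic data can and cannot establish.

## Constraint-based models and the FBA core

A model is a set of compartmentalized metabolites (BiGG-style ids,
`base_id` + `_` + compartment token), reactions with flux bounds in
mmol·gDW⁻¹·h⁻¹, boolean gene–protein–reaction (GPR) rules, and an
objective. Flux balance analysis maximizes the objective flux subject to
steady-state mass balance $S v = 0$ and the bounds. The LP (and the
branch-and-bound used below) is solved by a dense bounded-variable primal
simplex written for this package: phase-1/phase-2, Bland's anti-cycling
pivot rule, full refactorization per iteration, duals returned for the
mass-balance rows. At the package's scale (hundreds of columns) this is
exact and fast; it is deliberately not a general sparse solver. Shadow
prices are reported as the marginal change of the objective per unit of
external supply of a metabolite, the convention used when diagnosing
unsynthesizable biomass precursors.

Numerical conventions: steady state is enforced to 1e-6, bounds to 1e-9;
"growth" means objective flux above 1e-6; a deletion is *essential* when it
drops growth below 10% of the wild-type optimum. The growth and
essentiality thresholds are configurable arguments, recorded in every
result object; neither has a canonical literature value.

## Draft reconstruction from donor models

`transfer_reactions()` carries a donor reaction into the draft iff at least
one GPR gene maps through the ortholog table to a target gene. Because
ortholog groups mix true orthologs with recent paralogs, a one-to-many
mapping expands to an OR over the target co-orthologs — isozyme semantics,
never a fabricated complex. Donor genes with no target ortholog stay in
the rule under a donor namespace until `resolve_unmapped()` applies the
isozyme/complex rule on the disjunctive normal form: clauses (complexes)
containing an unmapped subunit are dropped; a reaction with no fully
mapped clause left is removed. DNF makes "top-level OR sibling"
well-defined for arbitrarily nested rules, and makes the keep/remove
decision provably equal to "satisfiable using mapped genes only", which is
how the tests check it.

Reactions with empty donor GPRs (spontaneous and orphan reactions) are
never transferred automatically; they are emitted on a candidate-orphan
list for manual opt-in, since a reconstruction should not inherit
unattributed chemistry silently. Structural duplicates across donors
collapse onto the first-transferred copy; on metadata conflicts the first
donor in the user-given order wins, and the merge is logged. Every donor
reaction ends in exactly one terminal log action
(`transferred`, `gpr_pruned`, `removed_complex`, `skipped_no_ortholog`),
so the provenance of the draft is replayable.

## Curation audits

Duplicate metabolites are proposed by a key of (canonical Hill formula,
charge, compartment), with an alias table for known synonym pairs such as
the upper/lower-case cytochrome-c variants that public databases carry;
name similarity only ranks candidates and never merges on its own, and
differing protonation states never auto-merge because charge is part of
the key. Duplicate reactions share a canonical stoichiometry signature:
ids sorted, coefficients rescaled so the lexicographically smallest
participant carries −1 (+1 when all coefficients share a sign), which is
invariant to direction and scale. Deduplication keeps the smallest id,
ORs the GPRs and takes the widest orientation-aligned bounds —
conservative retention of capability. Mass/charge balance is audited
exactly for integer stoichiometries and to 1e-6 when coefficients are
fractional; pseudo-elements `R`/`X` participate like ordinary elements so
lumped lipid species remain auditable; metabolites without formulas make a
reaction *unauditable*, which is reported, never skipped.

## The biomass objective and the lean/lipid-body split

Fatty-acid (FAME) panels measured across media spanning low to high lipid
states show a subset of fatty acids rising linearly with total fatty-acid
content while the rest stay flat. Writing $x$ for a sample's total
fatty-acid content (wt% of cell dry weight), each fatty acid $k$ is fit
as $y_k = m_k (x - x_0) + b_k$: the intercepts $b_k$ are the fatty-acid
content of lean cell mass (mostly phospholipid), the slopes $m_k$ the mass
composition of the accumulating lipid body (triacylglycerols and sterol
esters). Defining $x$ as $\sum_k y_k$ makes $\sum_k m_k = 1$ and
$\sum_k b_k = x_0$ exact identities.

That same closure means the residual sum of squares of the per-breakpoint
least-squares fits is *flat* in $x_0$ wherever the nonnegativity
constraints $m_k, b_k \ge 0$ are slack: with all samples at $x \ge x_0$,
the breakpoint is identified only by the leanest observation and the
nonnegativity boundary. The grid search (default resolution 0.05 wt%)
therefore takes the **largest** grid value attaining the minimal RSS (ties
at relative 1e-9) — the leanest sample when all intercepts stay
nonnegative there. This was a genuinely open design point; the chosen rule
makes noise-free data with a sample at the lean state recover the
generating parameters exactly, and is stated here rather than hidden in
code. Fatty acids count as *increasing* when their slope exceeds 0.02 and
its t-statistic exceeds 2 (configurable; the source data support only a
qualitative increasing/constant split); constant fatty acids are refit
with slope pinned to zero and the closure identities are restored by
rescaling. Data below the fitted breakpoint would be excluded and flagged;
the packaged generator never produces any.

`assemble_biomass()` converts macromolecule mass fractions and monomer
compositions into biomass coefficients,
$\text{coef} = F \cdot x_i / M_i$ (mmol·gDW⁻¹ from mass fraction $F$,
mol fraction $x_i$, residue mass $M_i$ in g/mmol), audits the total drain
to 1 g/gDW ± 1e-4, and adds growth-associated maintenance as mass-neutral
ATP hydrolysis. The lean fatty-acid composition ($b_k/\sum b$) enters the
biomass lipid term; the lipid-body composition ($m_k$) weighs separate
irreversible *demand* reactions for lipid-droplet triacylglycerols and
sterol esters (accumulation), with matching *sink* reactions, closed by
default, for mobilization. Keeping the lipid body out of the biomass
equation lets one model simulate growth, lipid accumulation and lipid
turnover without maintaining several biomass variants. Trace-element and
cofactor pools are supported as fixed small-coefficient drains
(default 1e-4 mmol/gDW each) but the demo fixture leaves them out: its
cofactors are catalytic and a drain would demand biosynthesis routes the
fixture deliberately does not carry.

## Energy-generating cycles

With every exchange, demand and sink closed, a thermodynamically sound
network can dissipate no energy currency at steady state. The audit
maximizes a dissipation pseudo-flux for each currency (ATP, GTP, NADH,
NADPH, FADH2 per compartment where present, and the trans-mitochondrial
proton gradient `h_c -> h_m`); any positive optimum is a defect. The
offending loop is then localized by a MIP minimizing the number of active
reactions subject to dissipation ≥ 1, with big-M linking constraints
(activity threshold 1e-4, 60 s per currency; on timeout the finding is
flagged "minimality unproven" rather than dropped). Before the MIP, the
network is reduced by iterative connectivity pruning — with boundaries
closed, a metabolite lacking a possible producer or consumer blocks every
reaction touching it — which strips all linear pathways and leaves only
potential cycles, and a fast flux-variability pass fixes the remaining
immobile reactions to zero. This keeps the binary count in the tens and
the audit deterministic on one CPU.

## Validation against phenotype arrays and fitness data

Phenotype-array wells are binarized on the dye signal (A590 − A750)
against a plate noise floor (25th percentile of negative-control wells
plus three standard deviations) unless calls are pre-recorded; the
original screens published calls, not thresholds, so the floor is
configurable. For each simulable well the exchange supplying that well's
element class is closed and the mapped metabolite's exchange opened at
the same uptake (nitrogen/phosphorus/sulfur plates keep glucose);
substrates mapping to several anomeric ids open all of them; unmappable
substrates are counted but excluded, mirroring how only a subset of array
conditions can ever be simulated. Concordance is reported as a 2×2
confusion matrix with accuracy and the Matthews correlation coefficient
(defined 0 on degenerate margins; equal to the Pearson correlation of the
two binary vectors, which is how the tests cross-check it).

Gene essentiality is compared per (gene, condition): predicted from
GPR-masked deletion FBA, observed when the gene is flagged globally
essential or its fitness score falls below a cutoff (default −2 on the
log2 scale; the source data state only that a cutoff was used). Genes are
partitioned by their observed calls into always / never / conditionally
essential — disjoint and exhaustive by construction — and accuracy is
additionally reported on the conditional subset, where the discrimination
is hardest. Media for the conditions are supplied by the caller; the
conditions are defined by the fitness table itself.

## Synthetic data and the demo fixture

The generators are pure functions of (seed, parameters); they restore the
global RNG state. `make_universe()` builds a feasible ground-truth
pathway (a hydration chain, so every metabolite has a distinct formula
and every reaction is balanced by construction), projects it into donors
with namespaced genes, and derives an ortholog map with controlled
coverage and spurious-link rates; duplicate-alias metabolites and
mass-imbalanced copies are injected at requested rates and ledgered, so
curation can be scored exactly. `make_fame()` inverts the segmented-line
model at an evenly spaced design of total contents over
$[x_0, x_0 + 35]$ wt% — a designed media panel from the lean state to a
strongly lipid-accumulating one, with measurement noise (truncated at 0,
then rescaled to exact closure) on the compositions only. An even design
with its leanest condition at $x_0$ is what the breakpoint estimator
needs to be consistent; nothing else about the fit depends on the design.
`make_phenotype_and_fitness()` flips the model's own growth and
essentiality calls with Bernoulli($q$) label noise and draws fitness
scores from N(0, 0.5) / N(−4, 1) for the resulting labels, resampled onto
the correct side of the −2 midpoint so that the flips are the *only*
label noise and a cutoff at the midpoint recovers them exactly.

The demo fixture (`demo_model()`) is a hand-curated ~115-reaction network
over cytosol, mitochondrion, peroxisome, endoplasmic reticulum, lipid
droplet and the extracellular space: glycolysis, pentose-phosphate and
TCA skeleton; ATP-citrate lyase as the cytosolic acetyl-CoA source
characteristic of oleaginous yeasts; a three-complex respiratory chain
with explicit proton translocation and ubiquinone-9 (nine isoprenyl
units) as quinone; the pentose route through D-arabinitol and D-ribulose
to D-ribulose-5-phosphate, with the conventional xylulokinase present but
terminating in an unconnected product — the enzyme is not expressed in
vivo, and the dead end encodes that flux must pass the arabinitol loop;
L-arabinose entry via L-arabinitol and L-xylulose; and peroxisomal
p-coumarate degradation through a beta-oxidation-like CoA route to
4-hydroxybenzoate, hydroxylation to protocatechuate, cytosolic
ortho-cleavage to 3-oxoadipate and mitochondrial conversion to
succinyl-CoA + acetyl-CoA. Every non-boundary reaction is mass- and
charge-balanced with real formulas; the lumped fatty-acid, sterol and
ubiquinone syntheses were balanced by element/charge algebra and are
verified by the package's own audit. Two deliberate simplifications: the
peroxisomal CoA activation is written ATP → ADP + Pi to avoid carrying
AMP/PPi handling in a demo network, and the 4-hydroxybenzoate
hydroxylation sits in the cytosol so the peroxisome needs no NADPH
supply. The maximum ATP yield per glucose implied by the wiring is 32
(`demo_atp_ceiling()`); the LP reaches 30 because cytosolic NADH enters
the chain without proton pumping.

## What the tests do and do not show

Synthetic universes have unique formulas per metabolite, no transport
ambiguity, and GPRs of at most two genes, so exact recovery there shows
the transfer/resolution logic is correct — not that real donor models,
with shared formulas, promiscuous transporters and deep complexes, would
reconstruct cleanly. The fitness generator draws label noise i.i.d.,
whereas real insertion data have gene-length and insertion-count
structure; cutoff-sensitivity analyses on real data remain the user's
responsibility. The fixture's growth rates are illustrative (10
mmol·gDW⁻¹·h⁻¹ default carbon uptake, a configurable convention), and
its biomass uses three amino acids and a glucan as stand-ins for full
monomer panels; its value is that every audit the package performs passes
on it exactly, so it serves as an executable specification of a clean
model. Problem sizes throughout (40-reaction universes, 29-gene deletion
screens over five media, 20-seed Monte-Carlo fits, 200 random LP
networks) were chosen as the smallest at which the checked properties
are non-trivial.
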