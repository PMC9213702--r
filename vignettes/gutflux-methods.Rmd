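---
title: "Methods: models, statistics and design choices in gutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in gutflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

`gutflux` links the composition of the gut microbiome in metabolic disease
to its metabolic capability. This vignette explains the models and
statistics it implements, the parameters that matter, what the synthetic
data does and does not emulate, and the design decisions taken where more
than one reading was defensible.

## Flux balance analysis

A genome-scale metabolic model (GEM) of one metagenomic species pan-genome
(MSP) is a stoichiometric matrix $S$ (metabolites × reactions), bounds
$lb \le v \le ub$ on each reaction flux (mmol/gDW/h), a biomass reaction
whose flux is the growth rate (h⁻¹), and exchange reactions — one
metabolite each, written so that negative flux is uptake and positive flux
is secretion. FBA assumes the cell is at steady state ($Sv = 0$) and that
evolution has tuned it toward maximal growth; it solves
$\max v_{\text{biomass}}$ subject to steady state and bounds.

A *diet* constrains the exchange lower bounds: metabolite $m$ with limit
$u_m$ gives its exchange bounds $[-u_m, ub]$, any metabolite outside the
diet gets uptake 0, and secretion is never limited (default cap
1000 mmol/gDW/h, the conventional "effectively unbounded" value in
constraint-based modelling). The `anaerobic` flag closes oxygen uptake and
*takes precedence* over an oxygen entry in the diet table — the flag
states the environment, the table states availability, and an anaerobic
gut does not become aerobic because a diet file lists oxygen.

The LP itself is solved by a two-phase primal simplex on the
bounded-variable form (`solve_lp()`), written for this package because the
optimisation layer had to be self-contained. Pivot and feasibility
tolerances are $10^{-9}$; Dantzig pricing with a Bland fallback guards
against cycling. Only the objective value and steady state are guaranteed
unique at an optimum — the flux vector is one optimal vertex, so
downstream comparisons use objective values and exchange-flux *patterns*,
never equality of full flux vectors. The test suite checks every optimum
for $\max|Sv| \le 10^{-6}$ and compares objectives against an independent
vertex-enumeration oracle on networks small enough to enumerate.

## Differential abundance and the selection rule

Case/control comparison uses the two-tailed Wilcoxon rank-sum test per
feature with Benjamini–Hochberg FDR control. The exact null distribution
is used when the pooled sample size is ≤ 20 with no ties (exactness is
cheap there); otherwise the normal approximation with tie and continuity
correction. A feature whose pooled values are all identical carries no
evidence and gets $p = 1$.

Significant MSPs then pass a second filter: one group's median must be
exactly 0 while the other's is strictly positive. This targets species
that are effectively *absent* from one side of the dysbiosis, which is
where species-level presence/absence claims are robust for zero-inflated
relative-abundance data. "Strictly positive" is taken literally; a median
of exactly zero in both groups fails the rule.

Enrichment direction compares group means: disease-enriched iff
mean(case) > mean(control). Exact ties go to control-enriched — a
documented, deterministic tie-break rather than a coin flip; ties are
essentially impossible for continuous abundances and only arise in
degenerate constructed inputs. The log2 fold change uses a pseudo-count of
half the smallest nonzero value in the table, the usual device for
zero-inflated compositions; the fold change is reported for display and
plays no role in selection.

FDR thresholds default to 0.01 at MSP, reaction and association level, and
are computed within disease, not pooled — each cohort is its own testing
family. The BMI-stratified comparison deliberately reports *raw* p against
α = 0.05 with no multiplicity adjustment: it is a focused confirmation on
a small pre-selected reaction set, not a discovery screen.

## The reactobiome

The reaction-abundance matrix personalises metabolic capability:
$RA(s, j) = \sum_i P(i, j)\,a(i, s)$ with $P$ the binary
species-by-reaction presence matrix and $a$ the relative abundance table —
a matrix product. Presence is binary by design: what is summed is which
species *can* run the reaction, weighted by how abundant they are, not how
many gene copies they carry. Species with abundance but no model
contribute nothing (and are logged); only a minority of gut species have
reconstructions, and this is the honest treatment of that gap.

Reactions significant in every disease are intersected, then filtered for
a direction consistent across diseases, then for a model-presence gap:
reaction retained only if its presence fraction differs by more than 20
percentage points between disease-enriched and control-enriched models.
KO mapping reports the union of KEGG-ortholog annotations over the
surviving reactions; the alternative reading — re-testing KO-level
abundances (KO abundance = sum of member reaction abundances) — is
available as `differential_kos()`.

## Community models

A personalised community model merges the sample's top-$N$ modelled
species ($N = 10$ by default, itself a compromise with problem size; ties
at the cut break lexicographically, and weights renormalise to sum 1).
Each species keeps a private cytosol (`_c_<i>` suffix on metabolite ids);
its exchange reactions are removed and its external metabolites join a
shared lumen (`_u`). Every lumen metabolite gets exactly one diet-input
reaction (`_d → _u`, bounded by the diet at the community level — totals,
not per species) and one output reaction (`_u → _f`); the `_d`/`_f`
species are boundary metabolites outside the mass balance.

"Growth constrained by abundance" is formalised as *equality coupling*:
each species' biomass reaction additionally produces a species-biomass
metabolite, and a single community biomass reaction consumes those at
stoichiometric coefficients equal to the abundance weights. Steady state
then forces $v_{\text{bio},i} = w_i\,v_{\text{community}}$, which is the
only reading that makes abundances binding while keeping one community
objective. A proportional-bound variant
($v_{\text{bio},i} \le w_i \cdot 1000$, species biomass pooled) is
available via `coupling = "bound"` for sensitivity analysis; it is a
relaxation, so its optimum can only be ≥ the equality optimum — a property
the tests assert. Species-internal bounds are *not* abundance-scaled: the
coupling already expresses composition, and rescaling interior bounds
would double-count it.

A single-species community at weight 1 collapses exactly to single-model
FBA (diet `[0, u_m]` input plus `[0, 1000]` output reproduces the exchange
range `[-u_m, 1000]`); the tests verify this equivalence to $10^{-6}$ on
every generated model, plus lumen mass balance and hand-derived optima on
two-species toys.

## Reaction–metabolite association

Each (reaction, metabolite) pair is fit as
`metabolite ~ log(reaction abundance + ε) + age + sex + BMI` by ordinary
least squares, ε again half the smallest nonzero abundance (abundances are
heavily right-skewed; the metabolite side is left on its measurement
scale). This is a deliberate simplification of mixed-model association
frameworks: the samples are treated cross-sectionally, so fixed effects
suffice and every number is transparent. The implementation residualises
both sides on the covariates once (Frisch–Waugh–Lovell) and computes all
pair coefficients and t-tests with matrix algebra — algebraically
identical to per-pair `lm()` (asserted in the tests to $10^{-8}$) and fast
enough to fit every pair. Numeric covariates are median-imputed; sex is
coded M = 1/F = 0 with unknowns imputed. Constant predictors or responses
are skipped with a message. Degenerate perfect fits (zero residual
variance with a nonzero effect) get $p = 0$; zero variance *and* zero
effect gets $p = 1$.

The BMI stratification splits at BMI > 30 vs ≤ 30; a sample at exactly 30
goes to the lower stratum (excluding it, as a strict double inequality
would, is impossible to apply to real data) and the count of boundary
samples is reported so the choice is visible.

## Model dissimilarity

Two conventions coexist for Jaccard comparison of reaction sets: the
distance $D = 1 - |R_i \cap R_j|/|R_i \cup R_j|$ and the similarity
$1 - D$. The package exposes both (`jaccard_distance()`,
`jaccard_index()`) and every summary states which it reports; conflating
them silently is a known source of confusion in model-comparison
summaries.

## The synthetic data

The generator emulates the statistical structure the analysis assumes, at
a scale chosen to keep the full pipeline in seconds on one CPU (defaults:
40 species of ~30–50 reactions, 60 cases + 60 controls per disease across
three disease labels, a 101-sample healthy "wellness" cohort, 200
metabolites):

- **Abundances** are log-normal (the standard stand-in for microbial
  rank-abundance curves), renormalised per sample. Planted differential
  species (10 by default, half per direction) are multiplied by 8 in
  their enriched group and zeroed with probability 0.7 in the depleted
  group — strong enough that the zero-median rule is satisfiable, which
  is precisely the regime the two-step selection targets.
- **Models** share one metabolite namespace and a functional core
  (fermentable sugars → pyruvate; glutamate → amino acids + ammonia;
  biomass), with growth-coupled secretion of acetate, propionate,
  butyrate, proline and indole via biomass byproduct coefficients.
  Disease-designated species secrete more acetate/propionate and consume
  more glutamate; control-designated species secrete more butyrate. The
  marker ("tartrate-like") subsystem — five reactions annotated with two
  KEGG orthologs, feeding tartrate into the central chain — is present in
  disease-enriched species with probability $(1+g)/2$ and in others with
  $(1-g)/2$, realising the configured presence gap $g = 0.8$ in
  expectation. Every emitted model is checked functional (grows on the
  shipped diet).
- **The wellness cohort** draws BMI across the obesity boundary (30 % of
  samples obese) and multiplies marker-carrier abundances by 3 in obese
  samples, planting the reaction–BMI association.
- **The metabolome** plants 10 (reaction, metabolite) pairs, half
  positive and half negative, with effect 1.5 per SD of transformed
  abundance against noise SD 1; all other metabolites are covariate
  signal plus noise.

Everything is a deterministic function of (config, seed), and the truth
manifest records every planted effect so recovery tests need no
re-derivation.

What the synthetic data does *not* emulate: real taxonomic composition
and phylogenetic correlation between species, compositional coupling
beyond per-sample renormalisation, sequencing depth and read-level noise,
gene-copy variation within species, realistic GEM scale (thousands of
reactions) or thermodynamic realism, and longitudinal correlation in the
wellness samples. Passing tests therefore demonstrate that the
*implementation* recovers planted structure under the stated statistical
assumptions — not that those assumptions hold in any real cohort.

## Pipeline scale and determinism

The default `run_pipeline()` builds community models for a seeded
subsample of 8 case and 8 control samples per community-disease cohort
(T2D and ACVD, mirroring which cohorts get community models), a scale
choice that keeps the default run in seconds; set
`community_samples_per_group = Inf` for all samples. All randomness —
generation, subsampling — derives from the config seed, and re-running
with an identical config reproduces identical outputs; the manifest
records per-stage row counts and parameters.

## Known limitations

- FBA returns one optimal vertex; alternate optima are not enumerated
  (no flux-variability analysis), so individual non-exchange fluxes
  should not be over-interpreted.
- The simplex is dense; it is comfortable at toy-community scale
  (hundreds of reactions) but not engineered for models with tens of
  thousands of reactions.
- The association model is fixed-effects only; repeated-visit designs
  need a mixed model outside this package's scope.
- Ten species per community is a truncation of real gut communities, and
  equality coupling is one defensible formalisation of
  abundance-constrained growth, not the only one — hence the bound
  variant for sensitivity checks.
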