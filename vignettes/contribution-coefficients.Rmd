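---
title: "Profiling taxon contributions to lignocellulose degradation with CAZyme read shares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling taxon contributions to lignocellulose degradation with CAZyme read shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazycontrib)
```

## The problem

Lignocellulose — the cellulose/hemicellulose/lignin composite of plant cell
walls — is degraded in nature by microbial consortia whose members divide the
labor: some genera supply the carbohydrate-active enzymes (CAZymes) that
depolymerize the substrate, while others live off the released sugars.
Because the sugars are public goods, a consortium can carry "sugar cheaters":
members that consume degradation products while contributing few
lignocellulolytic enzymes. Telling contributors from cheaters matters when
evaluating or engineering degradative consortia, and plain taxonomic
abundance cannot do it — an abundant genus may owe its abundance to
freeloading.

`cazycontrib` works at the annotation layer of a shotgun metagenome. Its
inputs are the three gene-level tables that standard pipelines produce from a
non-redundant gene catalog: per-gene mapped-read counts, per-gene taxonomic
lineages, and per-gene CAZy family assignments (dbCAN-overview style).
Everything upstream — read QC, assembly, gene prediction, read alignment, the
BLAST/HMM annotation itself — is out of scope; its outputs are this package's
inputs.

## The statistic

All quantities are read-count shares. With `N` the total clean reads of the
metagenome and `N_g` the reads mapped to genes of genus `g`, the genus
relative abundance is

  R_g = N_g / N.

For a function `f` (say, endoglucanase), the genes carrying at least one
CAZy family curated under `f` define the function's read pool `N_f`; the
genus-restricted sum `N_g-f` gives the genus's share of that pool,

  R_g-f = N_g-f / N_f,

and the **contribution coefficient** is the ratio

  CC(g, f) = R_g-f / R_g.

`CC = 1` is proportional representation: the genus supplies function-`f`
enzyme genes exactly in proportion to its resource occupancy. `CC > 1` marks
over-investment (a contributor when persistent across hydrolase functions),
`CC < 1` under-investment (a cheater when persistent). Two identities pin the
estimator down and are asserted in the test suite: each populated function
column of `R_g-f` sums to 1 over genera (including the `unassigned` bin), and
when every function read carries a genus bin, `sum_g R_g * CC(g, f) = 1` —
the community-weighted mean contribution is always parity. CC is also
invariant under uniform rescaling of all counts, so sequencing depth cancels.

Counting conventions, chosen for fidelity to how family-level CAZyme tallies
are reported:

* **Raw read counts, no length normalization.** The per-gene counts are used
  as the aligner reports them. CC is a ratio of shares built from the same
  counts, so any per-gene bias common to numerator and denominator cancels.
* **Multi-family genes count fully in every family/class they carry** (many
  lignocellulolytic enzymes are multimodular), but only **once per
  function**, even when several of their families map to that function.
* **Genus strings are used verbatim**, including composite bins such as
  `unclassified_f__Bacillaceae`; genes without a genus rank form the
  `unassigned` bin, which participates in all matrices.
* The `R_g` denominator is total clean reads `N` by definition; an
  `abundance_denominator = "annotated"` flag switches consistently to the
  mapped-read sum (all CCs then rescale by the mapped fraction — the tests
  verify exactly that relation).

## The function ontology

The packaged `function_map.tsv` is a frozen, curated transcription of a
published family-level inventory for a thermophilic cellulolytic consortium:
15 categories (three cellulases, two xylan main-chain hydrolases, a mannan
main-chain category, six debranching-enzyme categories, carbohydrate
esterases, lignin-modifying auxiliary activities, and binding modules), plus
substrate roll-ups `cellulose`, `hemicellulose`, `lignin`. A family may carry
several categories (GH51 carries four); subfamily blocks (`GH5`, `GH43`)
count as one family and absorb their subfamily labels, while exact subfamily
entries (`GH30_8`) take precedence over parent rollup. It is a curation, not
a derivation from CAZy releases — users can substitute their own TSV.

Curation decisions worth knowing:

* Where the inventory's per-family activity descriptions and the narrative
  per-function enumerations disagree, the enumerations win for category
  membership (they define the headline counts); the inventory wins for which
  families exist. Hence β-glucuronidase activity noted for GH1/GH30_8 does
  not place them in the 7-family uronic-acid `glucuronidase` set, and the
  main-chain mannan category keeps its 3-family curation (GH1, GH2, GH5)
  with GH26/GH113 retained under their other activities.
* One family label (`CH88`) is normalized to `GH88`, recorded in the
  fixture's `source_note`.
* `alpha_rhamnosidase` holds the two explicitly enumerated families (GH78,
  GH106); a summary count of three circulates alongside the two-family
  enumeration, and the enumeration was kept.
* `binding_module` is profiled but excluded from contribution functions and
  role calls: CBMs bind rather than cleave.

## Role calls

No numeric contributor/cheater rule is standard; the package makes the
qualitative notion explicit and configurable. Over the twelve catalytic
hydrolase functions (AA and esterase columns excluded by default — cheaters
typically retain those), a genus is a **contributor** when at least
`cheater_quantile` (default 75%) of its defined CCs exceed
`contributor_cutoff` (default 1), a **cheater** when at least that fraction
fall below `cheater_cutoff` (default 1), otherwise **intermediate**; genera
with no defined cells are **undetermined**. All three knobs are arguments of
`classify_roles()` and the `cazy_cc()` wrapper. Undefined cells (zero
abundance or empty function pool) are `NA` throughout and are never rendered
as zeros.

## The synthetic generator

Raw sequencing data are deliberately not consumed, so validation rests on a
generator that simulates the annotation layer itself:

1. each of `n_genes` genes draws a genus from the target profile (the
   remainder of the profile mass is the `unassigned` bin);
2. a gene of genus `g` becomes a CAZyme of category `f` with absolute
   probability `(1 - noncazyme_fraction) * base[f] * m[g, f]` — the
   allocation multiplier `m` scales enzyme investment without
   renormalization, so a uniformly low `m` genuinely means more non-CAZyme
   genes, which is what cheating is; the gene then draws a family uniformly
   within the category (subfamily blocks emit a concrete subfamily label);
3. reads are allocated hierarchically: genus totals are multinomial at the
   profile, then spread over the genus's genes with unit-mean gamma weights
   of variance `dispersion` (a Dirichlet-multinomial), giving the
   overdispersed per-gene coverage real catalogs show while keeping
   recovered abundances read-sampling limited (SE halves when depth
   quadruples).

Because families are shared between categories, the realized CC of a genus
is not the raw multiplier: the asymptotic value is the family-blended
investment divided by the community-weighted mean for that function (the
parity identity forces this). `expected_cc()` evaluates that expectation in
closed form, and `simulate_catalog()` returns it as the ground truth that
recovery tests assert against; it equals `m` exactly when families are
category-exclusive and profile-weighted multipliers average 1 — in
particular, all-multipliers-1 designs have expected CC exactly 1.

### The consortium preset

`tmc7_preset()` emulates a nine-genus thermophilic consortium with the
dominant-genus abundance profile fixed at the published composition (42.85%,
18.41%, 10.44%, 7.48%, 2.65%, 2.47%, 2.33%, 1.56%, 1.26%; 10.55%
unassigned). Planted structure: the two dominant genera over-invest in
hydrolases (`m = 1.25`), two rare genera cheat (`m = 0.2` on hydrolases,
`1.5` on AA/esterase), and the remaining five specialize — high (`1.7`) on
one block of functions, low (`0.4`) on the other, split along the
main-chain/debranching divide so that the planted pattern survives family
sharing. The closed-form expected CC of this design keeps every intermediate
genus at 6/12 functions on each side of parity with healthy margins, every
contributor cell above 1 and every cheater cell near 0.18.

Preset sizes were chosen once, by a power argument rather than realism in
every dimension: recovering per-cell CC requires roughly 25+ CAZyme genes
per genus-function cell for the rarest (1.26%) genus, giving
`n_genes = 50000` with `noncazyme_fraction = 0.5` at a depth of `1e6` reads
(about 17 reads per gene). A real catalog of this kind has a far lower
CAZyme gene share (~3.5%); at desk scale that density leaves single-digit
genes per cell and no recoverable structure, so the preset deliberately
enriches CAZymes and documents the deviation here. `dispersion = 0.3` gives
per-gene coverage with variance 30% above Poisson-proportional, a moderate
overdispersion. What passing recovery tests shows is therefore that the
estimator and role rule work at realistic relative abundances and planted
effect sizes under overdispersed counts — not that they would resolve the
same structure at a real catalog's CAZyme density, where per-cell noise
dominates for sub-2% genera.

## Worked example

```{r example}
cfg <- tmc7_preset(seed = 42, n_genes = 8000, total_reads = 2e5)
sim <- simulate_catalog(cfg)
fit <- cazy_cc(sim$catalog)
fit
summary(fit)
```

The planted cheaters sit at CC ~0.2 across hydrolase columns; compare any
cell against the design's ground truth:

```{r truth}
round(coef(fit)["Symbiobacterium", c("endoglucanase", "beta_xylosidase")], 2)
round(sim$truth$expected_cc["Symbiobacterium",
                            c("endoglucanase", "beta_xylosidase")], 2)
```

(This vignette-sized run is noisier than the full preset; role recovery
tests run at `n_genes = 50000`, depth `1e6`.)

## Numerical and degenerate-input choices

* Reported percentages round half-up to 2 decimals (matching how such
  tables are printed); all internal arithmetic is full precision.
* Result tables are written as UTF-8 TSV in C-locale lexicographic order of
  the first column unless a table carries an explicit order, so outputs are
  byte-stable across sessions and locales.
* The Circos export writes the integer `N_g-f` matrix in the tableviewer
  dialect and round-trips exactly; column sums equal `N_f` by construction.
* Zero-read functions stay in the matrices flagged with `NA` columns; empty
  catalogs profile to all-zero tables; `total_reads` below the mapped sum,
  duplicate gene identifiers, negative counts and malformed family labels
  are hard errors naming the offenders.
* Genera below 1% abundance are pooled into `others` only in the report
  table, never in the matrices.

## Known limitations

* The genus-share interpretation of published per-function percentages is
  read-based here; a gene-count mode (`mode = "genes"`) is provided because
  "share of degradation genes" can be read either way.
* No significance test for CC different from 1 is offered — there is no
  agreed null model for read-share ratios with gene-level overdispersion;
  CC values for sub-percent genera rest on few genes and should be read
  qualitatively.
* The ontology is a frozen curation for lignocellulolytic consortia; other
  substrates need a user-supplied map.
* The generator simulates annotations, not sequences: mis-assembly,
  chimeric genes, mis-binned taxonomy and annotation error are all outside
  what passing tests demonstrate.
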