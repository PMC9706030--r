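# cazycontrib

Who contributes the enzymes, and who just eats the sugar? In
lignocellulose-degrading microbial consortia the depolymerizing enzymes
(CAZymes — glycoside hydrolases, carbohydrate esterases, auxiliary
activities) are public-goods machinery: the sugars they release feed the
whole community, so a consortium can carry abundant members that contribute
few lignocellulolytic genes ("sugar cheaters"). Taxonomic abundance alone
cannot separate degraders from freeloaders.

`cazycontrib` profiles a consortium shotgun metagenome at the annotation
layer and estimates, per genus and per lignocellulolytic function, the
**contribution coefficient**

```
R_g   = N_g / N            genus relative abundance (read share)
R_g-f = N_g-f / N_f        genus share of function f's CAZyme reads
CC    = R_g-f / R_g
```

where `N` is the total clean read count, `N_f` the reads on genes carrying a
CAZy family curated under function `f`, and `N_g-f` the genus-restricted
part. `CC = 1` is proportional representation; persistently `CC > 1` across
hydrolase functions marks a contributor, persistently `CC < 1` a cheater.
The package is aimed at microbiome researchers who already have the standard
gene-level tables (per-gene read counts, lineages, dbCAN-style family hits)
and want the genus-by-function read-share matrices, the CC heatmap matrix,
role calls, and a Circos tableviewer export.

It ships:

* `read_catalog()` / `write_catalog()` / `write_table()` — TSV I/O and
  validation for the gene catalog;
* a curated, editable CAZy family→function ontology
  (`load_default_map()`, `families_for()`, `categories_of()`) covering
  cellulases, hemicellulose main-chain and debranching hydrolases,
  esterases, lignin-modifying AAs and binding modules;
* `cazyme_profile()`, `genus_abundances()`, `cazyme_read_fraction()` —
  class/family/section summaries;
* `function_distribution()`, `contribution_coefficients()`,
  `classify_roles()`, `export_circos_table()` — the distribution and CC
  matrices;
* `cazy_cc()` — the one-call fit returning a classed object with `print`,
  `summary`, `coef`, `residuals`, `plot` (heatmap) and `simulate` methods;
* a synthetic annotation generator (`sim_config()`, `simulate_catalog()`,
  `tmc7_preset()`, `expected_cc()`) with planted contributor/cheater
  structure and closed-form ground truth, so the whole pipeline is testable
  without sequencing data.

## Worked example

Simulate a nine-genus consortium with two planted cheaters and fit the
model (a desk-sized run; the validation suite uses 50,000 genes at 10^6
reads):

```r
library(cazycontrib)
cfg <- tmc7_preset(seed = 42, n_genes = 8000, total_reads = 2e5)
sim <- simulate_catalog(cfg)
fit <- cazy_cc(sim$catalog)
fit
#> Genus contribution model (CC = R_g-f / R_g)
#>   catalog: 8000 genes, N = 200000 clean reads (total denominator)
#>   10 genera x 14 functions; CAZyme reads: 53.87% of N
#>   roles: 1 contributor, 7 intermediate, 2 cheater, 0 undetermined
head(summary(fit), 4)
#>                  genus abundance n_functions median_cc min_cc max_cc         role
#>      Ruminiclostridium    0.4274          14     1.146  0.834  1.195  contributor
#>  Thermoanaerobacterium    0.1838          14     1.065  0.677  1.184 intermediate
#>             unassigned    0.1066          14     0.946  0.521  1.349 intermediate
#>            Geobacillus    0.1046          14     0.982  0.539  1.621 intermediate
round(coef(fit)["Symbiobacterium", c("endoglucanase", "beta_xylosidase")], 2)
#>   endoglucanase beta_xylosidase
#>            0.37            0.14
```

The recovered abundances track the planted profile (42.74% vs 42.85% for
the dominant genus), both planted cheaters are called at CC far below
parity, and at this reduced depth one planted contributor lands
intermediate — per-cell CC noise shrinks with the gene count per
genus-function cell, which is why the full-size validation runs recover all
planted roles (see the vignette for the power reasoning).

Real data enter through the three TSVs instead of the simulator:

```r
cat <- read_catalog("genes.tsv", "taxonomy.tsv", "cazy.tsv",
                    total_reads = 83777510)
fit <- cazy_cc(cat)
write_table(as_table(fit$cc), "cc_matrix.tsv")
export_circos_table(fit$distribution, "circos_input.txt")
```

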