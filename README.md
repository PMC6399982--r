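# bloodcoex

Weighted gene co-expression network analysis for case-control blood
transcriptomes, built as a single tested pipeline: expression filtering and
QC, unsigned network construction with data-driven soft-threshold
selection, topological-overlap clustering with a tree-based dynamic cut,
module eigengenes and module–trait association, intramodular hub genes,
hypergeometric cell-type and cross-study gene-list enrichment, and
per-gene mixed-effects (REML) differential expression.

The motivating setting is peripheral-blood transcriptomics of
intracerebral hemorrhage (ICH) versus vascular-risk-factor-matched
controls: groups of co-expressed genes (modules) often track specific
blood cell types (neutrophils, monocytes, T cells, NK cells,
erythroblasts), and the modules whose overall expression shifts with
diagnosis — together with their most interconnected ("hub") genes — are
candidate drivers of the peripheral immune response. The package is
equally applicable to any two-group log2-expression study with batch and
demographic covariates.

## The model in brief

* **Network**: Pearson correlation `cor(x_i, x_j)` between genes; unsigned
  adjacency `a_ij = |cor_ij|^β`. β is the lowest candidate whose signed
  scale-free fit R² of the connectivity distribution reaches 0.8.
* **Topological overlap**:
  `ω_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  `ℓ_ij = Σ_u a_iu a_uj`; genes overlap when they share neighbors.
* **Modules**: average-linkage clustering of `1 − ω`; branches with ≥ 100
  genes accepted by a tree cut; each module summarized by its eigengene
  (first principal component of standardized member expression).
* **Module–trait association**: Pearson correlation of each eigengene with
  the trait (diagnosis coded CTRL = 0 / ICH = 1), Student-t p on n − 2 df;
  modules selected at nominal p < 0.05.
* **Hubs**: top 5% of each module by intramodular connectivity
  `kIN_i = Σ_{j in module} a_ij`.
* **Enrichment**: exact hypergeometric upper tail P(X ≥ q) computed in
  log space (module vs cell-type signature, DEG list vs external DEG
  list).
* **Differential expression**: per gene,
  `y ~ diagnosis + sex + diagnosis:sex + age + time + (1 | scan_date)`
  fitted by REML; the diagnosis p-value tests the sex-averaged
  (least-squares-means) ICH − CTRL contrast; BH-FDR across genes; signed
  fold change `2^Δ` (reported as −1/ratio below 1); significant when
  FDR < 0.05 and |FC| > 1.2.

A synthetic-data generator (`sim_config()` / `generate_dataset()`)
produces log2 expression with planted latent-factor modules, diagnosis
shifts on selected module factors, sex/age/batch/draw-time covariate
effects, cell-type gene sets, low-expressed genes built to fail the QC
filters, and a ground-truth table — so every stage is testable without
external data.

## Worked example

```r
library(bloodcoex)

cfg <- pipeline_config(
  simulation = sim_config(n_genes = 1000L,
                          module_sizes = c(180L, 150L, 120L),
                          dx_effect_sizes = c(1.0, 0, 0), seed = 42),
  min_module_size = 80)
res <- run_pipeline(cfg)
res
#> Co-expression pipeline result
#>   900 genes x 66 samples after QC
#>   soft-threshold power: 13
#>   3 modules (sizes 177, 131, 115), 477 grey
#>   diagnosis-significant modules: turquoise
#>   DE genes (FDR & FC rule): 130 of 900
```

The 1000 simulated genes contain three planted modules; 100 low-expressed
genes are removed by the two expression filters (900 remain). The tree
cut recovers the three modules (sizes 177/131/115 of 180/150/120 planted;
the rest of the genes are unassigned, "grey"). Only the module whose
latent factor was shifted in ICH (turquoise, planted effect 1.0 SD) is
flagged by the eigengene–diagnosis association:

```r
res$module_trait$diagnosis[order(res$module_trait$diagnosis$p_value), ][1:3, ]
#>      module     trait correlation      p_value significant
#> 1 turquoise diagnosis  0.54218477 2.575442e-06        TRUE
#> 3     brown diagnosis -0.15924611 2.015419e-01       FALSE
#> 2      blue diagnosis -0.09687553 4.390456e-01       FALSE
```

Each module's hubs are its top-5% most intramodularly connected genes,
and each module is strongly enriched for its planted cell-type signature:

```r
head(res$connectivity[res$connectivity$hub, c("gene_id", "module", "kIN")], 3)
#>     gene_id    module      kIN
#> 75   G00075 turquoise 2.076652
#> 151  G00151 turquoise 1.860142
#> 155  G00155 turquoise 1.854234

res$enrichment[1:3, c("module", "gene_set", "overlap", "p_value")]
#>      module   gene_set overlap      p_value
#> 1 turquoise neutrophil     106 3.133358e-62
#> 5      blue   monocyte      83 2.055403e-57
#> 9     brown      tcell      69 5.715339e-53
```

130 of 900 genes pass the differential-expression rule (FDR < 0.05 and
|FC| > 1.2); the turquoise module carries the planted diagnosis effect,
so its members dominate that list. With `output_dir` set, every table
above is written as TSV together with a `run_log.txt` recording all
parameters.

A command-line front end lives at `inst/cli/bloodcoex.R`
(`simulate`, `run`, `run-sim` subcommands).

## Layout

* `R/` — implementation (simulation, preprocessing, network, modules,
  traits, enrichment, differential expression, I/O, pipeline).
* `tests/testthat/` — unit, property and acceptance tests with
  independent oracles in `helper-oracles.R`.
* `vignettes/bloodcoex-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the generator does and does not
  emulate, numerical decisions, limitations.
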