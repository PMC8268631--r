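# somatlas

**SOM portraits of paired expression and methylation cohorts.**

`somatlas` is an R package for *molecular cartography* of bulk omics
cohorts — the kind of analysis used to map the transcriptome and methylome
landscapes of glioma subtypes. It takes a gene × sample expression matrix
(log10 scale), a CpG × sample promoter methylation table, gene annotation
and patient phenotypes, and produces:

- **metagene portraits** — each sample (or subtype mean) rendered as a
  K × K image of a self-organizing map trained on gene profiles;
- **spot modules** — connected map regions of co-expressed (or
  co-methylated) genes, with per-sample calls, spot-number distributions
  and implication networks;
- **gene-set machinery** — GSZ scores (hypergeometric set-sum z per
  sample), gene-set maps over the grid, Fisher overlap tests;
- **phenotype maps** — per-unit Cox hazard ratios (prognostic map),
  covariate correlation maps (age, telomere-length ratio), female
  difference scores, Kaplan–Meier/log-rank for spot-defined groups;
- **layer integration** — expression–methylation covariance maps and the
  network of anti-correlated, gene-overlapping spot pairs that marks
  promoter-methylation-coupled modules.

A synthetic cohort generator plants subtype modules, methylation coupling
and survival hazards with known ground truth, so every stage of the
pipeline has a recovery test.

## The core model

Genes are points in sample space. A batch SOM compresses them onto a grid
of *metagenes* (codebook vectors): each epoch assigns genes to their
Euclidean best-matching unit, then updates every unit to the
Gaussian-neighborhood-weighted mean of the gene profiles, the radius
annealing linearly before freezing. The GSZ score of a gene set in sample
*s* with all-gene mean μ_s and population variance σ²_s is

    GSZ_s = (Σ_{g∈set} e_gs − n·μ_s) / sqrt(n·σ²_s·(N−n)/(N−1))

— standardized against drawing the set at random, so random sets score
mean 0, variance 1 exactly. Per-unit prognostic values are Cox log hazard
ratios per metagene SD (Newton–Raphson, Breslow ties). Coupled spots are
expression/methylation spot pairs with Fisher overlap p < 10⁻³ and
anti-correlated profiles.

## Worked example

```r
library(somatlas)

cfg <- cohort_config(n_genes = 1200, n_samples = 60, n_subtypes = 3,
                     n_modules = 3, genes_per_module = 80, seed = 7)
cohort <- generate_cohort(cfg)
print(cohort$truth)
#> Planted cohort truth: 3 modules ( 80, 80, 80 genes ), 3 subtypes; 2 methylation-coupled module(s)

expr   <- drop_sex_chromosomes(cohort$expr, cohort$annotation)
#> removed 24 gene(s) on chrX/chrY
expr_c <- center_genes(quantile_normalize(expr))
esom   <- train_som(expr_c, som_params(grid_k = 15, epochs = 20, seed = 1))
print(esom)
#> Batch SOM: 15 x 15 grid, 1176 genes, 60 samples
#>   epochs: 20  radius: 7.5 -> 0.5  init: pca_linear
#>   final quantization error: 7.0591

labels <- setNames(cohort$phenotype$subtype, cohort$phenotype$sample_id)
spots  <- detect_spots(overexpression_summary_map(esom, labels), esom,
                       q = 0.95, connectivity = 4)
print(spots)
#> 3 spot(s) (overexpression, q = 0.95, min_size = 3, 4-connectivity)
#>   A: 4 units, 47 genes, peak 0.7109
#>   B: 4 units, 45 genes, peak 0.7023
#>   C: 3 units, 49 genes, peak 0.6868

module_recovery(cohort$truth, spots)
#>    module best_spot jaccard n_module_genes
#> 1 module1         B  0.5625             80
#> 2 module2         C  0.6125             80
#> 3 module3         A  0.5875             80
```

Each planted module is found by exactly one spot (gene-set Jaccard 0.56 -
0.61 on this small, noisy cohort; 0.8 - 1.0 at the default study scale).
The prognostic map recovers the planted adverse module — the generator
ties survival hazard to module 1 (log-hazard log 2):

```r
surv <- data.frame(sample_id = cohort$phenotype$sample_id,
                   time  = cohort$phenotype$surv_time,
                   event = cohort$phenotype$surv_event)
pm <- prognostic_map(esom, surv)
print(pm)
#> Phenotype map (log_hr): 15 x 15, 225/225 valid units, range [-0.4908, 0.5007]

adverse_units <- unique(esom$bmu[cohort$truth$module_members$module1])
median(pm$grid[adverse_units])            # 0.349  <- elevated hazard
median(pm$grid[-adverse_units])           # -0.006 <- background
```

Units hosting module-1 genes carry a median log-HR of 0.349 per metagene
SD (HR ≈ 1.42 per SD; the planted per-activity-unit HR is 2), while the
rest of the map sits at zero. `plot(pm)` renders the blue–white–red map;
`covariance_map()`, `build_em_network()` and `sample_similarity()` continue
the analysis into the methylation layer.

The whole chain — simulate → preprocess → train both layers → spots →
gene sets → phenotype maps → integration — also runs as one call with a
config list or YAML file:

```r
run_pipeline(list(seed = 1,
                  som_expr = list(grid_k = 50), som_meth = list(grid_k = 30)),
             out_dir = "out")
```

writing all tables (TSV/CSV/GraphML) plus a manifest with parameters and
MD5 checksums; reruns with the same seed are byte-identical.

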