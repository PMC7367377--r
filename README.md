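# ssnet — sample-specific network functional biomarkers

`ssnet` identifies network-level biomarkers from a tumor/normal expression
cohort. Instead of asking which genes are differentially expressed, it asks
which *interactions* each individual sample perturbs, aggregates those
perturbations across the cohort into a functional network, and then screens
that network's genes and edges as diagnostic, subtyping and prognostic
markers. It was built for colon adenocarcinoma-style cohorts (hundreds of
tumors, tens of normals, a scored protein-interaction background network)
but is agnostic to tissue.

## The method

With *n* reference (normal) samples, every background edge gets a reference
Pearson correlation PCC<sub>ref</sub>. Adding one query sample and
recomputing gives a differential correlation per edge,

&nbsp;&nbsp;ΔPCC = PCC<sub>n+1</sub> − PCC<sub>ref</sub>,&nbsp;&nbsp;
z = ΔPCC / ((1 − PCC<sub>ref</sub>²)/(n − 1)),

and the significantly perturbed edges form that sample's **sample-specific
network (SSN)**. Tumor SSNs minus the union of normal SSNs, aggregated with
a strict >90% tumor-frequency rule, give the **functional network**; genes
with degree > 3 are **core genes**. Over-representation of the functional
genes in known gene sets uses the upper hypergeometric tail

&nbsp;&nbsp;p = Σ<sub>i≥k</sub> C(A,i)·C(N−A,n−i)/C(N,n)

with an explicit universe size N. Downstream modules provide a
class-balanced cross-validated SVM (tumor vs normal, pooled ROC/AUC),
consensus-clustering subtyping with representative one-vs-rest DEG
signatures and subtype–feature association, and survival screening of genes
(expression) and edges (per-sample ΔPCC) by median split, log-rank,
univariate and confounder-adjusted Cox, with LASSO-Cox panel selection.

Two statistical points documented in the methods vignette
(`vignettes/ssn-functional-biomarkers.Rmd`): the far tail of z is not
Gaussian but the product of two independent standard normals, and the
cohort-level pipeline (`ssn_functional_pipeline()`) therefore defaults to
that exact null plus per-sample Benjamini–Hochberg correction — without it,
the union of normal SSNs deletes ~87% of the network at 40 normals and
consistently perturbed edges cannot survive.

A synthetic-cohort generator (`simulate_cohort()`) emulates the structures
the pipeline assumes — correlated reference expression over a background
network, tumors that consistently perturb planted edges, six mean-shifted
subtypes, proportional-hazards survival, subtype-linked mutations — with
ground truth attached, so every stage is testable without any download.

## Worked example

```r
library(ssnet)

sim <- simulate_cohort(sim_config(seed = 1))
sim$expr
#> expression_matrix: 200 genes x 141 samples (100 tumor, 41 normal)

pipe <- ssn_functional_pipeline(sim$expr, sim$background)
pipe$functional_net
#> functional_network: 40 genes, 20 edges (frequency > 0.9 over 100 tumors)
head(pipe$functional_net$edges, 3)
#>   gene_a gene_b frequency
#> 1  g0003  g0179      0.96
#> 2  g0013  g0040      0.96
#> 3  g0017  g0019      0.95

# all 20 planted edges recovered, nothing else
setequal(with(pipe$functional_net$edges, paste(gene_a, gene_b, sep = "|")),
         sim$truth$planted_edges)
#> [1] TRUE

enrich_collection(pipe$functional_net$genes, sim$gene_sets)[, c("set", "A", "k", "p")]
#>               set  A  k            p
#> 1   planted_exact 40 40 4.877673e-43
#> 2 overlap_k10_A40 40 10 2.490816e-01
#> 3  overlap_k5_A25 25  5 5.899186e-01
#> 4  overlap_k0_A15 15  0 1.000000e+00
#> 5          random 30  4 8.966459e-01

crossval_auc(subset_expression(sim$expr, genes = pipe$functional_net$genes),
             seed = 1)
#> classification_result: pooled AUC = 1.00000 over 3 subgroups (1.000, 1.000, 1.000)
```

The functional network contains exactly the 20 planted edges (frequency =
the fraction of tumor SSNs containing each edge); the gene set equal to the
planted genes is overwhelmingly enriched while random or partially
overlapping sets are not; and the functional-gene expression panel separates
tumors from normals perfectly under subgroup-balanced 5-fold
cross-validation.

For real data, `read_expression_table()`, `read_scored_edges()` (STRING
export dialect, strict `score > 300` filter), `read_gmt()`,
`read_clinical_table()` and `read_mutation_table()` load the standard
formats; `filter_expressed_genes()` applies the >50%-expressed rule.

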