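# dmgscan

Differential mutation analysis of case-control exome cohorts from
SIFT-annotated SNV tables.

Tumour classes with different prognosis — hormone-receptor status, grade,
stage — can differ not only in gene expression but in which genes carry
deleterious mutations. dmgscan is for analysts who have per-sample SNV
annotation tables (ANNOVAR-multianno-style TSV or annotated VCF, with gene,
transcript isoform and SIFT score) plus a sample-to-class design table, and
want to know which **genes** are differentially mutated between two classes
and which individual **SNVs** occur at significantly different carrier
frequencies.

## The method

**Gene burden score.** SIFT annotations are filtered at the conventional
deleterious threshold (score ≤ 0.05); the burden of gene *i* in sample *j*
sums over its retained mutations *k*, averaging 1 − SIFT over the $N_k$
transcript isoforms each mutation is annotated on:

$$D_{ij} = \sum_k \frac{\sum_x (1 - S_{ijkx})}{N_k}$$

Each mutation contributes 0.95–1 regardless of isoform count, so the score
is an isoform-normalised, confidence-weighted deleterious mutation count.

**Differentially mutated genes (DMGs).** After dropping genes deleteriously
mutated in fewer than 5 samples, each gene's scores are compared between the
two classes with a two-sided two-sample t-test (pooled variance by default);
genes at p ≤ 0.001 are reported with Benjamini–Hochberg FDRs and fold
changes of class means (`Inf` when one class has zero burden).

**Differential SNVs.** Within DMGs, per-SNV carrier 2×2 tables give raw
cross-product odds ratios (zero cells reported as 0/`Inf`, no continuity
correction) and two-sided Fisher exact p-values (minimum-likelihood
convention, verified exhaustively against an independent implementation).
Reported SNVs must be ≥2-fold enriched in either direction, p ≤ 0.05, and —
by default — lie inside an annotated protein domain.

A seeded synthetic cohort generator (`simulate_cohort()`) produces sparse
annotated cohorts with planted gene burdens and planted differential SNVs,
so power and type-I behaviour are measurable; `stability_consensus()`
implements the two-of-three consensus rule for protein-stability
predictions; `run_pipeline()` + a YAML config drive the whole analysis with
a JSON run manifest.

## Worked example

Odds ratios and Fisher p-values for the ER-status SNV carrier counts
shipped with the package (from a published 98-tumour breast-cancer exome
cohort; counts are carriers out of class size, per class):

```r
library(dmgscan)
tab <- readr::read_tsv(system.file("extdata", "snv_carrier_counts.tsv",
                                   package = "dmgscan"))
er <- tab[tab$comparison == "ER", ]
res <- tibble::tibble(
  gene = er$gene_symbol,
  odds_ratio = odds_ratio(er$carriers_a, er$n_a - er$carriers_a,
                          er$carriers_b, er$n_b - er$carriers_b),
  fisher_p = fisher_exact_two_sided(er$carriers_a, er$n_a - er$carriers_a,
                                    er$carriers_b, er$n_b - er$carriers_b))
dplyr::arrange(res, fisher_p)
#> # A tibble: 8 × 3
#>   gene    odds_ratio  fisher_p
#>   <chr>        <dbl>     <dbl>
#> 1 SLC24A1     11.9   0.0000211
#> 2 PPP2R4      13.1   0.000429
#> 3 DPP3         0.15  0.000507
#> 4 GPR157       0.152 0.00101
#> 5 CSN3         5.89  0.00159
#> 6 FAM209B      7.2   0.00263
#> 7 KRT74        5.6   0.00453
#> 8 ERBB2        0.227 0.00624
```

SLC24A1's variant is carried by 23/27 ER− vs 13/40 ER+ samples — an
11.9-fold enrichment in the ER− class, p = 2.1×10⁻⁵; ERBB2's variant runs
the other way (OR 0.23), enriched in ER+ tumours.

On a synthetic cohort with one planted class-B burden (Δ mean score 0.6,
30 + 30 samples), the gene-level test recovers exactly the planted gene:

```r
sim <- simulate_cohort(simulation_config(
  n_samples_a = 30, n_samples_b = 30, n_genes = 200,
  planted_genes = tibble::tibble(gene = "PLANT", class = "B",
                                 burden_delta = 0.6),
  seed = 11))
m <- filter_low_prevalence(score_matrix(sim$variants, sim$design), 5)
compare_classes(m, sim$design, "class", "A", "B")
#> # A tibble: 1 × 9
#>   gene_symbol   p_value     fdr mean_a mean_b fold_change   n_a   n_b degenerate
#>   <chr>           <dbl>   <dbl>  <dbl>  <dbl>       <dbl> <int> <int> <lgl>
#> 1 PLANT         1.40e-8 2.75e-6      0  0.599           0    30    30 FALSE
```

The class-B mean of 0.599 matches the planted 0.6; the fold change (class A
over class B) is 0 because class A carries no burden in that gene. `tidy()`
returns the full per-gene table, `glance()` a one-row summary, and
`autoplot()` draws score heatmaps, volcano plots and carrier-frequency
plots for the three result types.

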