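# seedscreen

Seed-effect modeling and off-target cleaning for genome-wide pooled
shRNA screens.

## What problem this solves

Pooled shRNA screens assign each construct an essentiality score
(shES; more negative = stronger anti-proliferative effect). Two
screens of the same library on the same cancer cell lines agree only
moderately at the shRNA level, and a large part of the discrepancy is
*seed-mediated off-target activity*: an shRNA silences every
transcript whose 3' UTR pairs with the guide strand's seed region
(nucleotides 2–8), so part of its phenotype belongs to its seed 7-mer,
not its intended target.

`seedscreen` is for analysts of loss-of-function screens who want to

* quantify how reproducible two screens are at the shRNA, seed, and
  gene level (Spearman rank correlation over matched cell lines);
* estimate seed-driven phenotypes by averaging shESs over *shRNA
  families* — constructs sharing a seed — giving the seed essentiality
  score `seedES = mean(shES | same seed 2–8)`, with the position-12–18
  heptamer and permuted seed maps as negative controls;
* summarize shRNAs to gene essentiality scores with GARP (mean of the
  two most essential shRNAs per gene) or a Kolmogorov–Smirnov
  running-sum enrichment score (RIGER-style);
* remove shRNAs whose seeds have high off-target propensity — strong
  seed pairing stability (SPS below the 10th percentile) or low target
  abundance (TA above the 90th percentile) — and measure the gain in
  between-screen consistency;
* detect genetic-interaction (GI) and synthetic-lethal (SL) partners
  of driver genes by comparing gene scores between mutated and
  wild-type cell lines (Wilcoxon rank-sum; two-sided 0.05 for GI,
  one-sided 0.03 for SL), and show that cleaning makes partner lists
  more reproducible between screens;
* generate fully ground-truthed synthetic two-screen studies
  (`simulate_screens()`) to validate all of the above.

## A worked example

```r
library(seedscreen)

sim <- simulate_screens(smoke_config(rng_seed = 7))  # 200 genes x 5 shRNAs, 8 cell lines
res <- run_pipeline(sim)

glance(res$baseline)
#>   level n_pairs mean_rho sem_rho
#> 1 shrna       8    0.578  0.0109
glance(res$seed_consistency)
#>   level n_pairs mean_rho sem_rho
#> 1 seed        8    0.753  0.0194
res$cleaning_test
#>   statistic    p_value sidedness         method
#> 1      13.5 0.00000140 one_sided_greater paired_t
res$gi$pr
#> $before: n_hits 33, tp 12, precision 0.364, recall 0.375
#> $after:  n_hits 39, tp 16, precision 0.410, recall 0.500
```

Reading the numbers: the two simulated screens agree at rho = 0.58
shRNA-by-shRNA, but averaging within seed families lifts the matched
correlation to 0.75 — the seed-driven component is *shared* between
screens even though gene-level summaries treat it as noise. Removing
high off-target-propensity shRNAs significantly improves gene-level
concordance (paired t-test, p = 1.4e-6 across the 8 matched cell
lines), and both precision and recall of planted synthetic-lethal
partners rise after cleaning. `autoplot()`, `plot_family_size_curve()`,
`plot_class_consistency()` and `plot_overlap()` draw the corresponding
figures, and `run_pipeline(..., out_dir = )` writes every report as
TSV with a JSON manifest.

Real data enter through plain TSV readers (`read_es_matrix()` — GCT
1.2 supported via `format = "gct"` —, `read_shrna_annotations()`,
`read_seed_properties()`, `read_genotype_panel()`,
`read_matched_pairs()`, `read_replicates()`).

See `vignette("seed-effects")` for the model, the simulator's
generative assumptions, and the design decisions.

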