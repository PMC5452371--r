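---
title: "Seed-effect modeling and cleaning of pooled shRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-effect modeling and cleaning of pooled shRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide pooled shRNA screens estimate, for every construct in a
library, how strongly its expression depresses proliferation of a cell
line: the shRNA essentiality score (shES; more negative = more
essential). When two laboratories screen the same library on the same
cell lines, the shES profiles agree only moderately. A major reason is
that an shRNA silences not only its intended target but also every
transcript whose 3' UTR pairs with the *seed* region of its guide
strand (nucleotides 2–8). These miRNA-like off-target effects are a
property of the seed 7-mer, not of the intended target, and they are
*reproducible*: both screens carry them, but gene-level summaries
scramble them into apparent noise.

`seedscreen` implements the analysis workflow built on that
observation:

1. **Seed essentiality scores (seedES).** Group shRNAs into *families*
   sharing the seed 7-mer (`build_families()`, window 2–8 by default)
   and average member shESs per cell line (`family_es()`). The number
   of members is the *family size*; averaging over a family estimates
   the shared seed-driven phenotype with variance shrinking as
   1/size. Families larger than 14 members are dropped, below which
   point size bins become too sparse to compare (fewer than about 50
   families).
2. **Controls.** The same construction applied to guide positions
   12–18 — a region that does not drive target recognition — gives
   the heptamer control (`sliding_window_scan()` repeats the analysis
   at every window start). Permuting the shRNA-to-seed mapping
   (`permute_seed_map()`, size-multiset preserving) destroys family
   structure while keeping the score distributions.
3. **Gene summaries.** `garp()` (mean of a gene's two most essential
   shRNAs; a single shRNA stands as its own summary) and `riger_ks()`
   (unweighted Kolmogorov–Smirnov running-sum enrichment of a gene's
   shRNAs in the genome-wide ranking, with optional size-matched
   permutation normalization). `riger_ks` makes no claim of bit
   compatibility with the GENE-E implementation, whose internals are
   not public; the KS running sum is taken at face value. Note the
   sign conventions differ: GARP keeps the more-negative-is-essential
   scale, while a riger_ks score near +1 marks a gene whose shRNAs
   concentrate at the essential end.
4. **Seed-property cleaning.** Each seed 7-mer has a predicted seed
   pairing stability (SPS, more negative = stronger duplex) and a
   target-site abundance (TA). `derive_thresholds()` cuts both
   distributions at their 10th/90th percentiles; seeds below the
   strong-SPS cut or above the low-TA cut mark shRNAs with high
   off-target propensity, and `clean_dataset()` removes them (default
   policy: either flag suffices). The TA convention is literal to the
   source tables — the "low TA" class sits at *large* ta values — and
   a `ta_direction` flag accommodates tables using the intuitive
   direction.
5. **Consistency analysis.** All between-screen concordance is
   Spearman rank correlation over matched cell lines
   (`matched_correlation()`), because the two screens score abundance
   changes on different scales (normalized fold change vs
   shARP-style slopes); `nonmatched_baseline()` gives the background
   attributable to library structure alone, `replicate_qc()` drops
   cell lines with mean pairwise replicate correlation below 0.5, and
   `compare_reports()` compares paired per-cell-line correlations with
   a paired t-test when a Shapiro–Wilk gate (alpha = 0.05) accepts
   normality of the differences, a Wilcoxon signed-rank test
   otherwise.
6. **Genetic interactions.** `detect_partners()` compares a partner
   gene's GARP scores between driver-mutated and wild-type cell lines:
   two-sided Wilcoxon rank-sum at raw alpha 0.05 for genetic
   interaction, one-sided (more negative in mutants) at raw alpha 0.03
   for synthetic lethality, drivers needing at least two mutated
   lines. No multiplicity correction is applied by default, matching
   screening practice for pan-cancer discovery; Benjamini–Hochberg is
   available behind `adjust = "BH"`. `overlap_analysis()` counts
   per-driver partners detected in both screens before and after
   cleaning and tests the increase with a one-sided signed-rank test.

`run_pipeline()` wires these stages together and writes every report
plus a JSON manifest.

## Statistical components

The rank-sum and signed-rank tests switch between an exact and an
approximate branch at a combined sample size of 12: small enough that
exact enumeration is instant, large enough to cover cell-line-panel
comparisons with the exact distribution whenever ties permit. The
approximate branch is the normal approximation with tie and continuity
corrections. Both branches are validated in the test suite against
exhaustive enumeration of label assignments and sign patterns, which is
also why the package owns these wrappers rather than delegating the
policy to a generic library call. The signed-rank test accepts as few
as one non-zero difference so that two-driver overlap comparisons have
a defined (if powerless) p-value.

Percentile thresholds interpolate order statistics with the
median-unbiased rule (`quantile(type = 8)`); the rule is recorded in
the threshold table because cuts this close to distribution tails are
rule-sensitive.

Spearman correlations use pairwise-complete observations; a family's
score is missing only when every member is missing, and missing values
are never imputed anywhere in the pipeline.

## The simulator

`simulate_screens()` generates the paired study the analyses expect,
with full ground truth. Per shRNA *i*, cell line *c*, screen *k*:

$$\mathrm{shES}_{i,c,k} = m_k\big((1 - w_i)\,G_{g(i),c} +
  w_i\,(S_{s(i),c} + d_{i,c,k})\big) + \eta_{i,c,k} + \bar\varepsilon_{i,c,k}$$

* $G$ — on-target gene effects, shared between screens: a base
  essentiality (20% of genes essential, mean −2) plus a cell-line
  component (sd 0.6) carrying the genetic background.
* $S$ — seed effects, shared between screens. Most seeds are mild
  (sd 0.8); 80% of *flagged* seeds (strong SPS or low TA) are *toxic*,
  with base effect near −2: pervasive seed-mediated repression that
  depresses growth in every cell line. Toxicity is treated as largely
  constitutive, so its cell-line component is small (sd 0.05).
* $d$ — a screen-specific off-target deviation (sd 1.2): the part of
  an shRNA's off-target phenotype its seed identity does not capture
  (full-sequence context, expression milieu). Without this term a
  high-$w$ shRNA would be *more* consistent between screens, not less,
  and the strong-SPS subset could not show the reduced concordance the
  analysis is designed to detect.
* $w_i$ — the mixing weight, drawn Beta(8,2) for flagged seeds and
  Beta(2,8) otherwise. Class-driven weights make truth-aligned
  cleaning unambiguous in tests; a continuous coupling would blur the
  class boundaries without adding validation power.
* $\eta$ — a screen-level effect (sd 0.8 / 0.7) shared across that
  screen's replicates: protocol, timing and batch structure. This term
  carries most of the between-screen discordance while keeping
  within-screen replicate correlations realistic (about 0.7–0.85,
  comfortably above the 0.5 QC cut).
* $\bar\varepsilon$ — replicate noise (sd 1.0 / 0.9 per replicate),
  averaged over 4 replicates in screen A and 3 in screen B.
* $m_k$ — screen A is scored as-is; screen B through an affine map
  plus signed cube root, emulating a different scoring pipeline.
  Because every consistency measure is rank-based, any strictly
  increasing $m_k$ gives identical reports at the shRNA level;
  summaries that average scores before ranking (seedES, GARP) commute
  with affine maps exactly and with smooth monotone maps approximately.

Seed families follow a truncated geometric size distribution over
1..14. SPS and TA are drawn with correlation −0.5 so the two
high-propensity classes co-occur, as they do in heptamer property
tables; positions 12–18 draw from a heptamer pool of the same
cardinality as the seed pool, since 7-mer reuse at every position is
combinatorially forced in a genome-scale library.

The genotype panel plants 15 driver genes, each mutated in 6–10 of the
20 cell lines, with 8 synthetic-lethal partner genes per driver whose
gene effect is shifted by −1.8 in mutated lines (in both screens — the
interaction is biology, not assay).

**What the defaults emulate.** The default configuration was fixed
once so that the simulated study sits in the regime reported for
matched pan-cancer shRNA screen pairs: baseline matched shRNA-level
rho near 0.6, seedES consistency (families of six or more) near
0.70–0.75 and rising with family size to about 0.78, a flat permuted
and position-12–18 trace, markedly lower concordance for strong-SPS
and low-TA subsets, GARP gene-level rho improving by roughly +0.07
after cleaning, and cleaning improving the between-screen overlap of
GI partners for most drivers. `smoke_config()` is a 200-gene, 8-line
version of the same conditions that runs the full pipeline in seconds
and backs most of the unit tests; the acceptance analyses run at the
full default scale (1000 genes x 5 shRNAs x 20 cell lines), which
keeps every stage under a few minutes on one CPU.

**What the simulator does not emulate.** Read-count or microarray
deconvolution, PCR and infection noise, hairpin processing
heterogeneity beyond window shifts, copy-number artifacts, and any
correlation between a gene's essentiality and its shRNAs' seed
properties. Passing the simulation-based tests therefore shows the
pipeline recovers planted seed structure under this generative model,
not that any particular real screen pair satisfies the model.

## Numerical and design choices

* Ranking ties in `riger_ks()` break by entity id, making gene scores
  deterministic under score ties.
* `family_size_curve()` reports two error scales: the per-bin SEM over
  matched cell lines (the spread a screen analyst plots as error
  bars), and a bootstrap-over-families SE (`n_boot`) quantifying
  bin-composition uncertainty — the relevant scale when asking whether
  the curve rises monotonically, and the one the acceptance checks
  use (two combined SEs).
* Between-screen correlations use all shared entities
  (pairwise-complete per cell-line pair); matched pairs are always an
  explicit two-column table, never inferred from names.
* `detect_partners()` uses the full cell-line panel rather than the
  QC-passing matched subset: genotype comparisons want power across
  the compendium, and replicate QC addresses between-screen
  concordance, not within-screen validity.
* Synthetic-lethal precision/recall against planted truth is reported
  pooled over the two screens' hit lists
  (`pooled_precision_recall()`): per-screen precision at a raw 0.03
  threshold fluctuates with hits sitting near the cut-off, and
  pooling halves that variance without changing what is measured.
  With ~1000 candidate genes per driver at raw alpha, absolute
  precision is necessarily modest; the informative quantity is its
  change after cleaning.
* The cleaning policy joins the strong-SPS and low-TA flags with OR.
  AND and single-axis policies are selectable because the two axes
  carry partly independent information.

## Known limitations

* `riger_ks()` normalization permutes positions uniformly; it does not
  model the dependence between a gene's set size and shES correlation
  among its shRNAs.
* Threshold derivation assumes enough distinct property values to
  interpolate; degenerate (near-constant) axes are rejected rather
  than approximated.
* The pipeline treats the two screens symmetrically except for the
  scoring transform; asymmetric library subsets (shRNAs present in
  only one screen) are handled by intersection, which discards the
  screen-specific remainder.

## A worked example

```{r, eval = FALSE}
library(seedscreen)

sim <- simulate_screens(smoke_config(rng_seed = 7))
res <- run_pipeline(sim, out_dir = "reports")

glance(res$baseline)            # shRNA-level between-screen consistency
glance(res$seed_consistency)    # seedES consistency, families > 5
res$cleaning_test               # gene-level gain from cleaning
res$gi$overlap_gi$comparison    # GI overlap increase across drivers

autoplot(res$baseline)
fam <- build_families(sim$annotations)
plot_family_size_curve(
  family_size_curve(sim$screen_a, sim$screen_b, fam, sim$matched,
                    min_bin = 10, n_perm = 10, n_boot = 50))
```
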