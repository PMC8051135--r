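# chromstretch

Downstream regulatory-genomics analysis for paired-condition epigenome
studies — a progenitor and a differentiated cell state, each with a
ChromHMM-style chromatin-state segmentation, transcription-factor binding
sites, gene annotation and FPKM expression. The package is aimed at
analysts who already have segmentations and peak calls and need the
statistics that come after: enhancer calling, stretch-enhancer
classification, condition-sharing, binding-site chromatin-transition
classes, motif-density profiles, and an expression-matched permutation
test for stretch-enhancer enrichment near a signature gene set. A
synthetic-data generator with planted, ground-truth-known structure makes
the whole pipeline testable end to end without any external data.

## The core methods

* **Enhancer stitching.** Segments in enhancer states (default {2, 3}) are
  merged with the `mergeBed -d` convention (gap ≤ *d* merges; default
  *d* = 1 bp). A merged enhancer of length L is a **stretch enhancer**
  iff L > 3000 bp (strict).
* **Sharing by bidirectional overlap.** Enhancers *a*, *b* are shared at
  fraction *f* (default 0.25) iff
  `overlap(a, b) ≥ f·|a|` **and** `overlap(a, b) ≥ f·|b|`.
* **Transition classes.** With active states {1–6} and the state taken at
  the site midpoint base (unmarked = not active):
  B-only ∧ ¬active_A ∧ active_B → *repressed_to_active*;
  shared ∧ active_A ∧ active_B → *active_to_active*;
  A-only ∧ active_A ∧ ¬active_B → *active_to_repressed*; else *other*.
* **PWM scanning.** Log2-odds scores against a background, min–max
  normalised: `rel = (s − s_min)/(s_max − s_min)`; a window is a hit when
  `rel ≥ 0.8` (the JASPAR-style 80% confidence level). Motif density is
  reported as hits per bp per site, so profiles integrate to mean hits
  per site.
* **Expression-matched permutation test.** Observed statistic: the number
  of distinct stretch enhancers with ≥ 1 signature-gene TSS within 50 kb.
  Null: N gene sets resampled to match the signature's occupancy of 10
  quantile bins of log10(FPKM + 1). Empirical p = #{null ≥ observed}/N
  (so 2/10,000 → 0.0002), with the add-one estimate (k + 1)/(N + 1)
  alongside.

Coordinates are 0-based half-open (BED) throughout. See the methods
vignette (`vignettes/chromstretch-methods.Rmd`) for assumptions, defaults
and design rationale.

## Worked example

```r
library(chromstretch)

cfg <- simulation_config(seed = 1)           # the default study design
ds  <- simulate_dataset(cfg, what = c("genes", "peaks"))
ds
#> Simulated paired-condition dataset
#>   genome: 3 chromosome(s), 6.0 Mb total
#>   progenitor: 8713 segments, 726 enhancers (60 stretch), 3000 peaks
#>   differentiated: 8722 segments, 720 enhancers (41 stretch), 3000 peaks
#>   1500 genes (150 bound, 25 signature)

shared_enhancers(ds$enhancers$progenitor, ds$enhancers$differentiated)
#> Enhancer sharing (reciprocal overlap >= 0.25):
#>   set A: 726 enhancers, 101 shared, 625 unique
#>   set B: 720 enhancers, 101 shared, 619 unique
#>   fraction of union shared: 0.140; Venn components: 101 shared / 625 A-only / 619 B-only

stretch_b <- subset(ds$enhancers$differentiated, is_stretch)
permutation_enrichment_test(ds$truth$signature$gene_id, ds$genes, ds$expr,
                            stretch_b, n_perm = 10000, seed = 2)
#> Expression-matched permutation test (25 genes, +/- 50000 bp, 10000 permutations)
#>   observed proximal stretch enhancers: 29
#>   null mean 14.46 (range 4-27)
#>   empirical p = 0 (add-one estimate 9.999e-05)
```

The 25 planted signature genes sit near 29 distinct stretch enhancers of
the differentiated state, twice the expression-matched null expectation of
≈ 14.5, and no null resample reaches the observed count — the planted
enrichment is recovered. The bound-gene expression boost is recovered the
same way:

```r
mw <- bound_vs_unbound_expression_test(ds$expr, ds$truth$bound_genes)
#> p = 1.04e-35 (150 bound vs 1350 unbound, Mann-Whitney two-sided)
```

A thin CLI over the same functions lives in `exec/chromstretch`
(`simulate`, `call-enhancers`, `compare-enhancers`, `classify-peaks`,
`motif-density`, `enrich`, `proportions`, `frip`).

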