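---
title: "Methods: stretch-enhancer and binding-site analysis on simulated chromatin-state data"
author: "chromstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stretch-enhancer and binding-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstretch)
```

## The analysis this package implements

`chromstretch` implements the downstream, post-alignment statistics of a
paired-condition regulatory-genomics study: a progenitor cell state and a
differentiated cell state, each with an 11-state chromatin segmentation (a
ChromHMM-style hidden-Markov labelling of 200-bp bins from histone-mark and
open-chromatin data), transcription-factor binding-site sets, gene
annotation, and FPKM expression. Upstream steps — alignment, peak calling,
segmentation training — are out of scope; the package consumes their
standard text outputs (BED, segmentation BED, TSV, FASTA, bedGraph).

Five analyses are provided:

1. **Enhancer calling.** Segments in the enhancer states (states 2 and 3 by
   default) are stitched with the `mergeBed -d 1` convention: two segments
   merge when the gap between them is at most `max_gap` (default 1 bp).
   A merged enhancer strictly longer than 3 kb is a *stretch enhancer*.
   The 3-kb comparison is strict (`> 3000`), so a 3000-bp enhancer is
   typical and a 3001-bp enhancer is stretch.
2. **Enhancer sharing.** An enhancer is shared between conditions when some
   enhancer of the other condition overlaps it *bidirectionally* at 25%:
   the overlap must be at least 25% of the length of each partner. A single
   qualifying partner suffices; overlaps are not summed across partners,
   which is the most conservative reading of the criterion. Because the
   per-set shared counts can differ, the report carries both per-set counts
   and a Venn-style count of connected components containing members of
   both sets.
3. **Binding-site transition classes.** Each site is classified from its
   sharing label and the chromatin state at its midpoint base in each
   condition (states 1–6 are "active"; absence of a segment is "unmarked"
   and counts as not active): condition-B-only sites moving from inactive
   to active chromatin are *repressed_to_active*, shared sites active in
   both are *active_to_active*, condition-A-only sites losing activity are
   *active_to_repressed*, and everything else is *other*. The midpoint-base
   convention (rather than maximal-overlap state) is deterministic, cheap,
   and robust to peak-width variation.
4. **Profiles.** Aggregate signal profiles average a bedGraph step function
   in fixed offset bins around site midpoints. Motif-density profiles scan
   ±500 bp windows with a PWM at a JASPAR-style relative score threshold
   (`(score − min)/(max − min) ≥ 0.8`) and report hit-center density in
   hits per bp per site, so the profile integrates to mean hits per site.
   All hits are counted, including overlapping ones: the quantity is a
   density, not an annotation.
5. **Expression-matched permutation enrichment.** For a signature gene set,
   the observed statistic is the number of *distinct* stretch enhancers
   with at least one signature TSS within 50 kb (an enhancer near several
   signature genes counts once). The null is built by resampling gene sets
   matched on expression: universe genes are binned into 10 quantile bins
   of log10(FPKM + 1) in the differentiated condition and each target gene
   is replaced by a uniform draw, without replacement, from the non-target
   genes of its bin, so the resample reproduces the target's bin occupancy
   exactly. The empirical p-value is `#{null ≥ observed}/N` — the
   convention under which 2 extreme permutations out of 10,000 give
   p = 0.0002 — with the add-one estimate `(k+1)/(N+1)` reported alongside
   as the statistically safer quantity, since the plain ratio can reach an
   exact zero.

Supporting operations follow the same conventions: TSS proximity uses the
distance from a point to the nearest *covered* base of a half-open
interval (so a peak ending at 200 is 51 bp from position 250); peak sharing
between conditions uses a ≥ 1 bp overlap, the weakest defensible
convention, as a parameter open to sensitivity analysis; FRiP is the
fraction of read intervals overlapping any peak; co-staining proportions
round half up to integer percent (8/26 → 31%); the one-way ANOVA is the
classical fixed-effects F test; the bound-versus-unbound expression test is
a two-sided Mann–Whitney, exact when both groups have ≤ 20 tie-free values
and normal-approximated with tie and continuity correction otherwise —
chosen for distribution-free robustness on FPKM, where normality is
untenable.

## Coordinate and file conventions

All coordinates are 0-based, half-open (BED), everywhere, because every
input dialect is BED-family; there is no internal 1-based representation.
Chromosome names match by exact string equality. Strand is carried on genes
only — none of the analyses uses peak or enhancer strand. JASPAR matrices
are read as raw counts and converted to probabilities with a 0.25
pseudocount per cell, so log-odds are always finite. Writers are
byte-stable (tab separators, LF endings, sorted records), which is what
makes whole-dataset byte-reproducibility testable.

## The synthetic study design

The generator produces a complete paired-condition dataset whose planted
structure is known, so every downstream stage has a ground truth. The
default configuration is the package's study design; it was chosen once,
from the following considerations, and is not tuned per analysis.

**Genome and segmentation.** Three 2-Mb chromosomes at 200-bp resolution —
large enough for stable enhancer statistics and ≥ 25-gene signature sets,
small enough that a full dataset generates in seconds. States evolve as a
first-order Markov chain. The default transition matrix makes the enhancer
block {2, 3} sticky with within-block stay probability 0.84 and stationary
mass ≈ 0.15. Both values are analytic choices: enhancer run lengths are
then geometric with P(run > 15 bins) = 0.84^15 ≈ 0.073, so stretch
enhancers are ~5–8% of enhancers (the empirically expected band), and the
6-Mb genome carries ≈ 720 enhancers and ≈ 50 stretch enhancers per
condition. The stretch-enhancer *density* matters for the permutation
test: with ≈ 50 stretch enhancers, a random 25-gene set catches ≈ 19 of
them within ±50 kb (sd ≈ 3.5), while the planted signature catches ≈ 35,
so the planted effect is detectable yet the null is far from saturated.
A substantially denser stretch-enhancer landscape on a genome this size
would push the null count above the planted signal and make the enrichment
unmeasurable — density, not count, is what the desk-scale genome must
preserve relative to a real genome.

**Genes and expression.** ~1500 genes with TSSs uniform over the genome and
FPKM ~ log-normal(meanlog 2, sdlog 1.2) per condition (median ≈ 7 FPKM,
bulk of genes between 0.5 and 100 — a realistic dynamic range), rounded to
4 decimals so files round-trip exactly. 150 "bound" genes get a 4-fold
FPKM boost in the differentiated condition. The 25 signature genes are
relocated so each TSS lies within 10 kb of a distinct differentiated-
condition stretch enhancer — 10 kb is a typical enhancer–promoter distance
scale and sits well inside the 50-kb counting window. Signature genes'
expression is left untouched: the permutation null matches on expression,
so planting an expression effect as well would only entangle the two
analyses.

**Binding sites.** 4000 sites (3000 peaks per condition) in a 50/25/25
shared/A-only/B-only mix. Sites are laid out on a 1200-bp slot grid, one
site per slot, using only the three interior 200-bp bins of each slot with
±80 bp jitter; widths are 200–600 bp. This guarantees two things by
construction: sites never overlap (so the sharing truth labels are exact),
and each site's midpoint stays inside the bin whose chromatin state was
sampled. Condition-unique sites are placed, with probability 0.9
(`state_purity`), in bins active in their own condition and inactive in
the other, mirroring the strong association between unique binding and
chromatin-state transitions seen in real data.

**Sequence and motifs.** The genome is i.i.d. uniform A/C/G/T. Four
synthetic 8-bp motif families (POU-like octamer, bZIP-like TRE, HTH-like,
bHLH-like E-box; consensus probability 0.85) are planted per site with
probability 0.5 per applicable family: POU-like at every site, bZIP-like
at A-only sites, HTH-like and bHLH-like at repressed-to-active B-only
sites. A planted consensus is centred on the site midpoint. When several
families plant at one midpoint the class-specific family keeps offset 0
(a fair coin decides between HTH and bHLH, the loser moving to +16 bp) and
the POU-like plant moves to −16 bp; all offsets are recorded in the truth
table. At the 0.8 relative-score threshold an 8-bp family tolerates one
mismatch, giving a chance hit rate of ~8 × 10⁻⁴ per bp on both strands —
two orders of magnitude below a planted center-bin density — so planted
and background signal separate cleanly.

**Signal tracks.** Triangular bumps of height 10 over a flat 0.5 baseline,
discretised at 20 bp — the simplest shape whose binned aggregate profile
has a closed form.

**Randomness.** Each component (segmentation per condition, genes, peaks,
sequence) draws from its own sub-stream derived from the master seed, so
changing one component's parameters does not perturb the others, and the
whole dataset is a pure function of the configuration — two runs with the
same config write byte-identical files.

**What the generator does not emulate.** Read-level noise, GC bias,
nucleosome structure, correlated state emissions, enhancer–promoter loop
geometry, and realistic motif co-occurrence. Passing tests therefore
demonstrate that the *operations* are correct and that the statistics
behave as designed under a known model — not that the biological effect
sizes of any real system are recovered.

## Numerical choices and degenerate inputs

* Merging with `max_gap` follows the `-d` convention: gap ≤ `max_gap`
  merges; overlap and book-ending always merge.
* Nearest-gene ties (equidistant TSSs) break to the lexicographically
  smaller `gene_id` — deterministic and annotation-order independent.
* Quantile bins use R's type-7 quantiles with `findInterval(...,
  rightmost.closed = TRUE, all.inside = TRUE)`; a bin with fewer available
  non-target genes than required is an error naming the bin, not a silent
  relaxation.
* An empty enhancer set yields a `NaN` stretch fraction with a warning;
  an empty gene set yields a zero proximal count with a warning; an
  all-constant equal-mean ANOVA returns p = 1 with a warning; a
  permutation test in which no null value reaches the observed statistic
  returns p = 0 with a warning pointing at the add-one estimate.
* log2 fold-changes use a pseudocount of 1 on FPKM, defined for silent
  genes and monotone in the ratio. The upstream study used a dedicated
  differential-expression tool for this quantity; that tool's shrinkage
  behaviour is deliberately not imitated.
* The "top 5% most differentially expressed" selection takes
  `ceil(0.05 × n_expressed)` genes where expressed means FPKM > 0 in
  either condition.
* Where the sharing denominator of the headline "percent shared enhancers"
  is ambiguous (per-set versus union), both are computed; the printed
  fraction uses the union of both sets.

## Problem sizes used by the test suite

The statistical suites run at deliberately chosen desk scales: oracle
equivalence on ≥ 100 random instances per operation; null calibration of
the permutation test over 400 random target sets at N = 500 permutations
on one default dataset (the fraction of p ≤ 0.05 must land in
0.05 ± 0.02); planted-signature power over 20 seeds at N = 1000
(p ≤ 0.01 required in ≥ 19); and the class-specific motif-density
signature (≥ 5× center-bin dominance of each planted family over
non-planted families at its target class) over 20 seeds. These sizes give
each check a comfortable noise margin under the design analysis above
while keeping the full suite in the minutes range.

## Known limitations

* The interval engine is plain R over sorted vectors; it is comfortable at
  10⁴–10⁵ intervals but not engineered for whole-mammalian-genome peak
  atlases.
* PWM scanning is O(sequence × motif length) per window set with no
  suffix-indexing; scanning thousands of 1-kb windows is seconds, scanning
  whole genomes with motif compendia is not its use case.
* The Venn-style "shared component" count collapses chains of pairwise
  overlaps; with pathological nested enhancer structures the per-set
  counts remain the safer quantity.
* The permutation test conditions on the observed enhancer landscape; it
  does not model uncertainty in enhancer calling itself.
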