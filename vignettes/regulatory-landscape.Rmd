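---
title: "Methods: enhancer modalities and loop-based candidate nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer modalities and loop-based candidate nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(enhancerscape)
```

## The analysis model

`enhancerscape` integrates four assay layers for a transition between two
cellular states, A (prior/naive) and B (induced): ATAC-seq peaks (open
chromatin), H3K4me1 and H3K27ac ChIP-seq peaks (enhancer priming and
activity), a replicate RPKM expression matrix, and a table of significant
Hi-C interactions at fixed bin resolution. Peaks are inputs: peak calling,
alignment and Hi-C significance testing happen upstream.

The core definitions, all operating on 0-based half-open intervals:

* **Differential expression.** Per gene, condition means are taken on raw
  RPKM. Genes with `max(mean_A, mean_B) < 1` RPKM are set aside as
  `low_expression`. The rest receive a Welch two-sample test on
  `log2(RPKM + 1)` with Benjamini-Hochberg adjustment across tested genes.
  A gene is `up` when `mean_B / mean_A >= 1.5` and adjusted p `< 0.05`;
  `down` symmetrically on the inverted ratio.
* **TSS accessibility change.** A gene's promoter is open in a condition
  when at least one ATAC peak intersects the window of +/- 2 kb around its
  TSS; the A-to-B comparison classifies `gained`, `lost`, `stable_open`
  or `stable_closed`.
* **Condition-specific enhancers.** A call is a condition-B H3K27ac peak
  that also overlaps a B H3K4me1 peak and a B ATAC peak — the full active
  signature — and overlaps *no* A H3K27ac peak, so the activity mark is
  newly acquired. The B H3K27ac span is the region coordinate. Regions
  within 2 kb of any TSS are dropped by default so that promoters are not
  reported as enhancers.
* **Activation modality.** The prior-state (ATAC, H3K4me1) status of each
  call maps one-to-one onto four classes: `accessible` (ATAC+/K4me1-),
  `poised` (ATAC+/K4me1+), `unmarked` (ATAC-/K4me1-) and `de_novo`
  (ATAC-/K4me1+). Presence or absence of a peak is the entire class
  decision; quantitative H3K4me1 signal (RP10M) can be attached
  descriptively but never gates the class.
* **Enhancer-gene association.** Each call is assigned the gene whose TSS
  is closest to the region midpoint, with a signed distance in the gene's
  strand orientation.
* **Candidate nomination from loops.** For a gene of interest, an element
  is a supported candidate when it is accessible (ATAC) in at least
  `min_accessible` conditions, loops to the gene's promoter window in
  every required condition, and loops in no forbidden condition. "Loops
  to" means: a cis interaction with one anchor bin overlapping the
  element and the other overlapping the promoter window. This encodes the
  discriminating pattern of a developmentally pre-wired enhancer —
  accessible across the relevant lineage states, in contact with the
  promoter in the committed states, and without detectable contact in the
  pluripotent state.

Signal quantification uses tags-per-10-million (RP10M):
`count x 1e7 / library_size`, with binned profile matrices around anchor
positions for average-profile views.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `fc_threshold` | 1.5 | ratio | DE fold-change cutoff |
| `min_expression` | 1 | RPKM | expression floor before testing |
| `alpha` | 0.05 | – | adjusted-p cutoff |
| `tss_half_window` | 2000 | bp | promoter window half-width |
| `peak_half_window` | 10000 | bp | profile window around peak centers |
| `rp10m_scale` | 1e7 | tags | signal normalization constant |
| `hic_resolution` | 10000 | bp | loop anchor bin size |
| `hic_window` | 25000 | bp | provenance of the upstream loop extraction; carried in the manifest, not consumed |
| `distal_filter` | TRUE | – | exclude promoter-proximal calls |
| `distal_min_tss_distance` | 2000 | bp | distance defining "promoter-proximal" |

All thresholds live in one `analysis_config()` object, are echoed into
every run manifest, and a config file with an unknown key is an error so a
typo can never silently revert a threshold to its default.

## Numerical and convention choices

* **Coordinates** are BED-convention 0-based half-open end to end;
  adjacent intervals do not overlap. Overlap "presence" means >= 1 shared
  base; no reciprocal-fraction rule is applied, because none is defined
  for these data, and the 1 bp rule is the permissive, explicit default.
* **Nearest-TSS convention.** Distance is measured from the region
  midpoint (`floor((start+end)/2)`) to the TSS, as HOMER-style annotation
  does; the reported value is signed by the gene's strand (positive =
  midpoint downstream of the TSS) and is zero only when the midpoint sits
  exactly on the TSS. Ties between equidistant TSSs resolve to the
  lexicographically smaller gene identifier, making the assignment fully
  deterministic. Strand never affects which gene is chosen — enhancers
  act strand-agnostically.
* **Replicate reproducibility** keeps the replicate-1 coordinates of
  regions confirmed by any overlap in replicate 2. Keeping one
  replicate's spans (rather than a union or intersection) is
  deterministic and preserves the peak caller's original geometry.
* **The test engine.** The upstream study fit its expression contrasts in
  a proprietary ANOVA framework; with two groups that reduces to a
  two-sample location test, and the package substitutes a Welch t-test on
  `log2(RPKM + 1)` with BH adjustment. The thresholds, not the engine,
  define the filter, and `differential_expression()` is the single place
  to swap the engine. Genes whose replicates have zero variance in both
  conditions are untestable and fall back to p = 1 (counted and logged)
  rather than erroring.
* **Fold change** is the ratio of raw-RPKM means with no pseudocount;
  genes below the expression floor never reach the ratio, so division by
  zero cannot produce a spurious call.
* **Percentages** are rounded half-up at a configurable precision
  (default 0 decimals) and every reported percentage carries its raw
  numerator and denominator, so rounding never hides a count; a zero
  denominator reports `NA`, never an error.
* **Largest-remainder apportionment** converts class proportions into
  integer counts that sum exactly; quotas within 1e-9 of an integer are
  snapped first (avoiding floating-point misallocation), and remainder
  ties are broken toward the smallest provisional class.
* **Loop absence is absence of evidence by design**: "no loop in
  condition X" means no qualifying row in X's interaction table, exactly
  the form of the claim the nomination logic is built to encode.
  Trans-chromosomal interactions are annotated but never support a
  candidate.

## What the synthetic generator emulates

`simulate_study()` plants a complete two-condition study on a slotted toy
genome (4 chromosomes, one 40 kb slot per gene; ~16 Mb at the default 400
genes, scaling with gene count). Within each slot the TSS sits near the
slot origin and any planted regulatory element lies 12-15 kb downstream
of its target TSS — far enough to clear both the 2 kb distal filter and
the 10 kb loop-bin width, and close enough that the target is always the
nearest TSS. Planted truth covers:

* per-gene DE status (default 20% up, 13% down, log2 fold change 1) and
  TSS-accessibility change (68.5% of up genes gain, 37.2% of down genes
  lose — the observed study fractions);
* per-enhancer modality, apportioned by largest remainder from the
  observed class mix `(597, 386, 379, 120)/1482`, with every planted
  enhancer carrying the full induced-state signature and its prior-state
  marks following the class; decoy regions with a *pre-existing* H3K27ac
  peak exercise the acquisition filter;
* replicate RPKM values with multiplicative log-normal noise
  (`replicate_cv`, default 0.1), the standard dispersion surrogate for
  RNA-seq on the log scale;
* enhancer-promoter loops between resolution-aligned bins, present per a
  configurable condition pattern;
* optional tag tracks with counts proportional to peak presence.

Four replicates per condition are generated by default. This is the
smallest replicate count at which the planted twofold change at 10%
replicate CV is reliably detectable by an unmoderated two-sample test
after BH correction: at 2-3 replicates the variance estimate (2-4 degrees
of freedom) is noisy enough that several percent of genuinely changed
genes fail the adjusted-p cutoff by chance, which would say nothing about
the filter logic under test. Studies with fewer replicates are fully
supported; the default simply keeps the generator's planted truth
recoverable.

`peak_fdr_noise` models peak-calling error that persists across
replicates: each true peak is dropped with that probability and a
matching expected number of spurious peaks is scattered over the genome.
Replicate-to-replicate variation is modelled only as small boundary
jitter. Under dropout, a missing induced-state peak removes the call
itself, so class-recovery is quoted *among recovered calls*: at 5%
dropout roughly 86% of planted enhancers are still called and ~95% of
those receive the correct class, degrading monotonically with noise.

What the generator does **not** emulate: read-level sampling noise, peak
width/shape variation, correlated replicate failures, copy-number or
mappability artifacts, distance-dependent Hi-C contact background, or any
sequence content. Passing tests therefore demonstrate the correctness of
the integration logic under the declared noise model, not robustness to
every failure mode of real assays.

The En7-style fixture (`make_en7_fixture()`) is a five-condition
miniature of the candidate-nomination problem: one intronic element
accessible in all four non-pluripotent states and looped to the promoter
in the two committed states, two upstream decoys accessible everywhere
but never looped, and one looped but inaccessible decoy. Exactly one
element satisfies the full pattern, by construction.

```{r en7}
fx <- make_en7_fixture()
cand <- do.call(nominate_candidates,
                c(list(elements = fx$elements,
                       atac_by_condition = fx$atac_by_condition,
                       interactions_by_condition = fx$interactions_by_condition,
                       tss = fx$tss),
                  fx$nominate_args))
cand[, c("name", "n_accessible", "looped_conditions", "supported")]
```

## Problem sizes used in the test suite

The suite validates the indexed implementation against brute-force
all-pairs re-derivations on twenty randomized studies of ~90 genes / 30
enhancers each, checks printed-ratio arithmetic on one paper-scale study
(6,000 genes, 1,482 enhancers), measures DE recovery on 2,000 genes, and
measures noise degradation on ten seeds of 300-enhancer studies per noise
level. These sizes were chosen so each property is measured with enough
elements for stable proportions while the whole suite stays desk-scale.

## Known limitations

* The enhancer region anchor is the induced-state H3K27ac span; merging
  across marks, or anchoring on ATAC summits, would shift coordinates and
  slightly change nearest-TSS assignments.
* Presence/absence classification ignores signal strength by design; a
  weak-but-called prior-state peak and a strong one are the same class.
* Nearest-TSS association is a heuristic; it is exactly what the loop
  module exists to refine, and the two can disagree.
* `nominate_candidates()` carries interaction scores through unfiltered;
  if the upstream significance extraction was permissive, callers should
  filter the table before nomination.
* With only two conditions the nomination logic is under-constrained;
  its discriminating power comes from multi-condition designs like the
  five-state fixture.
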