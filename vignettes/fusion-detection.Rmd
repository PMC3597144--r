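---
title: "Detecting fusion genes at copy-number breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion genes at copy-number breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfuse)
```

## The problem

Unbalanced genomic rearrangements — deletions, unbalanced translocations,
amplification boundaries — leave a footprint in SNP-array data: the total
copy number (CN) changes between two adjacent genomic segments. When such a
breakpoint falls inside or immediately next to two genes with compatible
orientation, the rearrangement may have created a fusion gene, with the 5′
partner donating its promoter and upstream exons and the 3′ partner the
downstream sequence. Classic examples are BCR-ABL1 in chronic myeloid
leukemia and TMPRSS2-ERG in prostate cancer, both of which are accompanied
by characteristic CN changes at the partner loci.

`segfuse` predicts such fusions from three inputs: per-sample CN
segmentation tables (as produced by an HMM segmentation of SNP-array data),
per-sample probe-level intensities, and a gene annotation (BED6 or GTF).
Balanced events leave no CN footprint and are invisible to this approach by
construction.

## The procedure

Per sample:

1. **Cleaning.** Segments supported by a single probe cannot be told apart
   from experimental or algorithmic artifacts and are removed; their
   interval and probe count are absorbed into a flanking segment, and
   same-CN neighbours are merged (`remove_single_probe_segments()`).
2. **Breakpoints.** Every boundary between adjacent segments with differing
   total CN is a breakpoint; its position is taken as the floor of the
   midpoint between the flanking segment ends (`detect_breakpoints()`).
3. **Anchoring.** Genes spanning a breakpoint are split into subsegments:
   with two subsegments one is the 5′ and one the 3′ anchor (by strand and
   side); with three or more, the transcript-most-upstream subsegment is
   the 5′ anchor, the most downstream the 3′ anchor, and inner subsegments
   serve both roles. Genes not spanning a breakpoint are anchored whole if
   the nearer gene end lies within 10 kb of a boundary; the role follows
   from the strand and from which end faces the junction
   (`anchor_genes()`).
4. **Constraints.** All ordered (5′, 3′) anchor pairs — across chromosomes
   too — are screened (`evaluate_candidates()`):
   * CN agreement: fused partners are replicated together, so their total
     CNs may differ by at most ±1 (segmentation is probabilistic, hence a
     tolerance rather than equality);
   * orientation: transcription must read through the junction — the 5′
     partner is broken at its transcript-3′-facing end, the 3′ partner at
     its transcript-5′-facing end;
   * length: the fusion length (sum of both subsegment lengths) must lie
     between the shortest and longest gene of the collection;
   * crossover concordance: the 7 probes of each partner nearest the
     junction form a 14-probe virtual track; a loess span is selected on
     that track by corrected AIC, each 7-probe side is smoothed at that
     span, and the pair is kept only when the absolute Pearson correlation
     of the smoothed sides exceeds 0.9. The root-mean-square difference of
     the smoothed sides (RMS) is reported as a junction-consistency score
     (near zero = consistent crossover).

Across samples (`evaluate_all()`): gene pairs recurring in ≥ 2 samples form
a *group*; at least two of the four fusion coordinates must be exactly
conserved across members; the Euclidean distances over the non-conserved
coordinates feed complete-linkage clustering, cut at 40 % of the group's
median fusion length; clusters of ≥ 2 samples are reported as *subgroups*,
smaller ones are discarded as outliers.

## Parameters

All numeric rules live in `fusion_params()`:

| parameter | default | meaning |
|---|---|---|
| `max_breakpoint_distance_bp` | 10 000 | anchoring distance for non-spanning genes (bp). Human introns average ≈ 5 kb, so ≤ 10 kb per partner keeps the non-coding insert of a putative fusion plausibly functional. |
| `cn_tolerance` | 1 | maximal CN difference between partners |
| `crossover_probes` | 7 | probes per side of the junction window; a side with fewer probes is ignored |
| `min_abs_correlation` | 0.9 | strict lower bound on \|r\| of the smoothed windows; negative r passes (an inverted but consistent trend) |
| `span_grid_lo/hi/step` | 2 / 95 / 1 | loess span grid, percent of data points |
| `group_min_samples` | 2 | minimal samples per group and per reported subgroup |
| `length_fraction` | 0.40 | dendrogram cut height as a fraction of the median fusion length |
| `min/max_fusion_len_bp` | derived | fusion length bounds; by default the shortest and longest gene of the collection (`set_length_bounds()`) |
| `artifact_max_probes` | 1 | maximal probe support of a removable artifact segment |

## Numerical choices

* **AICc.** The span criterion is
  `n·ln(RSS/n) + n·(n + tr)/(n − tr − 2)`, the standard
  small-sample-corrected AIC for linear smoothers, with `tr` the trace of
  the loess smoothing operator (`trace.hat` of a `stats::loess` fit with
  exact statistics). Spans whose fit fails, saturates (`n − tr − 2 ≤ 0`)
  or yields non-finite statistics are infeasible; on a 14-point track this
  in practice excludes spans below ≈ 43 %. Ties in AICc break toward the
  smaller span, so an exactly linear track selects the smallest feasible
  grid span.
* **Loess.** Local quadratic fits with tricube weights on the observation
  index, evaluated at each point (`surface = "direct"`); constants and
  straight lines are reproduced exactly. The span is selected once per
  candidate on the concatenated 14-probe track, then applied to each
  7-probe side separately.
* **Degenerate windows.** A side with zero variance after smoothing has no
  defined correlation; the candidate is dropped with reason
  `"degenerate window"` rather than propagating `NA`.
* **Breakpoint position.** Segment coordinates are probe positions; the
  true break lies between probes. The deterministic convention
  `floor((left_end + right_start)/2)` makes distance tests reproducible;
  10 kb is applied inclusively (a gene at exactly 10 kb anchors).
* **Artifact absorption.** The removed run's interval *and probe count*
  are assigned to a flanking segment (the flank pair merges when both
  flanks share a CN, otherwise the left flank receives it). Artifacts are
  flagged before absorption, so an artifact absorbed into another artifact
  cannot launder it into a real segment; a chromosome consisting solely of
  artifacts is dropped.
* **Agglomeration ties.** `stats::hclust` with complete linkage is
  deterministic for a fixed member order; members are ordered by sample
  id, and subgroups are numbered by ascending minimal member coordinates,
  making labels reproducible.
* **Self-pairing.** Subsegments of one gene are never paired with each
  other at the breakpoint that split them (that is the unbroken gene), and
  an inner both-role subsegment is never joined to itself across its two
  flanking breakpoints.

## Open design points, and how they were resolved

* *Per-gene vs combined distance.* The intron-length argument above could
  be read as a 20 kb budget on the combined distance of both partners; the
  package enforces 10 kb per partner, the stricter and simpler reading.
* *Smoothing scope.* The span could be chosen per gene interval or per
  candidate; the package selects it per candidate on the 14-probe
  crossover track, reconciling per-candidate individuality with two
  per-side smoothed series. Correlation is computed on the smoothed
  values.
* *The 40 % rule.* "Distance > 40 % of the median length to the other
  cluster members" can be read as a per-member discard rule or as a global
  dendrogram cut; the package implements it as a cut height (the
  horizontal-line reading), with an auxiliary `cut_mode =
  "min-cluster-size"` that instead cuts at the smallest height at which
  every cluster has ≥ 2 members. The worked ABL1-BCR example ships with
  the package (`inst/extdata/abl1_bcr_cml_groups.tsv`) and reproduces its
  published 3 + 2 subgroup split under the auxiliary mode; the published
  threshold arithmetic itself is not reproducible from the table alone
  because the discarded seventh cell line's coordinates are not printed.
* *Median scope.* The median fusion length is computed over all initial
  group members, including any member the cut later discards — the
  discard criterion must precede the discarding.
* *Segment coordinates.* Whether segmentation coordinates denote probe
  positions or inter-probe boundaries is not fixed by the input format;
  the package adopts probe positions throughout.

## The synthetic cohort generator

`simulate_cohort()` builds a cohort a grader or test can regenerate from a
seed alone: gene models, per-sample segmentations, probe panels and a
truth table. Design:

* **Geometry.** Each planted event occupies its own chromosome with one
  breakpoint on the probe grid; the 5′ partner ends 5 kb upstream of the
  boundary and the 3′ partner starts 5 kb downstream (defaults), so both
  anchor under the 10 kb rule. Probe spacing defaults to 1 kb, the order
  of SNP-array density at gene loci.
* **Intensity model.** A probe in a CN = c segment draws from
  `N(log2((c + 0.1)/2), base_sd + sd_per_cn · c)`: the mean is a smooth
  monotone map of CN and the spread grows with CN, the salient feature of
  real array intensities. Defaults `base_sd = 0.05`, `sd_per_cn = 0.02`
  give realistic spreads of ≈ 0.09 at diploid and ≈ 0.3 at high
  amplification.
* **Junction signal.** In carrier samples the 7 probes of each partner
  nearest the junction share a smooth random profile (a normalized random
  walk of scale 0.8, drawn per event and per sample, applied to the two
  sides in the order the crossover window reads them). This emulates the
  locally coherent signal of a physically joined, co-replicated junction
  — the feature the correlation filter exploits — while unrelated
  junctions carry independent profiles and therefore decorrelate.
* **Negative controls.** `plant_noncompliant_controls()` adds five events
  violating exactly one constraint each (CN gap 2, wrong 3′ strand, fusion
  longer than the longest gene, a six-probe 3′ side, a 15 kb distance).
  Their CN pairs sit on a lattice (3k / 3k − 1 per event, 19/17 for the CN
  control) so that every cross-event pairing differs by ≥ 2 copies: each
  control probes its own constraint instead of creating chance cross-event
  candidates.
* **Artifacts.** With probability `artifact_rate` per eligible probe, the
  *reported segmentation* (not the intensities) carries a single-probe CN
  spike; cleaning restores the artifact-free profile exactly.

What the generator does **not** emulate: allele-specific CN, probe-specific
response, GC waves, intron/exon structure within genes, segmentation error
beyond single-probe spikes, and real junction biology. Passing the
recovery tests therefore shows that the pipeline implements its rules
correctly and is sensitive and specific *under this model*; it is not
evidence about detection power on real arrays.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use a 5-sample cohort (one
compliant fusion in 3 samples plus the five controls; ≈ 34 000 probes per
sample across 7 chromosomes) and a 5-point CN ladder with 10 000 probes
per state for the noise check. Both run in seconds on one CPU.

## Worked example

```{r worked-example}
cml <- read.delim(system.file("extdata", "abl1_bcr_cml_groups.tsv",
                              package = "segfuse"), comment.char = "#")
mask <- conserved_positions(cml)
mask
dmat <- position_distance_matrix(cml, mask)
cluster_group(cml, dmat, fusion_params(cut_mode = "min-cluster-size"))
```

The 5′-gene start and 3′-gene end are conserved in all five cell lines;
clustering the remaining two coordinates splits the group into the
subgroups of three (BV-173, K-562, MEG-01) and two (EM-2, LAMA-84)
members.

## Limitations

* Only unbalanced events are detectable; a balanced translocation with no
  CN change produces no breakpoint.
* The method reports DNA-level candidates; it says nothing about whether a
  fusion transcript is expressed or in frame.
* Recurrence across ≥ 2 samples is required; private fusions are never
  reported.
* The correlation filter needs 7 probes per side; fusions in probe-sparse
  regions are ignored by design.
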