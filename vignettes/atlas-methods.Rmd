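---
title: "Building and annotating an enriched gene atlas: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and annotating an enriched gene atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaskit)
```

`atlaskit` builds an enriched gene annotation by merging several GTF
catalogs in priority order and then annotates the merged genes from
multi-tissue RNA-seq: expression calling, tau tissue specificity,
positional classification against the closest protein-coding gene (PCG),
miRNA host tabulation and pairwise co-expression. This vignette documents
the underlying models, the parameters that matter, the numerical choices,
and what the synthetic fixtures do and do not establish.

## The aggregation model

All coordinates are 1-based inclusive; BED input (CAGE peaks) is converted
on read. Chromosome names are opaque strings, so unplaced scaffolds are
handled like chromosomes. Two gene models *overlap* when at least one
transcript of each has at least one exon pair sharing ≥ 1 bp on the same
strand; `[1,100]` and `[100,200]` meet at bp 100 and do overlap. Merging is
sequential: the priority-1 source is accepted wholesale (so its gene
models are by construction fully included in the atlas), and each later
locus is accepted only if none of its transcripts overlaps the growing
catalog. Rejection is whole-locus — if any transcript conflicts, the gene
is dropped and no transcript grafting is attempted, because any grafting
rule would have to invent transcript-reconciliation semantics the
aggregation model does not define.

Conflicts are restricted to the candidate's biotype class by default
(`same_class_only = TRUE`). This is the only reading under which genes
hosting other genes survive: a miRNA inside a PCG exon overlaps that exon,
but it is only compared against accepted *miRNAs*, so it is added. The
strict all-vs-all mode is retained as a flag for sensitivity analysis.
Note the geometric consequence: because the conflict test is exon-based, a
miRNA nested in an *intron* conflicts with nothing and survives in both
modes; only exon-nested genes distinguish the two. Raw biotypes collapse
to five classes (`pcg`, `lncRNA`, `miRNA`, `other_small_rna`, `other`)
through an editable mapping table (`biotype_class_map()`), shipped as a
TSV so that any source dialect can be accommodated; unknown strings fall
through to `other`.

Tie handling: accepted genes keep their native id; a cross-source id
collision is renamed `<id>__<source>` and logged. Rejected loci are logged
with the accepted genes they collided with, and their native ids are
attached to those genes as overlap-based cross-references — the same
mechanism by which databases that never share identifiers can still be
linked through the atlas.

CAGE support, used to justify a priority ordering, counts a transcript as
supported when its TSS (start of the first exon on `+`, end of the last on
`-`) lies within `slop` bp of a peak. The default slop is 30 bp. Peak
strand is ignored: CAGE peak sets are frequently unstranded after
remapping, and requiring a strand match would silently discard support; a
strand-matched variant would be a one-line change but is deliberately not
a parameter until a use case demands it.

## Expression layers and the expressed rule

TPM is computed from counts and gene lengths (exonic union); "TMM
expression" is FPKM on TMM-effective library sizes. The TMM factors are
computed in the package following the published recipe — reference column
= library whose upper-quartile count fraction is closest to the mean, M
and A values on the non-zero genes, double trim (30 % on M, 5 % on A),
precision-weighted mean, factors rescaled to geometric mean one — and the
test suite requires agreement with edgeR's implementation to 1e-6, which
pins down every detail of that recipe. Genes absent from a quantification
are treated as zero counts, not missing, so flags are deterministic.

Per-tissue profiles are *medians of project medians*: a first median
within each (tissue, project) over samples, then a median across projects.
This makes the profile invariant to duplicating a project's samples and
keeps one vote per project in unbalanced designs.

A gene is *expressed* when (1) its median TPM reaches 0.1 in at least one
tissue and (2) in at least one (tissue, project), at least 50 % of samples
individually have reads ≥ 6, TPM ≥ 0.1 and TMM expression ≥ 0.1. The two
clauses are combined as independent existentials (AND of two "there
exists" statements); this is the weakest reading of the rule and the
default, with `same_tissue = TRUE` available to force the qualifying
group into a tissue that already satisfies clause 1. Both thresholds and
the fraction are arguments. The per-sex variant requires 80 % of one sex's
samples to pass the same per-sample triple and refuses to run with fewer
than eight individuals per sex. Expression categories come from the best
tissue median: `< 0.1`, `[0.1, 1)`, `>= 1` TPM.

## Tau and the gap categories

Tau is computed on transformed medians `x_t`, default `log10(TPM + 1)`:
\[
\tau = \frac{\sum_{t=1}^{T}(1 - \hat x_t)}{T - 1},
\qquad \hat x_t = \frac{x_t}{\max_t x_t}.
\]
The +1 pseudocount is a deliberate choice: a raw `log10` of sub-1 TPM
medians would be negative and push tau outside `[0, 1]`, whereas with the
pseudocount zero-expression tissues contribute exactly `\hat x = 0` and
tau stays in the unit interval. An all-zero profile has no defined tau and
returns `NA` with a warning. Tau is computed over all tissues; the
expression floor filters *genes* (specificity analysis is restricted to
genes reaching 1 TPM somewhere), not tissues.

Tissue-specific genes (`tau >= 0.90`, best median ≥ 1 TPM) are categorized
by sorting medians in descending order (ties broken by tissue name, which
is safe because equal values can never straddle a fold-change gap) and
scanning consecutive pairs for the **first** ratio ≥ 2 (a zero denominator
counts as a gap). The first gap, rather than the largest, yields the
tightest specific group and is what separates "specific to one tissue"
from "specific to a small group". A gap after position 1 is `mono_TS`,
after 2–7 `poly2to7_TS`; a later gap or none at all falls into the
residual `poly8to47_TS`, whose `specific_tissues` list is all tissues when
no gap exists (the category means "no tight group", so no subset is
privileged).

## Positional classification and miRNA hosts

Classification is FEELnc-style. A transcript pair is *genic* when the
spans intersect — exonic if any exon pair shares a base (on either
strand; antisense exonic overlap is genic, not intergenic, matching the
genic taxonomy), intronic otherwise — and *intergenic* with an
orientation otherwise: same-strand up/down by which side of the partner's
transcription direction the focal gene sits on, divergent when the TSSs
face each other, convergent when the 3' ends do. Gene-level calls take the
best transcript pair under the precedence exonic > intronic > intergenic,
then smallest distance, then lexicographically smallest partner id (the
explicit tie-break keeps calls deterministic across platforms). Distance
is measured between *gene spans*, which is well-defined for
multi-transcript genes; in the corner case where spans touch while every
transcript pair is disjoint, the best transcript-pair gap is used so that
intergenic distances stay positive. The classification window defaults to
100 kb and the co-expression pairing window to 1 Mb; both are arguments.

miRNA hosts are genes of class `lncRNA` or `pcg` overlapping a miRNA; a
fully containing host is preferred and the smallest enclosing span wins
when several qualify, so a miRNA is attributed to its innermost host. The
relation is exonic when a miRNA exon shares a base with a host exon, else
intronic.

## Co-expression

Kendall tau-b (tie-corrected) is computed between the per-tissue median
vectors of each pair — rank-based, so the result is invariant to any
monotone transform of the profiles and independent of the log-transform
choice. P-values come from exact permutation enumeration for panels of up
to 8 tissues and otherwise from the normal approximation with the
tie-adjusted variance of the S statistic plus a continuity correction of
one unit (half the lattice spacing of S, clamped at p = 1); on tie-free
vectors of length 8 this approximation sits within about 0.013 of the
exact tail probability, which the test suite checks. Constant vectors
return `NA`. BH adjustment is applied within each pair-type batch
(lncRNA:PCG and PCG:PCG separately — per-type batching is what makes
per-type significant fractions meaningful), and a pair is significant when
`|tau| >= 0.55` and `q <= 0.05`. Summaries stratify by configuration and
by distance (≤ 5 kb vs > 5 kb) for intergenic pairs.

## The synthetic fixtures

The generator emulates the structure the pipeline consumes, not chicken
biology. Annotations: loci are laid out in disjoint 30 kb slots over
opaque chromosomes; each later source clones a stated fraction of the
previous source's loci under new ids (guaranteed same-strand exon
overlaps) and adds novel loci; miRNAs are planted inside same-strand PCG
introns and lncRNA exons of the priority-1 source and travel with the
last source. Expression: a 47-tissue panel, two projects per tissue with
four samples each, negative-binomial counts (dispersion 0.1) on
log-normal library sizes (sdlog 0.3, mean 2e6). Archetypes: uniform
background; single-tissue and 3-tissue spikes with ~0.15 TPM background
and 100×/50× folds; sex-biased genes (log2 fold 2 for males in one
tissue); co-regulated pairs sharing a latent per-tissue factor of
log-scale strength 1.5. Expected-TPM columns are normalized to one
million with the spiked genes' absolute values held fixed, so planted
levels survive re-quantification and the 0.1/1 TPM thresholds keep their
meaning. Gene lengths for quantification are the models' exonic union
lengths (150–800 bp exons, one to four per transcript), spanning the
mono-exonic-lncRNA to multi-exon-PCG range.

What passing tests on these fixtures shows: the merge equals exhaustive
enumeration, planted truths (overlaps, hosts, spikes, co-regulation) are
recovered through the full quantification path, and the statistics are
calibrated on nulls. What they do not show: robustness to real-data
pathologies — misassigned strands, overlapping same-class loci inside one
database, multimapping-driven count artifacts, batch effects between
projects, or tissue panels whose members are biologically correlated.
Conclusions about real catalogs still require the real inputs.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the merge and classifier
oracles on twenty fixtures of two to six sources with roughly 15–30 genes
per source, the spike-recovery simulation on 500 genes × 47 tissues × 376
samples, TMM cross-validation on ten 200-gene fixtures, and the
co-expression calibration on 1000 null and 500 half-planted pairs. These
sizes were chosen so the whole suite exercises every code path in a few
minutes on one core; all of them scale with the fixture arguments if a
larger study is wanted.

## Known limitations

* Whole-locus rejection means a later source can lose a locus whose
  non-conflicting transcripts would have enriched an accepted gene; no
  transcript-level reconciliation is attempted.
* The expressed rule's two clauses are decoupled by default; datasets in
  which clause 2 is satisfied only in a tissue with sub-threshold medians
  will be called expressed unless `same_tissue = TRUE`.
* Tau inherits the panel: adding or removing tissues changes tau and the
  gap categories, so values are comparable only within one panel.
* The co-expression mode is across-tissue only; within-tissue
  (across-sample) correlation is out of scope, as are partial correlations
  and network inference.
* The GTF writer emits gene/transcript/exon records only (no CDS/UTR
  features), which is sufficient for the locus-level analyses here.
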