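---
title: "Methods: condition-specific TFs and cis-element discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-specific TFs and cis-element discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismotif)
```

This vignette documents the statistical model behind `cismotif`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data validation does and does
not establish.

## The model

### Condition-specific TFs

The input is a log2-scale expression matrix (genes × samples) and a
design mapping each condition to treatment samples, control samples and
a dataset (a set of conditions profiled together, e.g. "shoot abiotic
stress"). Differential expression per condition uses a two-sided Welch
t-test; the fold change is the difference of group means on the log2
scale. A TF is a DETF when p < 0.01 (strict) and log2FC > 1 (strict;
induction only, because condition specificity is defined for strongly
induced regulators — a configuration flag admits |log2FC| > 1).

Differential expression alone does not make a TF condition-*specific*:
a TF induced everywhere is not informative about one condition. The
specificity statistic is the z-score of the TF's fold change in the
candidate condition against the distribution of its own fold changes
over all conditions of that dataset, with the sample (n−1) standard
deviation; z > 2 (strict) promotes a DETF to CsTF. By construction a
TF's z-scores across a dataset have mean 0 and sample sd 1, which the
test suite checks as an invariant.

Degenerate inputs: when both groups have zero variance the t statistic
is undefined; the p-value is set to 0 if the means differ and 1 if
they are equal, with a warning. When all fold changes of a TF are equal
(σ = 0) the z-score is undefined and the TF is not promotable.

### Co-expression groups

Group members are the condition's DEGs (p < 0.01, |log2FC| ≥ log2 1.5
— both signs, inclusive boundary) whose Pearson correlation with the
CsTF is ≥ 0.8, computed over **all** samples of the dataset rather
than only the condition's four arrays: specificity of the correlation
comes from breadth of conditions, not from the contrast that defined
the DEGs. Constant-expression genes have undefined correlation and are
excluded. The CsTF is excluded from its own member list by default
(its promoter would otherwise always contribute to enrichment);
`include_self = TRUE` restores it. Groups smaller than 10 members are
flagged discarded — a permissive floor motivated by the observation
that a CsTF with no co-expressed genes carries no promoter signal at
all; the floor is configurable.

Only positive correlation (≥ 0.8) defines membership; anticorrelated
genes are not used. Negative-correlation groups would conflate
activation and repression targets in one promoter pool and are left
out of scope.

### Background-calibrated k-mer enrichment

The promoter universe is the 1,000 bp immediately upstream of each
TSS (TSS base excluded), truncated at chromosome edges, uppercased,
with any promoter containing a non-ACGT base removed. Within a gene,
promoter intervals of different transcripts that overlap (or are
book-ended; `merge_gap` configurable) are merged into their union and
re-extracted, so one gene can legitimately own several disjoint
promoters, and a merged promoter may exceed 1,000 bp. Merging is
idempotent and order-independent.

Every 4–8-mer (Σ4^k = 87,296 motifs) is counted over this promoter
set by exact forward-strand matching with overlaps counted. Two
background quantities are stored per motif: the number of genes whose
promoter(s) contain it (presence) and its total occurrence count
(number); genes with several promoters count once for presence.
Forward-strand-only matching is deliberate: collapsing reverse
complements would identify a motif with its palindromic partner and
make the core-swapped element pair (GAAnnTTC vs TTCnnGAA)
indistinguishable; a `both_strands` switch is provided.

Enrichment of a motif in a group is the hypergeometric upper tail
P(X ≥ x). In presence mode the draw is the group's genes against the
gene-level background. In number mode the trials are the *valid match
start positions* Σ(L−k+1) in group promoters against the background
position total — the only reading under which x ≤ n is structurally
guaranteed and the hypergeometric draw is well defined (a `bases`
alternative using raw base counts is retained as a config switch).
The tail is computed with `stats::phyper()` and is verified in the
test suite against exhaustive subset enumeration for every parameter
combination with N ≤ 12 (maximum absolute error below 1e-12), plus
monotonicity-in-x and upper/lower tail sum identities.

A motif is *enriched* when both p-values are below 0.001 (raw
thresholds, no multiple-testing correction — an intentionally simple
rule; Benjamini–Hochberg can be applied downstream if desired). The
presence/number scatter is summarized by quadrant: 1 = both
significant, 2 = number only, 3 = neither, 4 = presence only. The
background gene universe defaults to all promoter-bearing genes; it
can be restricted to the expression-detected subset by subsetting the
promoter set before `build_background()`.

### Motif assembly

From a group's enriched 8-mers, all 3-mer windows (6 per 8-mer) and
4-mer windows (5 per 8-mer) are counted; a core appearing twice in one
8-mer counts twice. The top-10 cores of each length are ranked with
lexicographic tie-breaking, and ties at the cut-off are reported.
8-mers carrying a top 3-mer *or* a top 4-mer are selected (the union
reading keeps the selection non-empty when the two rankings disagree;
an intersection mode exists).

Selected 8-mers are mapped back onto the group's promoters;
occurrences sharing ≥ 1 base merge transitively into maximal regions
(book-ended occurrences stay separate). Regions are stacked into a
PSSM by a deterministic anchor rule: each region aligns at the start
of its leftmost occurrence of the group's top-ranked core, regions
lacking the core anchor at offset 0. Since regions arise from exact
overlapping 8-mer matches, relative offsets are already known, and a
heuristic gapped aligner would only add nondeterminism — this is why a
coordinate-anchored stack replaces a conventional multiple-alignment
step. The cost is that flanking sequence can smear outer columns when
regions carry heterogeneous flanks; the 50%-support end-trimming
(columns covered by fewer than half the regions are cut from the ends
only) mitigates this. Base frequencies use pseudocount 0 by default
(configurable); per-column information content is 2 − H(p) bits, and
the logo matrix scales frequencies by information content.

An 8-mer is a `full` palindrome when it equals its reverse complement
(there are exactly 4^4 = 256 such 8-mers), and `flank_k` (maximal
k ≤ 3) when the outer k base pairs are reverse-complementary but an
inner position breaks full palindromy — the class containing the
GAAnnTTC heat-shock element family with non-self-complementary
spacers. Region midpoints are binned (default 100 bp) by distance
upstream of the TSS, where the distance of offset m in a promoter of
length L is L − m.

## Synthetic data: what it emulates, and what not

`simulate_expression()` draws per-gene baselines N(8, 1.5²) (log2
units) plus i.i.d. per-sample noise N(0, 0.25²), shifts the planted
TF by +3 log2 units in its condition's treatment samples, and builds
target genes as the TF's centered profile plus noise scaled to an
expected Pearson correlation of 0.95. Conditions have 2 treatment and
2 control samples, matching the replication structure of the array
compendia this workflow is designed for. `simulate_promoters()` draws
i.i.d. promoter sequence at 50% GC and overwrites (not inserts, so
lengths stay exact) an 8-mer at a uniform position with probability
0.8 in target promoters and 0.05 elsewhere, with alternating +/−
strand TSS layout to exercise strand-aware extraction. All sampling
derives from a single integer seed via fixed per-component sub-seeds,
so adding genes does not perturb promoter draws and equal seeds give
byte-identical outputs.

This emulates exactly the statistical structure the method assumes —
condition-elevated TF expression, correlated targets, motif
over-representation against a uniform background — and none of the
things real data add: probe effects and saturation, correlated
background structure in promoters (CpG/TA skew, repeats), TSS
annotation error, or shared regulatory programs across conditions.
Passing the synthetic recovery tests therefore demonstrates
correctness of the machinery, not field performance on real
compendia.

One power property of the study design is worth stating explicitly:
with 2 replicates per group, the Welch test's degrees of freedom fall
between 1 and 2, so the two-sided p < 0.01 criterion requires
t between roughly 10 and 64. Even a 12-σ effect (+3 log2 units over
noise 0.25) then passes in only ~30% of random draws, because the
sample standard deviations of two observations are highly variable.
The z > 2 specificity criterion, by contrast, is recovered in
essentially all seeded runs. Consequently end-to-end recovery of a
planted TF *as a full CsTF call* is replicate-limited, not
implementation-limited; with 3 replicates the same effect passes in
> 99% of draws. The acceptance script reports both the full-call rate
and the z-only rate so the two criteria can be distinguished.

## Problem sizes and numerical choices

The validation suites run at desk scale, chosen as the smallest sizes
at which each property is informative: hypergeometric enumeration at
N ≤ 12 (3,094 parameter combinations); planted-motif recovery on 20
seeds of a 2,000-gene background with 1 kb promoters and a 60-gene
group; planted-TF recovery on 100 seeds of 8 conditions × 2
replicates; end-to-end runs on a few hundred genes with 300 bp
promoters. The background index is accumulated in gene chunks
(`genes_per_chunk`, default 100) so the full 87,296-motif index over
tens of thousands of 1-kb promoters fits in ordinary desktop memory,
and it serializes to TSV for reuse across groups.

Floating-point outputs in pipeline TSVs are written with 6 significant
digits and fixed column orders, making reruns byte-identical
(`run_manifest.json`, which records versions, is the only file
excluded from that comparison). Threshold comparisons follow the
printed conventions everywhere: strict for p < 0.01, log2FC > 1 and
z > 2; inclusive for |log2FC| ≥ log2 1.5 and PCC ≥ 0.8.

## Known limitations

- The TSS-proximity rule for merging per-gene promoters is interval
  overlap (plus book-ended adjacency); a distance-threshold variant is
  available via `merge_gap` but no annotation-derived rule is applied.
- Anchored stacking can differ from a gapped multiple alignment when
  merged regions are long and heterogeneous; logos should be read as
  summaries of exact 8-mer overlaps, not as gapped alignments.
- The enrichment background is uniform over the promoter set; no
  Markov or shuffled-sequence background is offered, so compositional
  biases of real genomes (e.g. AT-rich plant promoters) inflate
  significance of composition-like motifs and a practitioner should
  read absolute p-values accordingly.
- With two replicates per condition the DETF/DEG t-test is the power
  bottleneck of the whole pipeline (see above); group sizes and
  downstream enrichment inherit that variance.
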