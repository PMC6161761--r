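---
title: "Methods: evolutionary and epigenetic analysis of adjacent CNE pairs"
author: "cnepairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary and epigenetic analysis of adjacent CNE pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnepairs)
```

# The problem

Conserved noncoding elements (CNEs) are genomic intervals under evolutionary
constraint that do not overlap protein-coding exons; many act as enhancers or
other *cis*-regulatory elements. This package studies **pairs of adjacent
CNEs** — two CNEs with no conserved element between them — and asks three
questions:

1. Is the genomic distance between the two CNEs of a pair conserved over
   mammalian evolution, beyond what genome-size change alone predicts?
2. Are changes in that distance associated with transposable-element
   insertions and deletions in the inter-CNE sequence?
3. Do pairs whose inter-CNE distance is conserved, contracted or expanded
   carry different histone-modification (enhancer-activity) profiles?

Every stage of the pipeline is exercised end to end on synthetic data with
planted ground truth, so the statistical machinery can be validated without
any external downloads.

# Pair construction

Conserved-element sets are merged (adjacent elements closer than 100 bp are
joined, transitively and left to right) and filtered (merged elements shorter
than 100 bp are dropped). Elements are classified against a protein-coding
gene annotation with descending precedence exon > UTR > intron > intergenic;
non-exonic elements are CNEs. Adjacency is computed over *all* conserved
elements, coding included, and a pair is emitted only when both members are
noncoding — so a coding element between two CNEs breaks their adjacency
rather than being ignored. Pairs with a member longer than 1,000 bp are
excluded (such elements likely collapse several conserved elements); with the
100 bp minimum this brackets the size range of typical individual regulatory
elements.

Orthologs of each CNE in the other species are accepted as reciprocal best
hits (RBH): the top-scoring forward alignment is kept only if the top-scoring
reverse alignment of that target overlaps the original element by at least
1 bp. Ties are broken deterministically (score, then target start, then
chromosome). Pairs whose orthologs in *any* species lie more than 250,000 bp
apart — or on different chromosomes — are discarded entirely, to avoid
spurious inferences from wrong orthology or large rearrangements. A pair is
*mammalian conserved* when both CNEs have orthologs within that cap in
platypus (the deepest mammal in the panel, which makes the mammalian ancestor
reconstructible), and *deeply conserved* when the same holds in at least two
nonmammalian vertebrates. The 250 kb cap is applied to midpoint distances,
consistent with how the pair distance itself is measured; conservation in a
species does not require adjacency there, except in the cross-species
("adjacent-orthologous", AO) analysis where the paper-level definition
demands it.

# Ancestral reconstruction

Inter-CNE distances (midpoint to midpoint) observed at the tips of a dated
phylogeny are treated as a continuous character evolving by Brownian motion.
The maximum-likelihood estimate of the state at an internal node is the
generalized-least-squares mean
$$\hat x \;=\; \frac{\mathbf 1' C^{-1} x}{\mathbf 1' C^{-1} \mathbf 1},$$
where $C_{ij}$ is the shared path length from the target node to tips $i$ and
$j$ (the BM covariance of the tree rerooted at that node). The BM rate
$\sigma^2$ cancels, so it never needs to be estimated. The estimate is a
convex combination of the tip values (it always lies within their range) and
is affine-equivariant. Tests verify agreement with brute-force numerical
maximization of the joint BM likelihood over all internal states to within
$10^{-6}$, and with an independent phylogenetics implementation.

Practical choices:

* **Polytomies** need no resolution: only path lengths enter $C$, and any
  zero-length arbitrary resolution leaves all path lengths unchanged. A
  seeded `resolve_polytomies()` helper is provided for workflows that want a
  strictly binary tree.
* **Missing species** are pruned per pair (pairwise deletion), mirroring
  per-pair ortholog availability. A pair is reconstructible at the mammalian
  ancestor only if platypus is observed (the node must subtend data on both
  sides); such pairs are otherwise flagged and skipped, as are pairs with
  fewer than two mammalian observations.
* The trait is reconstructed on the raw bp scale, because the downstream
  statistic consumes raw distances. Transposon content is reconstructed as a
  **length** (covered bp within the midpoint span) with the same machinery,
  floored at zero (flagged when clamped).

# The nRDD and nRTD statistics

With $d_h$ the present-day inter-CNE distance, $d_r$ the reconstructed
ancestral distance, and $G_h, G_r$ the genome sizes (ancestor default
3,270,000,000 bp),
$$\mathrm{nRDD} = \frac{d_h/G_h - d_r/G_r}{\left(d_h/G_h + d_r/G_r\right)/2}.$$
Genome-size normalization removes the genome-wide expansion trend; dividing
the difference by the mean makes changes relative, so a doubling from a small
base ranks above a modest change from a large base. For positive inputs the
statistic is strictly inside $(-2, 2)$; positive values are expansions,
negative contractions. nRTD applies the same form to transposon-covered base
pairs $T_h, T_r$ within the midpoint span. Because transposon lengths can
legitimately be zero, the boundary values are attainable ($-2$ = complete
loss, $+2$ = pure gain) and $T_h = T_r = 0$ is **undefined** — transposon-free
pairs are reported as their own category rather than silently scored 0.

Pairs are ranked by nRDD into ten equal-sized groups (group 1 = strongest
contraction, group 10 = strongest expansion). The split is deterministic:
stable sort by (value, pair id), block sizes differ by at most one, and the
first groups absorb any remainder.

Two distinct inter-CNE conventions coexist deliberately, each where its
quantity is defined: distances and transposon lengths use the
**midpoint-to-midpoint span**, epigenetic summaries use the **inner-edge
interval** between the CNEs.

# Randomization tests

The transposon depletion test samples, per replicate, one length-matched
random interval per inter-CNE sequence (uniform start, fully inside a
chromosome) and compares real against random per-class densities with a
paired two-sided Wilcoxon signed-rank test (sidedness is not dictated by the
procedure itself, so the direction of the median paired difference is
reported separately). Two summaries are emitted per class:
`prop_significant`, the literal proportion of replicates with $p \le 0.05$,
and the headline `empirical_p = 1 - prop_significant`, which is small exactly
when the real densities differ consistently from random. Both conventions
appear in the literature one subtraction apart; emitting both removes the
ambiguity.

When the real regions are fixed, the replicate p-values are correlated
through them, and the significance proportion of a single experiment is not
a calibration diagnostic — it concentrates near 0 or 1 depending on the
draw. `null_calibration = TRUE` therefore redraws the "real" set per
replicate as well; each replicate then compares two samples from the same
null process, the p-values are independent, and `prop_significant` estimates
the per-replicate test's actual size (verified to land in $0.05 \pm 0.02$
over 1,000 replicates). The same dual reporting is used for the inter-CNE
enrichment randomization, which compares best-200-bp-window fold enrichments
of real inter-CNE sequences against length-matched random regions with an
unpaired rank-sum test.

Gain/loss calls compare $T_h$ and $T_r$ with a 1 bp tolerance (ancestral
estimates are continuous): loss = ancestral presence only, gain = present-day
presence only. A pair is transposon-free when all classes are absent (within
tolerance) in both genomes.

# Epigenetic profiles and the SOM

Per pair, tissue and histone mark (H3K27ac, H3K27me3, H3K4me1, H3K4me3,
H3K9me3; fold enrichment over the control, so 1.0 is background), four
regions are summarized: 300-bp windows centered on each CNE midpoint, the
inner-edge inter-CNE sequence, and the best 200-bp window inside it. The
window scan slides at the track bin size (25 bp; Roadmap-style tracks are
binned, so a 1 bp stride would be spurious precision) plus one end-anchored
window so the region tail is always covered. Inter-CNE sequences shorter
than 200 bp fall back to the whole-region mean, flagged. Note that the
"best window dominates the regional mean" property is guaranteed by the scan
only when signal mass is not concentrated exclusively at both extreme edges
of the region; with baseline-1 tracks and contiguous signal blocks, as here,
it holds and is asserted per pair in the tests. The two CNEs are relabelled
CNE_h/CNE_l by their overall H3K27ac level (mean of the CNE-window summaries
across tissues; ties go left), and features are assembled tissue-major as
tissue x (CNE_h, CNE_l, inter, best200) x mark — 420 columns for 21 tissues,
1,160 for 58.

Pairs are clustered with a Kohonen self-organizing map: 12 units on a 4 x 3
hexagonal grid (the closest-to-square layout for 12), codebooks initialized
to a random sample of input rows, online training for `t_max` iterations
drawing one row at a time, bubble neighborhood (constant update factor
inside the radius, zero outside). The learning rate declines linearly
0.05 to 0.01. The neighborhood radius declines linearly from half the grid
diameter to **zero**: early iterations order the map coarsely, late
iterations fine-tune the winner alone. A schedule that never drops below
radius 1 keeps dragging every unit's neighbors on each update and provably
fails the basic sanity requirement that training reduce quantization error
below that of the random initialization; the annealed-to-zero schedule
satisfies it and is the package default (both endpoints are exposed).
Features enter unscaled — fold enrichments share a scale across marks — with
a z-scaling option available.

Units are summarized by their mean enrichment per (region, mark) across
tissues and member pairs; unit summaries are clustered by complete-linkage
hierarchical clustering (Euclidean) cut at $k = 4$. Across two maps (e.g.
two species), units are matched as reciprocal Euclidean nearest neighbours,
and unmatched units inherit the cluster of their nearest matched unit.
Specific unit-to-cluster assignments are data outcomes, not constants: the
package reproduces the procedure, never hard-codes the labels.

# Enrichment statistics

Group-in-unit enrichment uses the odds ratio
$(N_{ij}/N_{i\bar j})/(N_{\bar i j}/N_{\bar i \bar j})$ with single-sided
(overrepresentation) Fisher exact p-values and Benjamini–Hochberg FDR across
the whole group x unit family (10 x 12 = 120 tests in the decile analysis).
The one-sided p-value is the exact hypergeometric tail $P[X \ge N_{ij}]$,
computed from the vectorized distribution function and verified against
exhaustive term-by-term enumeration for every table with total at most 60.
Wilcoxon tests use exact null distributions for small samples (signed-rank
$n \le 25$, rank-sum $n, m \le 12$) with zeros dropped and midranks for ties
— the exact branches are computed by convolution over doubled midranks, so
ties do not force an approximation — and the normal approximation with
continuity correction above those sizes.

# The synthetic-data generator

The generator emulates the full input stack with planted truth. Its defaults
are the study conditions, fixed once:

| Parameter | Default | Meaning |
|---|---|---|
| species panel | 23 vertebrates (16 mammals) | dated ultrametric tree, mammalian MRCA at 177 My |
| `n_pairs` | 500 | planted CNE-CNE pairs |
| `d_range` | 1,000–20,000 bp (log-uniform) | ancestral inter-CNE distances, kb-scale like the real medians |
| `sigma2` | 25 bp²/My | BM rate: ~70 bp drift sd over the tree depth, i.e. strong conservation |
| `class_fractions` | 0.3 / 0.4 / 0.3 | contracted / conserved / expanded, mirroring nRDD groups 1–3 / 4–7 / 8–10 |
| `shift_frac` | 0.5 | deterministic ∓50% change on the focal terminal branch |
| `min_distance` | 200 bp | lower clip for simulated distances |
| `tp_level` | 0.15 | ancestral inter-CNE transposon content (fraction of $d_r^*$), split 0.1/0.1/0.4/0.4 over DNA/LTR/LINE/SINE |
| `tp_gain_frac` | 0.5 | extra focal SINE/LINE content of expanded pairs, matching the planted expansion |
| `tp_background` | 0.46 | genome-wide transposon coverage (the random expectation) |
| `archetype_fractions` | 0.56 / 0.34 / 0.05 / 0.05 | inactive / inter-CNE-poised / CNE-poised / CNE-active epigenetic archetypes |
| `signal_amplitude`, `noise_sd` | 5, 0.25 | archetype fold-enrichment over baseline 1.0; Gaussian track noise |
| `n_tissues` | 3 | signal tracks per mark |

Design points worth knowing:

* The true ancestral distance $d_r^*$ is planted **at the mammalian MRCA**
  and tip values are simulated by BM outward over the tree rerooted there.
  BM is direction-free, so this is distribution-identical to simulating from
  the root conditioned on the MRCA state — and the planted value is exactly
  the quantity the estimator targets.
* Distances evolve on the raw bp scale with clipping at 200 bp. Clipping
  introduces a small upward bias at the bottom of the distance range; at the
  default rate the clip never triggers above ~200 bp ancestral distances, so
  recovery tests are unaffected.
* Each species gets one synthetic chromosome (auto-sized to 3x the span of
  placed elements). Elements are placed so midpoint distances match the
  simulated tip values **exactly**; CNE lengths are drawn once per pair from
  [100, min(1000, d−101)] so the inter-CNE gap never falls below the 100 bp
  merge threshold.
* A spacer conserved element overlapping a decoy protein-coding exon sits
  between consecutive pairs, so between-pair adjacencies are coding and
  never produce spurious CNE-CNE pairs; the chromosome tail carries decoy
  genes with exon/UTR/intron-overlapping elements to exercise the
  annotation filter. Background transposons (one uniform-length interval per
  5 kb window, 0.46 expected coverage) are emitted for the reference genomes
  outside the pair regions.
* Hit tables contain the true ortholog as best hit; a configurable fraction
  of decoy hits scores in [0.5, 0.95] of the best, and a separate fraction
  can be made reciprocal-best-violating to exercise RBH rejection.

What the generator does **not** emulate: sequence content (no FASTA
anywhere), assembly gaps, transposon subfamilies and ages, lineage-specific
rate variation, and correlated noise between tissues. Passing recovery tests
therefore demonstrates the correctness of the statistical machinery under
the stated model, not robustness to real-data artifacts such as alignment
error or assembly incompleteness.

# Validation at study scale

The standing acceptance checks run on a 500-pair data set under the default
conditions: ancestral distances are recovered with median relative error
below 5% (observed ~0.7%; the residual bias comes from the planted focal
shift leaking through the focal tip's small GLS weight); the nRDD sign
matches the planted class for at least 90% of shifted pairs (observed 100%);
and the SOM unit clusters recover the planted archetypes with adjusted Rand
index at least 0.7 (observed ~0.98). The planted group-in-unit enrichment
check simulates a 3x overrepresentation directly; 1,500 pairs are used for
that check (the regime where a single true signal reliably survives BH
across the 120-test family — at exactly 500 pairs the detection probability
of a 3x effect is near 50%, so a single-draw assertion would be
uninformative). Null calibration of the depletion test uses 1,000
independent replicates against a 10 Mb background genome at 0.46 coverage.

# Known limitations

* The BM model assumes a single rate across pairs and lineages; the
  estimator is exact under the model but underpowered for lineage-specific
  changes.
* RBH orthology is a proxy; the pipeline consumes alignment hit tables and
  does not run an aligner.
* The SOM objective is non-convex: different seeds give different (similarly
  good) maps. All seeds are explicit arguments.
* `empirical_p` inherits the granularity of its replicate count
  (1/`n_rep`).
* The paper-scale genome-wide counts (hundreds of thousands of elements)
  are out of desk-scale reach; correctness is established by closed-form
  oracles, null calibration and planted-truth recovery instead.
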