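# cnepairs

Evolutionary and epigenetic analysis of **pairs of adjacent conserved
noncoding elements (CNEs)** in R.

Comparative genomics has catalogued hundreds of thousands of conserved
noncoding elements in mammalian genomes, many of them *cis*-regulatory.
Beyond the elements themselves, the *distance* between two adjacent CNEs is
under evolutionary constraint, and changes in that distance — contractions
and expansions relative to the common mammalian ancestor — track
transposable-element turnover and the regulatory activity of the elements.
`cnepairs` implements that analysis as a tested, reusable pipeline for
computational biologists working on regulatory genome architecture:

* **Pair building** — merge/filter conserved-element sets, classify against a
  protein-coding annotation (exon > UTR > intron > intergenic), form pairs of
  adjacent CNEs, assign orthologs by reciprocal best hits, and classify
  mammalian / deep conservation (with a 250 kb ortholog-distance discard).
* **Ancestral reconstruction** — maximum-likelihood Brownian-motion estimates
  of inter-CNE distances and transposon content at the common mammalian
  ancestor. The ML state at a node is the generalized-least-squares mean
  `(1'C⁻¹x)/(1'C⁻¹1)`, with `C` the BM covariance of the tree rerooted at
  that node; the rate σ² cancels.
* **nRDD / nRTD** — the genome size-normalized relative difference

  ```
  nRDD = (d_h/G_h − d_r/G_r) / ((d_h/G_h + d_r/G_r) / 2)
  ```

  bounded in (−2, 2): negative = contraction, positive = expansion relative
  to the ancestor (`G_r` = 3,270,000,000 bp). nRTD is the same form on
  transposon-covered base pairs. Pairs are ranked into nRDD deciles.
* **Transposons** — per-class (DNA/LTR/LINE/SINE) densities, a
  length-matched randomization test for depletion (with a null-calibration
  mode), gain/loss calls against the ancestor, transposon-free detection.
* **Epigenetics** — per-pair histone-mark summaries (300-bp CNE windows,
  inter-CNE sequence, best 200-bp window), CNE_h/CNE_l sorting by H3K27ac,
  a tissue × region × mark feature matrix (420 columns for 21 tissues).
* **SOM clustering** — a hand-rolled online Kohonen map (12 hexagonal units,
  bubble neighborhood), unit summaries, reciprocal unit matching across
  maps, complete-linkage unit clusters.
* **Enrichment statistics** — odds ratios, single-sided Fisher exact tests,
  BH-FDR, exact small-sample Wilcoxon tests with midrank tie handling.
* **Synthetic data** — a generator that emulates the whole input stack
  (elements, orthology hit tables, transposons, signal tracks, a dated
  23-species tree) with planted ground truth: true ancestral distances,
  contraction/expansion classes and epigenetic archetypes per pair.

## Worked example

Simulate a 60-pair data set under the default study conditions and run the
full pipeline (100 depletion replicates for speed):

```r
library(cnepairs)
cfg <- sim_config(seed = 7L, n_pairs = 60L)
sim <- simulate_cne_data(cfg)
res <- run_cne_pipeline(sim, n_rep = 100L)

head(res$metrics[!is.na(res$metrics$nrdd),
                 c("pair_id", "d_h", "d_r", "nrdd", "nrdd_group", "category")], 5)
#>         pair_id   d_h     d_r   nrdd nrdd_group category
#> 1 p0001L|p0001R 19426 19358.8  0.057          5     both
#> 2 p0002L|p0002R  4969  3338.4  0.444          8     both
#> 3 p0003L|p0003R   622  1390.3 -0.718          1     both
#> 4 p0004L|p0004R  1828  1204.2  0.462         10     both
#> 5 p0005L|p0005R  3145  2124.5  0.438          7     both
```

Each planted pair is recovered with its present-day distance `d_h`, the
reconstructed ancestral distance `d_r`, the nRDD (pair 3 is a planted
contraction: `d_h` ≈ 0.5 × `d_r`, nRDD −0.72, decile group 1), and its
conservation category (`both` = conserved in platypus and in ≥ 2
nonmammalian vertebrates).

```r
res$depletion[, c("class", "prop_significant", "empirical_p", "direction")]
#>   class prop_significant empirical_p direction
#> 1   DNA             0.42        0.58  enriched
#> 2   LTR             0.05        0.95  enriched
#> 3  LINE             0.34        0.66      none
#> 4  SINE             0.14        0.86      none
#> 5 total             0.98        0.02  depleted
```

The planted inter-CNE sequences carry ~0.15 transposon coverage against a
0.46 genome background, so the overall depletion is detected
(`empirical_p = 0.02`, direction `depleted`) while individual classes are
noisier at 60 pairs.

```r
truth <- res$truth
arch <- truth$archetype[match(rownames(res$features), truth$pair_id)]
table(cluster = res$unit_clusters[res$assignments[!is.na(arch)]],
      archetype = arch[!is.na(arch)])
#>        archetype
#> cluster cne_active cne_poised inactive inter_poised
#>       1          0          0       28            1
#>       2          0          2        0            0
#>       3          0          0        0           26
#>       4          3          0        0            0
```

The four SOM unit clusters recover the four planted epigenetic archetypes
almost perfectly — the same structure the analysis reads off real data
(inactive pairs, pairs with a poised element inside the inter-CNE sequence,
poised CNEs, active CNEs).

## Documentation

The methods vignette (`vignettes/cnepairs-methods.Rmd`) documents the model
and its assumptions, all tunable parameters with defaults and rationale,
what the synthetic generator does and does not emulate, and the numerical
conventions (tie-breaks, clamping, degenerate inputs).
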