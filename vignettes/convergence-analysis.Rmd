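---
title: "Methods: convergence analysis of chromatin regulator targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence analysis of chromatin regulator targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `chromconverge`, the
choices that were genuinely open when it was designed, and what its
synthetic-data tests do and do not establish about real data.

## The experimental design the package serves

Two chromatin regulators are suspected of regulating a shared program: one
is profiled by ChIP-seq (two biological replicates plus input), the other's
targets are known from a histone-mark study and arrive as a gene list. Both
are perturbed and the transcriptomes of the perturbed tissues are compared
to controls by RNA-seq. Convergence is then quantified at two levels —
shared genomic targets and shared differentially expressed genes — and a
behavioral assay asks whether the phenotype follows. The package implements
the statistics of that design; it deliberately consumes peak calls and
count matrices rather than raw reads (alignment and peak calling are
well-served by existing tools and are out of scope).

## Replicate concordance

Peak calls from the two replicates are merged into disjoint regions
(book-ended intervals fuse, because a binding site split at an arbitrary
call boundary is one site), reads are counted per region per replicate, and
counts are normalized to library size. A region is kept when

* mean normalized reads > `min_mean` (default 100 reads, strict), and
* max/min replicate ratio < `max_ratio` (default 2, strict).

Both inequalities are strict, so a region sitting exactly at a threshold is
rejected. Three degenerate cases are decided explicitly: exactly one zero
count gives an infinite ratio (rejected, `high_ratio`); two zero counts
make the ratio undefined (rejected, `low_mean`); and normalization rescales
to the *mean* of the two library sizes, keeping values on a reads-like
scale so that the 100-read threshold retains its meaning. Rescaling to
anything else (say, per-million) would silently change what `min_mean`
means.

The optional clustering QC replaces a manual inspection step with a
reproducible criterion: peaks are represented by binned read-intensity
profiles (`bin` = 50 bp, `window` = 2000 bp) around their midpoints,
clustered by k-means with a fixed seed, and a cluster is flagged when its
mean center-bin intensity falls below `flag_fraction` (default 0.25) of the
global mean. With fewer distinct profiles than clusters, each distinct
profile is its own cluster. Flagged-cluster membership adds a `bad_cluster`
flag rather than silently deleting peaks.

## Promoter annotation and enrichment

Assignment is midpoint-based: wide peaks are otherwise ambiguous, and the
midpoint rule matches the distance-to-TSS logic of standard annotation
tools. The promoter window is **closed** and symmetric, ±`promoter_halfwidth`
(default 1000 bp) around the TSS, with promoter taking precedence over the
TES window, then gene-body containment, then intergenic. The annotation
model carries only TSS and TES per gene, so exon/intron/UTR subcategories
collapse into `gene_body`; with transcript-resolved annotation they would
split, but none of the package's statistics depend on that split.
Equidistant nearest-gene ties break to the lexicographically smallest
`gene_id` — arbitrary, but deterministic and documented.

Fold enrichment compares the observed category fractions to `n_random`
positions sampled uniformly with the *same width distribution* as the
peaks. Width-matching matters: single-base null positions understate the
promoter hit rate of wide peaks. At the default `n_random = 50000` the
Monte-Carlo error on a 10% category is under 2% relative; categories with
zero random mass report `fold = Inf` with a warning rather than a silent
division.

The TSS metaprofile flips minus-strand genes so bins run upstream to
downstream, averages over genes, and normalizes per million total reads.
Its reported mass therefore equals (reads inside windows) / (number of
genes × total reads in millions).

## The minimal NB differential-expression stage

This stage is a declared simplification of the full GLM machinery of
dedicated DE packages; it shares threshold semantics, not numerics.

1. **Background filter**: genes with total raw counts < `min_total`
   (default 10, strict) across all samples of the contrast are excluded
   and also removed from every downstream universe.
2. **Size factors**: median-of-ratios against per-gene geometric means;
   defined up to a common scale.
3. **Dispersion**: per-gene method of moments on normalized counts,
   `d = (pooled within-group variance − weighted mean) / weighted mean²`,
   floored at 1e-8, then averaged with equal weights against a parametric
   trend `d(µ) = a0 + a1/µ` fitted across genes. The equal-weights average
   halves the noise of a 4-df moment estimate while letting genuinely
   outlying genes keep half their own signal.
4. **Test**: Wald statistic on `log2((m2 + 0.5)/(m1 + 0.5))` with the NB
   delta-method standard error. The reference distribution is t with
   effective df = 4 × residual df, not the normal: with 2–3 replicates per
   group the normal reference is anticonservative in the far tail, and the
   factor 4 is exactly the variance reduction the dispersion shrinkage
   buys. The package's null-calibration test (≥ 20,000 gene-tests) checks
   the raw-p rejection rate at 0.05 lands in [0.03, 0.07].
5. **Calling**: BH adjustment over tested genes; `up` when padj < `alpha`
   (default 0.05) and fold change > `fc_threshold` (default 1.5); `down`
   when fold change < 1/`fc_threshold`; else `ns`. The threshold is
   applied to unshrunken fold changes — whether a shrunken estimate should
   be thresholded instead is a defensible alternative, so the threshold is
   a plain config value.

The sample QC uses `log2(normalized + 1)` — a pseudocount log transform,
not a variance-stabilizing transformation; it flattens variance enough for
sample-level Euclidean/Pearson comparisons, which is all it is used for.

## Overlap statistics

`P(X ≥ k)` is an exact hypergeometric upper tail summed in log space
(lgamma), accurate for enrichments far beyond double-precision tail
probabilities, and is verified in the tests against exact counting
enumeration for every instance with N ≤ 25. The universe is always an
explicit argument: different questions legitimately use different universes
(all annotated genes for genomic-target overlap; expressed genes for DE
overlap), and inferring one silently is how irreproducible p-values happen.
Query genes missing from the universe are added to it with a warning by
default (`lenient`, the common web-tool behavior); `strict` errors and
`intersect` drops them.

Direct/indirect classification encodes regulator logic: an activator's
direct targets are its bound genes that go *down* when it is lost; a
repressor's are its mark-loss genes that go *up*. Everything else
differentially expressed is potentially indirect. The directional breakdown
of shared DE genes is a 2×2 table tested against independence with a
two-sided Fisher exact test; its four cells must (and are asserted to) sum
to the shared total.

## Courtship statistics

The learning index LI = (mean naive CI − mean trained CI)/mean naive CI is
scale-free and undefined when naive courtship is zero (an explicit error,
not NaN). Within a genotype, naive vs trained CIs are compared by
Mann-Whitney: exact when the combined n ≤ 12 without ties, otherwise the
normal approximation with mid-ranks, tie correction and continuity
correction; completely tied data return p = 1.

Between genotypes, the LI difference is tested by resampling. The null
distribution pools CIs within each condition across genotypes (preserving
the naive/trained structure the LI needs), then draws bootstrap groups of
the original sizes with replacement and recomputes the difference; the
two-sided p uses the add-one estimator `(1 + #{|Δ*| ≥ |Δobs|})/(1 + B)`,
which cannot return zero. The literature uses "randomization test" and
"bootstrap" loosely for this design; resampling-with-replacement from the
condition-pooled null is the implemented default, and a label-permutation
variant is available behind `scheme = "permutation"`. The default
`n_replicates = 10000` puts the resolution of p near 1e-4.

## qPCR arithmetic

ΔΔCt with several reference genes combines them by arithmetic mean on the
Ct scale — the geometric mean of their expression, the standard choice when
no combination rule is stated. ChIP-qPCR fold enrichment is percent input
of the positive region over the mean percent input of two negative regions;
the input-dilution fraction is an explicit config value
(`input_fraction`, default 1%) because it is a property of the bench
protocol, not of the data. Both operations are invariant to adding a
constant to every Ct, which the tests assert.

## What the synthetic data emulates — and what it does not

The generators define the operating conditions under which the package's
statistical claims are tested:

* **Peaks**: ~2,600 regions per experiment (1,200 promoter-class true,
  600 distal true, 400 low-signal at mean 20 reads, 400 discordant at a
  3-fold replicate imbalance), NB counts with mean 500 and dispersion 0.05,
  on a 4 × 8 Mb genome with 2,000 genes. Replicates are depth-matched by
  default; with library sizes computed only from in-region reads, the
  discordant class itself would skew the totals and normalization would
  partially cancel the planted imbalance, which matched sequencing depth —
  the realistic situation — avoids.
* **Counts**: log-normal baselines (median 100), NB dispersion 0.05,
  deterministic DE assignment (exactly `round(de_fraction · n_genes)` genes
  per contrast, a controlled shared subset with directions independent
  between contrasts by default), and a planted lowly-expressed class to
  exercise the background filter.
* **Courtship**: beta-distributed CIs parameterized by (mean,
  concentration) — a bounded proportion needs a bounded distribution —
  with group sizes 56/59/60/62 matching a typical experiment, naive mean
  0.72, and trained means 0.30 (intact memory) vs 0.65 (deficit). These
  means are realistic round values chosen once; no published per-fly
  distributions exist to fit.

Passing tests on these conditions show the machinery is correct and
calibrated *under the stated models*: NB counts with a common dispersion,
reads placed uniformly within regions, beta-distributed indices,
independent samples. Real data add GC and mappability bias, peak-width
heterogeneity, correlated replicates, batch effects and dispersion trends
that the generators deliberately omit — so the tests validate the
statistics, not any claim about a particular dataset.

## Problem sizes and runtime choices

The test-suite and acceptance-script problem sizes are chosen so that the
binomial noise of a measured rate is small against the margin being
asserted: 1,800 true / 800 spurious regions for the recovery rates, 21,000
genes for null calibration, 400–1,000 simulated behavioral datasets with
1,000 bootstrap replicates each for the randomization-test calibration, and
50,000 random positions for enrichment folds. The full-oracle hypergeometric
sweep covers every (N ≤ 25, K, n, k) instance.

## Known limitations

* The DE stage fits no GLM and shrinks no fold changes; with complex
  designs (batch, paired samples) use a dedicated package and feed its
  output into the convergence statistics, which accept any table with
  `gene_id` and `status`.
* Annotation is gene-level; transcript isoforms and alternative TSSs are
  not modeled.
* The bootstrap null pools conditions across genotypes; if the two
  genotypes have very different CI variances the test's calibration under
  heteroscedasticity is not guaranteed by the included checks.
* Coordinates are 0-based half-open throughout; 1-based inputs must be
  declared at the readers.
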