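---
title: "riskstack: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riskstack: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riskstack` scores every gene for similarity to an established set of disease
risk genes by stacking two balanced random forests — one over developmental
expression trajectories, one over interaction-network shortest paths — with
prior gene-level predictors in a final forest. This vignette is the package's
own account of the method: what each stage assumes, which knobs matter, where
the design was genuinely open and what we chose, and what the synthetic-data
tests do and do not demonstrate.

## Trajectory features from irregular developmental expression

The expression input is a gene × sample matrix over brain regions and donor
ages. The data are irregular (regions differ in age coverage) and redundant
(several samples can share a region and age). Featurization proceeds:

1. **Region filter.** Regions with fewer than `min_samples = 20` samples are
   dropped; a region with exactly 20 stays. On the reference atlas this keeps
   16 of 26 structures.
2. **Age scale.** Age labels (`"8 pcw"`, `"4 mos"`, `"40 yrs"`) are mapped to
   post-conception weeks with fixed constants: birth = 40 pcw, 1 month =
   52/12 weeks, 1 year = 52 weeks. The downstream smoother only needs a
   strictly monotone age axis, so any such convention is equivalent up to
   grid placement; we fix this one for reproducibility.
3. **Smoothing and interpolation.** Per gene and region, replicate
   measurements at the same age are mean-averaged, the trajectory is
   LOWESS-smoothed with span `f = 2/3` and 3 robustness iterations (the
   smoother's classical defaults; nothing in the method prescribes others),
   and linearly interpolated onto a single global grid of `grid_size = 50`
   equally spaced ages spanning the minimum–maximum age over all retained
   samples. Grid points outside a region's observed range take the nearest
   smoothed endpoint value (constant extension). A per-region grid was the
   alternative; the global grid matches "covering the full span of ages" and
   keeps feature columns comparable across regions, at the cost of flat
   extrapolated stretches in regions with narrow coverage.
4. **Scaling.** Per gene, the concatenated (regions × grid) vector is
   z-scaled to mean 0, sd 1; constant genes map to all zeros. The original
   description ("for each gene, we z-scaled each timepoint") is ambiguous
   between row- and column-scaling; we adopt per-gene row scaling — it reads
   most naturally and makes trajectories magnitude-free, so only shape
   matters — and expose `scale = "timepoint"` for the per-column alternative.

Column order is deterministic (regions lexicographic, grid index ascending),
so feature matrices are byte-reproducible. With 16 regions and a 50-point
grid each gene gets 800 features.

## Network features

Interactions with confidence below `min_score = 0.4` are removed (a score of
exactly 0.4 stays), and the remaining graph is converted to an all-pairs
unweighted hop-count matrix — "minimum number of steps", not
confidence-weighted paths. Unreachable pairs, including isolated nodes, are
imputed with (max finite off-diagonal distance + 1): finite, and ordinally
"farther than anything observed". A numeric `sentinel` override is available.
The matrix is computed on the full node set rather than the largest connected
component, so isolated genes are scored too (their whole profile is the
imputed value).

## The balanced forest engine

Each tree is grown on exactly `per_class = 70` in-bag draws from each class,
sampled with replacement within class (the stratified-bootstrap convention of
the classical forest implementation; without-replacement is available). The
draws are made under the package's own RNG and recorded per tree, which makes
three things exactly checkable:

* **Class balance** — per-tree in-bag counts sum to `per_class` in each class.
* **OOB integrity** — a training gene's reported score uses only trees whose
  in-bag excluded it, and is reproducible from the stored masks to exact
  equality. A training row that is in-bag in every tree (possible only for
  tiny forests) falls back to the all-trees score with a warning.
* **Determinism** — a fixed seed yields byte-identical forests and scores.

Trees use Gini impurity, `mtry = floor(sqrt(p))`, and minimum node size 1 —
standard classification defaults, unstated in the original description.
Non-training genes are scored as the fraction of all trees voting positive.

**Backward elimination.** For the network model, features not appearing in at
least one internal split node of at least one tree are dropped and the forest
refit, until every retained feature is used. Each round refits with a fresh
seed derived deterministically from (base seed, round), so rounds are
reproducible but not identical; the per-round feature count strictly
decreases until termination. Note the regime dependence: with many trees
relative to features, nearly every feature is used somewhere by chance and
elimination converges immediately; selection pressure is strongest when the
total split count is small relative to the feature count. The test suite
exercises the discriminating regime with small forests (60 trees, 20 per
class) over 10 informative + 500 noise features, where on average ≥ 95% of
noise features are gone at termination.

## Stacking without leakage

Training labels are the positive gene set plus `n_negative = 1000` genes
sampled uniformly without replacement from the universe after removing the
positives and the full exclusion list (so no gene from the excluded database,
at any confidence level, can be a negative): 76 + 1000 = 1076 labels at the
reference geometry. Training genes are restricted to genes present in both
the expression and the network data, because both level-1 models need feature
rows for every training gene; the scored universe is the union of genes
scorable by either model. The level-2 feature table has ten fixed columns
(the two level-1 scores, then DAWN, Krishnan, DAMAGES, TADA_BF and the four
TADA FDR columns); missing values are imputed with the training-set median of
the column — median rather than mean because the FDR-like columns are heavily
right-skewed — and every imputation is flagged. For training genes the
level-1 entries are the OOB scores, so the level-2 forest never sees a
self-prediction; the test suite asserts this equality exactly.

A single top-level seed fans out to per-stage seeds through a fixed integer
derivation, so the whole pipeline is deterministic and stages can be re-run
independently.

## Evaluation statistics

* **Decile enrichment with a synonymous baseline.** Genes are ranked by score
  (ties broken lexicographically by identifier; decile sizes differ by at
  most one, decile 1 = top). Mutation classes count distinct individuals:
  recurrent LOF = loss-of-function de novo mutations in ≥ 2 probands,
  singleton = exactly 1, recurrent missense analogous; a gene can belong to
  several classes. The expected top-decile proportion is the fraction of
  genes with ≥ 1 synonymous de novo mutation that fall in decile 1 — a
  mutability correction, since long brain-expressed genes accumulate
  mutations at elevated rates. The p-value is the exact upper binomial tail
  P(X ≥ k), one-sided because enrichment is the hypothesis throughout.
  Two numerical notes: the tail is computed through the regularized
  incomplete beta (no underflow at magnitudes like 1e-14), and the test is
  mildly conservative under the null — the binomial is discrete, and the
  target and baseline gene sets share long genes, so the estimated baseline
  co-moves with the observed count. Observed null rejection at 0.05 in the
  test suite is ≈ 3–4%.
* **Worked example.** With the reported 32/44 recurrent-LOF genes in the top
  decile against a printed baseline of 0.196, the exact tail is 3.8e-14; the
  originally reported 4.9e-14 differs by a factor ≈ 1.3, attributable to
  rounding of the printed baseline. Order of magnitude agrees.
* **Covariate-adjusted association.** A maximum-likelihood logistic fit of
  benchmark-set membership on a score plus covariates (typically the five
  TADA columns), excluded genes removed first; reports the score
  coefficient's Wald Z and two-sided p. Perfect separation and score–covariate
  collinearity are flagged as errors rather than returning fragile estimates.
* **Rank-sum enrichment.** One-sided (subset greater). With no ties and small
  samples the exact permutation distribution is used (so enumeration oracles
  match to 1e-12); otherwise the normal approximation with tie and continuity
  corrections. All-tied input returns p = 1.
* **Fisher overlap.** 2×2 exact test against a background universe; the
  conditional maximum-likelihood odds ratio is reported as primary (the
  convention of the standard exact-test implementation) with the sample
  cross-product ratio alongside.
* **eQTL/GWAS bins.** Genes are split into 5% score quantile bins with the
  same tie-break as deciles; each eQTL record is a hit if its GWAS p < 0.01;
  the unit of counting is the record, not the gene. The top bin is compared
  to all lower bins by the exact test, and a cumulative odds ratio (bin-and-
  better vs lower) is reported per bin — 19 values for 20 bins, since the
  lowest bin has nothing below it.

## Size-constrained clustering

Top-decile genes are clustered on their induced subgraph with greedy
agglomerative modularity optimization, using edge confidences as weights (the
interactions are loaded unfiltered; an unweighted switch exists). Clusters
larger than `max_size = 200` are re-clustered on their own induced subgraph,
depth-first; recursion stops for a cluster when optimization yields no split,
in which case it is retained whatever its size and flagged (with the greedy
implementation used, a single-community result effectively occurs only for
edgeless subgraphs, so the flag is rare in practice). Clusters smaller than
`min_size = 30` are discarded, with each discarded gene and the reason
reported. Vertex order is fixed lexicographically, so results are
deterministic. Per-cluster statistics are the upper-tail hypergeometric
overlap with a reference set against a fixed background of 18,000 genes
(regardless of how many genes were clustered — the stated convention), and a
per-cluster exact test of pLI > 0.5 against all other clustered genes.

## The synthetic data and what the tests show

The generators produce every input the pipeline reads, with the statistical
structure the method assumes: positive genes follow smooth trajectory
archetypes (prenatal peak, postnatal rise, prenatal decline) with
region-specific amplitudes over irregular replicate-bearing ages, and two
regions sit below the sample filter; the network is a planted partition with
positives concentrated in 3 of 10 communities and confidences straddling the
0.4 filter; prior columns carry label signal with per-column missingness;
synonymous de novo rates follow a log-normal gene-length covariate only,
while LOF/missense rates are multiplied 10×/3× in positives; eQTL hit
probability is 0.3 for top-scoring genes vs 0.1 elsewhere; pLI is elevated in
the positive communities.

Defaults are sized to run the full pipeline in well under a minute on one CPU
(2000 genes, 16 + 2 regions, 60 donors) while keeping the reference label
geometry (76/1000). The acceptance suite runs the complete ensemble at these
conditions over 5 seeds (final AUROC ≥ 0.85 and within 0.02 of the best
level-1 model, chance level under permuted labels), checks calibration of the
enrichment tests over hundreds of null replicates, and verifies every
statistic against brute-force enumeration oracles. Scaled-down unit tests
(e.g. 400-gene null AUROC checks) use correspondingly wider chance bands,
since AUROC variance grows as the positive class shrinks.

What passing does **not** show: biological realism. The archetypes are three
smooth curves, not real developmental programs; network confidences are
independent of topology; GWAS p-values have no linkage structure; prior
columns are conditionally independent given the label. The tests demonstrate
that the machinery — featurization, balanced OOB stacking, elimination, the
statistics and clustering — behaves correctly and recovers signal it is
designed to see, not that the score would attain any particular real-data
performance.

## Known limitations

* Gene identifiers are opaque, case-sensitive strings matched exactly; no
  alias resolution across sources.
* The level-1 network model drops genes absent from the network; they are
  recovered in the final score only through meta-feature imputation, which
  pulls them toward the training median.
* The decile-enrichment null is mildly conservative (see above); reported
  p-values are exact tails, not recalibrated.
* An unsplittable cluster larger than `max_size` is retained and flagged, not
  forcibly partitioned.
* With forests large relative to the feature count, backward elimination is
  intentionally a no-op (every feature gets used by chance); it is a
  dimensionality-reduction device for wide feature matrices, not a general
  variable-selection method.
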