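---
title: "Methods: domain insertion permissibility profiling with dipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain insertion permissibility profiling with dipscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement

Domain insertion profiling asks, for every residue position of a protein,
whether the protein tolerates a large domain inserted there. A transposon
(MuA-type, leaving a 5-bp target-site duplication) places a cassette —
domain plus short linkers (Ala-Ser on the N side, Gly-Ser-Ala on the C
side) — at quasi-random positions of the coding sequence. Insertions occur
in six configurations (three frames, two orientations) of which only
in-frame, forward insertions are *productive*. For a membrane channel such
as Kir2.1, a variant that folds, assembles and traffics presents an
extracellular epitope; FACS therefore splits the expressing library into a
surface-expressed (SE) and a not-surface-expressed (NSE) pool, and each
pool's insertion sites are read out by junction sequencing.

**Permissibility** at residue *i* in replicate *j* is the enrichment

$$F(i,j) = \frac{r^i_{j,SE}}{t_{j,SE}} - \frac{r^i_{j,NSE}}{t_{j,NSE}},$$

the difference in read fractions between pools; the replicate mean
$G(i) = \tfrac{1}{n}\sum_j F(i,j)$ is the per-site score, which is
z-scored for structure mapping and binarized (1 = permissive) for model
training and site comparisons. **Differential permissibility** — the same
site tolerating one domain but not another — is the package's central
comparison: a candidate signature of latent allosteric capacity.

# The score ladder and its conventions

* **Totals.** $t$ is the pool's total *productive* read count
  ($t = \sum_i r^i$). This makes $F$ scale-free and gives an exact
  invariant: when every position has reads in both pools,
  $\sum_i F(i) = 0$. (Totals over all mapped reads would only rescale $F$.)
* **Missingness.** $F(i,j)$ is defined only where both pools have reads at
  $i$; otherwise NA. NA positions are excluded from means, z-scores,
  binarization and model training. The single deliberate exception is the
  dataset/position correlation analysis, where NA is replaced by 0 before
  correlating — dropping those rows entirely would discard most of the
  position universe and add sampling noise to between-dataset comparisons.
* **Replicate mean.** $G$ averages the replicates where $F$ is defined
  (`n_used` is reported); a strict divide-by-$n$ mode exists but biases
  partially-missing positions toward 0.
* **Near-zero trimming.** Positions whose raw enrichment sits in the open
  band $(-10^{-4}, +10^{-4})$ in too many datasets are ambiguous between
  "neutral" and "undersampled". `trim_near_zero()` keeps a position when
  the in-band fraction (NA counted as in-band) is at most `max_fraction`:
  6/16 for correlation analyses, 1/2 for property correlations, and
  per-profile for model training. Both `eps` and `max_fraction` are
  exposed; the band is an absolute raw-enrichment scale, so analyses at a
  different read-fraction scale should set `eps` accordingly.
* **Binarization.** Threshold 0 on $G$: enrichment toward the SE pool is
  permissive. The cut-point is exposed (`threshold`).
* **Percent rendering.** Coverage percentages round half-up at the
  caller's precision (170/293 → "58.0%", 293/435 → "67%").

# Insertion calling from junction reads

A junction read contains a reference anchor and a cassette anchor. The
caller locates the cassette anchor from a cassette *terminus* k-mer
(`min_anchor` = 15 nt by default): the cassette-start k-mer when the
cassette occupies the read's 3' end (upstream junction), the cassette-end
k-mer when it occupies the 5' end (downstream junction). Anchoring at the
terminus rather than maximally extending the reference match matters
because of the 5-bp target-site duplication: the reference flank abuts the
cassette terminus, and with probability ~1/4 the flanking base matches the
terminus base by chance, which would shift a maximal-extension breakpoint
by one or more bases. Both the read and its reverse complement are tried
against both cassette strands, so bottom-strand mates and
reverse-orientation insertions are handled uniformly.

Conventions: coordinates are 0-based half-open internally; the duplicated
5-mer is assigned to the reference and `nt_pos` is its first base; an
upstream-junction breakpoint therefore maps to `nt_pos = breakpoint - 5`
and a downstream one to `nt_pos = breakpoint`. `aa_pos = nt_pos / 3`
(1-based, "inserted after residue aa_pos") is defined for frame-0 calls; a
call is productive iff forward and frame 0. A reference anchor matching
two or more loci is ambiguous and the read is discarded. Mates are
reconciled by de-duplication — agreeing calls count once, disagreeing
pairs are discarded — with a stricter `policy = "drop"` variant that
discards pairs calling the same insertion twice, since the source
description of duplicate-call removal admits both readings.

# Differential analysis

* **Correlation matrices** (Pearson, NA-as-zero) between datasets or
  positions, ordered by average-linkage hierarchical clustering on
  $1 - r$; the linkage is a package choice, as no standard exists for
  these matrices.
* **Hamming criterion.** After binarization, a site is differential where
  the bits disagree, over sites non-NA in both profiles (XOR on joint
  support); reported as count and integer percent (69 of 229 → "30%").
* **Euclidean metric.** Per-site $|z_A - z_B|$, the 1-D Euclidean
  distance, for quantitative comparisons and rank-sum tests.
* **Region calling.** A centered moving average (window 15 residues, odd
  by construction) of $z_A - z_B$; each window averages its available
  values and returns NA below 8 contributing values (windows narrower than
  8, e.g. window 1, require all values). Regions are maximal runs
  exceeding +1 sample SD of the smoothed series — one-sided, matching how
  positive excursions are shaded in practice; a two-sided flag and a
  raw-series SD option exist.
* **Rank-sum comparisons** use the Mann-Whitney U with exact enumeration
  of all label assignments for $n_A, n_B \le 8$ and a tie-corrected normal
  approximation (no continuity correction) otherwise.
* **Structure export** writes per-residue scores into the B-factor column
  of a PDB file (2 decimals, sentinel −99.0 for unscored residues).

# Decision-tree models

Binarized permissibility is modeled from per-residue protein properties in
three categories (static, conservation, dynamic) with a CART tree grown on
Gini impurity, depth ≤ 4 to limit overfitting, `min_leaf` = 5 to guard
degenerate splits. Growth is deterministic: the largest impurity decrease
wins, ties resolved toward the lowest feature index then the lowest
threshold, so refits are bit-identical and predictions are invariant to
feature-column order in the absence of exact ties. Evaluation is
stratified 10-fold cross-validation (the repeated-CV reading of
"cross-validated 10 times" is noted but the 10-fold reading is used, and
folds are stratified because the class split is uneven); out-of-fold leaf
probabilities are pooled into one ROC (AUC by trapezoid rule) plus
precision/recall/accuracy-vs-cutoff curves. Feature importance is the
size-weighted total Gini decrease, normalized to sum 1.
`withhold_features()` refits without named features or a whole category
and reports the AUC change; complexity is reported as depth-vs-CV-score
rather than a pruning-parameter table.

# Flow-cytometry statistics

Events arrive as plain tables (one row per event: scatter, marker and dye
channels, acquisition index); no FCS dialect is parsed. The dye channel is
arcsinh-transformed with cofactor 150, a common cytometry default (the
transform is standard for this assay; the cofactor is a package choice).
Gating is an ordered list of rectangle and quantile gates;
quantile gates may derive their cut from a designated reference sample.

* **Function score.** The functional gate is the lower 50% of the
  wild-type dye histogram (more hyperpolarized = lower dye signal, since
  the anionic voltage dye partitions into depolarized cells and raises
  their fluorescence). A variant's score is the percent of its events
  below the wild-type median; wild type scores 50% on itself up to
  discreteness. Replicate scores are compared with one-sided Welch t
  tests against the no-channel control.
* **Light/dark dissimilarity.** The 15% most hyperpolarized cells of the
  non-illuminated sample define a gate; in/out counts of dark and light
  samples form a 2×2 table scored by the Pearson chi-squared statistic
  (no continuity correction). Because the statistic grows linearly with
  the event count, per-challenge values are normalized as $\chi^2 / N$
  before averaging over K⁺ challenges — this also corrects for the lower
  effective counts of photobleached, late-acquired samples. Division by a
  matched wild-type value is available as an alternative normalization;
  which correction the original analysis used is not recoverable, so both
  are implemented and $\chi^2 / N$ is the default.
* **Many-to-one tests.** Dunnett's single-step multivariate-t adjustment
  (via multcomp) of pooled-variance many-to-one t statistics against wild
  type; the Bonferroni fallback adjusts the same statistics and is
  therefore never less conservative.

# The synthetic-data generator

The generator emulates the study's data-generating process with known
ground truth; it is first-class, tested code, and every acceptance
property below runs on it.

* **Reference and cassettes.** A random stop-free CDS (ATG first, stop
  last). The default 437 codons leave 435 scoreable internal sites,
  mirroring the 435 candidate positions of the profiled channel. Cassette
  sequences are random stand-ins labelled after the compared domains.
* **Library.** Insertion positions are drawn with weight
  $w(p) = 1 - b\,e^{-p/\lambda}$ ($b = 0.8$, $\lambda = 150$ nt), an
  invented functional form reproducing the transposase's 5'-depressed
  coverage; orientation is uniform; counts are multinomial with
  `n_variants` = 1e5 trials (several tens of cells per productive
  position, within the coverage range a transfected mammalian library
  provides). Each replicate draws a fresh library, matching a design in
  which the complete workflow including library generation is replicated.
* **Ground truth.** Each site has a class and per-domain
  surface-expression probabilities: permissive 0.8, scaffold 0.05,
  intermediate 0.25, differential 0.7 for one random domain and 0.1 for
  the others (gap 0.6). Default mixture: 40% permissive, 35% scaffold,
  40/435 differential, remainder intermediate. The composition was chosen
  once, under two constraints that any recoverable design must satisfy:
  the p_se levels must span several well-separated ranks (a 3-level
  vector caps the achievable Spearman correlation with measured scores at
  0.897 purely through ties), and no class may sit near the enrichment
  zero-crossing — the library-mean p_se, ~0.41 under these defaults —
  where binarization is unstable by construction (hence intermediate at
  0.25, about 4 binomial SDs from the crossing at the default cell
  counts).
* **Sorting and sequencing.** Productive cells split SE/NSE binomially by
  the site's p_se; each pool is sequenced multinomially to
  `depth_per_pool` = 2e5 reads.
* **Reads.** Each variant yields one error-free pair spanning its two
  junctions (substitution errors optional), with the duplicated 5-mer on
  both flanks and ground truth encoded in the read ids for oracle tests.
* **Features.** 5 static and 21 conservation features are unit Gaussian
  noise. The 20 dynamic (normal-mode-like) features carry the signal: a
  site's level is its mean p_se rescaled to $[-1, 1]$ — depressed at
  rigid scaffold sites, elevated at flexible permissive sites, partial
  classes in between — multiplied by `effect_size` (default 1.0 SD) and
  an alternating mode sign, plus unit noise. An unsigned variant
  (permissive sites shifted, everything else at the mean) was considered
  and rejected as unphysical: it would make scaffold and intermediate
  sites indistinguishable in mobility.
* **Flow events.** Dye intensity is a two-component log-normal mixture
  (hyperpolarized meanlog log 150, depolarized meanlog log 1500, sdlog
  0.4); the hyperpolarized weight is
  $\textrm{activity} \times (1 + \textrm{light\_shift}) \times g(K^+)$
  with $g(k) = 1/(1 + (k/25)^2)$ decreasing in external K⁺ (half-effect
  25 mM, inside the 5–70 mM challenge range). Fluorescence channels decay
  as $e^{-\textrm{bleach\_rate}\, t}$ over the acquisition index; scatter
  channels are fixed log-normals. All mixture parameters are package
  choices — no generative model for the assay exists to copy.

# What the synthetic data does and does not show

The generator reproduces the *structure* of the experiment — positional
bias, frame/orientation bookkeeping, target-site duplication, pool
sorting, multinomial depth, replicate variation, feature categories with
only dynamic features informative, voltage-dye mixtures with bleaching —
but not the texture of real data: no PCR or amplification bias, no indel
or chimeric reads, no compensation/spillover between channels, no
position-correlated p_se structure along the chain (secondary-structure
runs), and protein properties are Gaussian stand-ins rather than computed
descriptors. Passing recovery tests therefore demonstrates that the
pipeline is correct and well-calibrated under the stated generative
model, not that real libraries will reach the same accuracies.
Printed-value checks (the 69/229 → 30% differential fraction, the
model-coverage percentages) exercise the arithmetic conventions on the
study's own counts, which are inputs, not simulations.

# Problem sizes and runtimes

The shipped analyses use 435 sites, 3 replicates, 1e5 variants and 2e5
reads per pool (seconds per stage); caller validation uses 10,000 read
pairs; null calibration of the dissimilarity statistic uses 2,000
repetitions of 2,000-event samples; tree-model checks use 50 refits and
100 label permutations of 10-fold CV. These sizes give stable estimates
(e.g. the Spearman recovery varies by ~0.005 across seeds) while keeping
the full suite in about a minute.

# Known limitations

* Exact-substring anchoring: reads with sequencing errors inside both
  anchors are dropped rather than rescued (a mismatch-tolerant mode
  exists but is not the default); indels are not modeled at all.
* The enrichment has no variance model or shrinkage — it is the plain
  difference of fractions, so low-coverage positions are noisy and are
  handled by trimming rather than by weighting.
* The binarization cut at 0 is a convention; sites near the library-mean
  surface-expression probability binarize unstably at finite depth, which
  is why trimmed universes are used for site comparisons.
* Dunnett adjustment assumes the usual equal-variance one-way layout; the
  Bonferroni fallback is the conservative escape hatch.
* The 6/16 trimming preset is kept as stated even though it cannot be
  reconciled with a 4-library × 3-replicate design; it is a plain
  parameter.
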