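---
title: "Methods: co-occurrence networks of nutrient-stimulated reservoir microbiomes"
author: "reservoirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks of nutrient-stimulated reservoir microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservoirnet)
```

## The analysis in one paragraph

`reservoirnet` asks of an OTU-by-sample count table: which taxa co-vary,
how is the resulting association network wired, and how does that wiring
change when the injected nutrient concentration is lowered? The estimator
at the core is a thresholded rank-correlation graph: Spearman's ρ for every
OTU pair, Benjamini–Hochberg (BH) control of the false discovery rate over
all pairs, and an edge wherever |ρ| > 0.6 with adjusted p < 0.01. Around it
sit the standard preprocessing steps of amplicon ecology (rarefaction,
relative-abundance filtering, alpha diversity), graph characterisation
(average degree, density, negative-edge fraction, betweenness), a
Monte-Carlo robustness assay (random node deletion), bipartite
nutrient–OTU networks, and a two-stage comparison with Mann–Whitney tests.

## Model and assumptions

**Correlation.** ρ is computed as the Pearson correlation of mid-ranks
(ties receive their average rank), so it is invariant under strictly
monotone transforms of any single variable — in particular under the
count-to-proportion transform and under the log-normal marginal of the
synthetic generator. The two-sided p-value uses the t-approximation
`t = ρ √((n−2)/(1−ρ²))` on n − 2 degrees of freedom. The approximation is
poor below roughly n = 4, so fewer than four samples is an error rather
than a warning. Plain Spearman ignores the compositional closure of
relative abundances; with hundreds of moderately even OTUs the closure
bias on any single pair is small, but it is a real assumption (see
Limitations).

**Edge calling.** The magnitude |ρ| is thresholded, not signed ρ: the
analysis reports substantial negative-edge percentages per network, which
a one-sided rule ρ > 0.6 could never produce, so the magnitude reading is
the only self-consistent one. The significance test is applied to the
BH-adjusted p-value by default (`use_adjusted = FALSE` restores raw-p
behaviour); adjusting over all V(V−1)/2 distinct pairs and then
thresholding is the conservative composition of the two stated rules.
Both thresholds are strict inequalities, so ρ exactly at 0.6 is excluded.
Zero-variance variables are flagged and excluded from edge calling — a
constant vector carries no rank information — rather than raising an
error, because rarefied low-depth tables legitimately produce them.

**Topology.** For an undirected simple graph, average degree is 2E/N and
density 2E/(N(N−1)); both identities are tested exactly, pre-rounding,
and the print method rounds to 3 decimals (percentages to 2) to match the
conventional reporting format. One published summary row (day 41 of the
motivating data set: 377 nodes, 1227 edges, printed average degree 8.509)
is internally inconsistent — 2·1227/377 = 6.510, although its density
0.017 checks out — so that row is treated as a typographical artefact and
excluded from quantitative checks rather than "corrected".

**Robustness.** A replicate removes ⌊f·N⌋ nodes uniformly without
replacement and counts the surviving nodes that retain at least one edge,
divided by the *original* node count N. The y-axis definition of this
assay is not standardised in the literature; the package therefore also
offers `denominator = "survivors"` and `measure = "lcc"` (largest
connected component) as switches, but all defaults and all tests use
non-isolated-over-original. Isolated nodes are retained in fitted
networks by default, which depresses the curve uniformly across networks
and so does not affect between-network comparisons.

**Stage comparison.** The Mann–Whitney U test (two-sided; exact for small
tie-free samples, normal approximation with tie correction otherwise) is
the default because none of the compared quantities is plausibly normal at
small n; Welch's t is available. Significance stars follow the usual
thresholds (* p < 0.05, ** p < 0.01, *** p < 0.001, strictly). Two
identical groups return p = 1. The unit of replication is per-sample for
diversity and per-network for negative fraction and robustness — a
documented package choice, since the alternative units (bootstrap draws,
pooled replicates) are equally defensible.

## Grouping samples into networks

With 7 sampling ports, a single day yields n = 7 samples, and no pair can
survive BH at α = 0.01 — the smallest achievable adjusted p across
thousands of pairs is far above the threshold. A per-day grouping is kept
(`group_by = "day"`) because it mirrors how such networks are usually
labelled, but the pipeline's default is `group_by = "window"`: each
stage's days are split into 4 contiguous windows (configurable), giving
networks of roughly 35–70 samples — enough for FDR-controlled edges while
preserving within-stage replication (4 networks per stage feed the
topology and robustness comparisons). `group_by = "stage"` pools each
stage into a single network; the pipeline then still reports group means
and directions but cannot test per-network metrics (p and label are NA).

## The synthetic community generator

The generator is the package's ground-truth instrument, not a fixture: it
emulates the two-stage long-core experiment so that every pipeline claim
can be scored against planted structure.

* **Design.** One sample per (day, port): 7 ports (labelled SP2–SP10 after
  the sampling-port convention of long-core rigs), days 1–60, low-nutrient
  stage from day 40 (samples on the boundary day belong to the reduced
  recipe, which applies from that day). 150 OTUs, 50,000 reads per sample.
* **Counts.** A latent standard-normal variable per OTU and sample is
  correlated within planted blocks by a one-factor model (loadings
  ±√ρ), mapped through `exp(scale·baseline + dispersion·z)` to heavy-tailed
  expected abundances, and each sample is drawn multinomially at the
  sequencing depth. Because Spearman is rank-based, the planted latent
  correlation is (up to counting noise) what the pipeline should recover —
  the copula layer gives direct control of the quantity being measured.
* **Negative associations.** A "negative" block splits its members into a
  positively and a negatively loading half; cross-half pairs have latent
  correlation −ρ. An all-pairs-negative block of size > 2 would not be a
  valid correlation matrix, so sign-split blocks are how negative edges
  are planted; the ground-truth edge list records every pair's true sign.
* **Two regimes.** The default block design gives the high stage 8 blocks
  of 5 OTUs (3 sign-split) and the low stage 12 blocks of 5 (2 sign-split),
  at latent ρ = 0.8, plus one TN-driven and one TS-driven block active in
  both stages. The low stage therefore has more planted connectivity,
  fewer negative pairs (~10% vs ~23% of planted edges), and — via
  `diversity_shift = 0.25`, which shrinks the low-stage baseline
  log-abundance spread — higher evenness. These defaults encode the
  qualitative contrast under study (diversity up, competition down,
  stability up after nutrient reduction) so that the pipeline's job is to
  recover it; effect sizes were chosen once as ecologically moderate
  (latent ρ well above the edge threshold, a ~0.3-bit Shannon shift) and
  are all scenario parameters.
* **Nutrients.** Concentration curves ramp from 0 to a high-stage plateau
  (TS: 150 mg/L reached after 17 days; TN and TP after 8 days), hold, and
  step down to half when the reduced feed reaches the port — halving
  mirrors a feed recipe in which the carbon and N/P sources are halved.
  Port k lags the injection end by k − 1 days (a lag is physically
  expected along the core; its magnitude is a free choice, set to 0–6
  days). A 5% lognormal batch fluctuation is shared by all ports at equal
  effective day, so zero-lag ports see identical curves and nutrient-driven
  OTUs respond to the same realised concentrations the analyst measures.
  Nutrient-driven blocks load on Gaussian scores of the measured
  concentration, keeping the copula marginals calibrated.
* **What it does not emulate.** No compositional interaction beyond
  closure, no aerobic→anaerobic succession dynamics, no taxon-specific
  growth kinetics, no sequencing error or chimeras, and taxonomy strings
  are synthetic labels. Passing the planted-recovery tests therefore shows
  the pipeline is correct and well-calibrated on rank-correlated
  compositions — not that real reservoir data satisfy its assumptions.

## Numerical choices and degenerate inputs

* Low-abundance filter: an OTU is retained when its **mean** relative
  abundance across all samples is ≥ 1e−4 (0.01%); "mean across samples" is
  the common convention where the criterion is otherwise ambiguous, and
  `criterion = "max"`/`"pooled"` are provided. The boundary value is
  retained (the rule removes strictly-below-threshold OTUs).
* Rarefaction: without replacement, one draw per sample, seed required;
  samples below depth are dropped with a warning naming them (erroring
  would make mixed-depth tables unusable). The default depth 41,051
  matches the preprocessing convention of the motivating data set.
* Shannon diversity uses log base 2 (bits) by default, the default of the
  QIIME diversity tooling; the base is an argument.
* BH adjustment is `stats::p.adjust(method = "BH")` over the upper
  triangle only, mirrored back symmetrically; adjusted values are clipped
  at 1 and verified against a sort-and-cummin oracle in the tests.
* Robustness replicates and all other randomness run under localised RNG
  (seeds never leak into the caller's stream); curves use an independent
  derived seed per fraction.
* Betweenness is computed on the unweighted graph — correlation
  magnitudes are not distances, and no weighting scheme is part of the
  method.
* Ties in Spearman use mid-ranks throughout; the brute-force oracle in the
  test suite recomputes ranks by counting, Pearson by the sum formulas,
  and BH by explicit sorting, so the equivalence tests are not circular.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data:
oracle equivalence on 100 random instances of ≤ 8 variables × ≤ 12
samples; exhaustive robustness enumeration on 6-node graphs against
2,000-replicate Monte Carlo; planted-edge recovery on 200-sample scenarios
(latent ρ = 0.9) averaged over 5 seeds; and direction recovery on the full
420-sample default scenario across 5 seeds. These sizes were chosen so
that the planted effects are comfortably identifiable while the whole
validation completes in about a minute on a laptop; the published networks
this pipeline is designed for (hundreds of nodes, thousands of edges) are
only represented through their printed node/edge counts, whose
average-degree and density identities the package reproduces exactly.

## Known limitations

* Spearman on relative abundances is blind to compositional effects; for
  strongly dominated communities a dedicated compositional method
  (SparCC, SPIEC-EASI) would be the right cross-check. That family is
  deliberately out of scope here.
* The t-approximation p-value is approximate under heavy ties at small n;
  an exact permutation p would be preferable below n ≈ 10.
* The robustness assay covers random removal only — no targeted attack by
  degree or betweenness, and no natural-connectivity metric.
* Networks built from few samples (per-day grouping with 7 ports) cannot
  pass FDR control; this is a property of the design, not of the
  implementation, and the window grouping exists precisely to address it.
* The generator's nutrient response is monotone by construction; real
  taxa may respond non-monotonically (optima), which rank correlation
  would miss.
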