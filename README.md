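# reservoirnet

Co-occurrence network analysis of nutrient-stimulated oil-reservoir
microbiomes.

In indigenous microbial enhanced oil recovery (IMEOR), nutrient solutions are
injected into a reservoir (or a laboratory long-core flooding device) to
stimulate the resident microbial community, and 16S rRNA amplicon samples are
drawn from sampling ports along the core over time. A recurring question is
how the *concentration* of the injected nutrients shapes the community: does
lowering the feed concentration increase bacterial diversity and make the
co-occurrence network more stable? `reservoirnet` implements the full
analysis pipeline behind that kind of study, for microbial ecologists and
reservoir engineers working with OTU count tables:

* **Preprocessing** — QIIME-style OTU table I/O, rarefaction to a common
  depth (default 41,051 reads), removal of OTUs with mean relative abundance
  below 0.01%, and per-sample alpha diversity (Shannon in bits, observed
  OTUs, Simpson, Pielou evenness).
* **Network inference** — all-pairs Spearman correlation ρ on relative
  abundances (mid-ranks; two-sided p from the t-approximation), Benjamini–
  Hochberg FDR correction over all V(V−1)/2 pairs, and an edge for every
  pair with |ρ| > 0.6 and adjusted p < 0.01. Edges carry the sign of ρ;
  negative edges are read as potential competition.
* **Topology** — per-network node/edge counts, average degree 2E/N, density
  2E/(N(N−1)), negative-edge fraction, and unnormalised betweenness
  centrality.
* **Stability** — robustness under random node removal: the proportion of
  nodes that keep at least one edge after deleting a random fraction of
  nodes (1000 Monte-Carlo replicates by default), as a single point (e.g. at
  50% removal) or as a full curve.
* **Nutrient–OTU networks** — total sugars (TS), total nitrogen (TN) and
  total phosphorus (TP) concentrations join the OTUs as variables; the fitted
  network is pruned to the nutrient-associated subgraph.
* **Stage comparison** — two-sided Mann–Whitney U tests (Welch optional) of
  diversity, negative-edge fraction and robustness between the high- and
  low-nutrient stages, starred at p < 0.05 / 0.01 / 0.001.
* **Synthetic communities** — a latent-Gaussian copula generator that plants
  correlation blocks (positive, sign-split negative, or nutrient-driven)
  into heavy-tailed multinomial count tables across a two-stage,
  port-lagged nutrient design, with the planted edge list returned as
  ground truth. Every downstream claim in the test suite is validated
  against that ground truth or against brute-force oracles.

## Worked example

Simulate the default two-stage experiment (150 OTUs, 7 ports × 60 days,
high-nutrient stage on days 1–39, low stage from day 40), fit a network to
the high-stage samples, and measure its stability:

```r
library(reservoirnet)

sc  <- sim_scenario()                 # the default two-regime design
sim <- simulate_community(sc, seed = 1)
sim$table
#> OTU table: 150 OTUs x 420 samples
#>   stages: high=273, low=147
#>   days 1..60, 7 ports; taxonomy attached

high <- subset_samples(sim$table, sim$table$metadata$stage == "high")
net  <- cooccurrence_network(high, label = "high")
net
#> Co-occurrence network [high]: 150 nodes, 100 edges (18.0% negative)
#>   thresholds: |rho| > 0.6, FDR-adjusted p < 0.01; n = 273 samples

robustness_random_removal(net, fraction = 0.5, n_reps = 1000, seed = 2)
#> Robustness at removal fraction 0.50: mean remaining 0.1557 (sd 0.0246, 1000 reps)
```

The network keeps 100 of the 100 planted high-stage edges within FDR
control; after deleting half its nodes at random, about 16% of the original
nodes still hold an edge. The full pipeline — rarefy, filter, fit one
network per day window, summarise topology, test stages — is one call:

```r
res <- run_pipeline(list(seed = 1))
res
#> Co-occurrence pipeline run (seed 1): 8 network(s)
#>    label n_nodes n_edges average_degree density negative_pct
#>  high_w1     150     100          1.333   0.009       18.00%
#>  high_w2     150      93          1.240   0.008       19.35%
#>  high_w3     150      84          1.120   0.008       21.43%
#>  high_w4     150      97          1.293   0.009       15.46%
#>   low_w1     150     150          2.000   0.013        7.33%
#>   low_w2     150     118          1.573   0.011       10.17%
#>   low_w3     150     110          1.467   0.010        6.36%
#>   low_w4     150     111          1.480   0.010        6.31%
#>
#> Stage comparisons (high vs low):
#>                  metric n_high n_low mean_high   mean_low statistic      p_value label
#>                 shannon    273   147 5.9266384 6.19598089      8741 1.380397e-21   ***
#>       negative_fraction      4     4 0.1856183 0.07543192        16 2.857143e-02     *
#>  robustness_at_fraction      4     4 0.1475617 0.19592333         0 2.857143e-02     *
```

Read: the low-nutrient stage has higher Shannon diversity (6.20 vs 5.93
bits, p ≈ 1e-21), a smaller fraction of negative edges (7.5% vs 18.6%), and
higher robustness at 50% removal (0.196 vs 0.148) — the diversity-up /
competition-down / stability-up signature the generator plants. With
`out_dir` set, every table, GraphML network and a manifest of file digests
is written; identical configurations reproduce the outputs byte for byte.
A YAML file holding the same configuration list can be passed instead:
`run_pipeline("pipeline.yaml")`.

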