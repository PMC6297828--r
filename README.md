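# cloneattractor

Longitudinal T-cell receptor (TCR) repertoires contain hundreds of thousands
of unique CDR3 amino-acid sequences per study — far too many, and far too
noisy, to use directly as dynamical variables or classifier features.
`cloneattractor` implements the **Clone-Attractor (CA)** representation: it
collapses highly similar CDR3 sequences into clusters that are treated as
single dynamical units, then analyses how the network of those units evolves
over time and which of them discriminate disease states. It is written for
immunologists and computational biologists working with AIRR-style clone
tables from longitudinal designs (e.g. tumor-prone transgenic mice vs.
controls sampled repeatedly over months).

## The method

1. **Clustering.** Unique CDR3 sequences are sorted by length and greedily
   clustered in one pass (UCLUST-style). A sequence joins the first cluster
   whose *representative* is within an association threshold λ = 3 under a
   weighted Levenshtein metric (deletion = insertion = 1.1,
   substitution = 1.9); otherwise it founds a new cluster. After every
   association the representative is refreshed to the cluster medoid. The
   weights are chosen so a member may differ from the representative by at
   most two indels, or one substitution plus one indel. Cluster sizes K
   follow a power law P(K) ∝ K^−α with α ≈ 3, the scale-free signature of
   repertoire organisation.

2. **Repertoire graphs.** For every (sample, time point), the filtered CAs
   (≥ 10 members, active in > 60% of time points) with positive amplitude
   form a graph; edges join CAs whose representatives are within distance 8.
   Two statistics summarise each graph: the Molecular Topological Index
   MTI = Σᵢ Σⱼ dᵢ (Aᵢⱼ + Dᵢⱼ) (degrees d, adjacency A, shortest-path edge
   counts D; lower for more branched graphs) and sBWC, the per-graph sum of
   betweenness-centrality components above the pooled median th₅₀ — "the
   amount of influential CAs". Persistent repertoires stay dense over time;
   diluting ones become sparse and branched, so both statistics separate the
   groups at late time points.

3. **Two-stage classification.** CA amplitudes per (sample, time point) are
   the features. After keeping CAs active in > 95% of data points, forward
   feature selection (all pairs, then greedy extension; top 50 subsets per
   dimension, ranked by leave-one-out cross-validation of a gaussian-kernel
   SVM) feeds an ensemble of m = 10 machines whose calibrated outputs are
   averaged. Stage 1 separates control from transgenic points; stage 2
   separates pre-cancer from cancer within the transgenic group. Robustness
   is probed by multiplicative gaussian noise nX = X(1 + V), V ~ N(0, σ²),
   σ = 0 … 0.25, reporting ROC/AUC per noise level.

A seeded synthetic generator (`simulate_repertoire()`) emulates the study
design (5 control + 10 transgenic samples × 8 time points, power-law
attractor sizes, members inside the association radius, control-group
dilution, planted discriminative CAs) so the whole pipeline is testable
without access restrictions. `match_public()` compares attractor
representatives against a curated public TCR table (e.g. a VDJdb export) at
distance 0/1.

## Worked example

```r
library(cloneattractor)

sim  <- simulate_repertoire(sim_config(), seed = 7)   # synthetic study
aset <- cluster_repertoire(sim$clones)                # greedy CA clustering
glance(aset)
#> # A tibble: 1 × 6
#>   n_attractors n_sequences total_count max_size lambda strategy
#>          <int>       <int>       <dbl>    <int>  <dbl> <chr>
#> 1         2970        4077     1487082       22      3 first_fit

powerlaw_fit(tidy(aset)$size)
#> <ca_powerlaw> alpha = 2.787 (log-binned LS, R^2 = 0.999); alpha_mle = 2.148;
#>   n = 2970 sizes in [1, 22]

activity <- attractor_activity(aset, sim$clones)
graphs   <- build_graphs(aset, activity)
measures <- measure_table(graphs)
```

4,077 unique sequences collapse into 2,970 attractors whose size
distribution has a fitted exponent α ≈ 2.8, close to the generating α = 3.
Summarising the graph statistics per group (median over each sample's time
points, then per group):

```r
#>   group        mti  sbwc
#> 1 control     268.     0
#> 2 transgenic 3226    352
```

The diluting control repertoires end with sparse, low-MTI graphs and no
influential hubs, while the persistent transgenic graphs stay dense — the
separation the graph stage is built to expose. The classification stage:

```r
cfg <- ml_config(dims = 2:3, top_k = 10, ensemble_size = 5, seed = 7)
two_stage_classify(activity, sim$metadata, cfg)
#> <ca_two_stage>
#>   stage 1 (control vs transgenic): dim = 2, noise-averaged AUC = 1.000
#>   stage 2 (pre-cancer vs cancer):  dim = 2, noise-averaged AUC = 1.000
#>   feature overlap (Jaccard): 0.22
```

Both stages recover the planted signal (AUCs are cross-validated with whole
samples held out and averaged over the noise grid), and the two stages
select mostly different attractors, mirroring the two distinct biological
processes the design plants.

Result objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures (`autoplot(powerlaw_fit(...))`, `plot_measures(measures,
sim$metadata, "sbwc")`, `autoplot(roc)`).

A thin command-line front end wrapping these functions ships in
`inst/cli/cloneattractor.R` (subcommands `simulate`, `cluster`, `network`,
`classify`, `match-db`, `run-all`); `run_pipeline()` is the equivalent
library entry point and writes a JSON run manifest alongside all stage
tables.

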