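---
title: "Clone-Attractor analysis of longitudinal TCR repertoires: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-Attractor analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic generator does
and does not emulate, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The Clone-Attractor representation

A longitudinal TCR-β repertoire study yields, per (sample, time point), a
table of unique CDR3 amino-acid sequences with abundance counts. Treating
each sequence as an independent variable is hopeless: the space is enormous,
single-sequence counts are noisy, and most sequences vanish between
consecutive time points, riddling any feature matrix with missing values.

The Clone-Attractor (CA) representation addresses all three problems at
once. Highly similar sequences — plausibly related clones plus their
measurement and somatic variants — are clustered, and each cluster becomes
one dynamical unit whose *amplitude* at a (sample, time point) is the summed
abundance of its members. Clustering shrinks the space by orders of
magnitude, averages away single-sequence noise, and converts absence into a
meaningful zero amplitude rather than a missing value.

### 1.1 The weighted edit metric

Distances between CDR3s are weighted Levenshtein costs (Wagner–Fischer
dynamic programming; no transposition operation): deletion 1.1, insertion
1.1, substitution 1.9, with association threshold λ = 3. The weights encode
a deliberate geometry for the association ball around a representative:

* two pure indels cost 2.2 ≤ 3 — admitted;
* one substitution plus one indel costs exactly 3.0 ≤ 3 — admitted;
* three indels (3.3) or two substitutions (3.8) — rejected.

Because the printed boundary case 1.9 + 1.1 = 3.0 sits *exactly* on the
threshold, every threshold comparison in the package uses ≤ with an absolute
tolerance of 1e-9; otherwise the decimal weights' floating-point
representations could flip the documented behaviour. With equal indel costs
the metric is symmetric and satisfies the triangle inequality (both are
property-tested against a memoized recursive oracle).

The DP core, including an early-exit bounded variant (row-minimum pruning,
exact whenever the true distance is within the cutoff) and the greedy
clustering pass, is implemented in C++ (Rcpp): clustering compares every
sequence against up to thousands of representatives, and an O(1)
length-difference rejection plus the bounded DP keeps a ~5,000-sequence run
around a second.

### 1.2 Greedy clustering and the medoid representative

Sequences are processed sorted by ascending length, ties broken
lexicographically — the sort criterion fixes only the length; a
deterministic intra-length order is required for reproducibility and
lexicographic order is the obvious canonical one. Each sequence is compared
to existing cluster representatives *in cluster-creation order* (a single
growing list); under the default `first_fit` strategy it joins the first
cluster within λ ("winner takes all"), under `nearest_fit` the closest one.
Both strategies are shipped because the method's description is ambiguous
between them; `first_fit` is the default as it matches the stated greedy
"first cluster that is found close enough" behaviour, and the package
asserts (on random fixtures) that `nearest_fit` never produces more
clusters. After every association the representative is refreshed to the
medoid — the member minimising the summed distance to all other members —
with ties broken by shorter length, then lexicographic order. Distance sums
are cached so the refresh is O(|members|) per association.

Clustering operates on the unique sequences pooled across all samples and
time points: one shared attractor space, from which per-sample activity is
recovered afterwards. The alternative (per-sample clustering) would make
cluster identities incomparable across the very graphs and feature matrices
the method builds.

The association log records, for every sequence, the cluster it joined and
its distance to the then-current representative, so the invariant "every
member was within λ at the moment of association" is auditable after the
fact; the test suite audits it on every synthetic fixture.

## 2. Repertoire graphs and their statistics

Attractors enter the graphs only if they have at least 10 members (smaller
clusters carry too little statistical support per node) and are active —
amplitude > 0 in at least one sample — in strictly more than 60% of time
points (a unit that appears only sporadically describes a sample, not a
phenomenon). The time-point filter is evaluated globally, before any
per-sample graph is built, so all graphs draw nodes from one shared set.
Within a (sample, time point), the nodes are the filtered CAs with positive
amplitude there, and edges join pairs whose representatives are within
weighted distance 8. Shortest paths count edges (hops), not edge weights.

Two statistics summarise a graph:

* **MTI** = Σᵢ Σⱼ dᵢ (Aᵢⱼ + Dᵢⱼ), with degree vector d, adjacency A and
  shortest-path matrix D. It grows with density and shrinks with
  "branchness" (on six nodes: complete 300 > path 128 > star 100, values the
  tests derive by brute force). D is undefined across components, so for
  disconnected graphs the index is evaluated per connected component and
  summed — unreachable pairs contribute nothing, and the definition reduces
  to the classical one on connected graphs while staying finite.

* **sBWC**: betweenness centrality (unnormalised, as the bare
  path-count-fraction definition carries no normalisation; computed via
  igraph, property-tested against exhaustive path enumeration) is pooled
  across *all* graphs; the pooled median is the threshold th₅₀, and each
  graph reports the sum of its components strictly above th₅₀. Strictness
  matters: when all values are equal, every sBWC is 0. Empty graphs
  contribute no values to the pool. Because the threshold is a pooled
  quantile, the unnormalised scale choice is self-consistent, and the
  `probs` argument lets users verify that the control/transgenic ordering
  does not depend on choosing the median specifically (the suite checks the
  40th and 60th percentiles).

Per-sample summaries are the median and standard deviation over that
sample's own time points. A single-time-point sample gets sd 0 with a
warning rather than NA, keeping downstream tables complete.

### 2.1 Cluster-size power law

The size distribution is fitted as P(K) ∝ K^−α by least squares on a
log-log histogram with geometric (factor-2) bins, each bin's count divided
by the number of integer sizes it covers. The regression is weighted by bin
counts: under Poisson counting error the variance of a log count is
approximately the reciprocal count, so count weights are the correctly
weighted least squares and keep one-observation tail bins from steering the
slope. On direct draws from a truncated K^−3 law at n = 2000 this estimator
has a standard deviation of about 0.05 across seeds, versus about 0.15
unweighted. A discrete maximum-likelihood estimate
(1 + n / Σ log(k/(k_min − 0.5))) is reported alongside as a diagnostic; it
is known to be biased at k_min = 1 and is not used for any decision. At
least 5 distinct sizes are required; degenerate input is an error, not a
guess.

## 3. The two-stage classifier

Features are CA amplitudes per (sample, time point) data point. Choices, in
the order the pipeline applies them:

* **Active filter.** Keep CAs with amplitude > 0 in strictly more than 95%
  of data points. "Data point" (sample × time point) is the default unit,
  matching the feature definition; a per-sample interpretation is available
  via `activity_scope = "sample"`.
* **Raw amplitudes by default.** Whether counts were normalised before
  classification is not specified by the method; both options exist
  (`normalize = TRUE` converts to per-point relative abundance) and the
  choice is recorded in the configuration.
* **Classifier.** Soft-margin SVM with gaussian kernel. The kernel width
  defaults to the median heuristic (1/(2·median²) of pairwise distances on
  scaled features) and the penalty C to 1 — unstated in the method, so the
  package uses reproducible, standard defaults and exposes both. Classes
  are weighted inversely to frequency in every fit: the study design is
  imbalanced (5 control vs 10 transgenic samples), and unweighted margins
  systematically favour the majority class in every cross-validation fold
  (see Section 3.1 below).
* **Forward selection.** All feature pairs are scored by LOOCV accuracy
  (libsvm's built-in n-fold cross-validation, deterministic at n folds);
  the top 50 subsets are extended by each unused feature, deduplicated *as
  sets*, re-scored, and so on until the best score stops improving by more
  than 1e-6 or dimension 8 is reached. Ties break by score, then by the
  lexicographic order of the sorted feature names. Point-level LOOCV is the
  default; `loocv_unit = "sample"` holds out whole samples, avoiding
  leakage across a subject's time points at the cost of fewer folds — the
  point-level default mirrors the method's own granularity and the leakage
  caveat is precisely why the ROC stage (below) holds out samples.
* **Ensemble.** The i-th of m = 10 machines trains on the i-th ranked
  subset; the committee output is the mean of the machines' outputs, each
  calibrated to [0, 1] by a logistic link on the SVM decision value
  (oriented so larger = positive class).
* **Noise robustness.** Evaluation data are perturbed multiplicatively,
  x → x(1 + v), v ~ N(0, σ²), σ ∈ {0, 0.05, …, 0.25}, machines stay trained
  on clean data (test-time robustness). ROC and trapezoidal AUC are
  computed per σ; the model dimension is chosen by the highest
  noise-averaged AUC, ties to the smaller dimension.

Stage 1 classifies control vs transgenic on all points; stage 2 re-runs the
identical pipeline on transgenic points only, labelled pre-cancer vs cancer
from the phenotype layer. The two selected feature lists and their Jaccard
overlap are reported.

### 3.1 Why ROC scores are cross-validated

Two naive evaluation schemes fail in opposite directions, and a no-signal
benchmark exposes both. Scoring the trained committee on its own training
points is resubstitution: on null data (planted effects switched off) it
yields AUC ≈ 0.7 — pure optimism. Holding out each sample but keeping
unweighted margins yields AUC ≈ 0.3: each held-out point is scored by a
model that saw one sample fewer of *its own* class, a prior-shift that
systematically ranks points below the other class ("anti-learning").
The package therefore (a) class-balances every SVM fit and (b) computes ROC
scores with whole samples held out and the committee refit per fold
(`evaluate_roc(holdout = "sample")`, the default; `holdout = "none"` exists
for diagnostics). Under this scheme the null benchmark sits at AUC ≈ 0.5
across seeds — the property the test suite asserts. Note one remaining
caveat: forward selection sees all data points, so selection bias is not
eliminated, only the scoring bias; with planted signals of realistic size
this is visible as slightly optimistic null AUCs (≈ 0.5–0.6), which is why
the null assertion carries a ±0.15 band.

## 4. The synthetic generator

`simulate_repertoire()` provides ground truth for every other module. What
it emulates, with defaults chosen once as the study conditions:

* **Design.** 5 control + 10 transgenic samples, 8 time points. Transgenic
  phenotypes progress healthy → pre-cancer → cancer with a per-mouse onset
  time drawn uniformly from time points 3–7 (the pre-cancer point is the
  last one before cancer, one per mouse).
* **Sizes.** 3000 attractors with sizes from a discrete power law, exponent
  3, truncated to 1–1000. At this scale roughly a dozen attractors reach
  the 10-member hub threshold, and about 4,000 unique sequences are
  emitted; tests run in seconds.
* **Sequences.** Seeds follow the CDR3 scaffold "CASS…F" (lengths 10–17,
  cosmetic). Hub seeds form a *chain*: consecutive hub seeds differ by 3
  substitutions (weighted distance 5.7), so neighbouring hubs are joined by
  graph edges (5.7 ≤ 8) while non-neighbours are not (11.4 > 8), giving the
  per-sample graphs non-trivial shortest-path structure (paths, not
  cliques) — without which betweenness, and hence sBWC, would be
  identically zero. The 3-substitution step also guarantees members of
  different hubs can never fall within λ of a foreign representative.
* **Members.** Each member differs from its seed by one substitution, one
  insertion, two insertions, or one substitution plus one insertion
  (probabilities 0.65/0.25/0.05/0.05 — substitution-dominant, as
  single-residue changes are the typical near-neighbour relation among
  similar CDR3s). Indels are insertions, and substitutions replace a
  residue by a lexicographically larger one, so every seed precedes all its
  members in the clustering's (length, lexicographic) processing order and
  provably founds its own cluster: the ground-truth partition aligns with
  the association radius by construction, which is what makes recovery a
  testable property (adjusted Rand ≈ 0.98 at defaults) rather than an
  approximate hope. The price is a mild asymmetry real data do not have
  (no deletion variants, substitutions skewed toward later alphabet
  letters); clustering of deletion variants and arbitrary substitutions is
  exercised separately by the unit fixtures.
* **Dynamics.** Amplitudes are log-normal (hub members meanlog log 20,
  small-cluster members log 5, sdlog 0.6), thinned by per-member detection
  (0.7 for hubs). Non-planted hubs are "dynamic" with probability 0.75:
  active always in transgenic samples, active with probability 0.7^(t−1) in
  controls — the minimal mechanism reproducing the dense-persistent vs
  branched-diluted divergence; no immunological kinetics are claimed.
  Planted and "persistent" hubs stay active everywhere.
* **Planted signal.** The 4 + 4 largest attractors are the stage-1 and
  stage-2 signal carriers: stage-1 amplitudes are multiplied by 4 in all
  transgenic points; stage-2 by 2 in cancer-labelled points only (weaker by
  design, so stage-2 performance trails stage 1). The null benchmark
  variant sets both multipliers to 1 and keeps everything else, including
  dilution — diluting hubs fail the 95% activity filter and therefore
  cannot leak group information into the feature set, which is what makes
  the null a genuine false-positive control.
* Every member is observed at least once (a member never seen in the clone
  table would silently shrink its cluster), and all member sequences are
  globally unique so the ground-truth map is a function.

What the generator does *not* emulate: V(D)J recombination statistics,
nucleotide-level variation, antigen-driven selection, per-mouse random
effects beyond the onset time, or sequencing depth variation. Passing tests
on synthetic data therefore demonstrate that the algorithms do what they
claim under the method's own assumptions — not that real repertoires
satisfy those assumptions.

## 5. Numerical and interface conventions

* Absence is zero: activity matrices cover the complete attractor ×
  (sample, time point) grid; writers emit explicit zeros.
* All threshold comparisons on the weighted-edit scale use ≤ with absolute
  tolerance 1e-9 (Section 1.1); the sBWC threshold uses strict >.
* λ = 0 is allowed and collapses clustering to exact identity — the
  documented degenerate boundary (every unique sequence its own cluster;
  downstream filters then empty the graphs with a warning).
* Database matching buckets "distance 1" by unit edit count (one operation
  of any kind), since near-identity to curated sequences is conventionally
  stated in operations; the weighted scale is available via
  `metric = "weighted"`.
* Every stochastic entry point takes a seed; `run_pipeline()` records the
  configuration hash, input digests and per-stage wall-clock in a JSON
  manifest sufficient to re-run identically. Graph exports are GraphML (via
  igraph) or GEXF (minimal writer), with node size = cluster size and edge
  weight = representative distance.
* Problem sizes used by the checks: the power-law recovery runs at 2000
  attractors (≈ 2,700 unique sequences); clustering invariants at ≈ 5,000
  sequences; classifier properties on the 120-point benchmark with
  selection budgets (dims 2–3, top-10) that keep each run in seconds —
  the selection *mechanics* are identical at every budget.

## 6. Known limitations

* The greedy pass is order-dependent by construction; determinism is
  guaranteed for a fixed input multiset, but a different sort convention
  would yield a (slightly) different partition.
* MTI on disconnected graphs is a package convention (per-component sum);
  other conventions (e.g. infinite or n-penalised distances) exist.
* The forward-selection convergence rule (improvement ≤ 1e-6, cap at
  dimension 8) is a pragmatic stopping criterion, not a statistical test.
* Stage-2 sample sizes (one pre-cancer point per transgenic mouse) are
  small; its AUCs carry correspondingly wide uncertainty.
* `alpha_mle` is a diagnostic only; for publication-grade exponent
  inference on real data a full discrete-MLE treatment with k_min selection
  would be preferable.
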