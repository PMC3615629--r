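---
title: "Signal propagation paths between staged expression biomarkers"
author: "stagePath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal propagation paths between staged expression biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagePath)
```

# The model

`stagePath` analyses a cohort of patients staged A–D (Dukes staging in
the motivating colorectal-cancer setting: A = confined to the innermost
layer, D = widely spread) together with an undirected protein
interaction network whose edges carry confidence scores in
[0.150, 1]. The working hypothesis is that disease progression is a
transition between network states: genes that discriminate A from B
mark the *early* activated region, genes discriminating C from D mark
the *late* region, and the disease signal travels from early to late
biomarkers along short, high-confidence interaction paths whose
endpoints are co-expressed in the intermediate patients.

The pipeline has five stages.

## 1. Biomarker selection (mRMR + IFS)

For one contrast (A vs B, or C vs D):

* **Discretization.** Each gene is ternarised at mean ± *k*·SD over the
  contrast samples (default *k* = 1, population SD, strict
  inequalities, boundary values → state 0). Mutual-information
  estimates on three states are stable at cohort-scale sample sizes;
  constant genes become all-zero vectors and carry no information.
* **mRMR ranking.** Greedy forward selection under plug-in mutual
  information (nats). The first gene maximizes MI(g, label); each next
  gene maximizes MI(g, label) / mean MI(g, selected) (MIQ, the
  default) or the difference form (MID). Deterministic ties resolve to
  input gene order; the mean redundancy is floored at machine epsilon
  so a zero-redundancy candidate is scored by its relevance alone.
* **IFS.** For every prefix k = 1…maxK of the ranking, the
  leave-one-out accuracy of a nearest-neighbour classifier (Euclidean
  distance on per-gene standardized expression; distance ties to the
  smallest sample index) is evaluated; the *smallest* k attaining the
  maximum accuracy is the optimal biomarker set — a parsimony
  tie-break, since "the" optimum must be reproducible.

`maxK` defaults to min(500, number of genes): accuracy curves at
realistic effect sizes flatten well before that, and the LOOCV cost
grows linearly in k.

## 2. The weighted network

Confidence scores map to edge distances ("intimacy")
`1000 × (1 − score)`, so a perfect interaction has distance 0 and the
weakest admissible one (0.150) has 850. The conventional score ranks
use strict lower bounds (> 0.400 medium, > 0.700 high, > 0.900
highest); consequently the screening threshold below — path length
< 300 — is exactly "shorter than one high-confidence-boundary edge",
and both are strict. Scores below 0.150 are never clamped; such edges
are dropped with a reported count. Duplicate undirected edges collapse
to their maximum score.

## 3. Transition screening

All ordered early × late pairs are tested (a gene sitting in both
biomarker sets is never paired with itself). Per pair:

* the Dijkstra shortest-path length under intimacy weights;
* the Pearson correlation over the pooled stage-B and stage-C samples,
  with the two-sided p-value from the t-distribution (n − 2 df).

One Benjamini–Hochberg adjustment is applied across the *whole* tested
family — not per early gene — and a pair is retained when length
< 300 and FDR < 0.001, both strict. Both criteria matter: positive and
negative correlations qualify alike (the sign is reported per path).

The pooled-B∪C choice (rather than per-stage testing) keeps one
correlation readout per pair — the quantity the path table reports —
and the family choice (all tested pairs) is the most conservative
scope for the adjustment.

For retained pairs the path's node sequence is reconstructed
deterministically: among equal-length shortest paths, the fewest hops
win, then the lexicographically smallest node sequence. The
reconstruction orients edges along the shortest-path DAG
(d(s,u) + w(u,v) + d(v,t) = d(s,t)) and walks it greedily, which stays
correct in the presence of zero-weight (score 1.0) edges.

## 4. Permutation FDR

Gene symbols are relabeled by a single random bijection over the union
of network node names and cohort gene identifiers, applied *jointly* to
both structures, N₂ times. Joint relabeling keeps network and cohort
mutually consistent, so the null hypothesis being sampled is "the
assignment of symbols to structural positions is random"; an
independent-bijections mode is available behind a flag. Per
permutation, each retained path's pair gets a permuted shortest-path
length and a permuted correlation FDR (recomputed over the same pair
family, so the values are comparable), and

FDR = N₁ / N₂, N₁ = #{permutations with permuted length < actual **and**
permuted FDR < actual},

with strict inequalities; an unreachable permuted pair (infinite
length) can never beat the actual path. The default N₂ is 20,000;
validation experiments here use 300–500, whose binomial Monte-Carlo
error is ample for calibration checks.

### What the null distribution of this FDR actually is

Under the relabeling null, a path's length rank and its correlation-FDR
rank are essentially independent (one is a property of the graph side,
the other of the expression side). The FDR is the *joint* beat-fraction
of two statistics; for independent uniform ranks U, V its population
value is U·V, whose CDF is

P(FDR ≤ t) = t − t·ln t  >  t.

So the null FDR is *not* uniform: it is stochastically smaller, with
maximal deviation 1/e ≈ 0.37 from the uniform CDF at t = 1/e, and
P(FDR ≤ α) ≈ α(1 − ln α) — e.g. 0.056 at α = 0.01 — which makes the
statistic anti-conservative if read as a per-path error rate. Only if
the two criteria were comonotone would uniformity hold. The acceptance
script measures both Kolmogorov–Smirnov distances (against the uniform
and against t − t·ln t) on null data; the product law fits closely
while the uniform does not. Users should therefore treat the
permutation FDR as a descriptive joint-extremity index, not a
calibrated p-value.

## 5. Hubs and overlap

Transition genes are the interior nodes of retained paths; endpoints
(the biomarkers) are excluded by default (`includeEndpoints` for
sensitivity analysis). Each path counts a gene at most once; hubs are
sorted by crossing count, ties alphabetically. The early/late overlap
is summarised by the expected overlap |S₁|·|S₂|/N (the hypergeometric
mean) and the classical 2×2 cross-product odds ratio, reported to 3
significant figures; disjoint sets give OR = 0, identical sets leave it
undefined.

# The synthetic-data generator

`simulateCohort()` draws background genes i.i.d. Gaussian with
gene-specific means (N(8, 2), a log-intensity-like scale) and SDs
(Uniform(0.5, 1.5)) — the simplest model under which the mutual
information and Pearson machinery behave as assumed; heavier-tailed
expression is deliberately not modelled. Early markers shift by
`effectSize` within-gene SDs between stages A and B, late markers
between C and D. Planted early→late pairs overwrite the late gene's
pooled B∪C values with `rho·standardized(early) + sqrt(1 − rho²)·noise`
rescaled to the late gene's scale — exactly the samples the screening
stage tests. `simulateNetwork()` wires each planted pair's intended
path with ≤ 5 edges of score ≥ 0.95 (five edges of weight ≤ 50 keep
the length below 300; a sixth would reach it), over an Erdős–Rényi
background whose scores follow a mixture with most mass in 0.15–0.4
and a thin tail above 0.9, so the 300 cutoff is genuinely selective.
The default stage sizes (44/94/91/61) mirror a staged colorectal
cohort; a configurable fraction of genes is left off the network to
exercise the biomarker-mapping step. Everything is deterministic under
the configuration seed.

What the generator does **not** emulate: platform artifacts,
normalization pipelines, probe-to-gene mapping, correlated background
co-expression, or degree-structured (scale-free) interaction topology.
Passing recovery tests on this generator demonstrates the pipeline's
correctness and selectivity, not its behaviour on real cohorts.

# Validation experiments and their problem sizes

The test-suite experiments run at desk scale, chosen once: recovery
uses 300-gene cohorts at the default stage sizes with 10 + 10 planted
markers (effect 3 SD), 5 planted pairs (ρ = 0.85) over 20 seeds; null
calibration uses 60-gene, 8 + 8-marker null cohorts with 500
permutations over 20 seeds; the shortest-path oracle covers all pairs
of 100 random ≤ 12-node graphs against exhaustive simple-path
enumeration; the tested-pair count is measured on a full-scale 136 ×
230 mapped-biomarker instance.

Two validation outcomes deserve comment rather than silence:

* **The screen recovers planted pairs essentially completely** (planted
  corridors are short and strongly co-expressed, and the dual criterion
  passes them while background pairs fail either the length or the FDR
  arm).
* **IFS optimal sets do not contain all planted markers at strong
  effects.** With every marker shifted by ≥ 3 SD, a handful of genes
  already separates the two stages perfectly, the LOOCV accuracy curve
  saturates at 1.0 by k ≈ 4–7, and the parsimony tie-break stops
  there: the optimal set is a *sufficient* discriminative set, not an
  exhaustive list of differential genes. This is inherent to
  IFS-with-parsimony on strongly separable data — visible here because
  the planted truth is known — and should temper completeness claims
  for optimal biomarker sets on any data this separable.

# Numerical and degenerate-input choices

* Population SD (÷ n) in discretization; sample SD in NN
  standardization (any consistent scale works there).
* Constant genes: all-zero discretized states (reported); excluded
  from correlation testing with a logged count; never retained.
* p-values are floored at the smallest positive double before BH to
  keep the (0, 1] contract for perfectly correlated planted pairs.
* All cutoff comparisons are strict, as are the confidence-rank
  boundaries; score 0.150 itself is admissible (rank "low").
* Ties: mRMR → input gene order; NN → smallest sample index; IFS →
  smallest k; equal-length shortest paths → fewest hops, then
  lexicographic; hubs → alphabetical.
* Seeds: one integer drives each generator; the pipeline derives
  per-stage sub-seeds so stages can be re-run independently yet
  reproducibly; reruns are byte-identical.

# Known limitations

* Expression input must already be gene-level and normalized; no GEO
  parsing or probe collapsing is provided.
* Exactly one shortest path per pair is used (no k-shortest or flow
  ensembles); path-node reports and hub counts describe that single
  deterministic path.
* The permutation FDR's null law is non-uniform (see above); its
  default 20,000 permutations are costly on large instances, and the
  implementation exploits label-permutation equivalence (distances are
  looked up in the original graph under the inverse relabeling) rather
  than rebuilding graphs.
* Multi-class (four-stage) classification is out of scope; only the
  two pairwise contrasts are implemented.
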