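---
title: "Methods: from expression nulls to drug-combination candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from expression nulls to drug-combination candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The per-gene Bayesian null and the doubled-variable p-value

For each gene, control expression is modeled as
\(x \sim \mathrm{Normal}(\mu, \sigma^2)\) with independent semi-conjugate
priors \(\mu \sim \mathrm{Normal}(w_0, v_0)\) and
\(\sigma^2 \sim \mathrm{InvGamma}(a_0, b_0)\). The defaults
\(w_0 = 0, v_0 = 10^4, a_0 = b_0 = 10^{-3}\) are vague: with 88 controls the
posterior is data-dominated and the posterior predictive is, to numerical
accuracy, the classical Student-t predictive
\(t_{n-1}\!\left(\bar x,\; s^2 (1 + 1/n)\right)\) — the test suite holds the
sampler to that closed form within ±0.01 at the 90th–99th predictive
percentiles.

Sampling is by two-block Gibbs: both full conditionals
(\(\mu \mid \sigma^2, D\) normal; \(\sigma^2 \mid \mu, D\) inverse-gamma)
are available in closed form, so no general-purpose MCMC engine is needed
and per-gene fits are fast enough to run for every gene of a cohort.
Defaults: 2 chains × 2000 draws after 1000 warmup iterations, 4000
posterior-predictive draws, seed required. Convergence is monitored by
split-\(\hat R\); values above 1.05 are recorded as a warning on the model
(never silently dropped).

The decision device is the *doubled* predictive variable \(y = 2x\): the
p-value of a tumor value is the upper-tail mass of the empirical density of
\(y\). Demanding \(p \le 0.05\) under the doubled density, together with the
fold-change gate \(\ge 2\), requires a tumor value to be extreme even
relative to a doubling of the control distribution — deliberately stricter
than a t-test, which on cohort-sized data calls a large fraction of the
genome up-regulated.

Numerical choices:

* The doubled density is a Gaussian kernel density estimate over 1024
  evenly spaced grid points with the Silverman rule-of-thumb bandwidth; the
  grid spans the doubled draws ± 3 bandwidths (the `stats::density`
  defaults, stated here as the contract).
* Tail masses are trapezoid-integrated from the right and clamped to
  \([0, 1]\); the threshold at level \(\alpha\) is the smallest grid value
  whose tail mass is \(\le \alpha\). With 4000+ predictive draws the mass
  of a single grid cell near the 5% threshold is below \(10^{-3}\), so the
  inversion error is well inside the Monte-Carlo tolerance (±0.005) the
  tests enforce.
* A zero-variance control vector degenerates the inverse-gamma posterior
  and is a hard error by default; an explicit `zero_var = "jitter"` policy
  instead adds deterministic jitter of sd \(10^{-6}\) with a warning. The
  noiseless recovery tests use that policy.
* Fold change divides by the arithmetic mean of controls; non-positive
  denominators (conceivable after a log2-to-linear transform of corrupt
  input) are errors, not NA propagation.

Two points the analysis leaves open were decided as follows. First, the
working scale: the doubling device and the fold-change gate are defined on
expression values, while public matrices often arrive log2-transformed;
the package operates on the linear scale and exponentiates log2 input
under an explicit `scale = "log2"` flag, so that "doubling" always means
doubling. Second, the "probability of a gene" used downstream is read as
the up-regulation probability \(1 - P(Y \ge x)\) — a density *value* at
\(x\) would be neither in \([0,1]\) nor monotone in \(x\), so the tail
reading is the only one that supports scoring and ranking.

No multiple-testing correction is applied at the 0.05 gates, matching the
analysis this package implements; a Benjamini–Hochberg option exists
(`adjust = "BH"`) but is off by default.

## Activated TFs

A TF is active in a sample when its targets are over-represented among the
sample's up-regulated genes: one-sided hypergeometric upper tail
\(P(X \ge k)\) with universe \(N\) = all genes tested (the expression
matrix, not the network), \(K\) targets in the universe, \(m\) up-regulated
genes, \(k\) up-regulated targets, gated inclusively at \(p \le 0.05\).
Network edges to genes outside the assay universe are dropped before
counting. A TF's own expression is not required to be up-regulated, and no
minimum target-set size is imposed — TFs with no usable targets simply get
\(p = 1\).

## Subgrouping by k-modes

Binary activation profiles are clustered with k-modes: Hamming
dissimilarity, cluster modes updated as per-column majority vectors
(ties to 1), assignment ties to the lowest-numbered cluster. One run is
seeded by Huang-style density initialization and `n_init - 1 = 9` further
runs from random distinct rows; the lowest-cost run wins, and the
within-run cost is asserted never to increase across iterations. Groups
are renumbered by descending size for stable reporting, and `k` defaults
to 3 but is a parameter; because no selection rule is printed for it, the
analysis workflow emits a cost-versus-k elbow table instead of pretending
one exists.

Each subgroup is characterized by its *center sample*: the member with
minimum Hamming distance to the cluster mode, ties broken by sample id. A
mode vector need not correspond to any real sample, so the nearest member
is used — this keeps "the subgroup's activated TFs" an observable profile.
A 2-D PCA projection of the centered binary matrix is computed for
visualization coordinates; plotting itself is out of scope.

## Upstream cascades and the core network

For each pathway (directed, signed gene graph) and each activated TF of a
subgroup, all simple paths from the pathway's start nodes (in-degree 0;
for fully cyclic pathways the source strongly-connected components, with a
warning) to the TF are enumerated, capped at `max_len = 12` edges with a
hard budget of \(10^5\) paths per (pathway, TF) pair — simple-path counts
are exponential in the worst case and the cap keeps desk-scale guarantees.
Cascades are scored by the arithmetic mean of member-gene up-regulation
probabilities, taken from the subgroup's center sample for consistency
with the subgroup characterization. The top 3 cascades are kept *per
(pathway, TF) pair*; the scope of "top 3" was ambiguous (per pathway, per
TF, or global) and the per-pair reading was chosen because it bounds the
merged network size by construction. Ties break toward shorter paths, then
lexicographically, so pruning is order-invariant.

Retained cascades merge into a per-subgroup core network: edge signs come
from the source pathways (sign conflicts keep both annotations and are
flagged), and node roles are `tf` for queried TFs, `start` for cascade
heads, `transduction` otherwise. Edge signs play no role in enumeration or
scoring — they are carried for the perturbation stage.

## Perturbation factors

Gene importance over a core network follows the impact-analysis
recurrence
\[
\mathrm{PF}(g_i) = \Delta E(g_i) + \sum_j \beta_{ij}
\frac{\mathrm{PF}(g_j)}{N_{ds}(g_j)},
\]
summing over direct upstream genes, with \(\beta = \pm 1\) from the edge
sign (overridable per edge) and \(N_{ds}\) the out-degree *within the
scored network* — PF is evaluated on the network being reported, not on
the full pathway collection. \(\Delta E\) is the up-regulation probability
of the center sample, the same density substitution used for cascade
scores, so genes with different control variances contribute comparably.

Acyclic networks are solved exactly by forward propagation in topological
order; cyclic ones by the dense linear system \((I - A)\,\mathrm{PF} =
\Delta E\); near-singular systems fall back to damped fixed-point
iteration (damping 0.9, at most \(10^4\) sweeps). Every returned solution
must satisfy the recurrence within \(10^{-8}\) at every node, otherwise
the offending strongly connected component is named in an error. On DAGs
the three routes agree within \(10^{-9}\) (property-tested). Genes present
in all subgroup networks are ranked by mean PF, ties by name.

## Drug and combination mapping

A drug maps onto a network when at least one catalog target is a network
gene (drug names case-insensitive after trimming; no synonym resolution).
A screen combination is validated when **both** members are mapped and the
synergy score strictly exceeds 8 — "higher than 8" is read as a strict
inequality, so a score of exactly 8 is excluded. Combination pairs are
order-normalized lexicographically on load, making \((A,B)\) and
\((B,A)\) records indistinguishable. Validated-combination targets are
ranked by row occurrence, each row contributing each listed target once.

## The synthetic-data generator

`simulate_study()` emulates, at reduced scale, the statistical structure
the pipeline assumes; all outputs are pure functions of (config, seed) and
come with planted truth. Stock conditions: 88 controls (the normal-cohort
size the null is designed around), 60 tumors in 3 subgroups, 240 genes
plus 12 TFs as expression rows, 8–12 targets per TF, planted fold 4,
per-gene \(\mu \in [2, 10]\) and \(\sigma \in [0.5, 2]\) (weak-to-strong
expression without degenerate variance), 4 pathways with planted cascades
of 3–5 edges, 24 drugs, and a synergy screen in which 20% of pairs exceed
the score-8 threshold. The planted fold must exceed 2 so planted genes
clear the fold gate in expectation; 4 gives a comfortable margin at the
stock noise level.

Structural guarantees that make recovery tests exact at zero noise: active
TFs get mutually disjoint target sets, decoy TFs draw targets from a
disjoint pool, pathway genes come from genes no TF targets, and decoy
pathway branches never open a second start-to-TF route. A small backbone
of transduction genes recurs in every planted cascade so the subgroup
networks overlap and the cross-group PF ranking is non-trivial. Group
sizes are multinomial with configurable proportions (equal by default) —
any particular observed split is data, not a generator contract.

What the generator deliberately does **not** emulate: RNA-seq count
over-dispersion, batch effects, copy-number or methylation layers,
TF-target weight heterogeneity, or pathway cross-talk. Passing recovery
tests therefore demonstrates correctness of the inferential machinery
under the model's own assumptions, not robustness to the full messiness of
real cohorts.

## Problem sizes and runtime

The test suite runs the full pipeline on a 160-gene, 9-TF, 3-pathway
noiseless study (about 4 s) and checks calibration and oracle agreement on
88-control fits with up to 20000 predictive draws; the complete suite
finishes in under a minute on one CPU. The analysis workflow uses the
stock 252-gene study and completes in about two minutes, dominated by the
per-gene Gibbs fits. These sizes were chosen so that every quantitative
guarantee is exercised at full strength while iteration stays interactive.

## Known limitations

* The doubled-variable device is calibrated for *up*-regulation only;
  down-regulation calling is intentionally absent.
* Enrichment p-values are raw; with hundreds of TFs the per-sample
  activation profiles inherit the usual multiplicity caveats (the BH
  option exists for sensitivity analyses).
* k-modes is a local optimizer; recovery guarantees hold for
  well-separated planted signatures, and real profiles may need larger
  `n_init`.
* KGML pathway files are not parsed; the SIF dialect
  (`source TAB relation TAB target`, relation in
  {activation, inhibition}) is the interchange format, and a KGML-to-SIF
  converter is a documented extension point.
* PF is the stated recurrence only — no permutation p-values or bootstrap
  as in full pathway impact analysis.
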