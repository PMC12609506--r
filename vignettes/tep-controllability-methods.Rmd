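---
title: "Methods: controllability-based target discovery in platelet signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: controllability-based target discovery in platelet signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepnet)
```

## The problem

Tumor-educated platelets (TEPs) are platelets whose transcriptome has been
reprogrammed by tumor-derived signals; their hyperactivation feeds back into
metastasis and thrombosis. Given (i) a curated table of directed, signed
protein interactions, (ii) per-gene differential-expression statistics
(TEPs versus non-cancer platelets), and (iii) a drug–target table, `tepnet`
reconstructs a platelet-specific signaling network, asks *where the network
can be steered from*, and ranks drugs and drug combinations that hit those
steering points. Everything is deterministic given the inputs and a seed, so
a run is a reproducible analysis, not a one-off.

## Network reconstruction

The reconstruction follows a fixed order, and each step only removes
material; the provenance log attached to the result records node/edge counts
after each step and is monotone non-increasing in edges.

1. **Curation filter.** Keep directed, signed interactions with a curation
   effort of at least 3 (inclusive). The threshold is the number of
   independent curation events supporting the interaction in the source
   database; 3 is the package default (`reconstruction_config()`), matching
   the quality bar used for well-curated signaling resources.
2. **Expression filter.** Keep interactions whose two endpoints are
   expressed: average expression at least 1 (inclusive, on the log2 scale
   that limma's `AveExpr` reports, roughly the first quartile in platelet
   RNA-seq), *or* detection in any supplied proteomics presence list.
3. **Sign-contradiction removal.** Each edge's sign is predicted as the sign
   of the product of its endpoints' log2 fold changes, but only when both
   endpoints are significant DEGs (|log2FC| > 0.58 and adjusted p < 0.05,
   strict); otherwise the prediction is *unknown* and can never contradict.
   An edge is dropped exactly when a known prediction disagrees with a known
   curated sign.
4. **Largest component.** The largest *weakly* connected component is kept
   (signaling networks include pure-source receptors that strong
   connectivity would discard), with ties broken toward the component
   containing the lexicographically smallest gene symbol so the result is
   deterministic.

Two derived networks reuse these pieces: the *DEG subnetwork* (edges with at
least one differentially expressed endpoint, contradiction-filtered, no
isolated nodes) and the *expanded interactome*, which skips the curation and
sign requirements entirely, collapses everything to unordered pairs, and is
used for proximity scoring. Parallel records for one ordered pair collapse
to a single edge; if curated signs conflict (+1 and −1) the collapsed edge
gets sign 0 with a warning — downstream contradiction filtering needs one
sign per edge, and an ambiguous pair should be allowed to survive on its
curation merits rather than be removed on a coin flip.

## Structural controllability

A directed network is structurally controllable from a set of *driver
nodes* if inputs there can steer the (generic) linear dynamics anywhere.
The package uses the standard bipartite encoding: each node splits into an
out-copy and an in-copy, each edge `u -> v` becomes the bipartite link
`out(u)–in(v)` (a self-loop lets a node match itself), and the driver nodes
of a maximum matching are the nodes with unmatched in-copies. The minimum
driver count is `N_D = max(N − |M*|, 1)`.

The matching itself is an augmenting-path (Kuhn) search written in the
package. The *canonical* matching processes nodes and adjacencies in
lexicographic order, so every deterministic quantity (the minimum steering
set, tie-breaks, reported driver sets) is reproducible; randomized variants
take an explicit seed. `igraph`'s independent bipartite matcher is used in
the test suite as a cross-check, never as the implementation.

### Node classes

* **critical / intermittent / redundant** — a node is critical if it is a
  driver in *every* maximum matching (equivalently: its in-copy has no link,
  or no in-neighbor extends to a maximum matching through it), redundant if
  it is matched in every maximum matching (removing its in-copy drops
  `|M*|`), intermittent otherwise.
* **indispensable / neutral / dispensable** — remove the node with its
  edges, recompute `N_D`; the count going up, staying, or going down gives
  the class.

Both classifications partition the node set, and every in-degree-0 node is
critical. **Perfect-matching special case:** when `|M*| = N` every singleton
is a valid minimum driver set; the package then reports `N_D = 1`, the
lexicographically smallest node as the conventional driver, classifies every
node intermittent, and assigns control capacity `1/N`. The alternative
reading ("always matched, therefore redundant") would contradict the nodes'
own MDS membership.

### Control capacity

Control capacity is the fraction of minimum driver sets containing a node.
For networks of at most 12 nodes (`exact_below`) all maximum matchings are
enumerated by a pruned recursive search and distinct driver sets are counted
exactly. Above that, enumeration is exponential, so the package samples: the
saturable in-copy sets form a transversal matroid, and a symmetric
basis-exchange walk (swap one saturated node for one unsaturated one, accept
if the set is still saturable — a single re-augmentation of the current
matching) is a Metropolis chain whose stationary distribution is uniform
over minimum driver sets. A naive alternative — re-running the matching with
randomized node orders — is visibly biased on small graphs (deviations above
0.15 from enumerated capacities on 12-node examples), which is why the walk
is used; with burn-in `10N` and thinning `N/2` the sampled capacities agree
with enumeration to a few hundredths at 1000 samples. Critical and redundant
nodes are pinned to capacity 1 and 0 exactly, whatever the estimator says.

### Control centrality

Control centrality is the generic dimension of the subspace controllable
from a single input at one node. By the classical structural results this is
the maximum number of state vertices covered by one *stem* (a directed path
starting at the input) plus vertex-disjoint cycles, all inside the node's
reachable set. A tempting shortcut — "1 + maximum matching of the bipartite
representation of the reachable subgraph with the node's in-copy removed" —
is wrong in general: it silently admits extra paths that do not start at the
input (for `i -> a`, `i -> b`, `a -> c`, `b -> d` it claims 4 where the true
generic rank is 3). The package instead solves the stem-plus-cycles
maximization exactly as a 0/1-cost assignment problem on an auxiliary graph
(an input vertex `u` with link `u -> node`, zero-cost return links `v -> u`,
zero-cost links per network edge, and a unit-cost slack per vertex meaning
"left uncovered"); the minimum assignment cost counts the uncovered
reachable vertices. The assignment solver is the dense shortest-augmenting-
path algorithm, cubic per node, which is why the pipeline computes the
metric only for the critical and indispensable nodes and only on networks of
at most `centrality_max_nodes` (default 150). The test suite checks the
implementation against numeric Kalman generic ranks with random edge weights
on 100 seeded digraphs.

A note on oracles: the matching count `N_D` is the minimum number of
*independent input signals*, where one signal may attach to several nodes.
A brute-force check that only allows dedicated one-node inputs disagrees on
graphs containing a perfectly matched cycle unreachable from the unmatched
nodes; the suite therefore verifies `N_D` against the smallest number of
*dense* generic input columns that reach full Kalman rank.

## Weighted subnetworks and gene scores

**Edge weights.** Each edge gets `W = 1 / |log2FC_i × log2FC_j|` when both
endpoints are significant with non-zero fold change, so strongly
co-regulated edges are cheap. The printed form of this rule (without the
absolute value) yields negative weights for discordant fold-change pairs,
which no shortest-path algorithm accepts; the absolute value preserves the
intent — more regulation, lower weight — and is a deliberate, documented
deviation. Edges with an uninformative endpoint get a penalty of 10× the
largest finite weight: traversable, so connectivity through non-significant
hubs is possible, but strongly discouraged. If no informative edge exists at
all, weights fall back to a constant (with a warning) and the extraction
degenerates to unweighted shortest paths.

**Controllable subnetwork.** One minimum-weight directed path per ordered
(critical, indispensable) pair, computed with Dijkstra distances; among
equal-weight paths the lexicographically smallest node sequence is retained
(greedy smallest-next-node along shortest-path edges, with a relative
tolerance of 1e-9 for floating-point ties). The subnetwork is the union of
retained paths — a shared edge counts once — and unreachable pairs are
logged, not errors. Retaining one path per pair (rather than all ties)
matches the single-path behavior of the standard shortest-path routine the
procedure mirrors; an all-paths variant would only enlarge the subnetwork by
tie sets.

**Node weights and proximity scores.** A node's weight is
`degree × |log2FC|` for significant genes and `degree × 1e-6` otherwise, so
non-significant genes report as 0 at the 2-decimal precision of result
tables. The proximity (Knode) score is
`K_i(s) = (2/p) Σ_{j ≠ i, d(i,j) ≤ s} (p_j − p̄)` with `p` the total weight,
`p̄` the mean, and `d` the unweighted geodesic distance. Three ambiguities
are resolved as follows: the normalization reads as `2/p`; the self term
`j = i` is excluded (the worked three-node example only reproduces with it
excluded); and the radius defaults to `s = 2` — direct neighbors plus second
neighbors, the shortest horizon that sees beyond trivial adjacency —
configurable, with a vector of radii averaged for an area-under-profile
variant. `K` is invariant under rescaling of all weights (the `2/p` prefix
absorbs the constant), so only the ranking carries meaning. The top decile
(ceiling of `0.10 N`, ties at the cut included) of scores and of weights
seed the *score subnetwork*, built from unweighted shortest paths — node
prioritization already encodes regulation there, so weighting edges again
would double-count it.

## Drug mapping and combinations

Prioritized nodes (by default the indispensable nodes inside the
controllable subnetwork) are intersected with a drug–target table; drugs
with empty coverage are dropped, ranking is by coverage count with
alphabetical tie-break, and the actionability filter keeps approved drugs
with known pharmacological action. Combinations are anchored (default: the
top-ranked drug): the anchor plus up to two partners, none interacting with
the anchor or each other, ordered lexicographically by covered-target count
(union, never sum), then inhibition strength, then a control score. The
strength contribution of a covered target is `1 / log10(ki + 10)` using the
lowest inhibition constant among the members that hit it — the published
procedure requires only something monotone decreasing in `ki`; the `+10`
offset keeps the contribution finite and positive across the realistic
nanomolar range, including `ki ≤ 1` where a bare `1/log10(ki)` diverges or
flips sign. The control score sums the covered targets' control-centrality
and betweenness ranks; keeping the three criteria lexicographic rather than
blending them keeps the ordering interpretable.

## The synthetic generator

`simulation_config()` describes the statistical structure the analysis
assumes, and its defaults are the package's study conditions:

* a 400-node, 8000-interaction raw interactome with preferential-attachment
  out-degrees (hubs exist, as in curated signaling resources). The raw table
  is deliberately dense: the curation filter (negative-binomial curation
  counts, size 0.35, mean 0.9, putting ~10–12% of interactions at effort
  ≥ 3) and the 55% directed-signed fraction cut it to a well-curated core,
  and the expression filter then yields a connected component of roughly
  200 nodes and 220 edges — the same distillation shape, scaled down, as a
  signaling network extracted from a bulk interactome snapshot;
* a gene table in which 15% of genes carry planted effects,
  |log2FC| ~ Normal(1.2, 0.4) — comfortably above the 0.58 DEG cutoff, as
  in real TEP contrasts where called DEGs sit well clear of the threshold —
  with near-zero raw p-values; null genes get Normal(0, 0.15) fold changes
  and uniform p. Raw p-values are Benjamini–Hochberg adjusted *inside* the
  generator so that the emitted table looks like real differential-
  expression output and is never re-adjusted downstream; average expression
  is log-normal so that the expression filter bites;
* a drug table whose target draws are biased toward high-degree nodes
  (hubs are empirically the druggable proteins; pass a plain character
  vector instead of a degree vector to switch the bias off for null
  experiments), log-uniform inhibition constants on [1, 10^4] nM, and
  interaction pairs sampled over 10% of drug pairs.

What the generator does *not* emulate: correlated expression between
interacting genes, curation effort correlated with degree, batch structure,
or gene-family redundancy. Tests passing on synthetic data therefore verify
the algorithms and their contracts, not biological conclusions about any
real platelet dataset.

Problem sizes used by the shipped tests and examples — toy graphs for exact
worked examples, seeded random digraphs of 4–12 nodes for oracle
comparisons, 40-node networks for the planted-recovery study, and
150-node/2600-edge simulations for the end-to-end pipeline — were chosen so
that every expected value is independently recomputable (by enumeration,
numeric rank, or a literal double loop) while the full suite stays quick to
run.

## Numerical and degenerate-input choices

* Strict inequalities for DEG calls (`|log2FC| > 0.58`, `p < 0.05`);
  inclusive thresholds for curation (≥ 3) and expression (≥ 1) — each
  matching the usual reading of "greater than" versus "at least".
* Duplicate gene rows collapse to the smallest adjusted p-value; the
  missing-value tokens `NA`, `--` and the empty string are accepted because
  result tables conventionally print `--` for non-significant fold changes.
* Empty networks, empty DEG sets, empty drug tables and unreachable
  source–sink pairs are ordinary conditions (empty outputs or logged pairs),
  not errors; an all-zero weight vector for Knode scoring *is* an error,
  since the score is undefined.
* All randomized procedures (capacity walk, simulators) run on a private
  RNG stream and restore the caller's `.Random.seed`.

## Known limitations

* The minimum steering set is one concrete MDS (the canonical matching's
  driver set); it provably contains all critical nodes and has size `N_D`,
  but its intermittent members depend on the tie-breaking order, and other
  implementations may report a different, equally valid set.
* Control centrality values depend on the exact network; across tools only
  the definition (generic single-input rank) is comparable.
* Control energy, Gramians, edge controllability and temporal networks are
  out of scope, as are identifier mapping, live database clients and
  expression-matrix processing: inputs are symbol-keyed tables.
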