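# tepnet

Controllability-based therapeutic target discovery in tumor-educated
platelet (TEP) signaling networks.

Platelets in cancer patients carry a reprogrammed transcriptome, and their
hyperactivation promotes metastasis and thrombosis. `tepnet` takes three
symbol-keyed tables — a curated protein-interaction export (OmniPath-style),
per-gene differential-expression statistics (limma-style), and a drug–target
table — and answers: *which proteins control this signaling network, and
which approved drugs (or safe combinations) hit those control points?*

## What it computes

1. **Network reconstruction.** Keep directed, signed interactions with
   curation effort ≥ 3; keep genes with average expression ≥ 1 or proteomic
   detection; predict each edge's sign as `sign(log2FC_i × log2FC_j)` (only
   when both ends are DEGs: |log2FC| > 0.58, adjusted p < 0.05); drop edges
   whose predicted and curated signs contradict; keep the largest weakly
   connected component. Every step is logged in a provenance table.
2. **Structural controllability.** With the bipartite out-copy/in-copy
   encoding, a maximum matching `M*` gives the minimum driver count
   `N_D = max(N − |M*|, 1)` (drivers = unmatched in-copies). Nodes are
   classified **critical / intermittent / redundant** (driver in every /
   some / no minimum driver set) and **indispensable / neutral /
   dispensable** (removal raises / keeps / lowers `N_D`), with per-node
   control capacity (fraction of MDSs containing the node — enumerated
   exactly on small networks, sampled by a uniform basis-exchange walk
   otherwise) and control centrality (generic dimension steerable from a
   single input, solved as a stem-plus-cycles assignment problem).
3. **Controllable subnetwork.** Edges weighted
   `W = 1/|log2FC_i × log2FC_j|` (penalized when uninformative); union of
   one cheapest Dijkstra path per (critical → indispensable) pair.
4. **Proximity scoring.** On the expanded undirected interactome: node
   weight `degree × |log2FC|`, Knode score
   `K_i(s) = (2/p) Σ_{j≠i, d(i,j)≤s} (p_j − p̄)`, and a score subnetwork
   joining the top decile of scores to the top decile of weights by
   unweighted shortest paths.
5. **Drug ranking.** Map prioritized nodes to drugs, keep approved drugs
   with known pharmacological action, rank by target coverage, and rank
   anchored, interaction-free combinations by (coverage, inhibition
   strength, control score).

`run_pipeline()` chains all stages; each stage is exported on its own. A
seeded generator (`simulation_config()`, `simulate_interactome()`,
`simulate_gene_stats()`, `simulate_drug_tables()`,
`write_simulated_inputs()`) produces inputs with the statistical structure
the analysis assumes, so everything is testable offline.

## Worked example

```r
library(tepnet)
fx <- load_reference_fixtures()

# a receptor hub: h -> a, h -> b, h -> c
star <- fx$toy_graphs$star4
classify_mds_membership(star)
#>              a              b              c              h
#> "intermittent" "intermittent" "intermittent"     "critical"
driver_count_and_set(star)
#> $n_drivers
#> [1] 3
#> $drivers
#> [1] "b" "c" "h"
round(control_capacity(star), 3)
#>     a     b     c     h
#> 0.667 0.667 0.667 1.000
```

The hub `h` has no incoming edge, so no matching can cover it: it is a
driver in every minimum driver set (critical, capacity 1). Each leaf is
interchangeable — two of the three leaves appear in any MDS (capacity 2/3).

Drug ranking over the indispensable nodes of the controllable subnetwork,
using the packaged drug–target fixture:

```r
nodes <- c("CAMK1","JAK2","MAPK14","PRKCD","PTK2","CASP3","MAPK1",
           "MAPK3","AKT1","APP","GAPDH","HSP90AA1","PRKCA")
head(rank_drugs(map_targets(nodes, fx$drug_targets)), 5)
#>                   drug n_targets                          targets
#> 1         Fostamatinib         5 CAMK1, JAK2, MAPK14, PRKCD, PTK2
#> 2          Minocycline         4      CASP3, MAPK1, MAPK14, MAPK3
#> 3 Acetylsalicylic acid         3              CASP3, MAPK1, MAPK3
#> 4     Arsenic trioxide         3               AKT1, MAPK1, MAPK3
#> 5               Copper         3             APP, GAPDH, HSP90AA1
```

Fostamatinib (an SYK inhibitor central to ITAM-mediated platelet
activation) tops the coverage ranking. Node weights recompute from the
high-score table's printed degree and fold change:

```r
hs <- fx$high_score_nodes
w <- compute_node_weights(setNames(as.numeric(hs$degree), hs$gene),
                          high_score_gene_stats(hs))
round(w[c("P2RY12", "TUBA4A", "GRB2", "LYN")], 2)
#> P2RY12 TUBA4A   GRB2    LYN
#>   0.49   0.13   0.00  11.52
```

`P2RY12` (degree 1, log2FC −0.49) gets weight 0.49; `GRB2` is not
significantly regulated, so its 37 connections contribute
`37 × 1e-6 ≈ 0` at reporting precision.

For a full synthetic run:

```r
cfg <- simulation_config(seed = 7)
rec <- simulate_interactome(cfg)
st  <- simulate_gene_stats(cfg, sprintf("G%04d", 1:400))
report <- run_pipeline(rec, st, seed = 7)
report
#> tepnet pipeline report
#>   network: 193 nodes, 223 edges; 86 driver(s)
#>   MDS classes: critical=54, intermittent=82, redundant=57
#>   removal classes: indispensable=18, neutral=122, dispensable=53
#>   controllable subnetwork: 60 nodes, 55 edges
#>   drug stage: no candidates
```

## Layout

- `R/` — reconstruction, matching/controllability, subnetworks and scoring,
  drug mapping, simulators, pipeline, readers/writers (TSV, SIF, GraphML).
- `inst/extdata/` — plain-text worked-example fixtures.
- `tests/testthat/` — unit and property tests, including independent
  oracles (numeric Kalman ranks, igraph's bipartite matcher, exhaustive
  path enumeration, literal double-loop scoring).
- `vignettes/tep-controllability-methods.Rmd` — the methods notes: model
  assumptions, parameter defaults, numerical choices, limitations.
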