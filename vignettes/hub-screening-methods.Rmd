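---
title: "Consensus hub-gene screening and enrichment: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus hub-gene screening and enrichment: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The inference chain

Network-pharmacology studies of natural compounds ask which proteins
mediate a compound's effect on a disease. The standard chain, which this
package implements end to end, is:

1. **Target assembly.** Predicted compound targets (e.g. from ligand- or
   pharmacophore-based servers) and disease-associated genes (from
   curated disease databases) are read as gene-symbol lists, normalised,
   merged per side, and intersected. The overlap is the candidate
   mechanism space.
2. **Interaction network.** The overlap genes are mapped onto a
   protein–protein interaction network given as a STRING-dialect edge
   list (`protein1`, `protein2`, `combined_score` on a 0–1000 scale).
   Only edges at or above a confidence cutoff are kept — the default
   900 corresponds to the "highest confidence 0.9" setting — and
   disconnected nodes are hidden.
3. **Three topological screens.**
   * *Median centrality screening*: degree (DC), betweenness (BC) and
     closeness (CC) are computed; nodes strictly above all three medians
     survive, the induced subgraph is rebuilt, and the screen repeats
     (two rounds by default).
   * *Dense-module detection* in the MCODE style: vertices are weighted
     by the core-clustering coefficient, complexes grow greedily from
     high-weight seeds, and a 2-core "haircut" trims stragglers.
   * *Maximal clique centrality*: every maximal clique is enumerated
     with the Bron–Kerbosch pivoting algorithm and each node scores
     `MCC(v) = sum over maximal cliques C containing v of (|C|-1)!`;
     the top 10 are kept.
4. **Consensus.** The three candidate lists intersect into the final
   hub set, ordered by final-round degree.
5. **Enrichment evidence.** Hypergeometric over-representation of the
   overlap (or any list) against a GMT collection with
   Benjamini–Hochberg FDR; and, when expression data are available, a
   two-group differential-expression screen feeding preranked GSEA.

## Centrality conventions

All shortest paths are unweighted. BC is *unnormalised* (each unordered
pair counted once, endpoints excluded; Brandes' accumulation); CC is
normalised *within each connected component*,
`CC(v) = (n_c - 1) / sum(d(v, u))`. This mixed convention is the one
under which published two-round thresholds of the form
"BC > 112.5, CC > 0.15, DC > 6" are mutually consistent — BC on the
pair-count scale, CC in (0, 1] — and it matches the defaults of the
CytoNCA plugin this screen emulates. Ties at a median are dropped
(strict `>`), which is why a perfectly regular graph such as a cycle
screens to the empty set (with a warning) rather than looping.

Centralities are *recomputed on the survivors' induced subgraph* each
round. Recomputation is what makes the second round's medians move the
way induced subgraphs do (degree medians rise, betweenness medians can
fall), and it is the behaviour implied by screening rounds whose
thresholds are not nested.

## MCODE parameters

The module detector uses the published plugin defaults, since studies
of this type rarely state them: degree cutoff 2 (nodes of lower degree
weigh 0), node-score cutoff 0.2 (a neighbour joins a complex when its
weight is at least 80% of the seed's), haircut on (complexes trimmed to
their 2-core), fluff off. Density is computed without self-loops,
`2E / (V(V-1))`, and a complex scores `density x size`. Equal-weight
seed ties break lexicographically so runs are reproducible. Which
MCODE-derived list enters the consensus is configurable
(`consensus_module`): top-cluster members by default, cluster seeds as
the alternative, because published workflows are usually silent on this
point.

## MCC arithmetic

`(|C|-1)!` overflows 64-bit integers for cliques of 21 nodes and loses
double-precision exactness well before that, so MCC scores are
accumulated in an internal arbitrary-precision integer (base-10^4 digit
vectors). The score table carries both a double approximation for
display and the exact decimal string; top-k selection compares the
exact strings, and the boundary-tie policy defaults to including every
tied node (reporting the actual list size) with a truncating
alternative for fixed-length lists.

## Enrichment statistics

ORA uses the exact hypergeometric upper tail `P(X >= k)` with BH
adjustment over the tested family. Because the universe used by
enrichment web servers is unknowable after the fact, the universe here
is explicit configuration: all genes of the collection by default,
restrictable to the network's node set. Terms with no query overlap are
excluded from the family by default (the behaviour of common enrichment
servers), includable by flag.

The DEG screen transforms expression to `log2(x + 1)` (tolerating
zeros), takes the difference of group means as log2FC, and applies a
two-sided Welch t-test per gene on the transformed values. Genes with
zero variance in both groups — e.g. entirely undetected genes — are
reported with `p = NA`, excluded from flagging, and warned about once.
Two significance conventions circulate for this screen (0.05 and 0.01),
so `alpha` is a required argument with both values shipped as named
presets (`deg_alpha_presets`) and no silent default.

Preranked GSEA ranks all genes by log2FC (descending, lexicographic
tie-break), uses metric weight 1, and builds its null by gene-set
relabeling: random equal-size member sets drawn from the ranked genes,
1000 permutations by default, all seeded. NES divides ES by the mean
|ES| of sign-matched permutations; nominal p is
`(more-extreme sign-matched permutations + 1) / (sign-matched + 1)`,
so the smallest attainable p is `1/(n_sign + 1)`; FDR pools normalised
permutation scores per sign. Ranking all genes (not only flagged DEGs)
is the default because flag thresholds are discontinuous; ranking a
restricted table is supported by passing it to `rank_genes()`.

## Synthetic data and what tests on it show

The generators produce every input the chain consumes, with recorded
ground truth that is verified against the emitted files at generation
time:

* `make_target_lists()` draws lists with an exact overlap from a
  synthetic universe (`G000001`, ... — never real symbols). The default
  study-shaped fixture uses a 2000-gene universe with 327/1668-gene
  lists overlapping in exactly 198 genes, the list sizes of the
  motivating workflow.
* `make_ppi()` builds a preferential-attachment backbone (2 edges per
  node), wires one designated hub to 30% of all nodes, and plants an
  8-clique *containing the hub*. Making the hub a clique member is a
  deliberate design choice: it is the configuration in which one
  planted structure is recoverable by all three screens at once, which
  is what an end-to-end consensus test needs. Edge confidences are
  drawn uniformly from [900, 1000] so the default cutoff keeps all of
  them; cutoff behaviour is tested separately with sub-900 rows.
* `make_planted_clique_graph()` is the classic planted-clique benchmark
  (K8 in G(150, p = 0.03) by default) used for module recovery rates.
* `make_expression()` simulates log-normal expression (log2-scale
  baseline Normal(5, 1.5), noise sigma = 0.5) with a planted DE set
  shifted by 2 on the log2 scale in 20-vs-20 samples, emitted as
  `2^z - 1` so the analysis transform recovers the simulated scale
  exactly, plus a GMT of the true set and decoys.

These generators emulate list sizes, scale-free degree structure,
planted density and log-scale effects. They do **not** emulate the
dependency structure of real interactomes (edge confidences independent
of topology), correlated co-expression, compositional or count noise,
or annotation bias in real gene-set collections. Passing
planted-structure tests therefore demonstrates algorithmic correctness
and statistical calibration, not biological validity on any particular
real dataset; database-dependent counts from any real study (node or
cluster counts, DEG totals, specific NES values) are reproducible only
from archived exports of those databases.

## Numerical and degenerate-input choices

* Confidence cutoffs are inclusive (`>= 900` for "0.9"), following the
  STRING "minimum required score" convention; 0–1 scores are
  auto-detected and scaled by 1000.
* Duplicate edges (including reversed duplicates) collapse keeping the
  maximum score; self-loops are dropped with a warning; malformed
  scores abort with the offending line number.
* Normalisation of symbols is uppercase-and-trim only — no alias
  mapping, so results cannot depend on an annotation snapshot.
  Identifier columns (e.g. UniProt accessions) are supported through an
  explicit user-supplied mapping file; unmapped rows drop with a
  warning.
* Isolated nodes: closeness 0, MCODE weight 0, MCC 1 (their singleton
  set is a maximal clique).
* An empty screening round returns the trace computed so far with a
  warning rather than an error; an empty query after universe
  restriction returns an empty ORA result with a warning.
* All stochastic steps (generators, GSEA permutations) run under local
  seeds that do not disturb the caller's RNG state, and the pipeline's
  outputs are byte-identical across runs with the same configuration
  and seed.

## Problem sizes used in the shipped tests

The test suite exercises exhaustive oracles on all labelled graphs of
4–5 nodes and random graphs up to 40 nodes, clique enumeration against
subset enumeration at 12 nodes, 100-replicate recovery experiments at
the generator defaults (hub graphs of 200 nodes, planted cliques in
150-node backgrounds), and calibration simulations of 200 replicates
with 200 GSEA permutations. These sizes were chosen so the full suite
documents the methods' behaviour at study-realistic scale while running
in a few minutes on a single core.

## Known limitations

* Betweenness and closeness are unweighted; confidence scores filter
  edges but do not weight paths.
* MCODE's "loops" option and phenotype-permutation GSEA (which requires
  per-sample relabeling of the expression matrix) are not implemented;
  gene-set permutation is the only null.
* ORA reproduces the generic hypergeometric test, not any particular
  server's modified statistic (e.g. EASE), so term counts from such
  servers are context, not targets.
* The consensus is a plain three-way intersection; no weighted rank
  aggregation is attempted.
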