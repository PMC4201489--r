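---
title: "Constraint-guided community detection with actively acquired supervision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-guided community detection with actively acquired supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscd)
```

## The problem

Community detection partitions the nodes of a network into groups that are
densely connected inside and sparsely connected between. Purely
unsupervised detectors use only topology; in many applications, however, a
domain expert can be asked whether two specific nodes belong together. That
answer is a pairwise constraint: *must-link* (same community) or
*cannot-link* (different communities). `sscd` implements a semi-supervised
detector that is driven entirely by such constraints, together with an
active-learning strategy that decides *which* pairs are worth asking a
(noiseless) oracle about, so that a handful of answers goes a long way.

The pipeline has four stages, each exposed as ordinary functions:

1. **Constraint closure** (`close_constraints`). Must-links are transitive,
   so their closure is computed with a union–find structure; combining a
   cannot-link $(a,b)$ with must-links then implies a cannot-link between
   every member of $a$'s group and every member of $b$'s group. A closed
   store is checked for consistency (`check_consistency`) before use.

2. **Random-walk similarity** (`compute_similarity`). Every node starts
   `walks_per_node` simple random walks of `l` steps; after each walk the
   count $s(u,v)$ is incremented by one for every unordered pair of
   distinct nodes in the walk's visited *set* (revisits do not
   double-count). Walkers tend to stay inside densely connected regions,
   so intra-community pairs accumulate higher counts. The community-to-node
   similarity is the member maximum,
   $s(C, v) = \max_{u \in C} s(u, v)$ (`community_similarity`).

3. **Constrained detection** (`detect_communities`). Every node named by a
   cannot-link seeds its own singleton community; seeds related by
   must-links are merged (the *skeleton*). Unclassified nodes sharing a
   must-link group with a classified node are absorbed, and the remainder
   are assigned greedily: while unclassified nodes remain, the
   (community, node) pair with the globally largest $s(C, v)$ is selected
   and the node — followed by its must-link group — joins that community.
   The output provably satisfies every closed constraint: cannot-link
   nodes are all seeds, and communities only ever merge under must-links.

4. **Active acquisition** (`acquire_constraints`). Candidate nodes with a
   high degree-based score are clustered cheaply by local similarity; the
   cluster hubs are queried pairwise against the oracle (phase 0), then
   members tying their hub's degree (phase `"ties"`), then boundary members
   with edges into other clusters (phase `"boundary"`), updating the
   constraint store after every single query and respecting query/node
   budgets.

Evaluation uses three standard metrics: modularity $Q$ (mixing-matrix
form, `modularity_q`), label-matched accuracy $A$ (`accuracy`, via the
iterative plurality matching in `match_labels`) and normalized mutual
information (`nmi`, $I/\sqrt{H_A H_B}$ with plug-in frequencies).

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `l` | `compute_similarity` | $n = \lvert V \rvert$ | walk length in steps |
| `walks_per_node` | `compute_similarity` | 1 | walks started per node |
| `score_fraction` | `active_config` | 0.5 | top fraction of distinct score values kept as candidates |
| `query_budget`, `node_budget` | `active_config` | unlimited | acquisition termination criteria |
| `phases` | `active_config` | ties + boundary | follow-up phases after the hub pairs |
| `dedup_representatives` | `active_config` | off | drop same-community hubs before querying |

The default `l = n` follows the rule that a walker starting anywhere can in
principle traverse the whole network, so every pair receives a defined
similarity. The default of one walk per node matches the original
formulation of the similarity simulation.

### Walk length, mixing, and walk count

The co-visitation similarity only carries community signal while the walk
remains *trapped* in its starting region. Once `l` exceeds the graph's
mixing scale, visit probabilities approach the degree-proportional
stationary distribution, intra- and inter-community counts converge, and —
because counts from a single walk per node are small integers — the greedy
max-rule expansion becomes noise-driven: one community can snowball by
repeatedly winning near-ties. Both effects are easy to measure:

```{r contrast, eval = FALSE}
g <- generate_planted_partition(rep(25, 4), p_in = 0.3, p_out = 0.02,
                                seed = 3, require_connected = TRUE)
blk <- g$truth$assignment
for (l in c(10, 25, 50, 100)) {
  S <- compute_similarity(g$network, l = l, seed = 42)
  same <- outer(blk[rownames(S)], blk[colnames(S)], "==")
  ut <- upper.tri(S)
  cat(l, mean(S[ut & same]) / mean(S[ut & !same]), "\n")  # intra/inter ratio
}
```

On this benchmark the intra/inter contrast shrinks several-fold between
`l = 10` and `l = 100`. We therefore recommend, and use throughout the
package's benchmark runs, **`l` about the expected community size**
(`n / k`, here 25) and **`walks_per_node = 20`** to shrink the Monte-Carlo
noise of the counts. On the 34-node karate fixture the same
variance-reduction (20 walks per node) recovers the two factions exactly;
see the README's worked example. Acceptance checks that reproduce a
published protocol verbatim keep that protocol's `l = n` and one walk per
node, and are assessed as the modal partition over 20 seeds.

### Known limitation: plurality hubs

With one walk per node the greedy expansion is sensitive to count noise
(ties and near-ties are frequent), and for boundary nodes whose
neighborhoods straddle two communities even the *expected* similarity can
favor the community with the higher-degree hub, since long walks visit
hubs in proportion to degree. On the karate fixture this shows up as the
classically ambiguous node 3 — adjacent to both faction hubs — being
placed with the larger hub in the modal run (`scripts/acceptance.R`
reports the modal accuracy it computes, 33/34 under the verbatim
protocol). More supervision resolves it: a single additional constraint
touching such a node pins it.

## Active acquisition: design choices

Several elements of the acquisition strategy are stated in the original
description only loosely; the package fixes them as follows, calibrated
against the published node selections on the karate fixture (hubs
{1, 34} selected with a single oracle query).

* **Node score.** `score(v) = d(v) / max_{u ∈ Γ(v)} d(u)`. A node scores
  at least 1 exactly when its degree is a local maximum, so the hub of a
  small community is kept even when bigger hubs exist elsewhere.
* **Candidate threshold.** The kept set is the top `score_fraction` of the
  *distinct* score values (ties included), not of the nodes; in a regular
  graph everyone is a candidate.
* **Local similarity.** `S(u, v) = |Γ(u) ∩ Γ(v)| + [u ~ v]` — purely
  local and cheap to evaluate over the candidate set.
* **Most similar neighbor.** Each candidate links to the *single* best
  candidate under `S`, ties broken toward the larger degree and then the
  smaller id. Linking to all tied maximizers instead lets one shared
  boundary candidate (karate's node 3 ties to both faction hubs) bridge
  otherwise separate clusters and collapse them into one, defeating the
  selection; the single-link rule keeps msn links pointing up the local
  degree hierarchy.
* **Representative dedup.** Benchmarks are sometimes run with a minimal
  covering set of hubs; `dedup_representatives = TRUE` emulates the manual
  pre-selection by dropping same-community hubs (keeping the larger
  degree, then larger score) before any constraint is generated. The
  ground-truth peeks used for the dedup are deliberately *not* recorded as
  constraints — the published benchmark runs behave as if the surviving
  hubs were simply chosen by hand.
* **Query order.** Hub pairs are queried in descending minimum degree;
  follow-up re-queries visit other hubs in descending degree; boundary
  rounds visit clusters in descending size. All orders resolve residual
  ties by node id, making acquisition fully deterministic.

## The synthetic benchmark

`generate_planted_partition` draws a planted-partition graph (a stochastic
block model with uniform within- and between-block probabilities): blocks
of given sizes, each intra-block pair an edge with probability `p_in`,
each inter-block pair with `p_out`. The package's standard regime — four
blocks of 25, `p_in = 0.3`, `p_out = 0.02` — gives well-separated but
noisy communities (expected intra-degree 7.2 against inter-degree 1.5).
The generator emulates the dense-inside/sparse-between structure the
detector assumes, with exact ground truth to back the oracle. It does
**not** emulate heavy-tailed degree or community-size distributions,
weighted or directed edges, or overlapping membership, so passing results
here demonstrate constraint handling and expansion behavior, not
robustness to the full heterogeneity of real networks.

## Numerical and degenerate-input conventions

* Greedy ties break by highest similarity, then smallest node id, then
  lowest community creation index — detection is deterministic given
  (network, constraints, similarity matrix).
* Nodes with zero similarity to every community (possible with short
  walks) are deferred until all positive-similarity nodes are placed, then
  attached to the community of their highest-degree classified neighbor;
  an isolated leftover goes to the largest community with a warning.
* `modularity_q` builds the mixing matrix with each intra-community edge
  contributing $1/m$ to $e_{ii}$ and each cross edge $1/(2m)$ to both
  off-diagonal cells, so the matrix sums to one; the result equals the
  degree-based formulation to machine precision (property-tested at
  `1e-12`).
* `nmi` uses natural logarithms and the $\sqrt{H_A H_B}$ normalization;
  if both partitions have zero entropy the value is 1, if exactly one
  does it is 0.
* Label matching breaks all frequency ties by structural keys (community
  size, then smallest member id) rather than label names, so accuracy is
  invariant under relabeling of either partition.
* Duplicate edges collapse with a warning on ingestion; self-loops are
  rejected. Constraint pairs are unordered and deduplicated.

## Problem sizes used by the test and acceptance runs

Unit and property tests run on graphs of 4–34 nodes (exhaustive closure
checks enumerate all 729 ML/CL labellings of the 6 pairs of 4 nodes);
benchmark recovery and sweep checks use the 100-node planted regime with
20 seeds and 10 repeats per random baseline. These sizes exercise every
code path while keeping the default suite fast; the implementation itself
is comfortable up to a few thousand nodes (the similarity matrix is dense,
so memory grows as $n^2$).
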