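---
title: "TopoICSim: model, parameters and design notes"
author: "topoicsim package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TopoICSim: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoicsim)
```

## The model

Each Gene Ontology aspect (biological process, molecular function, cellular
component) is a rooted directed acyclic graph (rDAG): terms are nodes, the
hierarchical relations `is_a` and `part_of` are child-to-parent edges, and
the aspect term itself is the root. Both relations are traversed identically
and unweighted; other GO relation types (`regulates` and friends) are not
hierarchical in the same sense and are dropped at parse time with a count.

**Information content.** Given an annotation corpus with `G_Tot` genes,
`IC(t) = -log(G_t / G_Tot)`, where `G_t` counts genes annotated to `t` *or
to any descendant of `t`* (propagated counts). Under propagation IC is
monotone non-decreasing from root to leaves, the root has IC 0 whenever the
gene universe equals the annotated genes, and a term that annotates no gene
carries the sentinel `+Inf`.

**Path weights.** A path is scored by its *inverse* information content,
`IIC(P) = sum over nodes of 1/IC(t)`: specific (high-IC) nodes contribute
little, generic nodes a lot. The aspect root and any node with IC 0 or
`+Inf` contribute nothing — `1/0` is undefined and `1/Inf` is zero, and
treating an all-genes term like the root keeps sparse corpora usable.
Between a term and one of its ancestors the *shortest* path minimises IIC
(computed with Dijkstra after pushing the node weight `1/IC(v)` onto each
edge into `v`, plus the start node's own contribution); from a term up to
the root the *longest* path maximises IIC (dynamic programming over a
topological order of the ancestor closure). Because IIC alone cannot
separate paths of different lengths with equal weight, each selected path is
weighted by its length in edges: `wSP = IIC x len`, `wLP = IIC x len`.

**Disjunctive common ancestors.** The distance between two terms is not
routed through the single deepest common ancestor but through every
*disjunctive* common ancestor: the minimal elements of the common-ancestor
set under the ancestor partial order (no immediate child of a disjunctive
ancestor is itself a common ancestor). The set-intersection phrasing
sometimes used for this definition is vacuous in an rDAG — a node's children
can never lie on its upward root path — so the package implements the
minimal-element (antichain) reading, which is the only one consistent with
the two-ancestor worked example the packaged fixture reproduces.

**Distance and similarity.** For each disjunctive common ancestor `x`,

```
D(t1, t2, x) = wSP(t1, t2, x) / wLP(x, root)
```

where the combined path runs up from `t1` to the hinge `x` and down to
`t2`; its IIC counts the hinge once and its length is the sum of both edge
counts. This combined-path convention (rather than summing two separately
weighted legs) is what reproduces the reference worked example, whose
numerator has five IIC terms multiplied by 4 = 2 + 2 edges. The term
distance is the minimum of `D(t1, t2, x)` over all disjunctive common
ancestors; identical terms have distance 0, and a pair whose only
disjunctive common ancestor is the root has distance `+Inf` (the root's
`wLP` is 0). Distances map to similarities with
`S = 1 - arctan(D) / (pi/2)`, strictly decreasing, with `S(0) = 1` and
`S(Inf) = 0`.

**Gene level.** For two genes with `n` and `m` annotation terms in one
aspect, the `n x m` term-similarity matrix is aggregated with `rcmax` by
default — the larger of the two directional best-match means — with `avg`
and `bma` available for comparison.

## Comparison measures

Five published gene-level measures are provided for benchmarking:
IntelliGO (IC-weighted term vectors with an LCA-based basis dot product and
cosine similarity), Wang (semantic-contribution profiles with edge factors
0.8/0.6 and best-match averaging), Resnik/Lord (IC of the LCA, averaged over
the annotation grid), Al-Mubaid (`exp(-0.2 x mean shortest path length)`)
and SimGIC (IC-weighted Jaccard over ancestor closures). Two definitions in
the IntelliGO lineage are not fully fixed in the literature we follow, so
they are explicit and configurable rather than claimed faithful: the inverse
annotation frequency is implemented as `log(G_Tot / G_t)` with propagated
counts (the standard IDF analogue, equal to the natural-log IC), and
evidence-code weights default to 1 for every code. Similarly, "lowest common
ancestor" is implemented as the *deepest* common ancestor (longest upward
root path, lexicographic tie-break) and reused across IntelliGO, Resnik and
Lord; a `max_ic` switch selects the maximum-IC ancestor semantics where
those differ.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `log_base` | `e` | IC logarithm base; rescales IC and hence IIC ratios |
| `propagate` | `TRUE` | count genes for all ancestors of annotated terms |
| `aggregator` | `rcmax` | gene-level matrix aggregation (`rcmax`/`avg`/`bma`) |
| `evidence` | all codes | GAF evidence-code filter; weighting is uniform |
| `w_is_a`, `w_part_of` | 0.8 / 0.6 | Wang semantic contribution factors |
| `alpha` | 0.2 | Al-Mubaid distance-to-similarity decay |
| `min_group_corr` | 0.5 | grouped-correlation admission threshold |

## Numerical choices

* Path selection is fully deterministic: IIC first (tolerance `1e-9`), then
  length (shorter for shortest paths, longer for longest paths), then the
  lexicographic node sequence. The distance minimisation over disjunctive
  ancestors tie-breaks toward the smaller combined weighted shortest path
  and then the lexicographically smaller ancestor id. All term orderings use
  radix (C-locale) sorting so results do not depend on the session locale.
* `D = 0/0` cannot arise: identical terms short-circuit to distance 0 before
  any ratio is formed, and a root hinge returns `+Inf` explicitly.
* Negative empirical `dcov^2` (floating error near independence) is clamped
  to 0 before square roots; `dcor` is defined as 0 when either marginal
  `dcov^2` is 0. Spearman p-values come from `stats::cor.test` (exact for
  small samples without ties, asymptotic otherwise).
* The IntraSet mean deliberately includes self-pairs (denominator `n^2`).
  This gives the discriminating power of identically distributed sets an
  upward bias of order `(1 - mu) / (n mu)` for sets of size `n` and mean
  similarity `mu`, which vanishes as sets grow; the acceptance suite tests
  DP near 1 on sets of 12 genes.

## Synthetic data: what it emulates and what it does not

The package is fully testable offline through three generators and one
fixed fixture.

* `metabolism_fixture()` is a stylized 11-term fragment of the BP
  metabolic-process neighbourhood. Its exact topology is the minimal DAG
  consistent with the reference path structure it reproduces: a unique
  combined path through GO:0071704 and alternative legs on both sides of the
  GO:0044237 branch so that IIC-based selection is exercised. Its IC values
  are injected reference values (3 decimals), not computed from any
  annotation release, and the tabulated candidate distances (2.75 and 1.076)
  it carries are used at their printed precision as regression anchors for
  branch selection and the arctan mapping. Recomputing those candidates from
  the 3-decimal ICs yields 3.554 and 1.091 — the second consistent with
  rounding of the tabulated inputs, the first not reproducible from the
  printed values by the stated formulas — so the formula-level behaviour is
  anchored by exhaustive-enumeration oracles instead.
* `random_rdag()` grows single-root DAGs by giving node `i` 1..3 parents
  among earlier nodes (80% `is_a`, 20% `part_of`); `random_corpus()`
  annotates synthetic genes to 1..10 uniform terms. Both are pure functions
  of their seed. Real GO is far larger, deeper and scale-free-ish, and real
  annotation counts are heavy-tailed; passing tests therefore demonstrate
  *algorithmic correctness* (agreement with exhaustive enumeration,
  symmetry, boundedness, determinism), not biological performance on a GO
  release.
* `correlated_pairs()` draws clustered bivariate Gaussians with a target
  within-cluster correlation to validate grouped-correlation recovery.

Problem sizes in the test and acceptance suites were chosen as the smallest
that exercise every code path with exhaustive oracles: 500 random DAGs of
5-12 terms (where full path enumeration is tractable) for the equivalence
suites, 200-term graphs with 100 pairs per group size for the
annotation-length-bias audit, and n = 2000 for correlation recovery.

## Design decisions in the open

* The published evaluation pipeline grouped (expression, annotation)
  similarity pairs with a 6x6 self-organising map. A SOM is stochastic and
  package-specific while the statistic of interest — the mean within-group
  correlation over groups passing the 0.5 threshold — is not tied to it, so
  `grouped_correlation()` uses deterministic quantile bins or a fixed 2-D
  grid, and accepts an arbitrary grouping function so a SOM (or the true
  cluster labels) can be injected.
* The annotation-length-bias audit on a real GO corpus is release-dependent;
  it is exercised here on synthetic graphs at reduced scale, checking that
  the Spearman statistic is finite and seed-stable rather than asserting any
  particular value.
* Batch interfaces fail loudly on genes without usable annotations; silent
  zeros would bias IntraSet statistics. A `skip` policy is available for
  pipelines and logs what it drops.

## Known limitations

* No OWL parsing, no `consider`/`replaced_by` remapping, no live GO
  downloads; the OBO reader covers the stanza subset GO releases use.
* Lin, Jiang and the CESSM variant measures are not implemented.
* IC has no corpus-free fallback; an annotation corpus (or an externally
  computed IC table) is required.
* Gene-level similarity is quadratic in annotation counts; memoisation
  caches term pairs per session but no persistent cache is provided.

## A worked call

```{r example}
fx <- metabolism_fixture()
disjunctive_common_ancestors(fx$graph, fx$leaves[1], fx$leaves[2])
term_similarity(fx$graph, fx$ic, fx$leaves[1], fx$leaves[2])[
  c("distance", "similarity", "ancestor")]
```
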