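---
title: "Node-based resilience clustering: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-based resilience clustering: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbrclust)
```

## The model

`nbrclust` clusters a numeric feature table by treating it as a graph
vulnerability problem.  Samples become the vertices of a k-nearest-neighbour
graph; an *attack set* $S \subset V$ is a set of vertices whose removal
disconnects the graph, and a good clustering corresponds to a *cheap,
damaging* attack: few removed nodes, many well-separated surviving
components.  Three node-based resilience measures formalise "cheap and
damaging", each as a minimum over attack sets:

* **Vertex attack tolerance (VAT)**
  $\tau(G) = \min_{S \neq \emptyset} |S| \,/\, (|V - S - C_{max}(V-S)| + 1)$,
  where $C_{max}(V-S)$ is the largest surviving connected component.  Small
  values mean a small attack strands many nodes outside the main component.
* **Normalized integrity**
  $I(G) = \min_S (|S| + C_{max}(V-S)) / |V|$, penalising attacks that leave
  only small components.
* **Tenacity**
  $T(G) = \min_S (|S| + C_{max}(V-S)) / \omega(V-S)$, where $\omega$ counts
  surviving components; it rewards attacks that shatter the graph into many
  pieces, and in practice tends to over-segment, which makes it useful as an
  upper bound on the cluster count.

The minimisation is NP-hard in general, so the package uses the
**Greedy-BC** heuristic: repeatedly remove the vertex with the highest
weighted betweenness centrality (recomputed after every removal), score
every removal prefix $S_1 \subset S_2 \subset \dots$ with the chosen
measure, and keep the best prefix.  On graphs of up to 15 nodes
`exact_resilience()` enumerates every subset and serves as the optimum the
heuristic is tested against: greedy is an upper bound on the true minimum,
and the test suite asserts this dominance on hundreds of random graphs.
The heuristic is not exact in general — on a 5-node path the tenacity
optimum needs the alternating attack set, which no betweenness-ordered
prefix contains — but it agrees with the exhaustive optimum on stars,
short paths, and bridged cliques, and those equalities are frozen as tests.

The full pipeline (`nbr_clust()`) is: build the graph, minimise a measure,
take surviving components as base clusters, optionally fold the attack set
back in, and merge or split to a requested cluster count $k$.

## Graph construction

Points are connected by a symmetrized kNN graph with Euclidean edge weights
computed after normalising every feature to $[0, 1]$.  Symmetrization is by
union (an edge exists if either endpoint lists the other among its $k$
nearest), which preserves the connectivity behaviour the pipeline relies on;
mutual-kNN is available via `mode = "mutual"` but does not guarantee a
connected graph at the same $k$.  The central parameter is the *minimal
connectivity* $k$ (`min_connectivity()`): the smallest $k$ whose graph is
connected.  Because edge sets are nested in $k$, connectivity is monotone
and the search is a binary search.  The canonical experiment uses six base
graphs: \{full feature set, correlation-filtered set\} × \{min-conn,
min-conn+1, min-conn+2\}, labelled kNN2/kNN3/kNN4.

Distance ties are broken by node index everywhere (neighbour lists, maximum
betweenness, merge scores), so a given input always produces the same
graph, attack set, and labelling.  Duplicate points are allowed and create
zero-weight edges; since shortest-path counting needs positive lengths,
betweenness computations floor weights at $10^{-12}$.

## Preprocessing

`impute_mean()` fills gaps with the column mean; `impute_regression()` fits
an ordinary least-squares model of each target feature on all other
features (rows with the target observed; predictor gaps mean-imputed for
the fit only) and clips predictions to the feature's known score range when
one is supplied.  A rank-deficient design falls back to mean imputation
with a warning.  `normalize_features()` uses known score ranges when given
and the observed range otherwise, with a message so runs are auditable.
`correlation_filter()` removes one member of the most-correlated pair
(the one with larger mean absolute correlation to the remaining features;
ties drop the later column) until no pair exceeds the threshold, 0.8 by
default.  Zero-variance columns have undefined correlations; these are
treated as 0 so constant features are never removed on that account.

## Cluster formation and adjustment

Surviving components become clusters with contiguous ids from 0.  In
`reassigned` mode every attack node is folded back by **iterated neighbour
plurality**: in rounds, each unassigned node adjacent to a labelled node
joins the cluster holding the plurality of its labelled neighbours, ties
preferring the larger cluster and then the lower cluster id.  This is
local, graph-respecting, and deterministic; a nearest-centroid variant was
considered and rejected because it ignores the graph topology the attack
was computed on.  In `no_reassignment` mode the attack set stays unassigned
as candidate outliers.  A caveat worth knowing: when two balanced clusters
are bridged by hub-like attack nodes adjacent to *all* nodes of both, the
plurality ties and the tie-break decides — correct by construction, but on
tiny balanced fixtures it can cost a node or two of agreement with planted
labels.

With more clusters than requested, pairs maximising the normalized-cut
score $E(C_1, C_2)/(|C_1|\,|C_2|)$ are merged (ties: lexicographically
smallest id pair).  With fewer, the cluster whose induced subgraph has the
*lowest* greedy resilience value is divided by re-running the attack inside
it; reassignment happens inside the subgraph before the next split
(reassign-then-adjust, recorded in provenance).  Clusters smaller than 3
nodes cannot split.  If no greedy prefix disconnects a cluster (complete
subgraphs are the canonical case), it is dissolved into singletons so each
split step strictly increases $k$; the adjustment trace records this as a
`dissolve`.

## Validation and selection

Nine internal validation indices score each configuration on the point
geometry: silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn, Xie–Beni,
SD, S\_Dbw, I, and CVNN.  The conventions that the formulas leave open are
fixed as follows:

* $\sigma(\cdot)$ in Scat is the per-dimension *population variance*
  vector, and $\|\sigma\|$ is the Euclidean norm of that vector.
* The S\_Dbw density radius is the mean cluster variance-vector norm; a
  point is "dense" at a midpoint $u_{ij}$ if it lies within that radius.
* The I index exponent defaults to $p = 2$; CVNN's neighbour count defaults
  to $NN = 10$ (both settable via `index_params()`).
* CVNN's compactness sums over clusters without dividing by $k$, exactly as
  its printed form.
* Singleton clusters contribute silhouette 0, and CVNN compactness 0.
* SD and CVNN are only meaningful relative to a family of compared
  configurations; `run_grid()` re-normalises them per (graph, measure,
  mode) family using the largest-$k$ `Dis` value and the family maxima of
  the raw separation/compactness terms.

Two graph-quality gates accompany the indices: Newman modularity of the
partition (threshold $\geq 0.6$) and the worst-cluster conductance — the
fraction of *all* graph edges with exactly one endpoint in the cluster
(threshold $\leq 0.07$).  Conductance aggregation across clusters is not
dictated by its definition; the maximum is used as the conservative gate,
with the mean also reported.  Unassigned attack nodes are excluded from
both edge tallies.  Configurations whose smallest cluster falls below a
size floor are discarded before voting; the floor is expressed as a
fraction of the sample (10/2680 by default) so it scales with dataset size.
Each index then casts one vote for the best admissible configuration in its
optimal direction, and configurations are ranked by votes, admissibility,
and silhouette.  The two attack-set modes are ranked separately because
they answer different questions (complete clustering versus
outlier-excluding clustering).

## The synthetic benchmark

`gaussian_mixture_table()` emulates the regime the method targets:
isotropic unit-variance Gaussian clusters with centres at least
`separation` standard deviations apart (default 8, a clearly separated
regime), optional uniform outliers standing in for erroneous records,
near-duplicate feature pairs for the correlation filter, and random
missingness.  `phenotype_like_table()` produces a 500 × 36 table shaped
like a multi-instrument phenotype battery: four graded severity subgroups
loading on every instrument, three engineered near-duplicates so the 0.8
correlation filter removes exactly three features, and ~0.1% missing cells
concentrated in two designated columns (the intended regression-imputation
targets).  Both generators are pure functions of their parameters and seed.

What these fixtures do **not** emulate: skewed cluster sizes, discrete and
bounded instrument scales with floor/ceiling effects, non-isotropic or
correlated within-cluster noise, and missingness that depends on severity.
Passing the recovery benchmarks therefore demonstrates correctness of the
machinery in the separable regime, not clinical validity on real phenotype
data.

Benchmark sizes were chosen to exercise the pipeline at meaningful scale
while keeping a full run cheap: recovery and selection use $n = 400$,
$d = 5$, four planted clusters at $8\sigma$, three seeded replicates over
$k \in \{2,\dots,5\}$, three measures, and both modes; greedy evaluations
are cached per (graph, measure), so varying $k$ and mode reuses one attack
search.  The oracle-equivalence property uses ~200 random connected graphs
of 6–10 nodes, where exhaustive enumeration is still exact.

## Known limitations

* Greedy-BC recomputes weighted betweenness after every removal; the
  default budget of $|V| - 2$ removals makes a full run $O(|V|^2 |E|)$ in
  the worst case, which is comfortable into the low thousands of nodes but
  not beyond.
* Tenacity's optimum can require attack sets no betweenness prefix
  contains (see the path example above); all three measures inherit the
  heuristic's upper-bound character.
* The modularity gate ($\geq 0.6$) is mathematically unreachable for
  balanced 2-cluster partitions (maximum 0.5), so $k = 2$ configurations
  can only win on votes, never on admissibility.
* Overlapping clusters and soft assignments are out of scope; the attack
  set is the only outlier construct.
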