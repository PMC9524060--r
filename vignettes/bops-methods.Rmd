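---
title: "Predicting small protein complexes by balanced-weight network segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting small protein complexes by balanced-weight network segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bops)
```

## The problem

Protein complexes — stable multi-subunit molecular machines — appear in a
protein–protein interaction network (PPIN) as cohesive vertex subsets.
Density-based clustering methods find the large ones readily, but small
complexes (ten subunits or fewer, which dominate curated catalogues such as
CYC2008) are easily absorbed into larger clusters or discarded as noise.
`bops` takes the opposite route: instead of growing clusters, it **cuts the
network into pieces small enough that every candidate can be examined
exhaustively**, then scores candidates by an explicit cohesion statistic and
keeps the most cohesive, mutually dissimilar ones.

The pipeline has three stages, each exposed as ordinary functions on tibbles
so the pieces can be used and inspected independently.

## Stage 1: balanced weights

Interaction confidences $w_e \in (0, 1]$ are rescaled before any cutting.
For an edge $e = (x, y, w_e)$, with $s_x$ the *strength* (weighted degree)
of endpoint $x$ in the original network,

$$bw_e = \frac{1}{2}\left(\frac{w_e^\beta}{s_x^{\beta-1}} +
  \frac{w_e^\beta}{s_y^{\beta-1}}\right).$$

The motivation is the core–attachment organisation of complexes: a core
protein accumulates strength from many strong interactions, an attachment
touches the network lightly. Dividing by endpoint strength means an edge
incident to a low-strength (peripheral) vertex is dampened least relative to
its neighbourhood, so attachment edges stay comparatively important while
hub–hub edges are discounted. Three identities pin the formula down and are
enforced by tests:

* $\beta = 1$ leaves every weight bit-identical;
* for $\beta \ge 1$, $bw_e \le w_e$ always, because each endpoint strength
  is at least $w_e$ (the dampening never inflates a weight — the rescaling
  is *relative*, changing the ranking of edges, not their scale);
* scaling all weights by $c > 0$ scales all balanced weights by $c$.

**Parameter.** $\beta$ (unitless, default **1.5**, sensible range 1.0–2.0).
Higher values push the weights further toward the topology-derived signal;
1.0 switches the stage off. Networks whose weights are already very
homogeneous benefit from larger $\beta$ (more spread for the cutter to work
with); noisy, high-variance weights argue for smaller values.

## Stage 2: minimum-bottleneck segmentation

The graph is split recursively until every piece has at most `maxp`
proteins. Each split is a **minimum-bottleneck cut**: among all bipartitions
of the piece, one minimising the *largest* deleted balanced weight,

$$\mathrm{cost} = \max \{ bw_e : e \text{ deleted} \}.$$

The optimum is found without search: delete all edges, sort them by balanced
weight descending, and re-insert them into a disjoint-set union. The first
edge whose insertion would reconnect the whole piece is the bottleneck; the
two components standing just before that insertion are the sides. This is
the classic maximum-spanning-forest argument — every bipartition must cut
some edge on the heaviest path between the two sides — and the exhaustive
oracle over all $2^{|V|-1}-1$ bipartitions confirms optimality on hundreds
of random graphs in the test suite.

A FIFO queue seeded with the connected components drives the recursion:
pop, emit if small enough, otherwise split and push both sides. Isolated
vertices ride along as singleton parts (they can never form a candidate of
size ≥ 2, but dropping them would silently change the vertex universe).

**Parameter.** `maxp` (proteins, default **20**). The enumeration stage
costs $O(2^{\texttt{maxp}})$ per part, so the default is a deliberate
compromise: big enough that a size-10 complex survives segmentation with
room to spare, small enough that exhaustive enumeration stays cheap. Values
above 25 trigger a warning; the mask representation caps parts at 31.

**Tie-breaking.** Equal balanced weights are ordered by the canonical
(lexicographic) edge key, so runs are deterministic; any tie order yields an
optimal-cost cut, but reproducibility demands one fixed choice.

## Stage 3: exhaustive candidates, cohesion, dedup

Every connected vertex subset of every part with size in
`[min_size, max_size]` (defaults 2–10) is enumerated exactly once by the
standard anchored scheme (grow only with never-seen neighbours; anchors in
lexicographic order). Each subset $S$ is scored on its induced subgraph with
balanced weights:

$$\mathrm{Cohesion}(S) = \frac{1}{|S|}\sum_{x \in S}
   s_x \cdot \frac{c_x + 1}{|S|},$$

with $s_x$, $c_x$ the within-$S$ strength and degree ($+1$ counts the
protein itself). The first factor rewards strong interaction, the second
rewards interacting with most of the set; in a uniform-weight clique the
score reduces to $(k-1) \cdot bw$, strictly increasing in clique size, which
is why a full planted clique outranks all of its sub-cliques.

Candidates are then sorted by cohesion (descending, ties on the canonical
member key) and scanned: a candidate is deleted when its neighbourhood
affinity $\mathrm{NA}(p, q) = |p \cap q|^2 / (|p||q|)$ to **any more
cohesive candidate — kept or already deleted —** reaches `sim_threshold`.
The chainwise rule matters: a two-protein set straddling a weak bridge is
dissimilar to every *kept* complex, but it is similar to a slightly larger
bridge-straddling set of higher cohesion, which in turn is similar to a yet
larger one, and the chain terminates in a genuine complex. Comparing only
against kept survivors would leave such fragments in the output; comparing
against all higher-ranked candidates removes them, and the survivors are
still pairwise dissimilar. Finally the most cohesive
`keep_fraction` (default 0.5, applied as $\lceil n \cdot f\rceil$ so a
non-empty ranking never empties) of the survivors is reported.

Because parts are vertex-disjoint, affinity between candidates from
different parts is identically zero, so deduplication is run per part and
the survivors re-ranked globally — an exact decomposition, verified in the
tests against the single global scan.

**Parameters.** `sim_threshold` (NA units, default **0.25**, the
conventional complex-matching threshold) and `keep_fraction` (default
**0.5**). `min_size` ≥ 2 because a one-protein "complex" is meaningless;
`max_size` defaults to 10, the small-complex regime, and may be raised to
`maxp` for an all-sizes run.

## Evaluation metrics

`evaluate_complexes()` implements the standard suite. With $N_{cp}$ /
$N_{cb}$ the numbers of predictions / references matched at
$\mathrm{NA} \ge \omega$ (inclusive, $\omega = 0.25$ by default):
precision $= N_{cp}/|P|$, recall $= N_{cb}/|B|$, F-score their harmonic
mean. Sn, PPV and ACC $= \sqrt{\mathrm{Sn}\cdot\mathrm{PPV}}$ are built from
the protein-overlap matrix $T_{pb} = |V_p \cap V_b|$. MMR is the total
weight of a maximum-weight bipartite matching between predictions and
references (edges where $\mathrm{NA} \ge \omega$), divided by $|B|$ — a
reference split across several predictions can collect credit from only one
of them. The matching is solved by igraph's weighted bipartite matcher and
cross-checked against a brute-force matcher on small instances.

Segmentation quality is measured separately by the **expected regression
ratio**: a reference $b$ is *recallable* from a vertex set $s$ when the
regression degree $|s \cap b|/|b|$ reaches $\delta$ (default 0.25), and ERR
is the fraction of network-recallable references still recallable from some
part. An un-cut network has ERR 1 by construction. The random baseline
(`random_segmentation()`) shuffles vertices into parts of the same sizes,
ignoring topology.

`min_p_value()` scores a complex's functional homogeneity as the smallest
hypergeometric upper-tail probability over annotation groups,
$P = 1 - \sum_{i=0}^{k-1}\binom{|F|}{i}\binom{|V|-|F|}{|C|-i}/\binom{|V|}{|C|}$,
evaluated via `phyper()` (log-space internally) and verified against
exhaustive draw enumeration for all universes up to 12. Raw minimum
p-values are reported; multiple-testing correction and GO-DAG term
propagation are out of scope.

## The synthetic generator

Real benchmark maps (Krogan, Gavin, Collins and their kin) are a few
thousand proteins with edge density around 0.002–0.007 and mean edge weight
0.36–0.78. `generate_planted_ppin()` emulates that regime so the whole
pipeline is testable offline: vertex-disjoint complexes of size 3–10 get
intra-complex edges at rate `p_in = 0.9` with Beta-distributed weights of
mean 0.8; all other pairs get background edges at rate 0.002 with mean 0.2
(Beta draws, concentration 10). The defaults (30 complexes, 400 background
proteins) land total density near 0.005. Each complex is resampled until
connected (up to 50 tries, then force-connected with a warning). A
`core_attachment` mode instead wires a fully connected core of
$\lceil s/2 \rceil$ proteins with attachments hanging off 1–2 core members
at background strength. All draws flow from one integer seed through a
private RNG stream, so outputs are byte-reproducible and the session RNG is
untouched.

What the generator deliberately does **not** model: overlapping complexes,
weight variance structure beyond a fixed concentration, degree
heterogeneity (hubs), and experiment-specific noise such as spoke/matrix
artefacts of AP-MS data. Passing tests on planted networks therefore
demonstrate algorithmic correctness and the direction of effects (e.g.
bottleneck cuts preserve complexes far better than random cuts), not
field performance on any particular experimental map.

## Numerical and degenerate-input choices

* Duplicate edges keep the maximum weight; self-loops are dropped but their
  vertex kept; weights must be positive (values above 1 are allowed — every
  formula is well-defined, and scale equivariance makes the choice moot).
* Empty networks, edgeless parts, empty complex sets and unannotated
  complexes all produce well-typed empty/`NA` results rather than errors;
  genuinely contradictory requests (splitting a disconnected piece,
  ERR with no recallable reference) raise typed errors.
* All string ordering uses C collation (`method = "radix"`), so output
  files are byte-identical across locales.
* Problem sizes in the tests — 200 oracle graphs of up to 12 vertices,
  planted networks of ~600 proteins, ten ERR seeds — were chosen so the
  whole suite exercises every code path in a few minutes on one core while
  keeping the brute-force oracles exact.

## Known limitations

* Complexes are non-overlapping by construction of the dedup stage; two
  complexes sharing most of a core cannot both be reported at the default
  threshold.
* Segmentation is irreversible: a complex cut across parts (ERR < 1) is
  unrecoverable downstream, which is exactly why ERR is reported as a
  diagnostic.
* Parts are capped at 31 vertices by the mask representation; `maxp` above
  25 is already impractical ($2^{\texttt{maxp}}$ candidates).
* The hypergeometric enrichment treats the annotation table as flat; no
  ontology structure is used.

## A worked run

```{r example}
fix <- generate_clique_fixture(c(3, 4, 5), bridge_weight = 0.05)
res <- run_bops(fix$network, keep_fraction = 1)
glance(res)
evaluate_complexes(res, fix$complexes)
```

The three bridged cliques come back exactly — every headline metric is 1 —
while all sub-cliques and bridge-straddling fragments are removed by the
chainwise dedup.
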