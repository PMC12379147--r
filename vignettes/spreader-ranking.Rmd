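---
title: "Ranking influential spreaders with entropy, degree and distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential spreaders with entropy, degree and distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadrank)
```

## The problem and the model

Given an undirected, unweighted network, which single node should seed a
spreading process to reach the most of the network? The operational ground
truth is the SIR epidemic model: seed one infected node, let infection travel
edges with probability $\beta$ per contact per step, let infected nodes
recover (permanently) with probability $\lambda$ per step, and record the
final number of ever-infected nodes. A node's *spreading ability* is the mean
of that outbreak size over many Monte-Carlo runs. Running SIR for every node
is expensive, so structural *centralities* are used as cheap predictors, and
their quality is judged by rank correlation with the SIR ranking.

The centrality this package is built around combines three signals:

$$EDDC(v) \;=\; \frac{\deg(v)}{N}\sum_{j \ne v}
  \frac{\sqrt{e(v) + e(j)}}{dist(v,j)},$$

with $e(v)$ the base-2 Shannon entropy of the node's neighbour-degree
distribution, $p(u) = \deg(u) / \sum_{k \in \Gamma(v)} \deg(k)$ for
$u \in \Gamma(v)$. Degree captures local connectivity; entropy distinguishes
nodes of equal degree by how evenly importance is spread over their
neighbours (a node whose neighbours all have the same degree has maximal
entropy $\log_2 \deg(v)$; a node dominated by one hub neighbour has low
entropy); the inverse hop distance makes nearby diversity count more than
remote diversity. The square root is deliberate: a linear sum $e(v)+e(j)$
would let high-entropy clusters dominate, while the radical grows
sublinearly and keeps rankings balanced on heterogeneous-degree networks.

### Conventions for degenerate inputs

* Degree-0 and degree-1 nodes have entropy 0 (empty sum / point mass).
* Unreachable pairs contribute 0 to every distance sum ($1/\infty = 0$);
  distances use an explicit `Inf` sentinel, never a large magic number.
* Isolated nodes score 0 in every distance-sum centrality, and closeness
  normalises by $N-1$ even on disconnected graphs (a per-component
  normalisation is available as an option).
* The local clustering coefficient of degree-$\le 1$ nodes is 0 (the
  denominator of the defining ratio vanishes).

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| $\beta$ | `sir_config()` | — | infection probability per infected–susceptible contact per step |
| $\lambda$ | `sir_config()` | 1 | recovery probability per step; 1 means each node transmits for exactly one step |
| `runs` | `sir_config()` | 1000 | Monte-Carlo repetitions per seed node |
| $\delta$ | `isolating_centrality()` | 2 | neighbour-degree threshold of ISC |
| `max_hops` | distance-sum measures | `Inf` | optional BFS cutoff; trades exactness for speed on large graphs |
| `n_steps`, `step` | `beta_grid()` | 15, 0.01 | evaluation grid $\beta_{th} + 0.01\,i$ above the epidemic threshold |
| `digits` | `monotonicity()` | 10 | rounding before tie counting, so float noise cannot fake uniqueness |

The evaluation grid is anchored at the heterogeneous mean-field threshold
$\beta_{th} = \langle k\rangle / (\langle k^2\rangle - \langle k\rangle)$:
below it outbreaks die out and every ranking looks alike; just above it is
where methods separate. `epidemic_threshold()` computes it from the degree
moments and refuses graphs where the denominator is non-positive (e.g. a
perfect matching), where no epidemic regime exists.

### Decisions taken where the definitions were open

* **ISC threshold set.** The isolating-centrality definition does not pin
  down the threshold set; this package uses
  $\mathrm{Deg}_\delta = \{u : \deg(u) \ge \delta\}$, so a hub whose
  neighbours are all below the threshold scores 0 — matching the measure's
  motivation that a high-degree node is not influential if its neighbours
  are weak. The predicate is isolated in one place in the code so the
  convention can be swapped.
* **Kendall correlation is tau-a**, $(N_c - N_d)/\binom{n}{2}$, with tied
  pairs counting in neither term. SIR mean outbreak sizes tie often and the
  untied denominator deliberately penalises uninformative (heavily tied)
  rankings; the tie-corrected tau-b is available behind `variant = "b"`.
  Correlations are computed between score vectors aligned on node identity,
  not between rank positions.
* **Performance gain** merges the printed positive/negative branches into
  $\eta = (\tau_C - \tau_\phi)/|\tau_\phi| \times 100$ (0 when the baseline
  tau is 0); in `evaluate_methods()` it is evaluated on the grid means.
* **Tie-break in rankings** is ascending node label (numeric when all
  labels are numeric), making top-k tables reproducible byte for byte.
* **SIR update order**: infections are computed from the infected set at
  the start of a step, then that set recovers. With $\lambda = 1$ the
  process is equivalent to directed bond percolation with one uniform per
  directed edge, which the simulator exposes (`contact_uniforms`) to allow
  exact monotone coupling across $\beta$ — the basis of a property test.
* **RNG discipline**: `spreading_ability()` derives one substream per node
  from the master seed, so adding nodes to a study never perturbs the
  streams of existing nodes, and every result is bit-reproducible from the
  seed. Shortest paths use plain BFS: on unweighted graphs it is the exact
  specialisation of heap-based Dijkstra.

## The synthetic generators, and what tests on them show

Experiments need graphs with controlled structure, generated in code:

* `erdos_renyi(n, p)` — homogeneous baseline; also the null model of the
  small-world diagnostic `small_world_report()`, which averages path length
  and clustering over density-matched draws and reports whether
  $L_{actual} \ge L_{random}$ and $CLC_{actual} \ge CLC_{random}$.
* `barabasi_albert(n, m)` — heavy-tailed degrees; node $i$ attaches
  $\min(m, i-1)$ edges, so the edge count is $m(n-m) + m(m-1)/2$.
* `watts_strogatz(n, k, p)` — small-world regime between lattice and random.
* `toy_network()` — the packaged 16-node, 21-edge demonstration network.
  Its edge list was never published; the packaged graph was *derived* from
  the published local facts (node 2's neighbourhood and neighbour degrees,
  all hop distances from node 2, and all 16 entropy values). Those facts
  pin the degree sequence exactly — the entropy values force per-node
  minimum degrees whose sum already equals $2E = 42$ — and a backtracking
  search over the distance-layer structure (shipped as
  `inst/scripts/toy_network_search.R`) shows the solution is unique. The
  reconstruction reproduces every published distance exactly and every
  published entropy within $10^{-3}$.

Synthetic graphs emulate degree heterogeneity, clustering and small-world
distances, but not the community structure, degree correlations or temporal
activity of real contact networks. Green tests on them certify the
*implementation* (formulas, conventions, reproducibility) and the
qualitative behaviour (EDDC correlating positively with SIR above
threshold); they do not certify that EDDC wins on any particular real
network, which should be checked per network with `evaluate_methods()` on a
user-supplied edge list.

## Numerical choices and problem sizes

Test and validation workloads are sized to run comfortably on one CPU:
oracle-equivalence checks compare every centrality against brute-force
reimplementations (Floyd–Warshall distances, exhaustive path enumeration for
betweenness on graphs of $\le 7$ nodes and a pair-DP oracle up to 30 nodes,
naive peeling for K-shell) at tolerance $10^{-9}$ on 100+ random graphs; SIR
analytic checks use $K_2$, where the mean outbreak size is exactly
$1 + \beta$, at 20000 runs (3 Monte-Carlo standard errors); the
EDDC-versus-SIR correlation check uses Barabási–Albert graphs of 200 nodes
at $\beta = 2\beta_{th}$ with 500 runs per node. The SIR simulator is
vectorised over the infection frontier (flattened adjacency, one uniform per
contact), which makes these budgets cheap; `max_hops` exists for graphs
orders of magnitude larger, where truncating the BFS frontier at 2–3 hops
preserves most of the ranking signal at a fraction of the cost.

One published worked-example value deserves a note: the step-by-step EDDC
illustration for toy node 2 prints a total (13.265) that is not consistent
with the formula it illustrates — evaluating the printed 15-term bracket
gives 13.013, and applying the $\deg/N = 4/16$ prefactor gives 3.253. This
package follows the formula literally; the test suite pins the aggregation
against an independent high-precision recomputation of the printed
expression rather than the printed total.

## Known limitations

* Undirected, unweighted graphs only; directed input edges are symmetrised.
* Exact EDDC needs all-pairs BFS, $O(N(N+E))$ time and $O(N^2)$ memory as
  implemented, fine up to a few thousand nodes; beyond that use `max_hops`.
* Kendall tau-a is computed by an $O(n^2)$ pair scan (blocked to keep memory
  linear), adequate for networks up to ~10^4 nodes.
* SIR here is synchronous discrete-time; continuous-time (Gillespie)
  dynamics, SIS/SEIR variants and interventions are out of scope.
* Monotonicity depends on the documented rounding rule; scores differing
  only past the 10th decimal count as ties.
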