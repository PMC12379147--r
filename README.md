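# spreadrank

Identifying the nodes that make the best *spreaders* — the seeds from which
an epidemic, rumour, or piece of information reaches the largest part of a
network — is a core problem in network science and systems biology. Degree
counts only immediate contacts; betweenness and closeness see global
structure but miss how *diverse* a node's neighbourhood is. `spreadrank`
implements the **Entropy Degree Distance Combination (EDDC)** centrality,
which fuses all three signals:

```
EDDC(v) = (deg(v) / N) * Σ_{j ≠ v}  sqrt(e(v) + e(j)) / dist(v, j)
```

where `e(v)` is the base-2 Shannon entropy of the distribution obtained by
normalising the degrees of `v`'s neighbours,

```
e(v) = − Σ_{u ∈ Γ(v)} p(u) log2 p(u),      p(u) = deg(u) / Σ_{k ∈ Γ(v)} deg(k),
```

`dist(v, j)` is the shortest-path (hop) distance, and `N` the node count.
The square root makes joint entropy contributions grow sublinearly so dense
high-entropy clusters cannot dominate the ranking; inverse-distance
weighting decays influence with network distance.

The package is aimed at anyone who needs to rank nodes by spreading ability
and to *validate* that ranking: alongside EDDC it ships

* the eight standard baselines — degree, betweenness, closeness, local
  clustering, isolating centrality (ISC), local-and-global centrality (LGC),
  K-shell, CLGC and ECLGC;
* a discrete-time Monte-Carlo **SIR** simulator giving each node's ground-truth
  spreading ability (mean final outbreak size over repeated epidemics seeded
  at that node), plus the heterogeneous mean-field epidemic threshold
  `β_th = <k> / (<k²> − <k>)`;
* ranking-evaluation metrics: Kendall **tau-a** against the SIR ranking,
  its mean over a β grid anchored just above the threshold, the
  **monotonicity** index of ranking uniqueness, the percentage
  **performance gain** η of one method over another, and top-k overlap
  tables;
* seeded Erdős–Rényi, Barabási–Albert and Watts–Strogatz generators, a
  small-world diagnostic, and a reader for the edge-list files distributed
  by networkrepository.com and sociopatterns.org.

## Worked example

The packaged 16-node toy network demonstrates the whole computation. Node 2
has neighbours {1, 3, 4, 5} with degrees (1, 3, 1, 4):

```r
library(spreadrank)
g <- toy_network()

neighbor_probabilities(g, 2)
#>         1         3         4         5
#> 0.1111111 0.3333333 0.1111111 0.4444444

node_entropy(g, 2)
#> [1] 1.752715
```

The degree-4 neighbour carries 4/9 ≈ 0.444 of the probability mass, and the
resulting neighbour-degree entropy of node 2 is 1.753 bits (a degree-1 node
such as node 1 has entropy exactly 0 — a point-mass distribution carries no
information). Ranking all nodes by EDDC:

```r
head(rank_nodes(eddc(g)))
#>   rank node    score
#> 1    1    6 3.868864
#> 2    2    8 3.613208
#> 3    3    5 3.580703
#> 4    4    9 3.486252
#> 5    5    2 3.253879
#> 6    6   11 3.224706
```

Node 6 tops the list: it is a degree-4 node whose neighbours have diverse
degrees and which sits close to everything else. Validating rankings against
SIR ground truth:

```r
cfg <- sir_config(beta = 0.25, runs = 200, seed = 42)
evaluate_methods(g, c("dc", "bc", "kshell", "eddc"), cfg, grid = c(0.2, 0.25, 0.3))
#> eval_report: 16 nodes, 21 edges; 3 beta grid points; 200 SIR runs/node
#> sigma(tau):
#>     dc     bc kshell   eddc
#> 0.7083 0.5278 0.5000 0.8083
#> monotonicity:
#>     dc     bc kshell   eddc
#> 0.5751 0.7656 0.2500 0.9834
#> gain of eddc (%):
#>     dc     bc kshell
#>  14.12  53.16  61.67
```

`sigma(tau)` is the grid-mean Kendall correlation with the SIR spreading
ranking (higher = closer to ground truth), `monotonicity` how uniquely each
method scores nodes (EDDC separates almost all 16; K-shell collapses them
into two shells), and the gain row the percentage improvement of EDDC's
`sigma(tau)` over each baseline.

The same pipeline is scriptable from a shell via `exec/spreadrank` with
subcommands `rank`, `sir`, `evaluate`, `generate` and `benchmark`, e.g.

```sh
Rscript exec/spreadrank evaluate --generator 'er,n=200,p=0.05' \
    --methods dc,cc,eddc --runs 500 --seed 7 --output-dir results/
```

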