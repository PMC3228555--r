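# netgem

Time-varying interaction strengths on a known gene-interaction network,
inferred from short expression time series.

## The problem

Temporal expression experiments typically measure a handful of time points,
far too few to model every gene--gene interaction independently. `netgem`
treats the interaction network $G=(V,E)$ as known, models each edge's
interaction strength as a discrete hidden state
$w_e(t) \in \{-2,-1,0,1,2\}$ (strongly repressing to strongly inducing), and
couples edges through gene functional categories: each edge's weight evolves
under a Markov chain whose transition matrix is a convex mixture of
category-level matrices,

$$w_e(t{+}1) \sim Q_e(w_e(t), \cdot), \qquad
  Q_e = \sum_h \alpha_{e,h} Q_h ,$$

with the mixture supported on the functional categories of the edge's two
genes (Dirichlet priors: weight $\lambda_p = 1$ on candidates,
$\lambda_o = 0$ elsewhere; pseudo-count priors on the rows of each $Q_h$).
Observed expression enters through the pairwise potential
$p(\mathbf{x}\mid\mathbf{w}) \propto \exp\big(\sum_{(i,j)} w_{ij} x_i x_j\big)$.
Gene-knockout strains share the evolution law but observe deterministically
damped weights $\Gamma^s_e\,w_e(t)$, with $\Gamma = 0$ on knockout-incident
edges and $\to 1$ far from the perturbation.

Parameters $\{Q_h, \alpha_{e,h}\}$ are estimated by EM with per-edge scaled
forward--backward recursions (linear in the number of time points); the most
probable weight trajectory of every edge is then decoded by Viterbi. Edges
and categories are ranked by *change scores* (mean absolute successive change
of the decoded trajectory; $\alpha$-weighted means at category level) and
selected by fitting an exponential distribution to the scores and keeping the
top-5% tail. A trace test calls dynamics significant when
$\mathrm{tr}(Q) \le 0.5\,W$.

The package also contains the full synthetic evaluation: an Erdős--Rényi
benchmark with trace-class transition matrices, an exact single-site Gibbs
sampler for the observation model (Rcpp), and ROC/AUC evaluation of edge- and
category-level detection against the simulated ground truth.

## Worked example

Simulate a small benchmark, fit the model, and score the dynamics:

```r
library(netgem)
set.seed(1)
bench <- generate_benchmark(n_genes = 50, n_edges = 120,
                            n_categories = 6, T = 8)
fit <- netgem(bench$data, bench$network, bench$annotation, seed = 1)
fit
#> Temporal interaction model fit
#>   120 edges, 8 time points, 1 strain(s), 6 categories
#>   EM: 57 iteration(s), converged, objective -1844.842
#>   log-evidence (pseudo-likelihood): -1140.588

head(fitted(fit), 3)          # decoded weight trajectories (edges x time)
#>              t1 t2 t3 t4 t5 t6 t7 t8
#> g0001--g0008  2  2  2 -2  2  2  2 -2
#> g0001--g0009 -2 -2 -2  2 -2 -2 -2 -2
#> g0001--g0010  2  2  2  2  2 -2  2  2

scores <- netgem_scores(fit, p = 0.05)
scores
#> Change scores (top-5% exponential tail):
#>   edges:      0 of 120 called significant (s* = 5.2176)
#>   categories: 0 of 6 called significant (s* = 5.3870)

head(scores$categories[order(-scores$categories$score), ], 3)
#>   category    score change_prob call
#> 3     C003 2.176235    4.155066   d0
#> 6     C006 2.024887    3.991419   d0
#> 4     C004 1.888752    3.842975   d0
```

The decoded trajectories show which interactions switch sign or strength and
when; the score table ranks categories by how much temporal change their
edges exhibit (`change_prob` is the total off-diagonal mass $W -
\mathrm{tr}(\hat Q_h)$ of the fitted category matrix). Here the three
top-scoring categories are exactly the three whose generating matrices came
from the dynamic trace class:

```r
roc_curve(setNames(scores$categories$score, scores$categories$category),
          bench$truth$category_class)
#> ROC: AUC = 1.0000 (3 positive, 3 negative)
```

Knockout strains are added by passing several expression matrices and a
knockout list; damping is computed from the topology:

```r
fit2 <- netgem(list(reference = x_ref, mutant = x_mut), network, annotation,
               knockouts = list(mutant = "SFP1"), seed = 1)
```

A thin command-line interface wraps the same functions
(`Rscript inst/cli/netgem.R simulate|fit|score|benchmark ...`; see
`?netgem_cli`), writing TSV/JSON outputs and Cytoscape-style edge-attribute
tables (`write_cytoscape_edges()`).

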