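---
title: "Inferring time-varying gene interactions with netgem"
author: "netgem developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-varying gene interactions with netgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgem)
```

## The problem

Short gene-expression time series (often 6--8 arrays) cannot support edge-by-edge
time-series modelling: there are orders of magnitude more interactions than
observations. **netgem** addresses this by (i) fixing the network topology to a
known interaction network (e.g. a high-confidence protein--protein interaction
network), (ii) discretising each edge's interaction strength, and (iii) borrowing
strength across edges through the functional categories of the genes, so that a
handful of category-level transition matrices -- not thousands of per-edge
parameters -- govern the dynamics.

## The model

Let $G=(V,E)$ be the known network, and let $w_e(t) \in \mathcal{W}$ be the hidden
interaction strength of edge $e$ at time $t$. The default state set is
$\mathcal{W} = \{-2,-1,0,1,2\}$ ($W = 5$): $-2$ strongly repressing, $0$
uncorrelated, $+2$ strongly inducing.

**Observation model.** Given all edge weights, expression values interact through
the pairwise potential

$$p(\mathbf{x} \mid \mathbf{w}) \;=\; \frac{1}{Z(\mathbf{w})}
  \exp\Big(\sum_{e=(i,j)\in E} w_e\, x_i x_j\Big),$$

an Ising-type model whose normalisation constant $Z$ is never computed: synthetic
observations are drawn from it by single-site Gibbs sampling, and inference uses a
per-edge factor (below) that does not require $Z$.

**Evolution model.** Each edge's weight follows a Markov chain,
$w_e(t+1) \sim Q_e(w_e(t), \cdot)$, with the effective transition matrix a convex
mixture over the $H$ functional categories,

$$Q_e = \sum_{h=1}^{H} \alpha_{e,h}\, Q_h, \qquad
  \alpha_{e,h} \ge 0,\; \textstyle\sum_h \alpha_{e,h} = 1 .$$

The mixture is supported on the edge's *candidate set*: the union of the
functional-category memberships of its two endpoint genes. A Dirichlet prior with
weight $\lambda_p = 1$ on candidates and $\lambda_o = 0$ elsewhere keeps the
support restriction exact. Rows of each $Q_h$ carry a Dirichlet prior
$\theta_h$ (pseudo-counts), non-informative by default.

**Knockout strains.** A strain $s$ with knocked-out genes observes damped weights
$\Gamma^s_e\, w_e(t)$ with $\Gamma^s_e \in [0,1]$ computed deterministically from
the topology: zero on edges incident to a knockout, approaching one far away. All
strains share the evolution law $Q$ itself.

## Inference

The hidden variables are the weight trajectory $w_e(\cdot)$ and the active
category $y_e(t)$ of each transition; the parameters are
$\Psi = \{Q_h, \alpha_{e,h}\}$, estimated by EM:

* **Emission factors.** For each edge, time and strain, the $W$ state weights
  $\exp(\Gamma^s_e\, w\, x_i x_j)$ are normalised over the states; strains are
  conditionally independent given the shared trajectory, so their normalised
  factors multiply. This per-edge pseudo-likelihood keeps edges conditionally
  independent and sidesteps $Z(\mathbf{w})$; it is exact for the relative
  evidence among states of one edge in isolation.
* **E-step.** A scaled forward--backward recursion per edge (uniform initial
  state distribution), linear in $T$; all edges are processed as one vectorised
  batch. Per-transition category responsibilities are
  $r_t(h) \propto \alpha_{e,h} Q_h(i,j)$ combined with the transition posterior
  $\xi_t(i,j)$.
* **M-step.** Dirichlet pseudo-count updates: $Q_h$ rows get expected transition
  counts (summed over edges and strains) plus $\theta_h$; $\alpha_e$ gets
  expected category usage plus $\lambda_{e,h}$. Adding the prior weight itself
  (posterior-mean style) rather than $\lambda - 1$ keeps the update well defined
  at $\lambda_o = 0$ and support-preserving.
* **Objective.** The penalised surrogate (data log-evidence plus the Dirichlet
  prior terms) is non-decreasing across iterations; the run stops when its
  relative change falls below `tol` ($10^{-6}$ by default, at most `max_iter`
  $= 200$ iterations).
* **Decoding.** After convergence, each edge's most probable state sequence is
  computed by the Viterbi recursion. Exact ties are broken toward the state
  closest to 0, then toward the lower state index, so uninformative edges decode
  to "uncorrelated" rather than to an arbitrary extreme.

Initialisation follows the priors: each row of each $Q_h$ is drawn uniformly and
normalised, and each $\alpha_e$ is drawn from the candidate-set Dirichlet; both
draws are controlled by the `seed` argument, and identical seeds give bit-identical
fits.

## Significance statistics

The decoded trajectories feed three statistics:

* **Edge change score** $s_T(e) = \frac{1}{T-1}\sum_{t=1}^{T-1}
  |w_e(t{+}1) - w_e(t)|$: the mean absolute successive change. The magnitude
  matters -- a swing from $-2$ to $+2$ counts four times a step from $-2$ to
  $-1$. We normalise by the number of transitions $T-1$; the `aggregate`
  argument also offers plain sums and squared differences.
* **Category change score** $s_T^h$: the $\alpha$-weighted mean of the change
  scores of the edges whose candidate set contains $h$. Categories carrying no
  weight score 0.
* **Trace test**: dynamics are called significant ($H_1$) when
  $\mathrm{tr}(Q) \le P \cdot W$ with $P = 0.5$ (the boundary belongs to
  $H_1$); `category_change_prob()` reports the complementary quantity
  $W - \mathrm{tr}(Q_h)$ used to rank categories.

Selection fits an exponential distribution to the scores by maximum likelihood
and keeps the top-$p$ tail: the critical value is
$s^\ast = \bar{s}\,\log(1/p)$, with $p = 0.05$ by default, and only scores
*strictly* above $s^\ast$ are selected.

## The synthetic benchmark

`generate_benchmark()` reproduces the package's evaluation conditions: an
Erdős--Rényi graph with 1000 genes and 5961 edges, $H = 200$ categories, genes
assigned to 1--4 categories (probabilities 0.5/0.3/0.15/0.05 -- a configurable
stand-in for the empirical membership-size distribution of yeast FunCat
annotations), category matrices sampled half/half from the two trace classes
($H_0$: $\mathrm{tr} > 0.5W$, via Dirichlet rows mixed toward the identity with
weight $\sim U(0.5,1)$; $H_1$: $\mathrm{tr} \le 0.5W$, by rejection), weight
trajectories over $T = 8$ time points, and $\{-1,+1\}$ node observations
Gibbs-sampled from the observation model with 50 burn-in sweeps per time point
(fresh chain each time point, as the observation model makes time points
conditionally independent given the weights). `run_roc_experiment()` runs the
full loop -- generate, fit, decode, score -- and evaluates edge- and
category-level detection of the trace class by ROC/AUC (trapezoidal rule, equal
to the Mann--Whitney statistic).

```{r mini-benchmark}
set.seed(1)
bench <- generate_benchmark(n_genes = 30, n_edges = 60, n_categories = 4,
                            T = 6)
fit <- netgem(bench$data, bench$network, bench$annotation, seed = 1)
fit
netgem_scores(fit, p = 0.05)
```

### What the benchmark does and does not emulate

The generator reproduces the *structure* of the inference problem: short series,
discrete hidden dynamics, category coupling, knockout damping. It does **not**
emulate continuous expression noise, probe-level artefacts, or normalisation
effects of real microarray data -- real data enter the fit as (centred) real
values through the same emission, so passing benchmark tests demonstrates the
machinery, not robustness to array noise.

One property of the benchmark deserves emphasis. With weights up to $|w| = 2$
and a mean degree of ~12, the observation model sits deep in the *frustrated*
regime of the pairwise potential: even an exactly-equilibrated sample leaves a
substantial fraction of edges with $x_i x_j \ne \operatorname{sign}(w_e)$
(roughly 20--35%, heterogeneously across edges), because no spin configuration
can satisfy all strongly-coupled, partially conflicting edges at once. The
per-edge emission factor, taken in isolation, implies a much cleaner channel
than the joint model actually delivers, so the posterior over-counts weight
transitions and the recovered transition matrices are biased toward low traces.
Detection of dynamic categories and edges therefore degrades relative to what
the per-edge factor alone would suggest: the class *ranking* survives (category
detection remains well above chance and consistently stronger than edge
detection, as the acceptance tests assert), but absolute trace recovery does
not. This is a property of coupling a factorised inference to a globally
coupled observation model, not an implementation artefact: the forward--backward,
Viterbi and responsibility computations match exhaustive enumeration to
$10^{-10}$, the Gibbs sampler matches exact enumeration in total variation, and
EM initialised at the generating parameters drifts away from them, showing the
bias lives in the (pseudo-likelihood) objective itself. Sparser networks and
weaker couplings reduce the effect.

## Numerical and design choices

* **Damping closed form.** Distance mode uses $\Gamma_i = 1 - 2^{-h_i}$ with
  $h_i$ the BFS distance to the nearest knockout ($\Gamma = 0$ at the knockout,
  halving of the deficit per hop, $\to 1$ far away; unreachable nodes get 1).
  Diffusion mode pins knockouts at 0 and iterates
  $\Gamma_i \leftarrow \beta \cdot \mathrm{mean}_{j \in N(i)} \Gamma_j$ from an
  all-ones start to a $10^{-8}$ fixed point. Edge damping is the minimum over
  the two endpoints, which guarantees exact zeros on knockout-incident edges.
* **Candidate sets.** The union of endpoint memberships. Edges whose endpoints
  are both unannotated share one implicit `.background` category with its own
  transition matrix, so every edge has at least one mixture component.
* **Degenerate inputs.** Self-loops are dropped with a warning; duplicate and
  reversed edge pairs are merged; an all-zero score vector makes the
  exponential tail fit error out rather than return an arbitrary threshold;
  emissions that vanish for every state raise `"degenerate emission"`.
* **Problem sizes in the test suite.** The enumeration oracles run at
  $(W \cdot H)^T \le 10^5$ (e.g. $W=2$, $H=2$, $T=4$); sampler correctness uses
  a 5-node graph with $10^6$ kept samples; the ROC experiment runs at a
  200-gene/1200-edge/40-category scale in the tests and at the full
  1000/5961/200 scale in `scripts/acceptance.R`; recovery experiments use
  mean-degree-2 graphs, the sparsity typical of high-confidence interaction
  networks.
* **Real data.** Expression tables are centred per strain with
  `normalize_expression()` (per-gene time mean by default; the strain grand
  mean as an option) so that the sign of the product $x_i x_j$ is meaningful;
  `binarize_expression()` optionally maps values to $\pm 1$ to mimic the
  synthetic regime.

## Limitations

* Inference is per-edge pseudo-likelihood, not exact inference in the joint
  pairwise field; globally coupled observation regimes bias transition
  estimates as described above.
* The number of states $W$ and categories $H$ are fixed inputs; no model
  selection is attempted.
* The damping schemes are deterministic topological heuristics; they do not
  model compensatory rewiring after a knockout.
* Expression is assumed comparable across genes after per-strain centring;
  upstream preprocessing (background correction, normalisation,
  summarisation) is out of scope.
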