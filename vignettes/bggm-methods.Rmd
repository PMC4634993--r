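---
title: "Bayesian Gaussian graphical models for functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Gaussian graphical models for functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bggm)
```

## The model

Functional connectivity between $p$ brain regions is treated as a covariance
selection problem.  The observed region-by-time matrix
$X = (x_1, \dots, x_n)^T$ is modeled as $n$ independent draws from a
zero-mean $p$-variate Gaussian with precision matrix $K$, so the likelihood
depends on the data only through the unnormalized scatter matrix
$\Sigma = X^T X$:

$$P(X \mid K) \propto |K|^{n/2} \exp\!\left[-\tfrac12 \langle K, \Sigma\rangle\right].$$

A zero entry $k_{ij} = 0$ means regions $i$ and $j$ are conditionally
independent given all others.  Collecting these zeros in an undirected graph
$G$ turns the model into a Gaussian Markov random field, and the scientific
object of interest becomes the *pair* $(G, K)$: the conditional-independence
structure and the connection strengths, read off as partial correlations
$r_{ij} = -k_{ij} / \sqrt{k_{ii} k_{jj}}$.

The prior on $K$ given $G$ is the G-Wishart distribution $W_G(\delta, D)$,
supported on the cone $P_G$ of positive-definite matrices with zeros off
$G$'s edge set.  It is conjugate: observing $(\Sigma, n)$ updates
$(\delta, D) \mapsto (\delta + n, D + \Sigma)$.  The prior on $G$ is
independent Bernoulli over edges with probabilities $\theta_{ij}$.  The
joint posterior is

$$P(G, K \mid X) \propto P(X \mid K)\, P(K \mid G)\, P(G).$$

Two model extensions share this skeleton.  *Data fusion* multiplies in a
Dirichlet-multinomial likelihood for a matrix $S$ of probabilistic-tractography
streamline counts: row $j$ of $S$ is modeled over the other $p-1$ regions
with concentration $\alpha$ on graph neighbors and $\beta$ on non-neighbors,
so anatomical evidence informs the same graph that constrains the functional
precisions.  An *informative prior* replaces the flat $\theta_{ij} = 0.5$
with structured probabilities; the shipped example sets $\theta = 1$ for
homotopic interhemispheric pairs, $0$ for all other interhemispheric pairs
and $0.5$ within hemispheres.

## Default hyperparameters

| Parameter | Default | Meaning |
|---|---|---|
| $\delta$ | 3 | G-Wishart degrees of freedom; 3 with $D = I_p$ is a vague prior on the precision |
| $D$ | $I_p$ | G-Wishart scale (unnormalized-scatter convention) |
| $\theta_{ij}$ | 0.5 | no a-priori preference for dependence or independence |
| $(\alpha, \beta)$ | (1, 0.5) | streamline concentrations: high counts favor an edge while allowing tractography noise |
| iterations | 50\,000 per chain | with 20% burn-in |
| chains | 2 | convergence assessed by cross-chain edge-probability discrepancy at 0.05 |
| retained draws | $T = 1000$ per chain | uniform thinning of the post-burn-in iterations |

The scatter matrix is used *unnormalized* ($\Sigma = X^T X$, never divided
by $n$) everywhere, including in the graphical-LASSO baseline, so the
benchmark penalties $\lambda \in \{5, 100\}$ are interpreted on that scale.
Standardization of each region to mean 0, variance 1 uses the population
($1/n$) variance so that "unit variance" is exact for the scatter-based
likelihood; a `denominator = "n-1"` flag is provided.  Whether simulated
series are standardized before inference is configurable and off by
default; empirical time series should be standardized as a matter of
course.

## Sampling $(G, K)$

The posterior is doubly intractable: the G-Wishart normalizing constant
$Z_G(\delta, D)$ has no closed form for general graphs, and it appears in
every graph-move acceptance ratio.  The sampler combines three exact
ingredients:

1. **Direct G-Wishart draws.**  An unconstrained Wishart draw with degrees
   of freedom $\delta + p - 1$ and scale $D^{-1}$ is projected onto $P_G$ by
   block-coordinate completion of its covariance: column $j$ of the working
   covariance is replaced by the regression prediction from $j$'s graph
   neighbors, sweeping until the matrix stabilizes, after which the inverse
   has (numerically) zeros off the edge set and the non-edges are set to
   exactly zero.  For the complete graph this is an ordinary Wishart draw;
   for the empty graph the diagonal elements are independent
   $\mathrm{Gamma}(\delta/2, d_{ii}/2)$ variates, and both limits are
   verified against their closed-form moments in the test suite.
2. **Conjugate refresh.**  Each iteration redraws $K$ exactly from
   $W_G(\delta + n, D + \Sigma)$ given the current graph, so the chain over
   $G$ is effectively collapsed.
3. **Single-edge exchange moves.**  One free pair $(i, j)$ is proposed
   uniformly per iteration.  Conditioning on all of $K$ except the block
   $(k_{ij}, k_{jj})$, the ratio of the edge-present to edge-absent
   conditional integrals has the closed form
   $N = \sqrt{2\pi / (a\,d_{jj})}\, \exp\!\big[(c\,d_{jj} + d_{ij})^2 /
   (2\,a\,d_{jj})\big]$, where $a$ and $c$ are scalars obtained from one
   linear solve against $K_{-j,-j}$.  The remaining ratio of *prior*
   constants $Z_G / Z_{G'}$ is cancelled by an exchange step: an auxiliary
   precision matrix is drawn from the prior under the proposed graph and the
   same conditional ratio is evaluated on it.  Because the auxiliary draw is
   exact, the exchange construction targets the correct posterior.  On
   acceptance the free block is redrawn from its exact conditional (a Gamma
   and a Gaussian variate), keeping every retained $K$ inside $P_{G}$.

Pairs with hard prior probabilities $\theta_{ij} \in \{0, 1\}$ are excluded
from the proposal set: hard-present edges are added at initialization and
never removed, hard-absent edges never appear, and the corresponding
precision entries are exactly zero in every draw.  This avoids $-\infty$
arithmetic and makes structural constraints exact rather than approximate.

Correctness of the whole loop is validated against an independent oracle:
for $p \le 3$ every graph is decomposable, so exact posterior edge
probabilities can be computed by enumerating all $2^{p(p-1)/2}$ graphs with
closed-form normalizing constants.  At $p = 3$, $n = 200$, two chains of
50\,000 iterations reproduce the exact edge probabilities to well within
0.02.

### Numerical choices

* The completion loop stops when the largest change of the working
  covariance falls below $10^{-8}$ *relative to its largest entry* (at most
  1000 sweeps).  A relative criterion is used because posterior-scale
  precisions grow like $n$ and an absolute threshold would not be
  scale-free.
* A far-tail unconstrained precursor (observed roughly once per $10^5$
  draws) can stall the completion; such precursors are rejected and redrawn
  rather than aborting the run.  Up to 10 restarts are attempted before an
  error is raised.  The conditioning this introduces is negligible relative
  to Monte-Carlo error.
* Graphs are serialized as upper-triangle bitstrings in column-major pair
  order; all frequency-based diagnostics (entropy, MAP probability, unique
  model counts) operate on these strings.
* All exported stochastic functions take an explicit seed and restore the
  caller's RNG state; compiled code draws from R's RNG so results are
  reproducible end to end.

## Normalizing constants

`log_normalizing_constant()` serves the enumeration oracle and the tests;
the MCMC itself never needs $Z_G$.  For decomposable graphs the constant
factorizes exactly over the maximal cliques and separators of a junction
tree, each factor a complete-graph (Wishart) constant; cliques and the
chordality test come from igraph's maximum-cardinality search.  For
non-decomposable graphs a Monte-Carlo estimator in the free-element
Cholesky parameterization is used: free elements are sampled from
$\chi$ and Gaussian laws, non-free elements are completed recursively, and
the estimator averages $\exp(-\tfrac12 \sum \psi^2_{\text{non-free}})$
with a delta-method standard error on the log scale.  The factorized and
Monte-Carlo routes are cross-checked against each other and against
closed forms in the tests.

## Point-estimate baselines

The maximum-likelihood precision is $\Sigma^{-1}$ (erroring informatively
when $n < p$ or the scatter is otherwise singular).  The graphical LASSO
maximizes $\log|K| - \langle\Sigma, K\rangle - \lambda \|K\|_1$ with the
penalty over off-diagonal entries (a `penalize_diagonal` flag is provided;
the objective in the source publication does not specify the convention).
The solver is blockwise coordinate ascent on the dual — maximize
$\log|W|$ subject to $|W - \Sigma| \le \lambda$ off the diagonal — with an
inner lasso coordinate descent per column.  Each column update solves its
subproblem exactly, so the dual objective is monotone non-decreasing; the
per-sweep values are returned for inspection.  Anchors verified in the
tests: $\lambda = 0$ reproduces $\Sigma^{-1}$; $\lambda$ beyond the largest
off-diagonal $|\Sigma_{ij}|$ yields an exactly diagonal estimate; at
$p = 2$ the solution matches a derivative-free optimizer of the objective.

## Evaluation machinery

Reconstruction quality against a ground truth $(R^*, T)$ uses the
element-wise error $\Gamma = |R^* - R|$ summarized as the total error
$\eta$, the true-positive error $\eta_{tp}$ and the true-negative error
$\eta_{tn}$ (masks are symmetrized; directionality is ignored).  When the
mask has no true edges or no true non-edges the corresponding component is
undefined and returned as `NA` with a warning.  Point estimates are placed
on the posterior's own scale by the standardized score
$z = (\eta_{\text{point}} - \mu)/\sigma$, with $\mu, \sigma$ the mean and
standard deviation of $\eta$ applied to each retained posterior draw
(per-draw transform, not the posterior mean).  Posterior shape is
summarized by the plug-in entropy (bits) of the empirical graph
frequencies and by the empirical probability of the modal graph; both are
computed from the discrete graph marginal of the retained samples, since a
continuous density for $K$ cannot enter a discrete entropy.

## The synthetic test bed

The generator produces the package's entire no-download validation data:

* `random_graph()` draws Erdős–Rényi graphs at a chosen density.
* `sample_ground_truth()` draws the true precision from a G-Wishart on the
  graph and rejects whole draws until every true edge carries
  $|r_{ij}| \ge$ `min_abs_partial` (default 0.25).  The default scale is
  *graph-informed*: a target precision with unit diagonal and
  $\pm$`target_partial` (0.45) off-diagonals on the edges, shrunk toward
  the identity until safely positive definite, with $\delta = 100$
  concentrating the draw around it.  Under a vague scale the probability
  that a dozen edges jointly clear the floor is essentially zero, so the
  floor would be unattainable; the graph-informed scale mimics calibrated
  benchmark networks in which true connections have clear effect sizes.
  Inference never sees these generator parameters.
* `simulate_timeseries()` draws $n$ i.i.d. Gaussian observations with
  covariance $K^{-1}$.
* `simulate_streamlines()` draws each region's row of counts from the
  Dirichlet-multinomial with concentrations $\alpha$ on edges and $\beta$
  elsewhere.  A `mismatch_rate` flips that fraction of pairs inside the
  streamline generator only, modeling contradiction between modalities
  while the functional data stay on the true graph.
  `ideal_streamlines()` is the noise-free limit: counts split equally over
  true neighbors.

What the generator does *not* emulate: haemodynamic forward dynamics,
shared-input or time-mixing corruptions, non-Gaussian noise, and
voxel-level aggregation of tracts.  Passing recovery tests therefore show
that the inference machinery is correct under its own model assumptions,
not that those assumptions hold for any particular scanner or protocol.

## Validation scenarios and their sizes

The test suite and `scripts/acceptance.R` use these study conditions,
chosen once as representative desk-scale problems:

* **Oracle agreement**: $p = 3$, $n = 200$, $\theta = 0.5$, two chains of
  50\,000 iterations versus exact enumeration (tolerance 0.02).
* **Sampler moments**: 20\,000 draws at $p \le 4$ against closed-form
  Wishart/Gamma moments (3.5 standard errors).
* **Recovery**: $p = 10$, $n = 2000$, density 0.3, effect-size floor 0.25;
  edge-probability ROC area $\ge 0.95$.
* **Fusion**: $p = 6$, $n = 150$, density 0.3, row totals 1000.  With
  noise-free consistent streamlines the plug-in entropy strictly drops
  relative to the fMRI-only run on the same data and seed.  With sampled
  (Dirichlet-multinomial) consistent counts the direction holds for most
  but not all scenarios — sampled tractography noise can legitimately add
  uncertainty about pairs the functional data had settled — so the sampled
  variant lives in a fixed-seed property test and the noise-free variant
  carries the strict claim.  With fully contradictory streamlines
  (`mismatch_rate = 1`) the mean partial-correlation variance over the
  contradicted pairs strictly increases; the increase concentrates on pairs
  where one modality is confident and the other dissents, while pairs with
  only marginal functional support can instead be *resolved* by the
  contradiction, which is why the summary is taken over all contradicted
  pairs rather than true edges only.

## Known limitations

* Cost per iteration is dominated by two direct G-Wishart draws; the
  implementation is comfortable for tens of regions but is not intended
  for hundreds (no parallel tempering, no GPU path).
* The exchange move flips one edge at a time; posteriors with strongly
  correlated edge sets mix more slowly, which is why two chains and a
  cross-chain discrepancy check are the default.
* The enumeration oracle is limited to $p \le 4$, and its non-decomposable
  constants are Monte-Carlo estimates with reported standard errors.
* Gaussianity of the time series is assumed throughout; heavy-tailed or
  strongly autocorrelated data violate the likelihood and are not
  detected by the package.
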