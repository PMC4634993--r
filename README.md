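# bggm — Bayesian Gaussian graphical models for functional connectivity

Functional connectivity between brain regions is usually summarized by
correlation, which confuses direct and indirect coupling, or by partial
correlation, which isolates direct coupling but is typically reported as a
single regularized point estimate.  `bggm` treats connectivity as a
covariance selection problem and infers the **joint posterior over the
conditional-independence graph and the partial correlations**: for region
time series `X` (n time points × p regions) it samples

    P(G, K | X)  ∝  P(X | K) · P(K | G) · P(G)

where the likelihood is zero-mean Gaussian with precision matrix `K`, the
prior `P(K | G)` is the conjugate G-Wishart distribution `W_G(δ, D)` on the
cone of positive-definite matrices with zeros off the graph `G`, and
`P(G)` is an independent Bernoulli edge prior `θ_ij`.  Partial correlations
are obtained per draw by `r_ij = −k_ij / √(k_ii k_jj)`.  The output is not
one network but a distribution over networks: per-edge inclusion
probabilities, per-edge partial-correlation distributions, and shape
diagnostics (plug-in entropy in bits, probability of the modal graph).

The package is aimed at researchers analyzing region-level fMRI (or other
approximately Gaussian multivariate) time series who want uncertainty on
both the structure and strength of direct connectivity.  It also
implements:

* **Data fusion** with probabilistic-tractography streamline counts via a
  Dirichlet-multinomial likelihood `P(S | G, α, β)` — anatomical and
  functional evidence inform the same graph;
* **Informative priors**, including a hemisphere/homotopy prior (homotopic
  pairs forced present, other interhemispheric pairs forced absent);
* **Baselines**: the maximum-likelihood precision `Σ⁻¹` and a
  graphical-LASSO solver (ℓ1-penalized precision estimation) with the
  benchmark penalties λ ∈ {5, 100} on the unnormalized-scatter scale;
* **Evaluation tools**: reconstruction errors η / η_tp / η_tn against a
  ground truth, posterior-relative z-scores for point estimates, ROC area
  of edge probabilities, and an exact enumeration oracle for p ≤ 4;
* **A synthetic test bed**: ground-truth graphs, graph-constrained
  precisions with a guaranteed effect-size floor, Gaussian time series and
  streamline counts with controllable cross-modal agreement.

The sampler is a single-edge exchange MCMC with exact conjugate G-Wishart
refreshes (compiled via RcppArmadillo); auxiliary prior draws cancel the
intractable G-Wishart normalizing constants, and the chain is validated
against exact enumeration.

## Worked example

Simulate a 5-region network, infer the posterior, and compare with the
graphical LASSO:

```r
library(bggm)

sc <- simulate_scenario(p = 5, n = 300, density = 0.4, seed = 42)
sum(sc$graph) / 2              # 7 true edges

cfg  <- mcmc_config(n_iterations = 20000, thin_to = 1000, n_chains = 2, seed = 1)
post <- sample_joint_posterior(sc$X, theta = 0.5, cfg)
post
#> <bggm_samples> p = 5, 2000 draws (2 chains x 1000), fMRI-only model
#>   seed 1, 20000 iterations, burn-in 4000, acceptance 0.024/0.021

sm <- posterior_summaries(post)
round(sm$edge_probabilities, 2)
#>    V1   V2   V3   V4   V5
#> V1  0 1.00 1.00 1.00 1.00
#> V2  1 0.00 0.03 1.00 0.05
#> V3  1 0.03 0.00 0.04 1.00
#> V4  1 1.00 0.04 0.00 1.00
#> V5  1 0.05 1.00 1.00 0.00
round(sm$partial_mean, 2)      # posterior-mean partial correlations
#>       V1    V2   V3    V4    V5
#> V1  1.00  0.48 0.42  0.47 -0.48
#> V2  0.48  1.00 0.00 -0.55  0.00
#> V3  0.42  0.00 1.00  0.00  0.59
#> V4  0.47 -0.55 0.00  1.00  0.30
#> V5 -0.48  0.00 0.59  0.30  1.00
```

All seven true edges carry posterior probability ~1 and the three absent
pairs stay near or below 0.05; the posterior-mean partial correlations
reproduce the ground truth `round(sc$R, 2)` to a few hundredths.
Posterior-shape diagnostics and a baseline comparison:

```r
posterior_entropy(post)                       # 0.75 bits
map_probability(post)$probability             # 0.88 — the modal graph
convergence_report(post)$max_discrepancy      # 0.017 (pass at 0.05)

err_bggm  <- reconstruction_errors(sc$truth, sm$partial_mean)
err_lasso <- reconstruction_errors(sc$truth,
  precision_to_partial(glasso_precision(scatter_matrix(sc$X), lasso_config(5))))
c(bggm = err_bggm$eta, glasso = err_lasso$eta)
#>       bggm     glasso
#> 0.01269083 0.03599317
z_score(err_lasso$eta, eta_distribution(post, sc$truth))
#> [1] 1.160442
```

Here the posterior-mean reconstruction error is about a third of the
LASSO's, while the LASSO point estimate still sits inside the posterior
error cloud (|z| < 2).  Fusion with streamline counts uses
`sample_fused_posterior(X, S, ...)`; a full file-based run (including a
reproducibility manifest) is `run_pipeline("config.yaml")`, and
`inst/cli/bggm.R` exposes `fit` / `simulate` / `glasso` / `evaluate` /
`summarize` subcommands for shell use.

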