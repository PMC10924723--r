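---
title: "Models and methods behind ratelink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ratelink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ratelink is a simulation-and-inference laboratory for one question: when
can a statistical test tell that rates of molecular and morphological
evolution are correlated across the branches of a phylogeny? This vignette
documents the generative models, the inference machinery, the five
detection tests, the tunable parameters, the numerical choices, and the
limits of what a passing test establishes.

## The stated world

All simulations start from an ultrametric chronogram (branch durations in
Myr). The defaults are chosen to mimic an angiosperm-scale problem:

* root age 139.40 Myr; trees of 18, 45, or 111 tips generated by a
  birth-death process conditioned on the tip count (`simulate_chronogram`,
  birth 0.1 / death 0.05 per Myr; only their ratio matters after rescaling
  to the root age). User chronograms in Newick are accepted verbatim.
* an uncorrelated lognormal relaxed clock: each branch's rate is an i.i.d.
  lognormal draw with expectation `mu` and log-scale standard deviation
  `sigma`. The mean molecular rate is 9.65e-4 substitutions/site/Myr, the
  mean morphological rate 1.83e-3 changes/character/Myr, and `sigma` takes
  the values 0.25, 0.75, or 1.25. We interpret "standard deviation" on the
  log scale (sdlog), with meanlog `log(mu) - sigma^2/2` so the expectation
  is exactly `mu`: values like 1.25 are dimensionless and commensurate with
  log-rate spread, whereas a natural-scale sd of 1.25 would dwarf a mean of
  1e-3.
* coupled morphological rates are a fixed multiple of the molecular rates:
  the morphological phylogram is the molecular phylogram scaled by 1.90,
  which is the ratio of the two mean rates above rounded to two decimals.
  Uncoupled rates are an independent lognormal draw with the morphological
  mean and the same `sigma`, on the same chronogram.
* molecular data: 1000-nt alignments under GTR+G+I. The generating
  parameter values (exchangeabilities {1,2,1,1,4,1}, frequencies
  {0.30,0.20,0.25,0.25}, gamma shape 0.5, p_inv 0.2) stand in for
  empirical estimates that are not printed in the source material; every
  tested property is independent of these particular values, and they are
  configurable.
* morphological data: 10, 100, or 1000 characters with 2 or 4 states under
  the symmetric Mk model, each character carrying an i.i.d. gamma
  (shape 1.39, mean 1) rate multiplier. Invariant characters are retained.
  Root states are stationary (uniform for Mk). An optional
  missing-at-random mask (`mask_missing`, default fraction 0.33) emulates
  the missing-data burden of empirical matrices; the simulations proper
  produce complete matrices.

The full factorial grid is 3 tree sizes x 3 character counts x 2 state
counts x 3 sigma levels = 54 scenarios, 20 replicates each, i.e. 1080
molecular/morphological pairs per coupling setting.

Site-level rate variation is continuous gamma on the simulation side and
4-category discrete gamma on the inference side, matching the asymmetry of
common simulation and inference tools. With a proportion `p` of invariant
sites, the site likelihood is `p * I(invariant-compatible) * pi(state) +
(1 - p) * mean_c L_c`, with the category rates at mean 1 (note that some
tools, e.g. phangorn, instead rescale the category rates by `1/(1-p)`; the
two conventions coincide after scaling branch lengths by `(1-p)`, and the
test suite pins this equivalence down).

Every stage derives its RNG seed deterministically from a master seed and
stage tags (`derive_seed`), so any replicate can be regenerated in
isolation and all pipelines are bitwise reproducible.

## Likelihoods and maximum-likelihood fitting

Likelihood computation is Felsenstein pruning over site patterns,
implemented once in C++ (RcppArmadillo) and shared by the ML and Bayesian
layers. Reversible rate matrices are eigendecomposed via the standard
symmetrization, so transition probabilities are two small matrix products
per branch and category. No per-node rescaling is applied: with at most a
few hundred tips and four states, partial likelihoods stay far from the
double-precision floor (site likelihoods are clamped at 1e-300 as a
guard).

Branch lengths are estimated on the fixed (true) topology only. Because
the models are reversible, the two root-adjacent branches are not
separately identifiable, so fits use the unrooted parameterization with
`2n - 3` free lengths. Optimization is coordinate-wise Brent on each
branch in `[0, 10]`, swept in preorder with cached partial likelihoods so
each one-dimensional problem costs O(patterns) rather than O(tree); sweeps
repeat until the total log-likelihood improves by less than 1e-6 (default)
with non-convergence flagged, never fatal. Substitution-model parameters
are held at their configured values during branch-length optimization;
this isolates the branch-length contrast between the linked and unlinked
models, and the information-criterion differences are unaffected because
both models share the same substitution parameters.

The unlinked model fits the two data sets independently (`2(2n-3)` free
lengths). The linked ("proportionate") model shares one branch-length set
`b`, with morphological lengths `c * b` for a single scalar `c`
(`2n - 3 + 1` free parameters). Joint optimization alternates
branch-length sweeps with one-dimensional updates of `c`; a plain
alternation zigzags along the ridge where `b` rescales against `c`, so
each iteration also applies a ridge-aligned move (`b <- t b`, `c <- c/t`,
morphological lengths unchanged) that reduces the remaining work to the
shape of `b`. On matched coupled data `c` lands at the generating 1.90
within a few percent.

Model selection uses `AIC = 2k - 2lnL`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
and `BIC = k ln(n) - 2lnL`, with `n` the total number of data columns
(alignment sites plus characters) -- an explicit convention, since the
effective sample size of phylogenetic data is genuinely ambiguous. AICc is
reported as undefined when `n <= k + 1`. The decision rule for "rates are
linked" is a strict `delta > 2.5` on the criterion difference (unlinked
minus linked); the same threshold is applied to BIC as to AICc.

For root-to-tip distances the unrooted fitted phylogram is re-rooted at
the chronogram's root bipartition, splitting the fitted basal length in
proportion to the chronogram's two basal durations (`root_phylogram`).
This replaces the outgroup-rooting step of an empirical pipeline, which is
out of scope here.

## Bayesian inference

`run_mcmc` samples per-branch rate multipliers (one set per partition, or
one shared set under the linked clock model), partition mean clock rates,
and the lognormal clock's log-scale sd, by Metropolis-within-Gibbs with
multiplicative proposals. Node times are fixed to the true chronogram by
default (`fix_times = TRUE`), which is the desk-scale design; optionally
internal node ages are sampled under a birth-death prior (coalescent-
point-process form, root age fixed, Exponential(1) priors on birth and
death rates).

Priors: multipliers are lognormal(-sigma^2/2, sigma) with sigma ~
Exponential(mean 1) under the lognormal clock, or Exponential(1) (fixed
coefficient of variation 1) under the exponential clock used for
model-mismatch experiments; mean clock rates have a diffuse lognormal
prior centred on 1e-3 with log-sd 3. Because node times are fixed in
absolute Myr, both partition means are identifiable and estimated; the
convention of fixing the morphological mean to 1 (appropriate when node
times are relative) is retained behind `morph_mean_fixed` but is off by
default. All tests that compare the partitions' branch rates use ranks, so
they are invariant to this scale convention.

Two moves matter for mixing and are worth documenting. A "rescale" move
trades scale between a partition's mean and its multipliers (likelihood-
invariant, Jacobian `d(1-ne)` on the log scale). A "funnel" move scales
sigma while mapping the multipliers so their standardized log-residuals
are preserved; the multiplier prior ratio then cancels against the
Jacobian exactly. Without the funnel move the sigma chain had an effective
sample size of ~16 per 2e5 proposals; with it, prior-only sampling
recovers all prior moments and the 3-taxon single-free-rate posterior
matches fine-grid quadrature with a CDF sup-norm of 0.009.

Proposal widths adapt toward 30% acceptance during the burn-in fraction
(default 10%) and are frozen afterwards. Default desk-scale settings are 2
chains of 2e5 proposals thinned to every 100; the reference-scale settings
(1e7 steps, thin 1000) are available through `mcmc_settings`. Effective
sample sizes use Geyer's initial monotone positive sequence estimator
(`effective_sample_size`); parameters below the threshold (default 200)
flag the result rather than discarding it.

Marginal likelihoods come from generalized stepping-stone sampling
(`gss_logml`): a pilot posterior run moment-matches an independent-normal
reference on the log-parameter scale, rung temperatures are the quantiles
of Beta(0.3, 1), rung 0 samples the reference i.i.d., and each subsequent
rung runs component-wise Metropolis on the tempered target. Desk-scale
defaults are 8 rungs x 1e4 steps (reference scale: 25 x 4e5). The
estimator is validated against the conjugate normal-normal closed form
and against quadrature on a one-parameter Mk toy. The log Bayes factor is
`logml_linked - logml_unlinked` (natural log) with a strict `> 1.0`
decision threshold.

## The five detection tests

1. **Root-to-tip distance correlations** (`root_to_tip_test`): Pearson
   correlation of the two patristic root-to-tip distance vectors, with a
   one-sided permutation p-value (default 20,000 permutations;
   `p = (1 + #(r_perm >= r_obs)) / (B + 1)`), optional removal of tips
   outside 1.5 IQR in either vector, and detection at `p < 0.05`.
2. **Independent sister-pairs contrasts** (`sister_pairs_test`): for each
   cherry, the contrast `[log(b1 + eps) - log(b2 + eps)] / sqrt(t)` with
   `eps = 1e-9` and `t` the pair's divergence time; Spearman correlation
   between the molecular and morphological contrast vectors, two-sided p,
   detection requires `p < 0.05` and `rho > 0`. Taxa are ordered
   lexicographically within each pair so the contrast sign is well
   defined. The exact composition of the transformation is not nailed
   down by the source material; this is the package's documented choice.
3. **Likelihood-based model selection** (`ml_modelsel_test`): linked
   vs unlinked ML fits compared by AICc and BIC at the strict 2.5
   threshold.
4. **Correlations of Bayesian branch rates** (`bayes_branchrate_test`):
   Spearman correlation between per-branch posterior mean (or median)
   rates of the two partitions, one-sided p for positive correlation,
   optionally after dropping the chronologically shortest fraction of
   branches (smallest duration in Myr; posterior-median durations when
   times are sampled).
5. **Bayesian model selection** (`bayes_modelsel_test`): strict
   `log BF > 1.0` for the linked clock model.

The shared Spearman utility uses average ranks for ties, exact p-values by
full enumeration of rank permutations for n <= 9 without ties (R's own
`cor.test` draws the same exact/approximate line at n = 9; enumerating
10! permutations in R is not worth the cost), and the t approximation
otherwise. All decision thresholds are strict inequalities, and no
multiple-testing adjustment is applied: each replicate yields one decision
per method.

## Evaluation harness

`grid_config` / `enumerate_grid` / `run_replicate` / `compute_rates` /
`export_tables` orchestrate the factorial study. Detection rates are exact
fractions of replicates; power is the rate on coupled data, the
false-positive rate the rate on uncoupled data; indeterminate or failed
inferences count as "not detected" (a conservative convention). Pooled
percentages are unweighted means over scenario cells, which equals the
replicate-weighted mean under the balanced design. One chronogram is
simulated per tree size and reused across scenarios and replicates,
mirroring a design built on fixed empirical subtrees. Wide "heatmap" CSVs
(rows: sigma x state count; columns: character count x tree size) are the
machine-readable twin of the usual figure layout.

## What a green test does and does not establish

The generator produces complete, perfectly model-matched data: no
missing cells (unless masked), no topology error, no among-character
correlation, no punctuated change, and coupling that is exactly
proportional on every branch. Green acceptance tests therefore establish
that the *methods* behave as specified under the stated world -- not that
real data meet these conditions. Two specific limitations surfaced by the
test suite deserve emphasis:

* The root-to-tip permutation test is anti-conservative under strong
  among-lineage rate variation even on *true* phylograms: both distance
  vectors inherit tree-structured covariance aligned at the same tips,
  which tip-label permutation does not neutralize. At 45 taxa the
  empirical type-I rate is ~0.22 at the nominal 0.05 level. The
  corresponding calibration criterion is deliberately left red in the
  acceptance suite rather than weakened; the sister-pairs test, whose
  contrasts are phylogenetically independent, calibrates correctly (its
  compound decision rule, two-sided p plus a positive-rho requirement,
  makes it conservative at roughly alpha/2).
* With few characters and high rate variation, many morphological ML tip
  branches fit to length 0 and the sister-pair log-contrast saturates at
  the pseudocount, degrading the test's ranks; its power can then be
  non-monotone in sigma. Monotonicity is asserted in the informative
  region of the grid.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| Branch-length upper bound | 10 changes/site | `optimize_branch_lengths` |
| Optimizer convergence | 1e-6 logL units between sweeps | same |
| Brent positional tolerance | 1e-10 + 1e-9 t | C++ kernel |
| Ultrametricity tolerance | 1e-9 relative (1e-6 for file input) | `assert_chronogram` |
| Site-likelihood floor | 1e-300 | C++ kernel |
| Sister-pair pseudocount | 1e-9 | `sister_pairs_test` |
| Discrete gamma categories | 4 (mean-of-section, renormalized) | both models |
| MCMC target acceptance | 0.3 (adaptive during burn-in) | `run_mcmc` |
| GSS ladder | quantiles of Beta(0.3, 1) | `gss_logml` |
| Decision thresholds | p < 0.05; delta IC > 2.5; log BF > 1 (all strict) | tests |
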