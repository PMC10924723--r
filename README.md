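# ratelink

Detecting correlated rates of molecular and morphological evolution on
phylogenies — a simulation-and-inference toolkit.

## The problem

Do lineages that evolve quickly at the sequence level also evolve quickly
in their morphology? A phylogenetic way to ask this is to compare, branch
by branch, the rate of molecular evolution (substitutions/site/Myr) with
the rate of discrete-character evolution (changes/character/Myr), and to
test whether the two sets of branch rates are correlated. Empirical
studies disagree, partly because several different statistical tests are
in use and their power and false-positive behaviour had not been mapped
out. ratelink implements the full laboratory needed to do that mapping:

* a **synthetic-data engine**: ultrametric chronograms (default root age
  139.40 Myr), uncorrelated lognormal relaxed-clock branch rates (mean
  molecular rate 9.65e-4 subs/site/Myr; log-scale sd σ ∈ {0.25, 0.75,
  1.25}), morphological phylograms either *coupled* (molecular branch
  lengths × 1.90, the ratio of the two mean rates) or *uncoupled*
  (independent draws, mean 1.83e-3 changes/character/Myr), 1000-nt
  GTR+Γ+I alignments, and 2- or 4-state Mk+Γ character matrices
  (among-character gamma shape 1.39), with optional missing-data masking;
* **fixed-topology maximum likelihood**: pruning-algorithm kernels
  (RcppArmadillo) for GTR+Γ+I and Mk+Γ, coordinate-wise branch-length
  optimization, and the *linked* ("proportionate": morphological lengths
  = c × molecular lengths) vs *unlinked* branch-length models compared by
  AICc and BIC;
* **Bayesian inference**: Metropolis-within-Gibbs sampling of per-branch
  rates under lognormal or exponential uncorrelated relaxed clocks
  (linked or unlinked across data partitions), ESS diagnostics, and
  generalized stepping-stone marginal likelihoods for Bayes factors;
* the **five detection tests**: (i) root-to-tip distance correlations
  with a permutation p-value, (ii) independent sister-pairs contrasts,
  (iii) likelihood-based model selection (ΔAICc/ΔBIC > 2.5), (iv)
  Spearman correlations of Bayesian posterior branch rates, (v) Bayesian
  model selection (log BF > 1);
* an **evaluation harness** that runs the factorial grid (3 tree sizes ×
  3 character counts × 2 state counts × 3 σ levels = 54 scenarios, 20
  replicates, 1080 data-set pairs per coupling setting) and tabulates
  power and false-positive rates.

## Worked example

```r
library(ratelink)

# one coupled scenario: 45 taxa, 100 binary characters, high rate variation
spec <- scenario_spec(n_taxa = 45, n_chars = 100, k_states = 2,
                      sigma = 1.25, coupled = TRUE, master_seed = 1)
res <- run_replicate(spec, methods = c("rtt", "sisters",
                                       "ml_aicc", "ml_bic"),
                     n_perm = 2000)
for (m in names(res)) print(res[[m]])
```

This prints (exact numbers from this seed):

```
<root_to_tip> statistic = 0.9003, p = 0.0004998, detected = TRUE (n = 45)
<sister_pairs> statistic = 0.5209, p = 0.03854, detected = TRUE (n = 16)
<ml_modelsel_aicc> statistic = 138.8, detected = TRUE (n = NA)
<ml_modelsel_bic> statistic = 518.7, detected = TRUE (n = NA)
```

Reading: the two root-to-tip distance vectors correlate at r = 0.90 with
a one-sided permutation p ≈ 5e-4; the 16 sister-pair contrasts correlate
at Spearman ρ = 0.52 (p = 0.039); and the linked branch-length model
beats the unlinked one by 138.8 AICc units (518.7 BIC units), far beyond
the 2.5 decision threshold. All four tests correctly detect the coupled
rates that this scenario simulated.

A reduced power/false-positive study and its CSV exports:

```r
cfg <- grid_config(tree_sizes = c(18, 45), char_counts = c(10, 100),
                   state_counts = 2, sigmas = c(0.25, 1.25),
                   n_replicates = 5, coupled = "both",
                   methods = c("rtt", "sisters", "ml_aicc", "ml_bic"),
                   n_perm = 2000, master_seed = 1)
results <- evaluate_grid(cfg)
tab <- compute_rates(results)
export_tables(tab, "results/")   # results_long.csv, heatmap_*.csv, summary_pooled.csv
```

Bayesian branch-rate test on the same data (desk-scale chains):

```r
pair <- generate_scenario_pair(spec)
aln   <- simulate_alignment(pair$mol_phylogram, nuc_model(), 1000, seed = 2)
chars <- simulate_characters(pair$morph_phylogram, morph_model(2), 100, seed = 3)
post <- run_mcmc(pair$chronogram, aln, chars,
                 clock = clock_model_spec("lognormal", "unlinked"),
                 settings = mcmc_settings(chain_length = 4e4, thin = 20, seed = 4))
summ <- summarize_branch_rates(post)
bayes_branchrate_test(summ$mol, summ$morph, statistic = "median")
```

## Command line

```sh
inst/cli/ratelink simulate --config cfg.json --outdir out/ --seed 3
inst/cli/ratelink infer-ml --topology t.nwk --aln a.fasta --chars c.nex --mode both --out fits
inst/cli/ratelink test --method rtt --mol mol.nwk --morph morph.nwk --n-perm 20000
inst/cli/ratelink evaluate --config grid.json --outdir results/ --seed 1
```

Config files are JSON with the same field names as `scenario_spec()` /
`grid_config()`.
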