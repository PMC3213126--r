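# ribopart

Partitioned Bayesian phylogenetics for multi-locus ribosomal DNA, with
simple indel coding and site-mixture models.

## The problem

Ribosomal supermatrices (SSU + ITS1–5.8S–ITS2 + LSU) mix conserved coding
regions with fast, indel-rich spacers. Before inferring a phylogeny from
such data one must choose a **partitioning regime** — how many partitions,
where the boundaries fall, whether the alignment gaps are recoded as their
own binary character partition, and whether within-partition heterogeneity
warrants a mixture of substitution processes. ribopart implements the full
comparison pipeline:

* **Simple indel coding (SIC)**: each distinct interior gap extent becomes a
  binary presence/absence character; containment inside a larger deletion is
  scored as inapplicable (`?`). Terminal gap runs are first converted to
  missing data (unsequenced flanks are not deletions).
* **Likelihood core**: GTR+Γ for nucleotides (4 discrete gamma categories,
  rate matrices scaled to one expected substitution per site per unit branch
  length), one- and two-parameter binary Markov models for the indel
  partition with the *variable-characters-only* ascertainment correction
  (the likelihood is conditioned on characters being variable, since an
  indel matrix contains no constant characters by construction), and
  K-component GTR+Γ site mixtures whose per-site likelihood is
  `sum_k w_k L(site | Q_k)`.
* **MCMC**: single-chain Metropolis–Hastings over topology (NNI), branch
  lengths (multipliers), simplex parameters (Dirichlet kernels) and the
  gamma shape; exponential priors on branch lengths and shape, Dirichlet(1)
  on simplices; bit-for-bit reproducible from the seed.
* **Model comparison**: stabilized harmonic-mean marginal likelihoods with
  block-bootstrap standard errors; `logBF = lnML_A − lnML_B` with the
  conventional `>2` positive / `>5` strong bands; mean −lnL, 95% HPD and
  tree length (TL) reported per regime; likelihood-saturation analysis over
  mixture components K.
* **Trees**: majority-rule consensus (strict `>` threshold) with supports
  equal to exact split frequencies (Bayesian posterior probabilities),
  mean branch lengths over supporting trees, clade posteriors, ASDSF
  convergence checks across replicate runs.
* **Synthetic data**: Yule trees, partition-heterogeneous GTR+Γ evolution,
  a superimposed branch-placed indel process with exact truth records, and
  the 15-regime catalog (2/4/6 partitions × indel-model variant × mixture
  ladder K = 1..7) for end-to-end validation.

## Worked example

Simulate a 20-taxon three-locus dataset with an indel-rich ITS-like block,
code the indels, and compare a 2-partition regime against a 4-partition
regime:

```r
library(ribopart)

sim <- simulate_study(n_taxa = 20,
                      part_lengths = c(ITS = 400L, LSU = 300L, SSU = 300L),
                      indel_rate = 0.02, seed = 7)
alignment_stats(sim$alignment)
#>   charset n_sites n_parsimony_informative prop_gap prop_missing
#> 1 ITS         400                     202   0.0555            0
#> 2 LSU         300                     234   0                 0
#> 3 SSU         300                     187   0                 0
indel_matrix_stats(sim$indel)
#>   n_characters n_parsimony_informative
#> 1           27                      15

ds  <- list(alignment = sim$alignment, indel = sim$indel)
cfg <- mcmc_config(n_generations = 4000, sample_interval = 10,
                   burn_in_generations = 2000, seed = 7)
t2  <- run_regime(ds, "2 partitions A", cfg)
t4  <- run_regime(ds, "4 partitions A", cfg)

cmp <- comparison_table(list(`2 partitions A` = t2, `4 partitions A` = t4))
cmp$table
#>   regime         mean_neg_lnl hpd_half_width mean_tl    lnml lnml_se
#> 1 2 partitions A       11451.           6.64    3.02 -11457.   1.46
#> 2 4 partitions A       10930.           8.00    3.43 -10936.   0.684
cmp$bf_matrix["4 partitions A", "2 partitions A"]
#> [1] 520.5772
bf_verdicts(cmp)["4 partitions A", "2 partitions A"]
#> [1] "strong"
```

The 4-partition regime (separate ITS/LSU/SSU models plus the indel
partition) beats the pooled 2-partition regime by ~520 log units of
evidence — "strong" on the conventional scale — and recovers a longer tree
(mean TL 3.43 vs 3.02), the signature of a model detecting superimposed
substitutions that the pooled model averages away. A consensus phylogram
with posterior supports comes from the sampled trees:

```r
cons <- majority_rule_consensus(post_burnin_trees(t4))
clade_posterior(post_burnin_trees(t4), c("t12", "t19"))
#> [1] 1
```

Traces are tibbles; `tidy()`, `glance()` and `autoplot()` work on traces
and comparison objects, and `saturation_sweep()` + `plot_saturation()`
produce the lnL-vs-K saturation curve for the mixture ladder.

A thin command-line front end over the same functions ships in
`inst/cli/ribopart.R` (subcommands `simulate`, `encode-indels`, `stats`,
`run`, `compare`, `consensus`, `saturation`).

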