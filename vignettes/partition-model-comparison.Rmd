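---
title: "Comparing partitioning regimes for ribosomal multi-locus phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing partitioning regimes for ribosomal multi-locus phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopart)
```

## The problem

Multi-locus ribosomal DNA datasets (SSU, the ITS1–5.8S–ITS2 region, LSU)
mix slowly evolving coding regions with fast, indel-rich spacers. A Bayesian
phylogenetic analysis of such a supermatrix must decide how to partition the
columns and which substitution process to give each partition, and whether
the alignment gaps — which carry phylogenetic signal of their own — should be
recoded and modeled. ribopart implements this whole decision pipeline at
desk scale: simple indel coding (SIC), partitioned GTR+Γ / binary-Markov /
site-mixture likelihoods, Metropolis–Hastings MCMC, Bayes-factor comparison
of partitioning regimes, likelihood-saturation analysis over mixture
components, and majority-rule consensus trees with posterior supports, plus
a synthetic-data generator so every stage can be validated against known
truth.

## Models and their assumptions

**Nucleotide partitions** evolve under GTR+Γ: a reversible rate matrix
parameterised by six exchangeabilities (a 6-simplex; the scale is not
identifiable) and four stationary frequencies, with among-site rate
variation from a discretized gamma distribution. We fix the number of
gamma categories at four, the field's convention, using mean-of-category
discretization over equiprobable quantile bins. A proportion-of-invariant-
sites parameter is deliberately absent: it absorbs the same signal as the
gamma shape and the two are notoriously non-identifiable together.

Every rate matrix is rescaled so a branch length of 1 means one expected
substitution per site. This makes tree lengths (TL, the edge-length sum)
comparable across partitioning regimes — a model that detects more hidden,
superimposed substitutions recovers a longer tree, which is itself a
diagnostic output of the comparison.

**The indel partition.** Gap extents in the spacer alignment are recoded by
simple indel coding: each distinct maximal interior gap run (start, end)
observed in at least one taxon becomes one binary presence/absence
character. A taxon scores 1 when it has a gap of exactly that extent, `?`
when one of its gaps strictly contains the extent (the character is
inapplicable inside a larger deletion — SIC variants differ here and this
choice follows the containment-as-missing operationalisation of the
FastGap-style coders), and 0 otherwise, including partial non-nested
overlap. A taxon unsequenced across the whole extent also scores `?`,
because absence of the indel cannot be asserted from absent data. Terminal
gap runs are converted to missing *before* coding (they are unsequenced
flanks, not deletions); the trimming rule is: per-taxon leading and
trailing gap runs become `?`, then columns missing in every taxon are
dropped. Interior gaps are never touched, so they remain codable.

The binary characters evolve under a one-parameter (symmetric) or
two-parameter (free stationary frequencies) reversible two-state Markov
model. Because an indel matrix contains no constant characters *by
construction*, the likelihood is conditioned on variability: each
character's likelihood is divided by `1 − P(constant pattern)` computed on
the same tree (the "variable-only" ascertainment correction). Without the
correction, branch lengths on the indel partition are systematically
underestimated.

**Site mixtures.** A K-component mixture fits K GTR+Γ matrices
simultaneously; each site's likelihood is the weighted sum over components,
so heterogeneous processes are captured without pre-assigning sites to
partitions. Components share the gamma shape, the category count and the
branch lengths; weights live on a K-simplex. Mixture implementations
differ on whether shapes are shared between components; sharing keeps the
parameterisation identifiable and is this package's documented choice.

**Partitioned totals.** A partitioning regime assigns one model per
partition; topology and branch lengths are shared while statefreq, revmat
and shape are unlinked. There are no per-partition rate multipliers — only
the three parameter blocks above are unlinked — so the total log-likelihood
is a plain sum over partitions.

## The sampler

A single cold Metropolis–Hastings chain (no Metropolis coupling — a
documented deviation from MrBayes-style defaults, adequate at the ≤50-taxon
scales this package targets) proposes, one per generation:

* **topology**: nearest-neighbour interchange (NNI) on a random internal
  edge. No SPR — a documented limitation for large trees.
* **branch lengths**: multiplier `exp(tune × (U − ½))` on one edge (always
  positive, so no reflection is needed).
* **simplex parameters** (exchangeabilities, frequencies, mixture weights):
  Dirichlet kernels centred on the current value, with the proposal
  concentration a tuning constant; with thousands of sites the posterior is
  tight and concentrations of a few thousand keep acceptance near 25%.
* **gamma shape**: log-scale multiplier.

Priors: i.i.d. exponential on branch lengths (default mean 0.1,
configurable — branch-length priors are known to move marginal likelihoods
materially, so this is a first-class config item), exponential (mean 1) on
the gamma shape, flat Dirichlet(1) on all simplices, uniform on topologies.
Burn-in is a fixed configured value plus diagnostics, not auto-detected.
Identical seeds reproduce a chain bit-for-bit.

Convergence diagnostics: autocorrelation-time ESS for scalar traces, and
the average standard deviation of split frequencies (ASDSF) across
replicate runs for topology, with the conventional < 0.01 flag. Study runs
refuse to pool replicate tree samples into a consensus when ASDSF fails,
unless forced.

## Comparing regimes

The regime catalog holds the fifteen standard designs: 2/4/6-partition
layouts of {pooled nucleotides | ITS, LSU, SSU | ITS1, 5.8S, ITS2, LSU,
SSU} plus the indel partition; the indel model one- or two-parameter; and a
mixture ladder K = 1..7 on the 6-partition layout. The "C" regimes are the
ladder's K = 1 baseline at each partition count.

Model evidence is estimated by the harmonic mean of sampled likelihoods,
computed stably in log space, with a Newton–Raftery δ-mixture stabilisation
(δ = 0.01) as the default and the naive log harmonic mean available for
comparison; a moving-block bootstrap provides a standard error. The
harmonic mean is known to carry an upward bias and to favour
parameter-rich models — our conjugate-model calibration puts the bias
under one log unit at a few hundred samples, well below the decision
thresholds — so verdicts use the conventional logBF > 2 (positive) and
> 5 (strong) bands, and mean −lnL and the evidence are always reported
separately, never conflated. HPD intervals are shortest sorted windows
with left-most tie-breaking.

The saturation analysis takes mean post-burn-in lnL against K and reports
successive improvements; the plateau is the first K whose improvement
drops below 10% (configurable) of the first step's improvement.

## The synthetic-data generator

`simulate_study()` emulates the structure of a ribosomal supermatrix
study: a Yule topology (pure birth) with i.i.d. exponential branch lengths
scaled to a target tree length; 3–5 nucleotide partitions evolving under
visibly distinct GTR+Γ processes (different exchangeabilities, frequencies
and shapes); an ITS-like first block on which a superimposed deletion
process places events on branches (Poisson counts proportional to branch
length, geometric lengths) inherited by all descendant taxa; and the SIC
binary partition derived from the result. The indel process is an
annotation layer over the substitution simulation, not a TKF-style
integrated insertion–deletion model: this keeps the truth bookkeeping
exact, because SIC recovery — not alignment inference — is the object
under test. Alignments are always already aligned; the generator never
creates alignment uncertainty, column misassignment, or the
concerted-evolution and secondary-structure constraints of real rDNA.
Passing tests therefore validate the pipeline's statistics and inference
machinery, not robustness to alignment error.

Default scales are 20–30 taxa and 1–3 kb so that a full pipeline exercise
finishes in minutes; the ~90-taxon scale of real studies is reachable
through the same configuration arguments.

## Numerical choices

* Likelihoods use Felsenstein pruning over compressed site patterns in
  compiled code, with per-pattern rescaling to avoid underflow; mixture
  and gamma classes are evaluated as a flat class list and combined by
  log-sum-exp.
* Transition matrices come from the eigendecomposition of the symmetrised
  reversible rate matrix; negative round-off entries are clamped at zero
  and rows renormalised.
* Internal column coordinates are 1-based inclusive (R convention); the
  single conversion point to the NEXUS standard's 1-based inclusive ranges
  is the I/O boundary, so charsets round-trip bit-exactly.
* Parsimony-informative counting excludes gaps, `?` and IUPAC ambiguity
  codes from the state tally (standard parsimony convention).
* Consensus uses strictly-greater-than-threshold split inclusion (ties at
  50% are excluded), which guarantees compatibility; supports are exact
  split frequencies; consensus branch lengths are means over the trees
  containing each split; split tabulation ties break on the lexicographic
  taxon bitmask.
* Degenerate inputs error early and specifically: ragged FASTA rows name
  the offending taxon, unknown symbols report the column, empty
  post-exclusion alignments refuse to proceed, and a zero-likelihood MCMC
  start suggests a different seed or start tree.

## Study sizes used by the shipped checks

The test suite and the acceptance script run the pipeline end-to-end at
sizes chosen as this package's desk-scale defaults: regime recovery on 30
taxa with three 300-site heterogeneous partitions and 3000-generation
chains (the matched-regime Bayes factor is in the hundreds of log units,
so short chains lose no discriminating power); mixture saturation on
20-taxon, 600-site two-component data; parameter recovery on 30 taxa ×
2000 sites (α = 0.5) with 7000-generation chains, topology fixed at the
generating tree so the check targets substitution-parameter calibration;
prior-only runs of 4–5 × 10⁴ generations. Real-study presets (millions of
generations, sampling every 1000th) are plain configuration values.

## Known limitations

* NNI-only topology moves and a single cold chain mix slowly on large or
  flat posteriors; the package targets desk-scale validation studies, not
  production inference on hundreds of taxa.
* The harmonic-mean evidence estimator, even stabilised, has high variance
  and a systematic bias toward complex models; Bayes factors within a few
  log units of a threshold should not be over-interpreted.
* SIC recovery degrades when indel events overlap densely (merged gap runs
  are coded as single extents); the generator's defaults keep expected
  overlap low, as in typical spacer alignments.
* Per-parameter credible-interval coverage at desk-scale chain lengths is
  Monte-Carlo-limited (ESS of tens to low hundreds); calibration checks
  pool across parameters accordingly.
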