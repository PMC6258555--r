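---
title: "Models and methods behind radpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpop)
```

# The scientific problem

radpop studies pairs of locally adapted ecotypes — in the motivating system,
short-winged beetles of tidal salt marshes versus long-winged beetles of
seasonally inundated marshes — using reduced-representation (RAD-like) SNP
and haplotype data. Three questions drive the toolkit:

1. **How did the two ecotypes diverge demographically?** Fitted on the joint
   allele frequency spectrum (JAFS) of a population pair.
2. **What distinguishes the genomic islands of divergence from the rest of
   the genome?** Per-locus haplotype statistics, outgroup normalization, and
   an empirical outlier scan.
3. **How much standing variation for the alternative ecotype does each
   population carry?** Allele classification, per-individual carriage, and
   resampling accumulation curves.

A structured-coalescent simulator generates data under the same model family
the inference assumes, providing ground truth for every pipeline stage.

# The divergence model family

Two demes (sizes `nu1`, `nu2` relative to the ancestral population) split
from a single ancestral deme of size 1 at time `tS`; time is measured in
units of `2 N_A` generations. Three gene-flow histories are expressible:

* **SI** — strict isolation: no migration after the split.
* **IM** — isolation with migration: constant migration since the split.
* **SC** — secondary contact: isolation from `tS` until `tSC`, then
  migration.

Migration is parameterized by the population rate `M_{i<-j} = 2 N_A m`,
where `m` is the per-generation probability that a gene copy in deme `i`
was contributed by deme `j`. Backward in time a lineage in deme `i`
therefore switches demes at rate `M_{i<-j}` per unit scaled time. This
convention makes the unit conversions exact identities: the simulator's
realized per-generation migrant fraction is `M / (2 N_A)`, the same
quantity the conversion layer reports.

Two heterogeneity flags capture the genomic consequences of divergent
selection without modelling selection dynamics:

* **2M (genomic islands)** — a fraction `P` of loci experiences reduced
  effective migration rates `MI` instead of `M`, in every epoch where
  migration is active.
* **hrf (linked selection)** — a fraction `Q` of loci has all effective
  sizes multiplied by a factor `hrf` in `(0, 1]`.

The two fractions are independent, so a locus is neutral / island / hrf /
island+hrf with probabilities `(1-P)(1-Q)`, `P(1-Q)`, `(1-P)Q`, `PQ`, and
the expected JAFS is the corresponding four-component mixture.

**Design choice — hrf scope.** Whether the linked-selection size reduction
also applies to the ancestral deme is genuinely open; radpop applies `hrf`
to all epochs, ancestral deme included, on the grounds that background
selection is a property of the locus (its local recombination and gene
density), not of an epoch. The mixture construction makes the alternative
easy to express by editing `.kernelArgs`, and none of the package's checks
depend on the choice.

**Design choice — island migration in every active epoch.** Island loci use
`MI` whenever migration is active (the IM phase and/or after secondary
contact). The wording of the model family leaves open whether islands are
only reduced at secondary contact; applying the reduction uniformly keeps
`P` interpretable as a time-invariant property of the locus.

# The simulator

`simulateLocus()` / `simulateDataset()` run a standard backward-in-time
structured coalescent per locus: competing exponential events (pairwise
coalescence at rate `1/nu_i` within a deme, per-lineage migration) with
epoch boundaries at the migration switch-off and the split. Mutation is
infinite-sites: the number of segregating sites is Poisson with mean
`theta_locus / 2` times the total branch length, each mutation placed on a
branch proportionally to its length and assigned a distinct position on the
locus. The kernel is implemented in C++ (as the field's coalescent
simulators are) and draws all randomness from R's RNG, so a single
`set.seed()` governs bit-identical reproduction.

An outgroup is attached by extending the root to the outgroup divergence
time: mutations on the ingroup stem are derived in all ingroup copies,
mutations on the outgroup branch are private to the outgroup, and the
outgroup allele defines the ancestral state for polarization. Diploid
individuals are formed by random pairing of haploid copies within a deme.

The default synthetic scenario (`demoScenario()`) emulates the
RAD-like study design: hundreds of 1,200-bp loci, 8 diploids per deme, an
island fraction `P = 0.3` (matching the observed 27–33% of the genome with
restricted gene flow), islands at 25% of the neutral migration rate (the
mid-range of the observed 31–99% reductions), secondary contact at one tenth of the
split time (the observed ratios range from roughly 0.04 to 0.2), and an
outgroup six split-times away (the outgroup species diverged several-fold
deeper than the ecotype split). The linked-selection settings `Q = 0.3`,
`hrf = 0.5` are plausible round values chosen once; the study system
provides no printed estimate for them. What the generator does **not**
emulate: within-locus recombination, sequencing error and depth variation,
missing data patterns, more than two demes, and selection acting during the
simulated history (selection is represented demographically through the
locus classes). Tests passing on these data therefore validate the
estimators and their implementation, not robustness to those real-data
complications.

# Spectra

`buildJafs()` counts, per segregating site, the derived copies in each
population. Missing genotypes are handled by per-site hypergeometric
projection to a target sample size (the standard projection trick, chosen
over discarding incomplete sites to mirror the ≥80%-presence retention
rule); sites with fewer called copies than the target are dropped.
`projectJafs()` applies the same hypergeometric redistribution to whole
spectra, `foldJafs()` collapses to minor-allele counts (ambiguous diagonal
cells carry half mass in each complementary cell so that total mass is
conserved), and the fixed corners `(0,0)` and `(n1,n2)` are always masked.
`readSfs()`/`writeSfs()` speak the de-facto plain-text SFS format of
diffusion-based SFS software. The question whether "projected to 24
individuals" means 24 diploids (48 copies) or 24 copies is left to the
caller — `projectJafs(j, 48, 48)` and `projectJafs(j, 24, 24)` are both
one-liners, and no default asserts either reading.

# Expected spectra, likelihood, and fitting

`expectedJafs()` estimates the expected JAFS per unit `theta` by Monte
Carlo: over replicate genealogies, the branch length subtending each
frequency class `(i, j)` is accumulated, and
`E[sites in class] = theta/2 * E[length]`. This branch-length weighting
removes all mutational noise from the estimate. The engine runs under a
fixed seed (common random numbers), making the likelihood surface a
deterministic function of the parameters whose precision is set by `reps`.
A deterministic diffusion solver would satisfy the same contract; the Monte
Carlo engine was chosen because it reuses the simulator kernel exactly, so
the generative model and the inference model agree by construction.

The fit maximizes a Poisson composite likelihood in which each unmasked
cell is an independent Poisson count with mean `theta * F[i, j]`; `theta`
is profiled analytically (`theta_hat = sum O / sum F`), so it never enters
the search space and is not counted in `k`. `AIC = 2k - 2 lnL` with `k`
the number of free demographic parameters.

**Design choice — the optimizer.** The residual Monte-Carlo noise of the
engine (hundreds of log-likelihood units on a 30,000-locus spectrum, driven
by rare frequency classes) defeats simplex descent: Nelder-Mead contracts
its simplex into the noise floor long before reaching the optimum. radpop
instead uses a two-stage compass (pattern) search on log10 parameters —
coordinate steps starting at half a decade and shrinking geometrically ride
the macro-scale gradient through the noise, followed by a refinement stage
at four times the engine precision. The replicated-runs protocol is kept:
each of `nStarts` runs starts from the best point so far perturbed by a
factor `U(1/3, 3)` per coordinate (the first from the geometric midpoint of
the bounds), and the replicate table records every run with the best five
flagged. Runs ending on a bound are flagged `bound-pinned`. A `symmetricM`
option ties `M21 = M12` (and `MI21 = MI12`); whether island migration
reduction is direction-specific is not asserted — both forms are
expressible.

Numerical notes: parameters are searched in log10 space within positive
bounds; `tSC` is clamped to `tS` whenever a proposal inverts the order;
an expected-spectrum cell of zero under observed data raises an error
(demanding more `reps`) rather than being clamped, because silently
flooring `log F` would bias the fit toward imprecise regions.

# Biological units

With the outgroup calibration — per-site divergence `d_out` and divergence
time `T_div` — the yearly mutation rate is `mu = (d_out / 2) / T_div`
(half the divergence accrues on each lineage). Then
`N_A = theta / (4 mu_gen L)`, `N_i = nu_i N_A`, `T = 2 N_A t` generations,
and `m_{i<-j} = M_{i<-j} / (2 N_A)`; `nu_i M_{i<-j}` is the effective
number of immigrant gene copies per generation. One generation per year is
the default (`genPerYear` exposes the assumption; the beetle is annual).

# Per-locus statistics

Nucleotide diversity and `d_XY` are mean per-site pairwise differences
(within and between groups), with missing alleles dropped pairwise.
Tajima's D uses the standard constants; it is reported as `NA` when no
site segregates rather than forced to a number. Haplotype F_ST is the
`1 - H_w / H_b` form (mean within-group over mean between-group pairwise
difference); per-SNP F_ST is the Weir–Cockerham variance-components
estimator with ratio-of-sums aggregation across loci, and negative values
are reported as-is for unbiased averaging. Both estimators are provided
because field practice computes both; the haplotype form has several
published variants, and the implemented one is declared rather than claimed
to be any particular historical variant. For loci carrying an outlier SNP,
haplotype groups can be split by base composition at the most strongly
supported SNP (`splitAt`), reproducing the grouping used for `pi_S` versus
`pi_L` comparisons. Dividing `d_XY` and `pi` by the per-locus divergence to
the outgroup removes the locus mutation-rate dependence.

The empirical outlier scan ranks per-SNP F_ST values and flags strict
exceedances of an upper quantile, assigning `-log10` empirical tail
probabilities as support scores. It deliberately stands in for model-based
Bayesian outlier detectors, which are out of scope; any external
support table can be supplied in their place.

# Standing genetic variation

Given classified outlier SNPs (one per RAD-tag, the most supported), the
allele associated with an ecotype is the pooled-frequency majority allele
across all populations of that ecotype — a symmetric, deterministic rule;
ties are flagged unassignable and excluded. Carriage of the
alternative-ecotype allele is counted per individual (missing genotypes
leave that individual's denominator), and `accumulationCurve()` resamples
`N` individuals without replacement, 100 replicates by default, recording
the proportion of outlier loci with at least one carrier. The closed-form
expectation `sum_l (1 - C(n - k_l, N) / C(n, N)) / L` is implemented
separately and doubles as the oracle for the Monte-Carlo path. Sampling
pools individuals within the focal ecotype by default; per-population
cohorts are an option, and neither mode is asserted as the original
figure's exact cohort definition.

# Problem sizes and verification scope

The test suite validates: coalescent expectations (`E[pi] = theta`, the
`theta / i` frequency spectrum at `n = 10` over 20,000 loci, island-model
F_ST against the closed form `1/(1 + 4M)`), agreement of the simulator's
joint spectrum with an independent coalescent simulator (total-variation
distance below 0.02 at 100,000 loci), parameter recovery on ten
30,000-locus secondary-contact datasets (median relative error of `nu2`
and `M` within 50%, positive rank correlation of `tS`), AIC model
selection (island-model data prefer SC2M over SI in at least 9 of 10
replicates at 5,000 loci), exact oracle agreement for every statistic, and
the closed-form accumulation expectation against exhaustive enumeration.
These sizes were chosen as the smallest at which the Monte-Carlo bounds
above are meaningful; larger runs only tighten them.

# Known limitations

* The expected-JAFS engine is stochastic; fits inherit a noise floor that
  limits parameter resolution to roughly 10–30% at the default precisions,
  which is also why replicated noisy-surface searches, not gradient
  methods, are used.
* No recombination within loci, no ancestral-misidentification correction
  (fold instead), no 3+ population models, no bootstrap/Godambe
  uncertainty.
* Asymmetric deme-specific `P` fractions are not expressible.
* Read-level filters (depth, genotype quality) are assumed applied
  upstream; the retention filters start from called genotypes.
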