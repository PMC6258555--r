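# radpop

Demographic inference and standing-variation analysis for two-ecotype
RAD-seq data.

## The problem

Populations that repeatedly adapt to the same contrasting habitats — here,
short-winged beetles of tidal salt marshes (`S`) versus long-winged beetles
of seasonally inundated marshes (`L`) — raise two linked questions: *how did
the ecotype pairs diverge demographically*, and *how much standing genetic
variation for the alternative ecotype does each population carry*? radpop
implements the full analysis chain for multi-locus SNP/haplotype data of a
population pair, together with a structured-coalescent simulator that
generates data under the same model family and provides ground truth for
every stage.

## The models at its core

**Divergence models on the joint allele frequency spectrum (JAFS).** Two
demes of relative sizes ν₁, ν₂ split from an ancestral population of size
N_A at time t_S (scaled by 2 N_A generations), with migration M_{i←j} = 2
N_A m either absent (SI), continuous (IM), or resumed at a secondary-contact
time t_SC (SC). Genomic heterogeneity enters through a fraction *P* of loci
with reduced island migration rates M(I) ("2M") and a fraction *Q* with all
effective sizes multiplied by *hrf* ("hrf", linked selection); the expected
spectrum is the four-component mixture. Fitting maximizes a Poisson
composite likelihood with θ profiled analytically, over replicated
derivative-free searches on log10 parameters, and models are ranked by
AIC = 2k − 2 lnL. Scaled estimates convert to biological units through the
outgroup-calibrated mutation rate μ = (d_out/2)/T_div, N_A = θ/(4μL),
T = 2 N_A t and m = M/(2 N_A).

**Per-locus statistics.** Nucleotide diversity π, absolute divergence d_XY,
Tajima's D, haplotype F_ST (1 − H_w/H_b) and per-SNP Weir–Cockerham F_ST,
with outgroup normalization (d_XY / d_XY,outgroup), LD decay, Mantel tests
and an empirical F_ST outlier scan.

**Standing variation.** For outlier SNPs (one per RAD-tag, the most
supported), the allele associated with each ecotype is the pooled-frequency
majority allele; the package reports per-individual carriage of
alternative-ecotype alleles and accumulation curves — the proportion of
outlier loci at which a random sample of N individuals carries at least one
alternative-ecotype allele, averaged over 100 replicates — plus the exact
hypergeometric expectation Σ_l [1 − C(n−k_l, N)/C(n, N)]/L.

## Worked example

Simulate a secondary-contact scenario with genomic islands, fit two
competing models, and quantify standing variation:

```r
library(radpop)

spec <- ScenarioSpec("SC2M",
  DemographyParams(nu1 = 1, nu2 = 1, tS = 1.5, tSC = 0.1,
                   M12 = 2, M21 = 2, MI12 = 0.04, MI21 = 0.04, P = 0.3),
  n1 = 8, n2 = 8, nLoci = 5000, locusLength = 1200,
  thetaLocus = 1, seed = 501L)
d <- simulateDataset(spec)
j <- buildJafsFromHaplotypes(d$haplotypes)
j
#> Jafs: 9 x 9 (unfolded), 2 masked cells, total mass 2.93e+04

fSI <- fitDemography(j, "SI",   nStarts = 1, reps = 300, maxit = 50,
                     engineSeed = 13L, seed = 1L)
fSC <- fitDemography(j, "SC2M", nStarts = 1, symmetricM = TRUE,
                     reps = 300, maxit = 50, engineSeed = 13L, seed = 1L)
c(AIC_SI = aic(fSI), AIC_SC2M = aic(fSC))
#>   AIC_SI AIC_SC2M
#> 7379.148  951.470
```

The island model wins by roughly 6,400 AIC units: strict isolation cannot produce
the shared intermediate-frequency polymorphism that post-contact gene flow
leaves in the spectrum. Converting the fitted parameters with the
outgroup calibration (per-site divergence 0.03587, split 620,000 years,
so μ ≈ 2.9×10⁻⁸ mutations/site/year):

```r
bio <- convertToBiological(fSC, calibrationInputs(0.03587, 620000,
                                                  L = 5000 * 1200))
round(c(N_A = bio$NA_, T_S_years = bio$TS_years, m12 = bio$m12), 8)
#>          N_A    T_S_years          m12
#> 6.552066e+03 2.442999e+04 5.396000e-05
```

the ancestral size in individuals, the split time in years and the
per-generation migrant fraction implied by the fit. The standing
variation side on the same data:

```r
wc   <- fstWC(d$genotypes)
scan <- empiricalOutlierScan(wc$fst, q = 0.95)
```

followed by `selectTopSnpPerLocus()`, `classifyAlleles()`,
`perIndividualCarriage()` and `accumulationCurve()` — see
`runDemoPipeline(seed = 1)` for the whole chain wired together (it writes
VCF, FASTA, SFS and TSV outputs plus a seed-stamped log), and
`vignettes/radpop-methods.Rmd` for the modelling choices.

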