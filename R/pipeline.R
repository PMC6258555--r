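#' @include AllClasses.R constructors.R simdata.R spectra.R demography.R
#' @include unitconv.R popstats.R standvar.R filters.R io.R
NULL

#' Default synthetic study scenario
#'
#' The generator's stand-in for a RAD-like two-ecotype dataset: a secondary
#' contact model with heterogeneous gene flow and linked selection
#' (`SC2M_hrf`), 800 loci of 1,200 bp, 8 diploid individuals per deme, an
#' island fraction `P = 0.3` with island migration at 25% of the neutral
#' rate (the mid-range of observed island reductions), a linked-selection
#' fraction `Q = 0.3` with effective size halved,
#' split time 1 and secondary contact 0.1 (in units of 2 N_A generations),
#' and an outgroup at 6 split-time units. `thetaLocus = 5` gives realistic
#' per-site diversities of roughly 0.004 at 1,200 bp loci.
#'
#' @param seed RNG seed.
#' @param nLoci,n1,n2 optional size overrides.
#' @return a [ScenarioSpec-class].
#' @export
demoScenario <- function(seed = 1L, nLoci = 800L, n1 = 16L, n2 = 16L) {
  ScenarioSpec("SC2M_hrf",
               DemographyParams(nu1 = 0.5, nu2 = 1, tS = 1, tSC = 0.1,
                                M12 = 2, M21 = 2, MI12 = 0.5, MI21 = 0.5,
                                P = 0.3, Q = 0.3, hrf = 0.5),
               n1 = n1, n2 = n2, nLoci = nLoci, locusLength = 1200L,
               thetaLocus = 5, outgroupTime = 6, seed = seed)
}

#' Run the full synthetic pipeline end to end
#'
#' Chains every stage on a synthetic dataset: simulation (with truth labels),
#' VCF / FASTA / TSV export, SNP filtering, JAFS construction, a reduced-scale
#' model comparison (SI vs SC), conversion of the best fit to biological
#' units, per-locus haplotype statistics with outgroup normalization, a
#' per-SNP F_ST outlier scan, allele classification and standing-variation
#' accumulation curves. Every run writes a log with the seed and parameter
#' echo; identical seeds reproduce identical outputs.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @param nLoci number of loci simulated.
#' @param fitReps,fitStarts,fitMaxit reduced-scale engine precision and
#'   optimizer effort for the demo model comparison.
#' @return invisibly, a list with the simulated data, filter report, fitted
#'   model table, biological estimates, locus statistics, outlier table and
#'   accumulation curves.
#' @export
runDemoPipeline <- function(seed = 1L, dir = tempfile("radpop_demo"),
                            nLoci = 400L, fitReps = 300L, fitStarts = 3L,
                            fitMaxit = 150L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- demoScenario(seed = seed, nLoci = nLoci)
  log <- c(sprintf("radpop %s demo pipeline", as.character(utils::packageVersion("radpop"))),
           sprintf("seed: %d", seed),
           sprintf("scenario: %s", spec@modelId),
           sprintf("params: %s", paste(names(paramVector(spec@params)),
                                       paramVector(spec@params),
                                       sep = "=", collapse = " ")),
           sprintf("nLoci: %d locusLength: %d thetaLocus: %g", spec@nLoci,
                   spec@locusLength, spec@thetaLocus))

  d <- simulateDataset(spec, popNames = c("popS", "popL"),
                       ecotypes = c("S", "L"), habitat = c(-1, 1))
  writeGenotypeVcf(d$genotypes, file.path(dir, "genotypes.vcf"))
  writeHaplotypesFasta(d$haplotypes, file.path(dir, "haplotypes.fasta"),
                       ecotypes = c(popS = "S", popL = "L"))
  write.table(d$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sampleMetadata(d$genotypes), file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  filt <- applyFilters(d$genotypes, minMaf = 0.01, minPresence = 0.8)
  write.table(filt$report, file.path(dir, "filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  jafs <- buildJafs(d$genotypes, "popS", "popL")
  writeSfs(jafs, file.path(dir, "jafs.sfs"))
  jproj <- projectJafs(jafs, 12, 12)

  cmp <- compareModels(jproj, c("SI", "SC"), nStarts = fitStarts,
                       reps = fitReps, maxit = fitMaxit, engineSeed = seed,
                       seed = seed)
  write.table(cmp[, c("model", "k", "lnL", "AIC", "dAIC")],
              file.path(dir, "model_comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  best <- attr(cmp, "fits")[[cmp$model[1]]]

  calib <- calibrationInputs(dOut = 0.03587, TDivYears = 620000,
                             L = as.numeric(spec@nLoci) * spec@locusLength)
  bio <- convertToBiological(best, calib)

  stats <- locusStats(d$haplotypes, groupS = "popS", groupL = "popL")
  stats <- normalizeByOutgroup(stats)
  write.table(stats, file.path(dir, "locus_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  wc <- fstWC(d$genotypes)
  scan <- empiricalOutlierScan(wc$fst, q = 0.95)
  rd <- SummarizedExperiment::rowData(d$genotypes)
  outliers <- data.frame(snp = rownames(wc), locus = rd$locus, pos = rd$pos,
                         support = scan$support,
                         stringsAsFactors = FALSE)[scan$outlier, ]
  outliers <- selectTopSnpPerLocus(outliers)
  outliers <- classifyAlleles(d$genotypes, outliers)
  write.table(outliers, file.path(dir, "outliers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  carriage <- perIndividualCarriage(d$genotypes, outliers, "L")
  nL <- sum(SummarizedExperiment::colData(d$genotypes)$ecotype == "L")
  curve <- accumulationCurve(d$genotypes, outliers, "L",
                             NGrid = seq_len(min(8L, nL)), reps = 100L,
                             seed = seed)
  write.table(data.frame(N = curve@N, mean = curve@mean, sd = curve@sd,
                         reps = curve@reps, seed = curve@seed),
              file.path(dir, "accumulation_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  log <- c(log, sprintf("best model: %s (dAIC runner-up: %.2f)",
                        cmp$model[1], cmp$dAIC[2]),
           sprintf("outlier SNPs kept: %d", nrow(outliers)))
  writeLines(log, file.path(dir, "run_log.txt"))

  invisible(list(dir = dir, scenario = spec, data = d,
                 filterReport = filt$report, jafs = jafs,
                 modelComparison = cmp, bestFit = best, biological = bio,
                 locusStats = stats, outliers = outliers,
                 carriage = carriage, curve = curve))
}
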