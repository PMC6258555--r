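#' Demographic model parameters
#'
#' Parameter vector of the two-deme divergence model family. Sizes are relative
#' to the ancestral population (`nu1`, `nu2`, dimensionless), times are in
#' units of 2 N_A generations (`tS` split time, `tSC` onset of secondary
#' contact), migration is the population rate `M = 2 N_A m` (gene copies per
#' unit scaled time; `M12` into population 1 from population 2). `MI*` are the
#' island-class (reduced) migration rates, `P` the island fraction of the
#' genome, `Q` the fraction under linked selection with effective size scaled
#' by `hrf`, and `theta` the dataset-wide ancestral mutation rate
#' `theta_A = 4 N_A mu L`.
#'
#' @slot nu1,nu2 numeric, relative deme sizes (> 0).
#' @slot tS,tSC numeric, split and secondary-contact times (`tSC <= tS`).
#' @slot M12,M21,MI12,MI21 numeric, population migration rates (>= 0).
#' @slot P,Q numeric in `[0, 1]`, heterogeneity fractions.
#' @slot hrf numeric in `(0, 1]`, linked-selection size reduction factor.
#' @slot theta numeric, `4 N_A mu L` (NA until estimated).
#'
#' @export
setClass("DemographyParams",
  slots = c(nu1 = "numeric", nu2 = "numeric", tS = "numeric", tSC = "numeric",
            M12 = "numeric", M21 = "numeric", MI12 = "numeric",
            MI21 = "numeric", P = "numeric", Q = "numeric", hrf = "numeric",
            theta = "numeric"),
  prototype = prototype(nu1 = 1, nu2 = 1, tS = 1, tSC = 0, M12 = 0, M21 = 0,
                        MI12 = 0, MI21 = 0, P = 0, Q = 0, hrf = 1,
                        theta = NA_real_)
)

setValidity("DemographyParams", function(object) {
  num <- c(nu1 = object@nu1, nu2 = object@nu2, tS = object@tS,
           tSC = object@tSC, M12 = object@M12, M21 = object@M21,
           MI12 = object@MI12, MI21 = object@MI21, P = object@P,
           Q = object@Q, hrf = object@hrf)
  if (any(lengths(lapply(num, I)) != 1L) || any(!is.finite(num)))
    return("all parameters must be finite scalars")
  if (any(num < 0)) return("all parameters must be >= 0")
  if (object@nu1 <= 0 || object@nu2 <= 0) return("nu1 and nu2 must be > 0")
  if (object@tSC > object@tS) return("tSC must not exceed tS")
  if (object@P > 1 || object@Q > 1) return("P and Q must lie in [0, 1]")
  if (object@hrf <= 0 || object@hrf > 1) return("hrf must lie in (0, 1]")
  TRUE
})

#' Simulation scenario
#'
#' Full specification of a synthetic multi-locus dataset: model identifier
#' (`"SI"`, `"IM"`, `"SC"`, optionally suffixed `"2M"` and/or `"_hrf"`, e.g.
#' `"SC2M_hrf"`), parameters, haploid sample sizes per deme, locus count and
#' length, per-locus population mutation rate `theta_locus = 4 N_A mu l`, an
#' optional outgroup divergence time (units of 2 N_A generations), and a seed.
#'
#' @slot modelId character model identifier.
#' @slot params a [DemographyParams-class] object.
#' @slot n1,n2 integer haploid sample sizes (>= 2).
#' @slot nLoci integer number of loci (>= 1).
#' @slot locusLength integer locus length in bp.
#' @slot thetaLocus numeric per-locus population mutation rate (> 0).
#' @slot outgroupTime numeric scaled outgroup divergence time, `NA` for none;
#'   when present must exceed `params@tS`.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("ScenarioSpec",
  slots = c(modelId = "character", params = "DemographyParams",
            n1 = "integer", n2 = "integer", nLoci = "integer",
            locusLength = "integer", thetaLocus = "numeric",
            outgroupTime = "numeric", seed = "integer")
)

setValidity("ScenarioSpec", function(object) {
  if (is.null(parseModelId(object@modelId)))
    return(sprintf("unknown model id '%s'", object@modelId))
  if (object@n1 < 2L || object@n2 < 2L) return("n1 and n2 must be >= 2")
  if (object@nLoci < 1L) return("nLoci must be >= 1")
  if (object@locusLength < 1L) return("locusLength must be >= 1")
  if (!is.finite(object@thetaLocus) || object@thetaLocus <= 0)
    return("thetaLocus must be > 0")
  if (!is.na(object@outgroupTime) && object@outgroupTime <= object@params@tS)
    return("outgroupTime must exceed the split time tS")
  TRUE
})

#' Per-locus phased haplotypes
#'
#' A list of loci, each a list with elements `h` (integer matrix of 0/1
#' alleles, rows = haploid copies, columns = segregating sites), `positions`
#' (0-based site positions within the locus), `group` (character label per
#' row, e.g. deme or ecotype), `class` (locus class: `"neutral"`, `"island"`,
#' `"hrf"` or `"island_hrf"`), optional `outgroup` (0/1 vector defining the
#' ancestral state per site) and optional `tmrca`.
#'
#' @slot loci named list of per-locus records.
#' @slot locusLength integer locus length in bp.
#'
#' @export
setClass("HaplotypeSet",
  slots = c(loci = "list", locusLength = "integer")
)

setValidity("HaplotypeSet", function(object) {
  for (nm in names(object@loci)) {
    loc <- object@loci[[nm]]
    if (!is.matrix(loc$h)) return(sprintf("locus %s: h must be a matrix", nm))
    vals <- loc$h[!is.na(loc$h)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
      return(sprintf("locus %s: alleles must be 0/1", nm))
    if (length(loc$positions) != ncol(loc$h))
      return(sprintf("locus %s: positions/site count mismatch", nm))
    if (length(loc$group) != nrow(loc$h))
      return(sprintf("locus %s: one group label per haplotype required", nm))
    if (!is.null(loc$outgroup) && length(loc$outgroup) != ncol(loc$h))
      return(sprintf("locus %s: outgroup length mismatch", nm))
    all01 <- rbind(loc$h, if (!is.null(loc$outgroup)) loc$outgroup)
    if (ncol(loc$h) > 0) {
      rng <- apply(all01, 2, function(x) length(unique(na.omit(x))))
      if (any(rng < 2))
        return(sprintf("locus %s: site monomorphic across ingroup+outgroup", nm))
    }
  }
  TRUE
})

#' Joint allele frequency spectrum
#'
#' Matrix of site counts indexed by derived-allele count in population 1
#' (rows, `0..n1`) and population 2 (columns, `0..n2`). Masked entries are
#' excluded from all sums and likelihoods; the fixed corners `(0, 0)` and
#' `(n1, n2)` are always masked. Folded spectra are zero above the
#' minor-allele diagonal.
#'
#' @slot counts numeric matrix `(n1 + 1) x (n2 + 1)`.
#' @slot mask logical matrix, `TRUE` = masked.
#' @slot folded logical flag.
#' @slot totalSites numeric, callable sequence length behind the spectrum
#'   (`NA` when unknown).
#'
#' @export
setClass("Jafs",
  slots = c(counts = "matrix", mask = "matrix", folded = "logical",
            totalSites = "numeric")
)

setValidity("Jafs", function(object) {
  if (!identical(dim(object@counts), dim(object@mask)))
    return("counts and mask dimensions differ")
  if (any(object@counts[!object@mask] < 0, na.rm = TRUE))
    return("negative unmasked entries")
  if (!object@mask[1, 1] || !object@mask[nrow(object@mask), ncol(object@mask)])
    return("corner cells (0,0) and (n1,n2) must be masked")
  if (object@folded) {
    n1 <- nrow(object@counts) - 1L; n2 <- ncol(object@counts) - 1L
    ij <- outer(0:n1, 0:n2, "+")
    if (any(object@counts[ij > (n1 + n2) / 2] != 0))
      return("folded spectrum has mass above the minor-allele diagonal")
  }
  TRUE
})

#' SNP genotypes with sample and site metadata
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay `"GT"` (sites x individuals, diploid genotypes coded 0/1/2 =
#' copies of the alternate allele, `NA` = missing), `rowData` columns `locus`,
#' `pos` (0-based within-locus or within-scaffold position), `ref`, `alt`, and
#' `colData` columns `population`, `ecotype` (`"S"` short-winged tidal /
#' `"L"` long-winged seasonal), `habitat` (-1 tidal, +1 seasonal).
#'
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' required")
  gt <- SummarizedExperiment::assay(object, "GT")
  vals <- gt[!is.na(gt)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    return("genotypes must be 0, 1, 2 or NA")
  need_rd <- c("locus", "pos", "ref", "alt")
  if (!all(need_rd %in% colnames(SummarizedExperiment::rowData(object))))
    return(sprintf("rowData must contain %s", paste(need_rd, collapse = ", ")))
  need_cd <- c("population", "ecotype", "habitat")
  if (!all(need_cd %in% colnames(SummarizedExperiment::colData(object))))
    return(sprintf("colData must contain %s", paste(need_cd, collapse = ", ")))
  hab <- SummarizedExperiment::colData(object)$habitat
  if (!all(hab %in% c(-1, 1)))
    return("habitat must be coded -1 (tidal) or +1 (seasonal)")
  TRUE
})

#' Result of a replicated model fit
#'
#' @slot modelId character model identifier.
#' @slot params named numeric vector of best-fit parameter values (full
#'   vector; inactive entries at their null values).
#' @slot lnL numeric, log composite likelihood of the best run.
#' @slot k integer, number of free parameters.
#' @slot AIC numeric, `2 k - 2 lnL`.
#' @slot thetaHat numeric, profiled theta estimate.
#' @slot replicates data.frame, one row per optimization run (start, end, lnL,
#'   AIC), sorted by AIC, with the best five flagged.
#' @slot status character, `"ok"` or a warning status such as
#'   `"bound-pinned"`.
#'
#' @export
setClass("FitResult",
  slots = c(modelId = "character", params = "numeric", lnL = "numeric",
            k = "integer", AIC = "numeric", thetaHat = "numeric",
            replicates = "data.frame", status = "character")
)

setValidity("FitResult", function(object) {
  if (abs(object@AIC - (2 * object@k - 2 * object@lnL)) > 1e-8)
    return("AIC must equal 2k - 2 lnL")
  if (nrow(object@replicates) > 1 &&
      is.unsorted(object@replicates$AIC, na.rm = TRUE))
    return("replicate table must be sorted by AIC")
  TRUE
})

#' Standing-variation accumulation curve
#'
#' Mean proportion of outlier loci at which a random sample of `N` individuals
#' of the focal ecotype carries at least one allele associated with the
#' alternative ecotype, averaged over replicates.
#'
#' @slot ecotype character, focal ecotype sampled.
#' @slot N integer grid of sample sizes.
#' @slot mean,sd numeric per-N mean and SD of the proportion across replicates.
#' @slot reps integer replicate count.
#' @slot seed integer seed used.
#' @slot replicates matrix (reps x length(N)) of per-replicate proportions, or
#'   a 0-row matrix when not kept.
#'
#' @export
setClass("AccumulationCurve",
  slots = c(ecotype = "character", N = "integer", mean = "numeric",
            sd = "numeric", reps = "integer", seed = "integer",
            replicates = "matrix")
)

setValidity("AccumulationCurve", function(object) {
  if (length(object@mean) != length(object@N) ||
      length(object@sd) != length(object@N))
    return("mean/sd must align with the N grid")
  if (any(object@mean < -1e-12 | object@mean > 1 + 1e-12))
    return("proportions must lie in [0, 1]")
  TRUE
})
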