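#' Parse a model identifier
#'
#' Splits an identifier such as `"SC2M_hrf"` into its base divergence model
#' (`"SI"`, `"IM"` or `"SC"`) and the heterogeneity flags: `twoM` (genomic
#' islands with reduced effective migration) and `hrf` (linked selection via a
#' locally reduced effective size). Returns `NULL` for an unknown id.
#'
#' @param modelId character scalar.
#' @return list with elements `base`, `twoM`, `hrf`, or `NULL`.
#' @examples
#' parseModelId("SC2M_hrf")
#' @export
parseModelId <- function(modelId) {
  if (!is.character(modelId) || length(modelId) != 1L) return(NULL)
  m <- regmatches(modelId,
                  regexec("^(SI|IM|SC)(2M)?(_hrf)?$", modelId))[[1]]
  if (length(m) == 0L) return(NULL)
  list(base = m[2], twoM = m[3] == "2M", hrf = m[4] == "_hrf")
}

#' All supported model identifiers
#' @return character vector.
#' @export
modelIds <- function() {
  as.vector(outer(outer(c("SI", "IM", "SC"), c("", "2M"), paste0),
                  c("", "_hrf"), paste0))
}

#' Construct demographic model parameters
#'
#' @param nu1,nu2 relative deme sizes.
#' @param tS,tSC split and secondary-contact times (2 N_A generations).
#' @param M12,M21 population migration rates `2 N_A m` (into 1 from 2, and
#'   into 2 from 1).
#' @param MI12,MI21 island-class migration rates.
#' @param P,Q island and linked-selection genome fractions.
#' @param hrf linked-selection effective-size factor.
#' @param theta dataset-wide `4 N_A mu L` (optional until fitted).
#' @return a [DemographyParams-class] object.
#' @examples
#' DemographyParams(nu1 = 1, nu2 = 0.5, tS = 1, M12 = 2, M21 = 2)
#' @export
DemographyParams <- function(nu1 = 1, nu2 = 1, tS = 1, tSC = 0,
                             M12 = 0, M21 = 0, MI12 = 0, MI21 = 0,
                             P = 0, Q = 0, hrf = 1, theta = NA_real_) {
  new("DemographyParams", nu1 = nu1, nu2 = nu2, tS = tS, tSC = tSC,
      M12 = M12, M21 = M21, MI12 = MI12, MI21 = MI21, P = P, Q = Q,
      hrf = hrf, theta = theta)
}

#' Coerce a DemographyParams object to a named vector
#' @param params a [DemographyParams-class] object.
#' @return named numeric vector.
#' @export
paramVector <- function(params) {
  c(nu1 = params@nu1, nu2 = params@nu2, tS = params@tS, tSC = params@tSC,
    M12 = params@M12, M21 = params@M21, MI12 = params@MI12,
    MI21 = params@MI21, P = params@P, Q = params@Q, hrf = params@hrf)
}

#' Build DemographyParams from a named vector
#' @param x named numeric vector with any subset of the parameter names.
#' @param theta optional theta value.
#' @return a [DemographyParams-class] object.
#' @export
paramsFromVector <- function(x, theta = NA_real_) {
  args <- as.list(x)
  args$theta <- theta
  do.call(DemographyParams, args)
}

#' Construct a simulation scenario
#'
#' @param modelId model identifier (see [modelIds()]).
#' @param params a [DemographyParams-class] object.
#' @param n1,n2 haploid sample sizes per deme.
#' @param nLoci number of loci.
#' @param locusLength locus length (bp).
#' @param thetaLocus per-locus `4 N_A mu l`.
#' @param outgroupTime scaled outgroup divergence time (`NA` = no outgroup).
#' @param seed RNG seed.
#' @return a [ScenarioSpec-class] object.
#' @examples
#' ScenarioSpec("IM", DemographyParams(M12 = 1, M21 = 1), n1 = 8, n2 = 8,
#'              nLoci = 100, thetaLocus = 2)
#' @export
ScenarioSpec <- function(modelId, params, n1, n2, nLoci,
                         locusLength = 1200L, thetaLocus,
                         outgroupTime = NA_real_, seed = 1L) {
  new("ScenarioSpec", modelId = modelId, params = params,
      n1 = as.integer(n1), n2 = as.integer(n2), nLoci = as.integer(nLoci),
      locusLength = as.integer(locusLength), thetaLocus = thetaLocus,
      outgroupTime = as.numeric(outgroupTime), seed = as.integer(seed))
}

#' Construct a joint allele frequency spectrum
#'
#' @param counts numeric matrix `(n1 + 1) x (n2 + 1)` of site counts.
#' @param mask logical matrix; defaults to masking only the fixed corners.
#' @param folded logical flag.
#' @param totalSites callable length behind the spectrum.
#' @return a [Jafs-class] object.
#' @export
Jafs <- function(counts, mask = NULL, folded = FALSE,
                 totalSites = NA_real_) {
  counts <- as.matrix(counts)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  mask[1, 1] <- TRUE
  mask[nrow(counts), ncol(counts)] <- TRUE
  new("Jafs", counts = counts, mask = mask, folded = folded,
      totalSites = totalSites)
}

#' Construct a genotype table
#'
#' @param gt sites x individuals matrix with entries 0/1/2/NA.
#' @param siteInfo data.frame with columns `locus`, `pos` (0-based), `ref`,
#'   `alt` (one row per site).
#' @param sampleInfo data.frame with columns `population`, `ecotype`,
#'   `habitat` (one row per individual).
#' @return a [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(gt, siteInfo, sampleInfo) {
  gt <- as.matrix(gt)
  if (is.null(rownames(gt)))
    rownames(gt) <- if (!is.null(rownames(siteInfo))&&
                        !identical(rownames(siteInfo),
                                   as.character(seq_len(nrow(siteInfo)))))
      rownames(siteInfo) else paste0("snp", seq_len(nrow(gt)))
  if (is.null(colnames(gt))) colnames(gt) <- paste0("ind", seq_len(ncol(gt)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = gt),
    rowData = S4Vectors::DataFrame(siteInfo, row.names = rownames(gt)),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = colnames(gt)))
  new("GenotypeTable", se)
}

#' Construct a haplotype set
#' @param loci named list of per-locus records (see
#'   [HaplotypeSet-class]).
#' @param locusLength locus length in bp.
#' @return a [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(loci, locusLength) {
  if (is.null(names(loci))) names(loci) <- paste0("locus", seq_along(loci))
  new("HaplotypeSet", loci = loci, locusLength = as.integer(locusLength))
}

# ---- accessors ----

#' Jafs accessors
#'
#' `jafsCounts`/`jafsMask` return the count and mask matrices, `isFolded` the
#' folded flag, `sampleSizes` the haploid sample sizes `c(n1, n2)`, and
#' `jafsSum` the total unmasked mass.
#'
#' @param x a [Jafs-class] object.
#' @return matrix, logical, integer vector or numeric as described.
#' @name jafs-accessors
NULL

#' @rdname jafs-accessors
#' @export
jafsCounts <- function(x) x@counts

#' @rdname jafs-accessors
#' @export
jafsMask <- function(x) x@mask

#' @rdname jafs-accessors
#' @export
isFolded <- function(x) x@folded

#' @rdname jafs-accessors
#' @export
sampleSizes <- function(x) c(n1 = nrow(x@counts) - 1L,
                             n2 = ncol(x@counts) - 1L)

#' @rdname jafs-accessors
#' @export
jafsSum <- function(x) sum(x@counts[!x@mask])

#' FitResult accessors
#'
#' @param x a [FitResult-class] object.
#' @return the requested component.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
bestParams <- function(x) x@params

#' @rdname fit-accessors
#' @export
modelId <- function(x) x@modelId

#' @rdname fit-accessors
#' @export
aic <- function(x) x@AIC

#' @rdname fit-accessors
#' @export
thetaHat <- function(x) x@thetaHat

#' @rdname fit-accessors
#' @export
fitReplicates <- function(x) x@replicates

#' Log-likelihood of a fitted demographic model
#' @param object a [FitResult-class] object.
#' @param ... ignored.
#' @return an object of class `"logLik"` with attribute `df = k`.
#' @export
setMethod("logLik", "FitResult", function(object, ...) {
  structure(object@lnL, df = object@k, class = "logLik")
})

#' Number of loci in a haplotype set
#' @param x a [HaplotypeSet-class] object.
#' @return integer.
#' @export
nLoci <- function(x) length(x@loci)

#' Per-locus truth class labels
#' @param x a [HaplotypeSet-class] object.
#' @return named character vector.
#' @export
locusClasses <- function(x)
  vapply(x@loci, function(l) l$class %||% NA_character_, character(1))

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- show methods ----

setMethod("show", "DemographyParams", function(object) {
  v <- paramVector(object)
  cat("DemographyParams:\n ")
  cat(paste(names(v), signif(v, 4), sep = "="), sep = " ")
  cat("\n theta =", format(object@theta), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec: model %s, n1=%d n2=%d, %d loci x %d bp, theta_locus=%g\n",
              object@modelId, object@n1, object@n2, object@nLoci,
              object@locusLength, object@thetaLocus))
  if (!is.na(object@outgroupTime))
    cat(sprintf(" outgroup at t=%g\n", object@outgroupTime))
})

setMethod("show", "Jafs", function(object) {
  n <- sampleSizes(object)
  cat(sprintf("Jafs: %d x %d (%s), %d masked cells, total mass %.4g\n",
              n[1] + 1L, n[2] + 1L,
              if (object@folded) "folded" else "unfolded",
              sum(object@mask), jafsSum(object)))
})

setMethod("show", "HaplotypeSet", function(object) {
  ns <- vapply(object@loci, function(l) ncol(l$h), integer(1))
  cat(sprintf("HaplotypeSet: %d loci of %d bp, %d haplotypes, mean %.1f segregating sites\n",
              length(object@loci), object@locusLength,
              if (length(object@loci)) nrow(object@loci[[1]]$h) else 0L,
              mean(ns)))
  cls <- table(locusClasses(object))
  if (length(cls))
    cat(" classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: model %s, lnL = %.3f, k = %d, AIC = %.3f (%s)\n",
              object@modelId, object@lnL, object@k, object@AIC,
              object@status))
  free <- object@replicates
  cat(sprintf(" %d optimization runs, theta_hat = %.4g\n",
              nrow(free), object@thetaHat))
})

setMethod("show", "AccumulationCurve", function(object) {
  cat(sprintf("AccumulationCurve (ecotype %s, %d reps, seed %d):\n",
              object@ecotype, object@reps, object@seed))
  print(data.frame(N = object@N, mean = round(object@mean, 4),
                   sd = round(object@sd, 4)), row.names = FALSE)
})
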