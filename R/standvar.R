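#' @include AllClasses.R constructors.R
NULL

# validate an outlier table: one row per SNP, with locus and support columns
.checkOutlierTable <- function(outliers) {
  need <- c("snp", "locus", "pos", "support")
  if (!all(need %in% names(outliers)))
    stop("outlier table must contain columns ", paste(need, collapse = ", "))
  if (anyDuplicated(outliers$snp)) stop("outlier table must have one row per SNP")
  if (any(!is.finite(outliers$support))) stop("support scores must be finite")
  invisible(outliers)
}

#' Keep the most strongly supported SNP per locus
#'
#' When several outlier SNPs sit on the same RAD-tag, only the SNP with the
#' highest support is retained; ties are broken deterministically by lowest
#' position, then lexicographic SNP id.
#'
#' @param outliers data.frame with columns `snp`, `locus`, `pos`, `support`.
#' @return the filtered data.frame, one row per locus.
#' @export
selectTopSnpPerLocus <- function(outliers) {
  .checkOutlierTable(outliers)
  ord <- order(outliers$locus, -outliers$support, outliers$pos, outliers$snp)
  o <- outliers[ord, , drop = FALSE]
  res <- o[!duplicated(o$locus), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify outlier alleles by ecotype association
#'
#' For each outlier SNP, the allele with the higher pooled frequency across
#' all populations of the short-winged tidal ecotype (`"S"`) is taken as
#' S-associated and the other as L-associated; SNPs with exactly equal pooled
#' frequencies are flagged unassignable (`NA`) and excluded downstream.
#'
#' @param gt a [GenotypeTable-class] with both ecotypes present.
#' @param outliers outlier table (see [selectTopSnpPerLocus()]); `snp` ids
#'   must match rownames of the genotype table.
#' @return the outlier table with a column `sAllele` (`"alt"`, `"ref"` or
#'   `NA`).
#' @export
classifyAlleles <- function(gt, outliers) {
  .checkOutlierTable(outliers)
  cd <- SummarizedExperiment::colData(gt)
  if (!all(c("S", "L") %in% cd$ecotype))
    stop("both ecotypes S and L must be present")
  g <- SummarizedExperiment::assay(gt, "GT")
  ix <- match(outliers$snp, rownames(g))
  if (anyNA(ix)) stop("outlier SNPs missing from the genotype table: ",
                      paste(outliers$snp[is.na(ix)], collapse = ", "))
  gS <- g[ix, cd$ecotype == "S", drop = FALSE]
  fAltS <- rowSums(gS, na.rm = TRUE) / (2 * rowSums(!is.na(gS)))
  outliers$sAllele <- ifelse(fAltS > 0.5, "alt",
                             ifelse(fAltS < 0.5, "ref", NA_character_))
  outliers
}

# logical carrier matrix: individuals x outlier loci, TRUE when the genotype
# holds >= 1 copy of the alternative-ecotype allele. Missing genotypes -> NA.
.carrierMatrix <- function(gt, outliers, focalEcotype) {
  if (!"sAllele" %in% names(outliers))
    stop("run classifyAlleles() first")
  keep <- !is.na(outliers$sAllele)
  outliers <- outliers[keep, , drop = FALSE]
  cd <- SummarizedExperiment::colData(gt)
  g <- SummarizedExperiment::assay(gt, "GT")
  ind <- which(cd$ecotype == focalEcotype)
  if (!length(ind)) stop("no individuals of ecotype ", focalEcotype)
  ix <- match(outliers$snp, rownames(g))
  sub <- g[ix, ind, drop = FALSE]
  # alternative ecotype's allele: for focal L it is the S-associated allele
  altIsAlt <- if (focalEcotype == "L") outliers$sAllele == "alt"
              else outliers$sAllele == "ref"
  carry <- matrix(NA, nrow = length(ind), ncol = nrow(outliers),
                  dimnames = list(colnames(sub), outliers$snp))
  for (s in seq_len(nrow(outliers))) {
    gs <- sub[s, ]
    carry[, s] <- if (altIsAlt[s]) gs >= 1 else gs <= 1
  }
  carry
}

#' Per-individual carriage of alternative-ecotype alleles
#'
#' For each individual of the focal ecotype, the fraction of outlier loci at
#' which its genotype carries at least one copy of the allele associated with
#' the alternative ecotype; loci with a missing genotype are excluded from
#' that individual's denominator.
#'
#' @param gt a [GenotypeTable-class].
#' @param outliers classified outlier table (see [classifyAlleles()]).
#' @param focalEcotype `"L"` or `"S"`.
#' @return named numeric vector, one proportion per individual.
#' @export
perIndividualCarriage <- function(gt, outliers, focalEcotype) {
  carry <- .carrierMatrix(gt, outliers, focalEcotype)
  apply(carry, 1, function(x) mean(x, na.rm = TRUE))
}

#' Resampling accumulation curve of standing variation
#'
#' For each sample size `N`, draws `reps` random subsets (without replacement)
#' of `N` individuals of the focal ecotype and records, per replicate, the
#' proportion of outlier loci at which any sampled individual carries at least
#' one copy of the alternative-ecotype allele; within a replicate a missing
#' genotype counts as a non-carrier. Deterministic given `seed`. By default
#' individuals are pooled across the populations of the focal ecotype; with
#' `population` set, only that cohort is sampled.
#'
#' @param gt a [GenotypeTable-class].
#' @param outliers classified outlier table.
#' @param focalEcotype `"L"` or `"S"`.
#' @param NGrid integer vector of sample sizes (each <= cohort size).
#' @param reps replicates per N.
#' @param seed RNG seed.
#' @param population optional single population label restricting the cohort.
#' @param keepReplicates keep the per-replicate matrix.
#' @return an [AccumulationCurve-class].
#' @export
accumulationCurve <- function(gt, outliers, focalEcotype, NGrid,
                              reps = 100L, seed = 1L, population = NULL,
                              keepReplicates = FALSE) {
  if (!is.null(population)) {
    cd <- SummarizedExperiment::colData(gt)
    gt <- gt[, cd$population == population]
  }
  carry <- .carrierMatrix(gt, outliers, focalEcotype)
  carry[is.na(carry)] <- FALSE
  n <- nrow(carry); L <- ncol(carry)
  NGrid <- as.integer(NGrid)
  if (any(NGrid > n)) stop("NGrid exceeds the cohort size (", n, ")")
  set.seed(seed)
  props <- matrix(NA_real_, reps, length(NGrid))
  for (k in seq_along(NGrid)) {
    for (b in seq_len(reps)) {
      ix <- sample.int(n, NGrid[k])
      props[b, k] <- sum(colSums(carry[ix, , drop = FALSE]) > 0) / L
    }
  }
  new("AccumulationCurve", ecotype = focalEcotype, N = NGrid,
      mean = colMeans(props), sd = apply(props, 2, sd),
      reps = as.integer(reps), seed = as.integer(seed),
      replicates = if (keepReplicates) props else matrix(numeric(0), 0, 0))
}

#' Exact expectation of the accumulation curve
#'
#' Closed-form hypergeometric expectation of the resampling procedure: with
#' `k_l` carrier individuals at locus `l` in a cohort of `n`, the expected
#' proportion for sample size `N` is
#' `sum_l (1 - choose(n - k_l, N) / choose(n, N)) / L`.
#'
#' @inheritParams accumulationCurve
#' @param N single sample size.
#' @return expected proportion.
#' @export
exactAccumulationExpectation <- function(gt, outliers, focalEcotype, N,
                                         population = NULL) {
  if (!is.null(population)) {
    cd <- SummarizedExperiment::colData(gt)
    gt <- gt[, cd$population == population]
  }
  carry <- .carrierMatrix(gt, outliers, focalEcotype)
  carry[is.na(carry)] <- FALSE
  n <- nrow(carry)
  if (N > n) stop("N exceeds the cohort size")
  k <- colSums(carry)
  mean(1 - choose(n - k, N) / choose(n, N))
}
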