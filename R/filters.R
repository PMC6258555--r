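#' @include AllClasses.R constructors.R
NULL

#' SNP retention filters
#'
#' Applies the standard RAD-seq retention filters in a fixed order:
#' (1) presence — keep sites genotyped in at least `minPresence` of the
#' individuals; (2) minor allele frequency — keep sites whose MAF, computed
#' over called alleles only, is strictly greater than `minMaf`;
#' (3) neutral-set exclusion — when a support table is supplied, remove every
#' SNP on a locus (or scaffold, via `exclusionBy`) that contains any SNP with
#' support strictly above `supportThreshold`; (4) one SNP per locus — keep one
#' uniformly random retained SNP per locus (seeded). Presence precedes MAF so
#' allele frequencies are computed on adequately genotyped sites.
#'
#' @param gt a [GenotypeTable-class].
#' @param minMaf minor-allele-frequency threshold (default 0.01, strict `>`).
#' @param minPresence minimum fraction of genotyped individuals (default
#'   0.80).
#' @param oneSnpPerLocus logical; thin to one random SNP per locus.
#' @param support optional data.frame with columns `snp` and `support` used
#'   for neutral-set exclusion.
#' @param supportThreshold exclusion threshold on the support score (default
#'   3, i.e. log10-support > 3).
#' @param exclusionBy rowData column defining the exclusion granularity
#'   (default `"locus"`).
#' @param seed seed for the random one-per-locus pick.
#' @return list with `genotypes` (filtered [GenotypeTable-class]) and
#'   `report` (data.frame of per-stage removals).
#' @export
applyFilters <- function(gt, minMaf = 0.01, minPresence = 0.80,
                         oneSnpPerLocus = FALSE, support = NULL,
                         supportThreshold = 3, exclusionBy = "locus",
                         seed = 1L) {
  g <- SummarizedExperiment::assay(gt, "GT")
  rd <- SummarizedExperiment::rowData(gt)
  nInd <- ncol(g)
  stages <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage)
    removed <<- c(removed, before - after)
    remaining <<- c(remaining, after)
  }

  keep <- rep(TRUE, nrow(g))

  pres <- rowSums(!is.na(g)) / nInd
  k2 <- keep & pres >= minPresence
  note("presence", sum(keep), sum(k2)); keep <- k2

  called <- 2 * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  maf <- pmin(alt / called, 1 - alt / called)
  k2 <- keep & !is.na(maf) & maf > minMaf
  note("maf", sum(keep), sum(k2)); keep <- k2

  if (!is.null(support)) {
    if (!all(c("snp", "support") %in% names(support)))
      stop("support table needs columns snp and support")
    grp <- rd[[exclusionBy]]
    hot <- support$snp[support$support > supportThreshold]
    hotGroups <- unique(grp[match(hot, rownames(g))])
    hotGroups <- hotGroups[!is.na(hotGroups)]
    k2 <- keep & !(grp %in% hotGroups)
    note("neutral_exclusion", sum(keep), sum(k2)); keep <- k2
  }

  if (oneSnpPerLocus) {
    set.seed(seed)
    idx <- which(keep)
    pick <- unlist(lapply(split(idx, rd$locus[idx]), function(ix)
      if (length(ix) == 1L) ix else sample(ix, 1L)))
    k2 <- rep(FALSE, nrow(g)); k2[pick] <- TRUE
    note("one_per_locus", sum(keep), sum(k2)); keep <- k2
  }

  if (!any(keep)) warning("no SNPs survive the filters")
  report <- data.frame(stage = c("input", stages),
                       removed = c(0L, removed),
                       remaining = c(nrow(g), remaining))
  list(genotypes = gt[keep, ], report = report)
}
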