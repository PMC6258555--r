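#' @include AllClasses.R constructors.R
NULL

# total pairwise differences and comparable lengths for all pairs of rows.
# h: 0/1 matrix over segregating sites (NA = missing). Monomorphic sites are
# identical by construction, so a pair's comparable length is locusLength
# minus its incomplete segregating sites.
.pairDiffs <- function(h, locusLength) {
  n <- nrow(h)
  if (n < 2L) stop("need at least 2 sequences")
  if (!anyNA(h)) {
    cnt <- colSums(h)
    diffs <- sum(cnt * (n - cnt))             # over all pairs
    return(list(totalDiff = diffs, totalLen = choose(n, 2) * locusLength,
                perPair = NULL))
  }
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- numeric(nrow(idx)); l <- numeric(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    a <- h[idx[p, 2], ]; b <- h[idx[p, 1], ]
    ok <- !is.na(a) & !is.na(b)
    d[p] <- sum(a[ok] != b[ok])
    l[p] <- locusLength - sum(!ok)
  }
  list(totalDiff = sum(d), totalLen = sum(l), perPair = cbind(d, l))
}

#' Nucleotide diversity of a set of sequences
#'
#' Mean per-site pairwise difference within a group: the average over all
#' sequence pairs of the number of differing sites divided by the pairwise
#' comparable length. Sites with a missing allele in a pair are dropped for
#' that pair only.
#'
#' @param h 0/1 matrix over segregating sites, rows = sequences (`NA` =
#'   missing allele).
#' @param locusLength total locus length in bp (monomorphic sites included).
#' @return per-site nucleotide diversity.
#' @examples
#' h <- rbind(c(0, 0, 0), c(1, 1, 1))
#' nucleotideDiversity(h, 100)  # 0.03
#' @export
nucleotideDiversity <- function(h, locusLength) {
  pd <- .pairDiffs(as.matrix(h), locusLength)
  if (is.null(pd$perPair)) return(pd$totalDiff / pd$totalLen)
  mean(pd$perPair[, 1] / pd$perPair[, 2])
}

#' Absolute divergence between two groups of sequences
#'
#' Mean per-site pairwise difference over all between-group pairs (d_XY).
#'
#' @param hA,hB 0/1 matrices over the same segregating sites.
#' @param locusLength total locus length in bp.
#' @return per-site d_XY.
#' @export
dxy <- function(hA, hB, locusLength) {
  hA <- rbind(hA); hB <- rbind(hB)
  if (ncol(hA) != ncol(hB)) stop("sequence lengths differ between groups")
  tot_d <- 0; tot_l <- 0
  for (i in seq_len(nrow(hA))) for (j in seq_len(nrow(hB))) {
    a <- hA[i, ]; b <- hB[j, ]
    ok <- !is.na(a) & !is.na(b)
    tot_d <- tot_d + sum(a[ok] != b[ok])
    tot_l <- tot_l + locusLength - sum(!ok)
  }
  tot_d / tot_l
}

#' Tajima's D
#'
#' `D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants as functions of the sample size; `pi_hat` is the mean pairwise
#' difference in counts and `S` the number of segregating sites within the
#' input. Returns `NA` (undefined) when `S = 0`.
#'
#' @param h complete 0/1 matrix over candidate sites, rows = sequences
#'   (`n >= 4`).
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajimasD <- function(h) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  if (anyNA(h)) stop("Tajima's D requires complete data")
  cnt <- colSums(h)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  k <- cnt[seg]
  pihat <- sum(k * (n - k)) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Haplotype-based F_ST
#'
#' `1 - H_w / H_b`, with `H_w` the mean pairwise difference pooled over
#' within-group pairs of both groups and `H_b` the mean between-group pairwise
#' difference. Ranges over `(-Inf, 1]`; equals 1 only when both groups are
#' internally monomorphic and differ. Undefined (`NA`) when `H_b = 0`.
#'
#' @param hA,hB 0/1 matrices over the same sites (>= 2 sequences each).
#' @return haplotype F_ST.
#' @export
fstHaplotype <- function(hA, hB) {
  hA <- as.matrix(hA); hB <- as.matrix(hB)
  if (nrow(hA) < 2L || nrow(hB) < 2L)
    stop("need at least 2 sequences per group")
  if (ncol(hA) != ncol(hB)) stop("sequence lengths differ between groups")
  L <- max(1L, ncol(hA))
  wA <- .pairDiffs(hA, L); wB <- .pairDiffs(hB, L)
  Hw <- (wA$totalDiff + wB$totalDiff) /
    (choose(nrow(hA), 2) + choose(nrow(hB), 2))
  Hb <- dxy(hA, hB, L) * L
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}

#' Per-SNP Weir-Cockerham F_ST
#'
#' Variance-components estimator for diploid genotypes (no inbreeding
#' correction beyond the heterozygosity term): per SNP the among-population
#' (`a`), among-individual (`b`) and within-individual (`c`) components, with
#' `fst = a / (a + b + c)`; the multi-locus estimate aggregates as the ratio
#' of sums (ratio of averages). Negative per-SNP values are reported as-is.
#'
#' @param gt a [GenotypeTable-class] or a sites x individuals 0/1/2 matrix.
#' @param pops population label per individual (defaults to the table's
#'   `population` column).
#' @return data.frame with one row per SNP (`a`, `b`, `c`, `fst`); the
#'   multi-locus ratio-of-sums estimate is attached as attribute
#'   `"overall"`.
#' @export
fstWC <- function(gt, pops = NULL) {
  if (is(gt, "GenotypeTable")) {
    if (is.null(pops)) pops <- SummarizedExperiment::colData(gt)$population
    g <- SummarizedExperiment::assay(gt, "GT")
  } else {
    g <- as.matrix(gt)
    if (is.null(pops)) stop("pops required for a bare matrix")
  }
  pops <- as.character(pops)
  plev <- unique(pops)
  r <- length(plev)
  if (r < 2L) stop("need at least 2 populations")

  comp <- t(apply(g, 1, function(row) {
    ni <- pi_ <- hi <- numeric(r)
    for (k in seq_len(r)) {
      x <- row[pops == plev[k]]
      x <- x[!is.na(x)]
      ni[k] <- length(x)
      if (ni[k] == 0) return(c(NA, NA, NA))
      pi_[k] <- sum(x) / (2 * ni[k])
      hi[k] <- mean(x == 1)
    }
    if (any(ni < 2)) return(c(NA, NA, NA))
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }))
  colnames(comp) <- c("a", "b", "c")
  res <- as.data.frame(comp)
  denom <- res$a + res$b + res$c
  res$fst <- ifelse(is.na(denom) | denom == 0, NA_real_, res$a / denom)
  rownames(res) <- rownames(g)
  ok <- !is.na(denom) & denom != 0
  attr(res, "overall") <- sum(res$a[ok]) / sum(denom[ok])
  res
}

#' Per-locus haplotype statistics
#'
#' For every locus of a haplotype set: total nucleotide diversity, per-group
#' diversity, between-group d_XY, divergence to the outgroup (when present),
#' Tajima's D (overall and per group) and haplotype F_ST. `groupS`/`groupL`
#' name the labels (in the per-locus `group` vector) forming the short- and
#' long-winged-associated sets. When `splitAt` provides a site position for a
#' locus, haplotypes are instead split by base composition at that site (the
#' top outlier SNP); the allele group containing the majority of
#' `groupS`-labelled copies is taken as the S set.
#'
#' @param hs a [HaplotypeSet-class].
#' @param groupS,groupL character vectors of group labels.
#' @param splitAt optional named vector: locus id -> 0-based site position of
#'   the top outlier SNP.
#' @return data.frame with one row per locus (columns `locus`, `class`,
#'   `nSites`, `nSeqS`, `nSeqL`, `piTot`, `piS`, `piL`, `dXY`, `dXYOut`,
#'   `tajD`, `tajDS`, `tajDL`, `fstHap`).
#' @export
locusStats <- function(hs, groupS, groupL, splitAt = NULL) {
  L <- hs@locusLength
  rows <- lapply(names(hs@loci), function(nm) {
    loc <- hs@loci[[nm]]
    inS <- loc$group %in% groupS
    inL <- loc$group %in% groupL
    if (!is.null(splitAt) && nm %in% names(splitAt)) {
      s <- match(splitAt[[nm]], loc$positions)
      if (is.na(s)) stop("locus ", nm, ": split position not found")
      grp1 <- loc$h[, s] == 1L
      sIsGrp1 <- sum(grp1 & inS) >= sum(!grp1 & inS)
      inS <- if (sIsGrp1) grp1 else !grp1
      inL <- !inS
    }
    hAll <- loc$h[inS | inL, , drop = FALSE]
    hS <- loc$h[inS, , drop = FALSE]
    hL <- loc$h[inL, , drop = FALSE]
    dOut <- if (!is.null(loc$outgroup) && ncol(loc$h) > 0)
      dxy(hAll, matrix(loc$outgroup, 1), L) else NA_real_
    if (!is.null(loc$outgroup) && ncol(loc$h) == 0) dOut <- 0
    data.frame(
      locus = nm, class = loc$class %||% NA_character_,
      nSites = ncol(loc$h), nSeqS = nrow(hS), nSeqL = nrow(hL),
      piTot = if (nrow(hAll) >= 2) nucleotideDiversity(hAll, L) else NA_real_,
      piS = if (nrow(hS) >= 2) nucleotideDiversity(hS, L) else NA_real_,
      piL = if (nrow(hL) >= 2) nucleotideDiversity(hL, L) else NA_real_,
      dXY = if (nrow(hS) >= 1 && nrow(hL) >= 1) dxy(hS, hL, L) else NA_real_,
      dXYOut = dOut,
      tajD = if (nrow(hAll) >= 4 && !anyNA(hAll)) tajimasD(hAll) else NA_real_,
      tajDS = if (nrow(hS) >= 4 && !anyNA(hS)) tajimasD(hS) else NA_real_,
      tajDL = if (nrow(hL) >= 4 && !anyNA(hL)) tajimasD(hL) else NA_real_,
      fstHap = if (nrow(hS) >= 2 && nrow(hL) >= 2) fstHaplotype(hS, hL)
               else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize divergence and diversity by outgroup divergence
#'
#' Divides `dXY` and `piTot` by the per-locus divergence to the outgroup,
#' removing the locus mutation-rate dependence; loci with zero outgroup
#' divergence are flagged `NA`.
#'
#' @param stats data.frame from [locusStats()] (needs `dXY`, `piTot`,
#'   `dXYOut`).
#' @return the data.frame with `normDxy` and `normPi` columns added.
#' @export
normalizeByOutgroup <- function(stats) {
  if (!all(c("dXY", "piTot", "dXYOut") %in% names(stats)))
    stop("stats must contain dXY, piTot and dXYOut")
  ok <- !is.na(stats$dXYOut) & stats$dXYOut > 0
  stats$normDxy <- ifelse(ok, stats$dXY / stats$dXYOut, NA_real_)
  stats$normPi <- ifelse(ok, stats$piTot / stats$dXYOut, NA_real_)
  stats
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of diploid allele dosages between SNP pairs.
#' Monomorphic SNPs give `NA`.
#'
#' @param gt a [GenotypeTable-class].
#' @param pairs 2-column matrix of site indices; `NULL` computes all pairs
#'   within each locus.
#' @param minMaf minimum minor-allele frequency for a SNP to enter (0 = no
#'   filter; 0.1 reproduces the usual decay-curve subset).
#' @return data.frame with `site1`, `site2`, `dist` (bp) and `r2`.
#' @export
ldR2 <- function(gt, pairs = NULL, minMaf = 0) {
  g <- SummarizedExperiment::assay(gt, "GT")
  rd <- SummarizedExperiment::rowData(gt)
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(split(seq_len(nrow(g)), rd$locus),
      function(ix) if (length(ix) >= 2) t(combn(ix, 2)) else NULL))
    if (is.null(pairs)) return(data.frame(site1 = integer(), site2 = integer(),
                                          dist = numeric(), r2 = numeric()))
  }
  pairs <- rbind(pairs)
  maf <- apply(g, 1, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  r2 <- numeric(nrow(pairs)); dist <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dist[p] <- abs(rd$pos[i] - rd$pos[j])
    if (is.na(maf[i]) || is.na(maf[j]) || maf[i] < minMaf || maf[j] < minMaf ||
        maf[i] == 0 || maf[j] == 0) { r2[p] <- NA_real_; next }
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    if (sum(ok) < 3 || sd(g[i, ok]) == 0 || sd(g[j, ok]) == 0) {
      r2[p] <- NA_real_; next
    }
    r2[p] <- cor(g[i, ok], g[j, ok])^2
  }
  data.frame(site1 = pairs[, 1], site2 = pairs[, 2], dist = dist, r2 = r2)
}

#' Binned LD decay
#'
#' @param ld output of [ldR2()].
#' @param breaks distance bin boundaries (bp).
#' @return data.frame with bin midpoints, mean r2 and pair counts.
#' @export
ldDecay <- function(ld, breaks) {
  bin <- cut(ld$dist, breaks = breaks, include.lowest = TRUE)
  ok <- !is.na(ld$r2) & !is.na(bin)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  agg <- tapply(ld$r2[ok], bin[ok], mean)
  cnt <- tapply(ld$r2[ok], bin[ok], length)
  data.frame(mid = mids, meanR2 = as.numeric(agg[levels(bin)]),
             n = ifelse(is.na(cnt[levels(bin)]), 0L, cnt[levels(bin)]))
}

#' Mantel test by permutation
#'
#' Pearson correlation between the off-diagonal entries of two square
#' symmetric matrices; significance by jointly permuting the rows and columns
#' of the second matrix. One-sided p-value
#' `(1 + #\{perm r >= observed r\}) / (1 + nPerm)`.
#'
#' @param matA,matB square symmetric matrices of equal size.
#' @param nPerm number of permutations.
#' @param seed optional seed.
#' @return list with `r` and `p`.
#' @export
mantelTest <- function(matA, matB, nPerm = 999L, seed = NULL) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  if (!identical(dim(matA), dim(matB)) || nrow(matA) != ncol(matA))
    stop("matrices must be square and of equal size")
  if (max(abs(matA - t(matA))) > 1e-8 || max(abs(matB - t(matB))) > 1e-8)
    stop("matrices must be symmetric")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(matA)
  lt <- lower.tri(matA)
  obs <- cor(matA[lt], matB[lt])
  ge <- 0L
  for (b in seq_len(nPerm)) {
    ix <- sample.int(n)
    if (cor(matA[lt], matB[ix, ix][lt]) >= obs) ge <- ge + 1L
  }
  list(r = obs, p = (1 + ge) / (1 + nPerm))
}

#' Empirical F_ST outlier scan
#'
#' Flags SNPs whose F_ST exceeds the empirical `q`-quantile (strictly, so ties
#' at the threshold are not flagged) and assigns each SNP a support score
#' `-log10` of its empirical upper-tail probability. A generic stand-in for
#' model-based outlier detectors: the support score plays the role of a
#' log10 Bayes-factor-like quantity.
#'
#' @param fst numeric vector of per-SNP F_ST values (NAs never flagged).
#' @param q upper quantile threshold (default 0.99).
#' @return data.frame with `fst`, `support` and logical `outlier`.
#' @export
empiricalOutlierScan <- function(fst, q = 0.99) {
  nOk <- sum(!is.na(fst))
  if (nOk < 100L)
    warning("fewer than 100 informative SNPs; the empirical tail is coarse")
  thr <- quantile(fst, q, na.rm = TRUE, names = FALSE)
  upper <- vapply(fst, function(x) {
    if (is.na(x)) return(NA_real_)
    mean(fst[!is.na(fst)] >= x)
  }, numeric(1))
  data.frame(fst = fst, support = -log10(upper),
             outlier = !is.na(fst) & fst > thr)
}
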