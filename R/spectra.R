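#' @include AllClasses.R constructors.R
NULL

#' Build a joint allele frequency spectrum from genotypes
#'
#' Entry `(i, j)` counts sites with `i` derived copies among the haploid
#' copies of population 1 and `j` in population 2. Genotype codes are taken as
#' derived-allele dosages when `polarized = TRUE` (the convention produced by
#' [simulateDataset()], where the outgroup allele defines the ancestral
#' state); with `polarized = FALSE` the spectrum is folded to minor-allele
#' counts. Sites with missing genotypes are handled by per-site hypergeometric
#' projection to the target sizes `m1`, `m2` (default: the full haploid sample
#' sizes, so that only fully called sites enter whole); sites with fewer
#' called copies than the target are dropped.
#'
#' @param gt a [GenotypeTable-class].
#' @param pop1,pop2 population labels (may be vectors of labels pooled
#'   together).
#' @param polarized logical; `FALSE` folds the spectrum.
#' @param m1,m2 target haploid sizes for per-site projection (`NULL` = full).
#' @param totalSites callable length behind the spectrum (optional).
#' @return a [Jafs-class].
#' @examples
#' spec <- ScenarioSpec("IM", DemographyParams(M12 = 1, M21 = 1), n1 = 4,
#'                      n2 = 4, nLoci = 30, thetaLocus = 2, seed = 2L)
#' d <- simulateDataset(spec)
#' buildJafs(d$genotypes, "pop1", "pop2")
#' @export
buildJafs <- function(gt, pop1, pop2, polarized = TRUE,
                      m1 = NULL, m2 = NULL, totalSites = NA_real_) {
  cd <- SummarizedExperiment::colData(gt)
  g <- SummarizedExperiment::assay(gt, "GT")
  i1 <- cd$population %in% pop1
  i2 <- cd$population %in% pop2
  if (!any(i1) || !any(i2)) stop("population labels not found")
  g1 <- g[, i1, drop = FALSE]
  g2 <- g[, i2, drop = FALSE]
  if (is.null(m1)) m1 <- 2L * sum(i1)
  if (is.null(m2)) m2 <- 2L * sum(i2)

  d1 <- rowSums(g1, na.rm = TRUE); c1 <- 2L * rowSums(!is.na(g1))
  d2 <- rowSums(g2, na.rm = TRUE); c2 <- 2L * rowSums(!is.na(g2))
  keep <- c1 >= m1 & c2 >= m2
  counts <- matrix(0, m1 + 1, m2 + 1)

  full <- keep & c1 == m1 & c2 == m2
  if (any(full)) {
    idx <- d1[full] * (m2 + 1) + d2[full] + 1   # row-major cell index
    tab <- tabulate(idx, nbins = (m1 + 1) * (m2 + 1))
    counts <- counts + matrix(tab, m1 + 1, m2 + 1, byrow = TRUE)
  }
  for (s in which(keep & !full)) {
    w1 <- dhyper(0:m1, d1[s], c1[s] - d1[s], m1)
    w2 <- dhyper(0:m2, d2[s], c2[s] - d2[s], m2)
    counts <- counts + outer(w1, w2)
  }
  j <- Jafs(counts, totalSites = totalSites)
  if (!polarized) j <- foldJafs(j)
  j
}

#' Project a spectrum to smaller sample sizes
#'
#' Standard hypergeometric down-projection: each entry is redistributed over
#' the smaller sample sizes by the product of hypergeometric sampling
#' probabilities in the two dimensions. Masked input cells are excluded;
#' unmasked mass is conserved up to the mass moved into the masked corners of
#' the target. Folded spectra are projected on their raw counts and refolded
#' (the result does not depend on how mass was split between complementary
#' cells).
#'
#' @param j a [Jafs-class].
#' @param m1,m2 target haploid sizes (`m_k <= n_k`).
#' @return a [Jafs-class] of dimensions `(m1 + 1) x (m2 + 1)`.
#' @export
projectJafs <- function(j, m1, m2) {
  n <- sampleSizes(j)
  if (m1 > n[1] || m2 > n[2])
    stop("projection targets must not exceed current sample sizes")
  counts <- j@counts
  counts[j@mask] <- 0
  A <- outer(0:m1, 0:n[[1]],
             function(ip, i) dhyper(ip, i, n[[1]] - i, m1))
  B <- outer(0:m2, 0:n[[2]],
             function(jp, jj) dhyper(jp, jj, n[[2]] - jj, m2))
  proj <- A %*% counts %*% t(B)
  out <- Jafs(proj, totalSites = j@totalSites)
  if (j@folded) {
    out@folded <- FALSE
    out <- foldJafs(out)
  }
  out
}

#' Fold a spectrum to minor-allele counts
#'
#' Combines entry `(i, j)` with its complement `(n1 - i, n2 - j)`; ambiguous
#' cells on the diagonal `i + j = (n1 + n2) / 2` receive half of the combined
#' mass in each of the two complementary cells so total mass is conserved. A
#' folded cell is masked when either of its unfolded preimages was masked.
#'
#' @param j an unfolded [Jafs-class].
#' @return a folded [Jafs-class].
#' @export
foldJafs <- function(j) {
  if (j@folded) stop("spectrum is already folded")
  n1 <- nrow(j@counts) - 1L; n2 <- ncol(j@counts) - 1L
  tot <- outer(0:n1, 0:n2, "+")
  rev2 <- function(m) m[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
  comb <- j@counts + rev2(j@counts)
  out <- matrix(0, n1 + 1, n2 + 1)
  keep <- tot < (n1 + n2) / 2
  diag_ <- tot == (n1 + n2) / 2
  out[keep] <- comb[keep]
  out[diag_] <- comb[diag_] / 2
  mask <- j@mask | rev2(j@mask)
  mask[tot > (n1 + n2) / 2] <- TRUE
  new("Jafs", counts = out, mask = mask, folded = TRUE,
      totalSites = j@totalSites)
}

#' Read / write a spectrum in the plain-text SFS format
#'
#' The dialect used by diffusion-based SFS software: first line
#' `"<n1+1> <n2+1> <folded|unfolded>"`, second line the row-major entries,
#' third line a row-major 0/1 mask (1 = masked).
#'
#' @param path file path.
#' @param maskCorners when the stored mask line is all zero, still mask the
#'   fixed corners (default `TRUE`).
#' @return `readSfs` returns a [Jafs-class]; `writeSfs` returns `path`
#'   invisibly.
#' @export
readSfs <- function(path, maskCorners = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed SFS file: need header and data")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- suppressWarnings(as.integer(hdr[1]))
  d2 <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(d1) || is.na(d2)) stop("malformed SFS header")
  folded <- length(hdr) >= 3 && hdr[3] == "folded"
  vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (anyNA(vals)) stop("non-numeric SFS entries")
  if (length(vals) != d1 * d2) stop("SFS entry count does not match header")
  counts <- matrix(vals, d1, d2, byrow = TRUE)
  mask <- matrix(FALSE, d1, d2)
  if (length(lines) >= 3L) {
    mv <- suppressWarnings(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]]))
    if (anyNA(mv) || length(mv) != d1 * d2)
      stop("malformed SFS mask line")
    mask <- matrix(mv == 1L, d1, d2, byrow = TRUE)
  }
  if (maskCorners) { mask[1, 1] <- TRUE; mask[d1, d2] <- TRUE }
  new("Jafs", counts = counts, mask = mask, folded = folded,
      totalSites = NA_real_)
}

#' @rdname readSfs
#' @param j a [Jafs-class] to write.
#' @export
writeSfs <- function(j, path) {
  d <- dim(j@counts)
  hdr <- sprintf("%d %d %s", d[1], d[2],
                 if (j@folded) "folded" else "unfolded")
  writeLines(c(hdr,
               paste(format(as.vector(t(j@counts)), scientific = FALSE,
                            trim = TRUE), collapse = " "),
               paste(as.integer(as.vector(t(j@mask))), collapse = " ")),
             path)
  invisible(path)
}
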