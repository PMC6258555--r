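#' @include AllClasses.R constructors.R
NULL

# Demographic kernel arguments for one locus class. Island-class loci use the
# island migration rates MI in every epoch where migration is active; hrf-class
# loci have both demes and the ancestral deme scaled by hrf (linked selection
# modelled as a locus-wide Ne reduction).
.kernelArgs <- function(params, modelId, locusClass) {
  mi <- parseModelId(modelId)
  if (is.null(mi)) stop("unknown model id: ", modelId)
  island <- locusClass %in% c("island", "island_hrf")
  hrfcls <- locusClass %in% c("hrf", "island_hrf")
  m12 <- if (island) params@MI12 else params@M12
  m21 <- if (island) params@MI21 else params@M21
  migStop <- switch(mi$base,
    SI = 0,
    IM = params@tS,
    SC = params@tSC)
  if (mi$base == "SI") { m12 <- 0; m21 <- 0 }
  f <- if (hrfcls) params@hrf else 1
  list(nu1 = params@nu1 * f, nu2 = params@nu2 * f,
       m12 = m12, m21 = m21, tSplit = params@tS, migStop = migStop,
       nuAnc = f)
}

.lociClassNames <- c("neutral", "island", "hrf", "island_hrf")

# class probabilities (1-P)(1-Q), P(1-Q), (1-P)Q, PQ
.classProbs <- function(params)
  setNames(c((1 - params@P) * (1 - params@Q),
             params@P * (1 - params@Q),
             (1 - params@P) * params@Q,
             params@P * params@Q), .lociClassNames)

# draw distinct 0-based site positions for S mutations on a locus
.drawPositions <- function(S, locusLength) {
  if (S > locusLength)
    stop("more segregating sites (", S, ") than positions (", locusLength,
         "); reduce thetaLocus")
  sort(sample.int(locusLength, S)) - 1L
}

#' Simulate one locus under the structured coalescent
#'
#' Generates the 0/1 haplotypes of a single locus backward in time: migration
#' at rates `M` (or the island rates `MI` for island-class loci) while gene
#' flow is active (always for IM, on `[0, tSC)` for SC, never for SI), deme
#' sizes `nu1`, `nu2` (scaled by `hrf` for hrf-class loci, ancestral deme
#' included), a single ancestral deme of size 1 from the split time backward,
#' and infinite-sites mutation with per-locus rate `thetaLocus`. Time is in
#' units of 2 N_A generations; the per-lineage backward migration rate is
#' `M_{i<-j}` per unit scaled time, so the realized per-generation migrant
#' fraction is `M / (2 N_A)`. Uses (and advances) R's RNG stream.
#'
#' @param spec a [ScenarioSpec-class].
#' @param locusClass one of `"neutral"`, `"island"`, `"hrf"`, `"island_hrf"`.
#' @return a locus record: list with `h` (0/1 matrix, `n1 + n2` rows),
#'   `positions` (0-based), `group` (deme label per row), `class`, `tmrca`.
#' @examples
#' spec <- ScenarioSpec("IM", DemographyParams(M12 = 1, M21 = 1),
#'                      n1 = 4, n2 = 4, nLoci = 1, thetaLocus = 2)
#' set.seed(1)
#' str(simulateLocus(spec))
#' @export
simulateLocus <- function(spec, locusClass = "neutral") {
  stopifnot(locusClass %in% .lociClassNames)
  validObject(spec)
  a <- .kernelArgs(spec@params, spec@modelId, locusClass)
  sim <- cpp_sim_haplotypes(spec@n1, spec@n2, a$nu1, a$nu2, a$m12, a$m21,
                            a$tSplit, a$migStop, a$nuAnc, spec@thetaLocus,
                            -1, 1L)[[1]]
  list(h = sim$h,
       positions = .drawPositions(ncol(sim$h), spec@locusLength),
       group = rep(c("pop1", "pop2"), c(spec@n1, spec@n2)),
       class = locusClass, tmrca = sim$tmrca)
}

#' Simulate a complete multi-locus dataset
#'
#' Draws a locus class for every locus with probabilities
#' `(1-P)(1-Q), P(1-Q), (1-P)Q, PQ` for neutral / island / hrf / island+hrf,
#' simulates each locus under its class, attaches an outgroup sequence when
#' `spec@outgroupTime` is set, and pairs haploid copies at random within each
#' deme into diploid individuals. Deterministic given `spec@seed`.
#'
#' @param spec a [ScenarioSpec-class]; `n1` and `n2` must be even for the
#'   diploid genotype table.
#' @param popNames,ecotypes,habitat labels attached to demes 1 and 2 (defaults:
#'   deme 1 is the short-winged tidal ecotype `"S"`, habitat -1).
#' @param genotypes build the diploid genotype table (set `FALSE` for
#'   haplotype-only runs, e.g. with odd sample sizes).
#' @return list with `haplotypes` ([HaplotypeSet-class]), `genotypes`
#'   ([GenotypeTable-class]) and `truth` (data.frame of per-locus class
#'   labels).
#' @examples
#' spec <- ScenarioSpec("SC2M", DemographyParams(tS = 1, tSC = 0.1, M12 = 2,
#'     M21 = 2, MI12 = 0.04, MI21 = 0.04, P = 0.3),
#'   n1 = 8, n2 = 8, nLoci = 50, thetaLocus = 2, seed = 7L)
#' d <- simulateDataset(spec)
#' d$haplotypes
#' @export
simulateDataset <- function(spec,
                            popNames = c("pop1", "pop2"),
                            ecotypes = c("S", "L"),
                            habitat = c(-1, 1),
                            genotypes = TRUE) {
  validObject(spec)
  set.seed(spec@seed)
  probs <- .classProbs(spec@params)
  classes <- sample(.lociClassNames, spec@nLoci, replace = TRUE, prob = probs)

  loci <- vector("list", spec@nLoci)
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    a <- .kernelArgs(spec@params, spec@modelId, cls)
    sims <- cpp_sim_haplotypes(spec@n1, spec@n2, a$nu1, a$nu2, a$m12, a$m21,
                               a$tSplit, a$migStop, a$nuAnc, spec@thetaLocus,
                               -1, length(idx))
    for (k in seq_along(idx)) {
      loci[[idx[k]]] <- list(
        h = sims[[k]]$h,
        positions = .drawPositions(ncol(sims[[k]]$h), spec@locusLength),
        group = rep(popNames, c(spec@n1, spec@n2)),
        class = cls, tmrca = sims[[k]]$tmrca)
    }
  }
  names(loci) <- sprintf("locus%04d", seq_len(spec@nLoci))
  hs <- HaplotypeSet(loci, spec@locusLength)
  if (!is.na(spec@outgroupTime)) hs <- attachOutgroup(spec, hs)

  gt <- if (genotypes)
    .pairIntoDiploids(hs, spec@n1, spec@n2, popNames, ecotypes, habitat)
  truth <- data.frame(locus = names(loci), class = classes,
                      stringsAsFactors = FALSE)
  list(haplotypes = hs, genotypes = gt, truth = truth)
}

# random pairing of haploid copies within each deme into diploids
.pairIntoDiploids <- function(hs, n1, n2, popNames, ecotypes, habitat) {
  if (n1 %% 2L || n2 %% 2L)
    stop("n1 and n2 must be even to form diploid individuals")
  ord1 <- sample.int(n1)
  ord2 <- n1 + sample.int(n2)
  a_idx <- c(ord1[seq(1, n1, 2)], ord2[seq(1, n2, 2)])
  b_idx <- c(ord1[seq(2, n1, 2)], ord2[seq(2, n2, 2)])
  nInd <- (n1 + n2) / 2

  nSites <- vapply(hs@loci, function(l) ncol(l$h), integer(1))
  tot <- sum(nSites)
  gt <- matrix(NA_integer_, tot, nInd)
  locusVec <- character(tot); posVec <- integer(tot)
  at <- 0L
  for (nm in names(hs@loci)) {
    loc <- hs@loci[[nm]]
    S <- ncol(loc$h)
    if (S == 0L) next
    derived <- loc$h
    if (!is.null(loc$outgroup)) {
      # ancestral state = outgroup allele
      flip <- loc$outgroup == 1L
      derived[, flip] <- 1L - derived[, flip]
    }
    rows <- at + seq_len(S)
    gt[rows, ] <- t(derived[a_idx, , drop = FALSE] +
                      derived[b_idx, , drop = FALSE])
    locusVec[rows] <- nm
    posVec[rows] <- loc$positions
    at <- at + S
  }
  siteInfo <- data.frame(locus = locusVec, pos = posVec,
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  rownames(gt) <- paste(siteInfo$locus, siteInfo$pos, sep = "_")
  colnames(gt) <- sprintf("%s_ind%02d",
                          rep(popNames, c(n1 / 2, n2 / 2)),
                          c(seq_len(n1 / 2), seq_len(n2 / 2)))
  sampleInfo <- data.frame(
    population = rep(popNames, c(n1 / 2, n2 / 2)),
    ecotype = rep(ecotypes, c(n1 / 2, n2 / 2)),
    habitat = rep(habitat, c(n1 / 2, n2 / 2)),
    stringsAsFactors = FALSE)
  GenotypeTable(gt, siteInfo, sampleInfo)
}

#' Attach an outgroup sequence to simulated haplotypes
#'
#' Extends the root branch of each locus genealogy to the outgroup divergence
#' time and adds Poisson infinite-sites mutations on the two resulting
#' branches: mutations on the ingroup stem are derived in every ingroup copy,
#' mutations on the outgroup branch are private to the outgroup. The outgroup
#' allele defines the ancestral state at every site. Requires the per-locus
#' TMRCA recorded by the simulator; uses R's RNG stream.
#'
#' @param spec a [ScenarioSpec-class] with `outgroupTime` set (must exceed
#'   `tS`).
#' @param hs a [HaplotypeSet-class] produced by [simulateDataset()] /
#'   [simulateLocus()].
#' @return the haplotype set with an `outgroup` 0/1 vector per locus.
#' @export
attachOutgroup <- function(spec, hs) {
  tOut <- spec@outgroupTime
  if (is.na(tOut)) stop("outgroupTime is not set on the scenario")
  if (tOut <= spec@params@tS) stop("outgroupTime must exceed the split time")
  theta <- spec@thetaLocus
  for (nm in names(hs@loci)) {
    loc <- hs@loci[[nm]]
    if (is.null(loc$tmrca)) stop("locus ", nm, " has no recorded TMRCA")
    divT <- max(tOut, loc$tmrca)
    nIn <- nrow(loc$h)
    sStem <- rpois(1, theta / 2 * (divT - loc$tmrca))
    sOut <- rpois(1, theta / 2 * divT)
    loc$outgroup <- rep(0L, ncol(loc$h))
    if (sStem + sOut > 0) {
      avail <- setdiff(seq_len(hs@locusLength) - 1L, loc$positions)
      if (length(avail) < sStem + sOut)
        stop("locus ", nm, ": not enough free positions for outgroup mutations")
      newPos <- sample(avail, sStem + sOut)
      newH <- cbind(
        matrix(1L, nIn, sStem),      # stem: all ingroup derived
        matrix(0L, nIn, sOut))       # outgroup-private
      newOut <- c(rep(0L, sStem), rep(1L, sOut))
      h <- cbind(loc$h, newH)
      og <- c(loc$outgroup, newOut)
      pos <- c(loc$positions, newPos)
      o <- order(pos)
      loc$h <- h[, o, drop = FALSE]
      loc$outgroup <- og[o]
      loc$positions <- pos[o]
    }
    hs@loci[[nm]] <- loc
  }
  validObject(hs)
  hs
}

#' Accumulate a JAFS directly from simulated haplotypes
#'
#' Counts, for every segregating site, the number of derived copies in each
#' deme (derived = allele differing from the outgroup when an outgroup is
#' present, otherwise the mutant allele 1) and accumulates the joint spectrum.
#' This is the simulator's internal spectrum, against which
#' [buildJafs()] on the genotype table can be cross-checked.
#'
#' @param hs a [HaplotypeSet-class].
#' @param group1,group2 group labels defining populations 1 and 2 (defaults:
#'   first two distinct labels).
#' @return a [Jafs-class] object.
#' @export
buildJafsFromHaplotypes <- function(hs, group1 = NULL, group2 = NULL) {
  labs <- unique(hs@loci[[1]]$group)
  if (is.null(group1)) group1 <- labs[1]
  if (is.null(group2)) group2 <- labs[2]
  i1 <- hs@loci[[1]]$group == group1
  i2 <- hs@loci[[1]]$group == group2
  n1 <- sum(i1); n2 <- sum(i2)
  counts <- matrix(0, n1 + 1, n2 + 1)
  for (loc in hs@loci) {
    if (ncol(loc$h) == 0L) next
    derived <- loc$h
    if (!is.null(loc$outgroup)) {
      flip <- loc$outgroup == 1L
      derived[, flip] <- 1L - derived[, flip]
    }
    i <- colSums(derived[i1, , drop = FALSE])
    j <- colSums(derived[i2, , drop = FALSE])
    for (s in seq_along(i)) counts[i[s] + 1, j[s] + 1] <-
        counts[i[s] + 1, j[s] + 1] + 1
  }
  Jafs(counts)
}
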