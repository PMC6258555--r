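# Small in-code fixtures shared across test files.

# a tiny genotype table: `counts` is a sites x individuals dosage matrix
makeGT <- function(counts, populations, ecotypes = NULL, habitat = NULL,
                   locus = NULL, pos = NULL) {
  counts <- as.matrix(counts)
  nInd <- ncol(counts); nSites <- nrow(counts)
  if (is.null(ecotypes)) ecotypes <- rep(c("S", "L"), length.out = nInd)
  if (is.null(habitat)) habitat <- ifelse(ecotypes == "S", -1, 1)
  if (is.null(locus)) locus <- paste0("tag", seq_len(nSites))
  if (is.null(pos)) pos <- rep(0L, nSites)
  GenotypeTable(counts,
                siteInfo = data.frame(locus = locus, pos = pos,
                                      ref = "A", alt = "T"),
                sampleInfo = data.frame(population = populations,
                                        ecotype = ecotypes,
                                        habitat = habitat))
}

# random 0/1 haplotype matrix with every site segregating
randomHaps <- function(n, S) {
  h <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
  for (s in seq_len(S)) {
    if (length(unique(h[, s])) == 1) h[sample(n, 1), s] <- 1 - h[1, s]
  }
  h
}

# a hand-written VCF with known per-stage filter outcomes (see
# test-filters-io.R for the enumeration)
writeToyVcf <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", 1:10)), collapse = "\t"))
  gts <- function(...) paste(c(...), collapse = "\t")
  rows <- c(
    # tagA:100 fully called, MAF 5/20
    gts("tagA", 100, "a1", "A", "T", ".", ".", ".", "GT",
        rep("0/1", 5), rep("0/0", 5)),
    # tagA:200 called in 7/10 -> presence 0.7 fails
    gts("tagA", 200, "a2", "A", "G", ".", ".", ".", "GT",
        rep("0/1", 4), rep("0/0", 3), rep("./.", 3)),
    # tagB:50 monomorphic (MAF 0) fails MAF
    gts("tagB", 50, "b1", "C", "T", ".", ".", ".", "GT", rep("0/0", 10)),
    # tagB:60 fully called, MAF 1/20
    gts("tagB", 60, "b2", "C", "A", ".", ".", ".", "GT",
        "0/1", rep("0/0", 9)),
    # tagB:70 called in 8/10 (presence 0.8 passes), MAF 3/16
    gts("tagB", 70, "b3", "G", "A", ".", ".", ".", "GT",
        "1/1", "0/1", rep("0/0", 6), "./.", "./."),
    # tagC:10 multi-allelic -> skipped at read time
    gts("tagC", 10, "c0", "A", "T,G", ".", ".", ".", "GT",
        rep("0/0", 9), "0/2"),
    # tagC:20 fully called, MAF 8/20
    gts("tagC", 20, "c1", "T", "C", ".", ".", ".", "GT",
        rep("0/1", 8), rep("0/0", 2)),
    # tagD:5 called in 5/10 -> fails presence
    gts("tagD", 5, "d1", "A", "C", ".", ".", ".", "GT",
        rep("0/1", 3), rep("0/0", 2), rep("./.", 5)))
  writeLines(c(hdr, rows), path)
  path
}

toyMetadata <- function() {
  data.frame(sample = paste0("ind", 1:10),
             population = rep(c("p1", "p2"), each = 5),
             ecotype = rep(c("S", "L"), each = 5),
             habitat = rep(c(-1, 1), each = 5))
}

# shared toy cohort for the accumulation tests: 6 L individuals, 5 loci
toyCohort <- function() {
  set.seed(203)
  nL <- 6
  g <- matrix(0, 5, nL + 2)
  # columns 1:2 are S individuals fixed for alt
  g[, 1:2] <- 2
  # carriers among L individuals (alt dosage >= 1), chosen with known counts
  carriers <- list(3, c(3, 4), c(3, 4, 5), c(3, 4, 5, 6, 7, 8), integer(0))
  for (l in 1:5) g[l, carriers[[l]]] <- 1
  gt <- makeGT(g, populations = c("pS", "pS", rep("pL", nL)),
               ecotypes = c("S", "S", rep("L", nL)),
               locus = paste0("o", 1:5), pos = rep(0L, 5))
  rn <- rownames(SummarizedExperiment::assay(gt, "GT"))
  ot <- classifyAlleles(gt, data.frame(snp = rn, locus = paste0("o", 1:5),
                                       pos = 0L, support = 1))
  list(gt = gt, ot = ot, k = c(1, 2, 3, 6, 0), n = nL)
}

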