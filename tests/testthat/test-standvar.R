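test_that("top-SNP selection keeps the max-support SNP with stable ties", {
  ot <- data.frame(snp = c("s1", "s2", "s3"), locus = c("t1", "t1", "t2"),
                   pos = c(5L, 9L, 1L), support = c(3, 5, 2))
  top <- selectTopSnpPerLocus(ot)
  expect_equal(top$snp, c("s2", "s3"))

  # already one per locus: identity
  one <- ot[c(1, 3), ]
  expect_equal(selectTopSnpPerLocus(one)$snp, one$snp)

  # ties break by position then id
  tie <- data.frame(snp = c("b", "a"), locus = "t", pos = c(3L, 3L),
                    support = c(7, 7))
  expect_equal(selectTopSnpPerLocus(tie)$snp, "a")
  tie2 <- data.frame(snp = c("b", "a"), locus = "t", pos = c(2L, 3L),
                     support = c(7, 7))
  expect_equal(selectTopSnpPerLocus(tie2)$snp, "b")

  set.seed(201)
  big <- data.frame(snp = paste0("s", 1:1000),
                    locus = paste0("t", sample(1:120, 1000, replace = TRUE)),
                    pos = sample.int(1200, 1000, replace = TRUE),
                    support = round(runif(1000, 0, 10), 3))
  top <- selectTopSnpPerLocus(big)
  oracle <- tapply(big$support, big$locus, max)
  expect_equal(nrow(top), length(oracle))
  expect_equal(top$support, as.numeric(oracle[top$locus]))
})

test_that("allele classification follows the pooled S-frequency majority", {
  # SNP fixed alt in S, absent in L -> alt is S-associated
  g <- rbind(c(2, 2, 0, 0), c(1, 1, 1, 1))
  gt <- makeGT(g, populations = c("p1", "p1", "p2", "p2"),
               ecotypes = c("S", "S", "L", "L"),
               locus = c("t1", "t2"), pos = c(0L, 0L))
  ot <- data.frame(snp = rownames(SummarizedExperiment::rowData(gt)),
                   locus = c("t1", "t2"), pos = c(0L, 0L), support = c(5, 4))
  ot$snp <- rownames(SummarizedExperiment::assay(gt, "GT"))
  cls <- classifyAlleles(gt, ot)
  expect_equal(cls$sAllele[1], "alt")
  expect_true(is.na(cls$sAllele[2]))  # exactly 0.5 in S: unassignable
})

test_that("classification recovers the deme truth at diverged loci", {
  spec <- ScenarioSpec("SI", DemographyParams(tS = 6), n1 = 10, n2 = 10,
                       nLoci = 150, thetaLocus = 1.5, seed = 202L)
  d <- simulateDataset(spec, popNames = c("pS", "pL"), ecotypes = c("S", "L"))
  g <- SummarizedExperiment::assay(d$genotypes, "GT")
  cd <- SummarizedExperiment::colData(d$genotypes)
  # fixed differences: S ecotype all alt while L all ref, or vice versa
  fS <- rowMeans(g[, cd$ecotype == "S", drop = FALSE]) / 2
  fL <- rowMeans(g[, cd$ecotype == "L", drop = FALSE]) / 2
  fixed <- (fS == 1 & fL == 0) | (fS == 0 & fL == 1)
  rd <- SummarizedExperiment::rowData(d$genotypes)
  ot <- data.frame(snp = rownames(g)[fixed], locus = rd$locus[fixed],
                   pos = rd$pos[fixed], support = 5)
  ot <- selectTopSnpPerLocus(ot)
  cls <- classifyAlleles(d$genotypes, ot)
  truthAllele <- ifelse(fS[match(cls$snp, rownames(g))] == 1, "alt", "ref")
  expect_gte(mean(cls$sAllele == truthAllele), 0.95)
})

test_that("per-individual carriage counts alternative-ecotype alleles", {
  # 3 L-individuals x 4 outlier loci; alt allele is S-associated everywhere
  g <- rbind(c(2, 2, 0, 1, 0),   # locus o1
             c(2, 2, 1, 0, 0),   # o2
             c(2, 2, 0, 0, 2),   # o3
             c(2, 2, NA, 1, 1))  # o4 (one missing genotype)
  gt <- makeGT(g, populations = c("pS", "pS", "pL", "pL", "pL"),
               ecotypes = c("S", "S", "L", "L", "L"),
               locus = paste0("o", 1:4), pos = rep(0L, 4))
  rn <- rownames(SummarizedExperiment::assay(gt, "GT"))
  ot <- classifyAlleles(gt, data.frame(snp = rn, locus = paste0("o", 1:4),
                                       pos = 0L, support = 1))
  carr <- perIndividualCarriage(gt, ot, "L")
  # hand count: ind3 carries at o2 only (o4 missing -> denominator 3),
  # ind4 at o1 and o4, ind5 at o3 and o4
  expect_equal(unname(carr), c(1 / 3, 2 / 4, 2 / 4))

  # homozygous own-allele everywhere -> 0; heterozygous everywhere -> 1
  g0 <- rbind(c(2, 0), c(2, 0))
  gt0 <- makeGT(g0, populations = c("pS", "pL"), ecotypes = c("S", "L"),
                locus = c("oA", "oB"), pos = rep(0L, 2))
  rn0 <- rownames(SummarizedExperiment::assay(gt0, "GT"))
  ot0 <- classifyAlleles(gt0, data.frame(snp = rn0, locus = c("oA", "oB"),
                                         pos = 0L, support = 1))
  expect_equal(unname(perIndividualCarriage(gt0, ot0, "L")), 0)
  g1 <- rbind(c(2, 1), c(2, 1))
  gt1 <- makeGT(g1, populations = c("pS", "pL"), ecotypes = c("S", "L"),
                locus = c("oA", "oB"), pos = rep(0L, 2))
  ot1 <- classifyAlleles(gt1, data.frame(snp = rownames(SummarizedExperiment::assay(gt1, "GT")),
                                         locus = c("oA", "oB"), pos = 0L,
                                         support = 1))
  expect_equal(unname(perIndividualCarriage(gt1, ot1, "L")), 1)
})

test_that("the exact accumulation expectation matches the closed form", {
  tc <- toyCohort()
  for (N in 1:6) {
    expected <- mean(1 - choose(tc$n - tc$k, N) / choose(tc$n, N))
    expect_equal(exactAccumulationExpectation(tc$gt, tc$ot, "L", N), expected)
  }
  # boundary cases: all carriers -> 1, no carriers -> 0
  kAll <- rep(6, 5)
  expect_equal(mean(1 - choose(6 - kAll, 3) / choose(6, 3)), 1)
})

test_that("exact expectation equals exhaustive subset enumeration", {
  tc <- toyCohort()
  carry <- t(vapply(1:5, function(l) {
    g <- SummarizedExperiment::assay(tc$gt, "GT")
    cd <- SummarizedExperiment::colData(tc$gt)
    g[l, cd$ecotype == "L"] >= 1
  }, logical(6)))
  carry <- t(carry)  # individuals x loci
  for (N in c(1, 2, 3, 5)) {
    expect_equal(exactAccumulationExpectation(tc$gt, tc$ot, "L", N),
                 oracleAccumExhaustive(carry, N), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo accumulation converges to the exact expectation", {
  tc <- toyCohort()
  curve <- accumulationCurve(tc$gt, tc$ot, "L", NGrid = 1:5, reps = 10000,
                             seed = 7L, keepReplicates = TRUE)
  for (k in 1:5) {
    exact <- exactAccumulationExpectation(tc$gt, tc$ot, "L", k)
    se <- curve@sd[k] / sqrt(curve@reps)
    expect_lt(abs(curve@mean[k] - exact), 3 * se + 1e-12)
  }
  # N = cohort size: every replicate equals the segregating fraction exactly
  full <- accumulationCurve(tc$gt, tc$ot, "L", NGrid = 6, reps = 50,
                            seed = 8L, keepReplicates = TRUE)
  expect_true(all(full@replicates == mean(tc$k > 0)))
})

test_that("a single carrier per locus reduces the curve to N / n", {
  g <- matrix(0, 4, 6)
  g[, 1:2] <- 2
  for (l in 1:4) g[l, 2 + l] <- 1  # exactly one carrier per locus
  gt <- makeGT(g, populations = c("pS", "pS", rep("pL", 4)),
               ecotypes = c("S", "S", rep("L", 4)),
               locus = paste0("o", 1:4), pos = rep(0L, 4))
  ot <- classifyAlleles(gt, data.frame(
    snp = rownames(SummarizedExperiment::assay(gt, "GT")),
    locus = paste0("o", 1:4), pos = 0L, support = 1))
  for (N in 1:4)
    expect_equal(exactAccumulationExpectation(gt, ot, "L", N), N / 4)
})

test_that("the exact expectation is non-decreasing in N", {
  set.seed(204)
  for (rep in 1:20) {
    n <- sample(4:9, 1); L <- sample(3:8, 1)
    g <- matrix(0, L, n + 1)
    g[, 1] <- 2
    for (l in seq_len(L)) {
      k <- sample(0:n, 1)
      if (k > 0) g[l, 1 + sample(n, k)] <- 1
    }
    gt <- makeGT(g, populations = c("pS", rep("pL", n)),
                 ecotypes = c("S", rep("L", n)),
                 locus = paste0("o", seq_len(L)), pos = rep(0L, L))
    ot <- suppressWarnings(classifyAlleles(gt, data.frame(
      snp = rownames(SummarizedExperiment::assay(gt, "GT")),
      locus = paste0("o", seq_len(L)), pos = 0L, support = 1)))
    vals <- vapply(seq_len(n), function(N)
      exactAccumulationExpectation(gt, ot, "L", N), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("accumulation curves are deterministic given the seed", {
  tc <- toyCohort()
  c1 <- accumulationCurve(tc$gt, tc$ot, "L", NGrid = 1:4, reps = 50, seed = 3L)
  c2 <- accumulationCurve(tc$gt, tc$ot, "L", NGrid = 1:4, reps = 50, seed = 3L)
  expect_identical(c1@mean, c2@mean)
  expect_error(accumulationCurve(tc$gt, tc$ot, "L", NGrid = 10, reps = 5,
                                 seed = 1L), "cohort")
})
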