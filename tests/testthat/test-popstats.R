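test_that("diversity and divergence match brute-force recounts", {
  h <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(nucleotideDiversity(rbind(h[1, ], h[1, ]), 100), 0)
  expect_equal(nucleotideDiversity(h, 100), 0.03)
  expect_equal(dxy(h[1, , drop = FALSE], h[2, , drop = FALSE], 100), 0.03)

  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:6, 1); S <- sample(1:12, 1); L <- sample(50:200, 1)
    h <- randomHaps(n, S)
    expect_equal(nucleotideDiversity(h, L), oraclePi(h, L),
                 tolerance = 1e-12)
    k <- sample(2:(n - 1), 1)
    expect_equal(dxy(h[1:k, , drop = FALSE], h[(k + 1):n, , drop = FALSE], L),
                 oracleDxy(h[1:k, , drop = FALSE],
                           h[(k + 1):n, , drop = FALSE], L),
                 tolerance = 1e-12)
  }
})

test_that("pairwise-complete deletion drives missing-data handling", {
  h <- rbind(c(0, 0), c(1, NA), c(1, 1))
  # pairs: (1,2): 1 diff over L-1; (1,3): 2 over L; (2,3): 0 over L-1
  L <- 10
  expect_equal(nucleotideDiversity(h, L), mean(c(1 / 9, 2 / 10, 0 / 9)))
  expect_error(dxy(matrix(0, 1, 3), matrix(0, 1, 2), 10), "lengths differ")
})

test_that("Tajima's D matches an independent implementation", {
  expect_equal(tajimasD(matrix(0L, 4, 0)), NA_real_)
  h0 <- matrix(c(0, 0, 0, 0), 4, 1)  # monomorphic input: S = 0
  expect_equal(tajimasD(h0), NA_real_)

  # frozen toy alignment, n = 4
  toy <- rbind(c(0, 0, 1, 0, 1),
               c(0, 1, 1, 0, 0),
               c(1, 0, 0, 1, 0),
               c(1, 0, 0, 1, 1))
  expect_equal(tajimasD(toy), oracleTajimaD(toy), tolerance = 1e-12)

  set.seed(102)
  for (rep in 1:50) {
    h <- randomHaps(sample(4:9, 1), sample(1:15, 1))
    expect_equal(tajimasD(h), oracleTajimaD(h), tolerance = 1e-12)
  }

  # two equal-frequency haplotype classes over many sites: D > 0
  h <- rbind(matrix(0, 4, 30), matrix(1, 4, 30))
  expect_gt(tajimasD(h), 0)
})

test_that("haplotype F_ST behaves at its boundaries and matches the oracle", {
  A <- matrix(0, 3, 4); B <- matrix(1, 3, 4)
  expect_equal(fstHaplotype(A, B), 1)
  expect_equal(fstHaplotype(A, A), NA_real_)  # H_b = 0 undefined

  # a random split of one panmictic sample: ratio-of-sums F_ST near zero
  set.seed(103)
  spec <- ScenarioSpec("SI", DemographyParams(tS = 0), n1 = 4, n2 = 4,
                       nLoci = 500, thetaLocus = 2, seed = 113L)
  d <- simulateDataset(spec)
  hw <- hb <- 0
  for (l in d$haplotypes@loci) {
    if (ncol(l$h) == 0) next
    cnt1 <- colSums(l$h[1:4, , drop = FALSE])
    cnt2 <- colSums(l$h[5:8, , drop = FALSE])
    hw <- hw + (sum(cnt1 * (4 - cnt1)) + sum(cnt2 * (4 - cnt2))) /
      (2 * choose(4, 2))
    hb <- hb + sum(cnt1 * (4 - cnt2) + cnt2 * (4 - cnt1)) / 16
  }
  expect_lt(abs(1 - hw / hb), 0.05)

  for (rep in 1:50) {
    hA <- randomHaps(sample(2:5, 1), 8)
    hB <- randomHaps(sample(2:5, 1), 8)
    expect_equal(fstHaplotype(hA, hB), oracleFstHap(hA, hB),
                 tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham F_ST matches the ANOVA oracle per SNP", {
  set.seed(104)
  for (rep in 1:50) {
    nPer <- sample(3:8, 1)
    g <- matrix(rbinom(3 * 2 * nPer, 2, runif(1, 0.2, 0.8)), nrow = 3)
    pops <- rep(c("x", "y"), each = nPer)
    res <- fstWC(g, pops)
    for (s in 1:3) {
      o <- oracleWC(g[s, ], pops)
      if (is.na(res$fst[s])) {
        expect_true(is.na(o$fst) || o$a + o$b + o$c == 0)
      } else {
        expect_equal(res$fst[s], o$fst, tolerance = 1e-9)
        expect_equal(res$a[s], o$a, tolerance = 1e-9)
      }
    }
  }
})

test_that("identical population compositions give near-zero WC F_ST", {
  g <- rbind(rep(c(0, 1, 2, 1), 2), rep(c(2, 2, 0, 0), 2))
  res <- fstWC(g, rep(c("x", "y"), each = 4))
  # identical compositions: estimate may be slightly negative, never clamped
  expect_true(all(res$fst < 0.05))
  expect_true(is.numeric(attr(res, "overall")))
})

test_that("the multi-locus WC estimate is a ratio of sums", {
  set.seed(105)
  g <- matrix(rbinom(40, 2, 0.4), nrow = 5)
  pops <- rep(c("x", "y"), each = 4)
  res <- fstWC(g, pops)
  ok <- !is.na(res$fst)
  expect_equal(attr(res, "overall"),
               sum(res$a[ok]) / sum((res$a + res$b + res$c)[ok]),
               tolerance = 1e-12)
})

test_that("outgroup normalization rescales and flags divided-by-zero loci", {
  st <- data.frame(dXY = c(0.02, 0.01), piTot = c(0.01, 0.005),
                   dXYOut = c(0.02, 0))
  out <- normalizeByOutgroup(st)
  expect_equal(out$normDxy, c(1, NA_real_))
  expect_equal(out$normPi, c(0.5, NA_real_))
})

test_that("locusStats summarises simulated loci coherently", {
  spec <- ScenarioSpec("SI", DemographyParams(tS = 3), n1 = 6, n2 = 6,
                       nLoci = 30, thetaLocus = 2, outgroupTime = 10,
                       seed = 106L)
  d <- simulateDataset(spec)
  st <- locusStats(d$haplotypes, groupS = "pop1", groupL = "pop2")
  st <- normalizeByOutgroup(st)
  expect_equal(nrow(st), 30)
  expect_true(all(st$dXY >= 0, na.rm = TRUE))
  expect_true(all(st$piTot >= 0 & st$piTot <= 1, na.rm = TRUE))
  # deep isolation: divergence between demes exceeds within-deme diversity
  expect_gt(mean(st$dXY, na.rm = TRUE), mean(st$piS, na.rm = TRUE))
  expect_true(all(st$fstHap <= 1, na.rm = TRUE))
  # d_XY to the outgroup dominates ingroup divergence
  expect_true(all(st$normDxy < 1.5, na.rm = TRUE))
})

test_that("haplotype groups can be split at the top outlier SNP", {
  loc <- list(h = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
              positions = c(10L, 20L),
              group = c("a", "a", "b", "b"), class = "island")
  hs <- HaplotypeSet(list(locus1 = loc), 100L)
  st <- locusStats(hs, "a", "b", splitAt = c(locus1 = 10))
  expect_equal(st$nSeqS, 2L)
  expect_equal(st$fstHap, 1)
})

test_that("LD r2 is 1 for duplicated SNPs and NA for monomorphic ones", {
  g <- rbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2), rep(1, 6),
             c(2, 1, 0, 1, 2, 0))
  gt <- makeGT(g, populations = rep("p1", 6),
               locus = rep("tagA", 4), pos = c(0L, 50L, 100L, 150L))
  ld <- ldR2(gt)
  dup <- ld[ld$site1 == 1 & ld$site2 == 2, ]
  expect_equal(dup$r2, 1, tolerance = 1e-12)
  expect_equal(dup$dist, 50)
  expect_true(all(is.na(ld$r2[ld$site1 == 3 | ld$site2 == 3])))
  # perfectly anti-correlated dosages also give r2 = 1
  anti <- ld[ld$site1 == 1 & ld$site2 == 4, ]
  expect_equal(anti$r2, 1, tolerance = 1e-12)
})

test_that("independent SNPs decay to the sampling floor of r2", {
  set.seed(107)
  nInd <- 40
  g <- matrix(rbinom(200 * nInd, 2, 0.5), ncol = nInd)
  gt <- makeGT(g, populations = rep("p1", nInd),
               locus = rep("tagA", 200), pos = seq_len(200))
  pairs <- cbind(seq(1, 199, 2), seq(2, 200, 2))
  ld <- ldR2(gt, pairs = pairs)
  # E[r2] for independent sites is about 1/(n - 1)
  expect_lt(abs(mean(ld$r2, na.rm = TRUE) - 1 / (nInd - 1)), 0.02)
  dec <- ldDecay(ld, breaks = c(0, 1, 2, 300))
  expect_equal(nrow(dec), 3)
  expect_equal(sum(dec$n), sum(!is.na(ld$r2)))
})

test_that("Mantel r and p agree with exhaustive enumeration", {
  set.seed(108)
  mkDist <- function(n) {
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  }
  A <- mkDist(4); B <- mkDist(4)
  exact <- oracleMantelExact(A, B)
  got <- mantelTest(A, B, nPerm = 20000, seed = 1)
  expect_equal(got$r, exact$r, tolerance = 1e-12)
  # permutation p converges to the enumerated tail probability
  expect_lt(abs(got$p - exact$p), 0.02)

  same <- mantelTest(A, A, nPerm = 999, seed = 2)
  expect_equal(same$r, 1)
  expect_lt(same$p, 0.05)
})

test_that("Mantel p-values are approximately uniform under the null", {
  set.seed(109)
  n <- 6
  ps <- replicate(400, {
    m1 <- matrix(0, n, n); m1[lower.tri(m1)] <- runif(15)
    m2 <- matrix(0, n, n); m2[lower.tri(m2)] <- runif(15)
    mantelTest(m1 + t(m1), m2 + t(m2), nPerm = 49)$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_gt(mean(ps < 0.2), 0.10)
  expect_lt(mean(ps < 0.2), 0.30)
})

test_that("the empirical outlier scan flags strict exceedances only", {
  set.seed(110)
  x <- runif(200)
  expect_equal(sum(empiricalOutlierScan(x, q = 1.0)$outlier), 0L)
  allEq <- empiricalOutlierScan(rep(0.3, 200), q = 0.95)
  expect_equal(sum(allEq$outlier), 0L)
  sc <- empiricalOutlierScan(x, q = 0.9)
  expect_equal(sum(sc$outlier), sum(x > quantile(x, 0.9)))
  expect_true(all(sc$support >= 0))
  expect_warning(empiricalOutlierScan(runif(50)), "fewer than 100")
})

test_that("island loci are enriched among empirical outliers", {
  spec <- ScenarioSpec("SC2M",
                       DemographyParams(tS = 2, tSC = 0.05, M12 = 4, M21 = 4,
                                        MI12 = 0.02, MI21 = 0.02, P = 0.2),
                       n1 = 12, n2 = 12, nLoci = 600, thetaLocus = 2,
                       seed = 111L)
  d <- simulateDataset(spec)
  wc <- fstWC(d$genotypes)
  scan <- empiricalOutlierScan(wc$fst, q = 0.9)
  rd <- SummarizedExperiment::rowData(d$genotypes)
  isIsland <- d$truth$class[match(rd$locus, d$truth$locus)] == "island"
  tab <- table(flagged = scan$outlier, island = isIsland)
  ft <- fisher.test(tab)
  expect_gt(ft$estimate, 1)
  expect_lt(ft$p.value, 0.05)
})
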