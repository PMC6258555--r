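test_that("panmictic limit gives the 1/i marginal spectrum", {
  F <- expectedJafs(DemographyParams(tS = 0), "SI", 4, 4, reps = 20000,
                    engineSeed = 2L)
  m <- jafsCounts(F)
  pool <- vapply(1:7, function(k) sum(m[outer(0:4, 0:4, "+") == k]),
                 numeric(1))
  # i * F_i should be flat
  expect_lt(max(abs(pool * (1:7) - mean(pool * (1:7)))) / mean(pool * (1:7)),
            0.05)
})

test_that("expected spectrum is symmetric under deme exchange", {
  p <- DemographyParams(nu1 = 1, nu2 = 1, tS = 1, tSC = 0.3, M12 = 1.5,
                        M21 = 1.5)
  F <- jafsCounts(expectedJafs(p, "SC", 5, 5, reps = 30000, engineSeed = 3L))
  expect_lt(sum(abs(F - t(F))) / sum(F), 0.05)
})

test_that("long isolation concentrates mass on the axes and fixed cells", {
  F <- jafsCounts(expectedJafs(DemographyParams(tS = 10), "SI", 4, 4,
                               reps = 10000, engineSeed = 4L))
  F[1, 1] <- 0; F[5, 5] <- 0
  onAxes <- sum(F[1, ]) + sum(F[, 1]) + F[5, 1] + F[1, 5] - F[1, 1]
  expect_gt(onAxes / sum(F), 0.95)
})

test_that("P = 0 and Q = 0 reduce the mixture to the homogeneous model", {
  p0 <- DemographyParams(tS = 1, tSC = 0.2, M12 = 1, M21 = 1, MI12 = 0.01,
                         MI21 = 0.01, P = 0, Q = 0, hrf = 0.5)
  a <- expectedJafs(p0, "SC2M_hrf", 4, 4, reps = 2000, engineSeed = 5L)
  b <- expectedJafs(p0, "SC", 4, 4, reps = 2000, engineSeed = 5L)
  expect_identical(jafsCounts(a), jafsCounts(b))
})

test_that("mixture class weights always sum to one", {
  set.seed(30)
  for (rep in 1:20) {
    p <- DemographyParams(P = runif(1), Q = runif(1), hrf = runif(1, 0.1, 1))
    expect_equal(sum(radpop:::.classProbs(p)), 1, tolerance = 1e-12)
  }
})

test_that("the Poisson theta profile is the analytic optimum", {
  # single unmasked cell, O = 2, F = 1
  O <- matrix(0, 3, 3); O[2, 2] <- 2
  FF <- matrix(0, 3, 3); FF[2, 2] <- 1
  ll <- jafsLogLik(Jafs(O), Jafs(FF))
  expect_equal(ll$thetaHat, 2)
  expect_equal(ll$lnL, 2 * log(2) - 2 - log(2))

  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    O <- matrix(rpois(n * n, 5), n, n)
    FF <- matrix(runif(n * n, 0.1, 3), n, n)
    jO <- Jafs(O); jF <- Jafs(FF)
    ll <- jafsLogLik(jO, jF)
    grid <- oracleThetaGrid(O[!jafsMask(jO)], FF[!jafsMask(jF)])
    expect_equal(ll$thetaHat, grid, tolerance = 1e-9)
  }
})

test_that("observed = model gives theta_hat 1 and the saturated value", {
  set.seed(12)
  FF <- matrix(runif(25, 0.5, 4), 5, 5)
  j <- Jafs(FF)
  ll <- jafsLogLik(j, Jafs(FF))
  expect_equal(ll$thetaHat, 1)
  O <- FF[!jafsMask(j)]
  expect_equal(ll$lnL, sum(O * log(O) - O - lgamma(O + 1)))
})

test_that("the likelihood is invariant to rescaling the model spectrum", {
  set.seed(13)
  O <- Jafs(matrix(rpois(25, 6), 5, 5))
  FF <- matrix(runif(25, 0.2, 2), 5, 5)
  l1 <- jafsLogLik(O, Jafs(FF))
  l2 <- jafsLogLik(O, Jafs(7.3 * FF))
  expect_equal(l1$lnL, l2$lnL, tolerance = 1e-10)
  expect_equal(l1$thetaHat, 7.3 * l2$thetaHat, tolerance = 1e-10)
})

test_that("zero model mass under observed data is an error, not a clamp", {
  O <- matrix(0, 3, 3); O[2, 1] <- 4
  FF <- matrix(1, 3, 3); FF[2, 1] <- 0
  expect_error(jafsLogLik(Jafs(O), Jafs(FF)), "zero where data")
})

test_that("a fully fixed fit evaluates the point likelihood with k = 0", {
  spec <- ScenarioSpec("SI", DemographyParams(nu1 = 1, nu2 = 1, tS = 0.5),
                       n1 = 4, n2 = 4, nLoci = 500, thetaLocus = 1,
                       seed = 14L)
  d <- simulateDataset(spec)
  j <- buildJafsFromHaplotypes(d$haplotypes)
  f <- fitDemography(j, "SI", fixed = c(nu1 = 1, nu2 = 1, tS = 0.5),
                     reps = 500, engineSeed = 7L)
  expect_equal(f@k, 0L)
  expect_equal(f@AIC, -2 * f@lnL)
  expect_true(is.finite(f@thetaHat))
})

test_that("fits are deterministic given the master seed", {
  spec <- ScenarioSpec("SI", DemographyParams(nu1 = 1, nu2 = 0.5, tS = 1),
                       n1 = 4, n2 = 4, nLoci = 2000, thetaLocus = 1,
                       seed = 15L)
  d <- simulateDataset(spec)
  j <- buildJafsFromHaplotypes(d$haplotypes)
  f1 <- fitDemography(j, "SI", nStarts = 2, reps = 200, maxit = 30,
                      engineSeed = 8L, seed = 4L)
  f2 <- fitDemography(j, "SI", nStarts = 2, reps = 200, maxit = 30,
                      engineSeed = 8L, seed = 4L)
  expect_identical(bestParams(f1), bestParams(f2))
  expect_identical(f1@lnL, f2@lnL)
  expect_identical(f1@replicates, f2@replicates)
  expect_equal(f1@AIC, 2 * f1@k - 2 * f1@lnL)
})

test_that("SI recovers the relative deme size from its own data", {
  spec <- ScenarioSpec("SI", DemographyParams(nu1 = 1, nu2 = 0.5, tS = 1),
                       n1 = 8, n2 = 8, nLoci = 15000, thetaLocus = 1,
                       seed = 16L)
  d <- simulateDataset(spec)
  j <- buildJafsFromHaplotypes(d$haplotypes)
  f <- fitDemography(j, "SI", nStarts = 2, reps = 600, engineSeed = 9L,
                     seed = 5L)
  expect_lt(abs(bestParams(f)[["nu2"]] - 0.5) / 0.5, 0.5)
})

test_that("comparing a model with itself gives a zero AIC difference", {
  spec <- ScenarioSpec("SI", DemographyParams(tS = 1), n1 = 4, n2 = 4,
                       nLoci = 1000, thetaLocus = 1, seed = 17L)
  d <- simulateDataset(spec)
  j <- buildJafsFromHaplotypes(d$haplotypes)
  tab <- compareModels(j, c("SI", "SI"), nStarts = 2, reps = 200,
                       maxit = 25, engineSeed = 10L, seed = 6L)
  expect_equal(tab$dAIC, c(0, 0))
  expect_true(all(diff(tab$AIC) >= 0))
})

test_that("replicate tables are AIC-sorted with the best five flagged", {
  spec <- ScenarioSpec("SI", DemographyParams(tS = 1), n1 = 4, n2 = 4,
                       nLoci = 1000, thetaLocus = 1, seed = 18L)
  d <- simulateDataset(spec)
  j <- buildJafsFromHaplotypes(d$haplotypes)
  f <- fitDemography(j, "SI", nStarts = 6, reps = 150, maxit = 20,
                     engineSeed = 11L, seed = 7L)
  tab <- fitReplicates(f)
  expect_false(is.unsorted(tab$AIC))
  expect_equal(sum(tab$bestFive), 5L)
  expect_equal(f@lnL, max(tab$lnL))
})
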