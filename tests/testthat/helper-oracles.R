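# Independent brute-force oracles. These deliberately re-derive each statistic
# along a different route than the package implementation.

# mean per-site pairwise difference, all-pairs loop
oraclePi <- function(h, L) {
  n <- nrow(h)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(h[i, ] != h[j, ]) / L
    np <- np + 1
  }
  tot / np
}

oracleDxy <- function(hA, hB, L) {
  tot <- 0
  for (i in seq_len(nrow(hA))) for (j in seq_len(nrow(hB)))
    tot <- tot + sum(hA[i, ] != hB[j, ]) / L
  tot / (nrow(hA) * nrow(hB))
}

# Tajima's D from the textbook constants, written independently
oracleTajimaD <- function(h) {
  n <- nrow(h)
  freqs <- colSums(h)
  seg <- freqs > 0 & freqs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pihat <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pihat <- pihat + sum(h[i, seg] != h[j, seg])
  pihat <- pihat / (n * (n - 1) / 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pihat - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# haplotype F_ST through explicit H_w / H_b averages
oracleFstHap <- function(hA, hB) {
  pairsum <- function(h) {
    n <- nrow(h); tot <- 0
    if (n < 2) return(c(0, 0))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + sum(h[i, ] != h[j, ])
    c(tot, n * (n - 1) / 2)
  }
  wa <- pairsum(hA); wb <- pairsum(hB)
  Hw <- (wa[1] + wb[1]) / (wa[2] + wb[2])
  cross <- 0
  for (i in seq_len(nrow(hA))) for (j in seq_len(nrow(hB)))
    cross <- cross + sum(hA[i, ] != hB[j, ])
  Hb <- cross / (nrow(hA) * nrow(hB))
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}

# Weir-Cockerham theta via the ANOVA mean-squares formulation (distinct from
# the implementation's direct a/b/c algebra)
oracleWC <- function(genoRow, pops) {
  plev <- unique(pops)
  r <- length(plev)
  ni <- pbar_i <- hi <- numeric(r)
  for (k in seq_len(r)) {
    x <- genoRow[pops == plev[k]]
    x <- x[!is.na(x)]
    ni[k] <- length(x)
    pbar_i[k] <- mean(x) / 2
    hi[k] <- mean(x == 1)
  }
  if (any(ni < 2)) return(NA_real_)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pbar_i) / sum(ni)
  s2 <- sum(ni * (pbar_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# fold a spectrum by re-binning each site's (i, j) configuration
oracleFoldRecount <- function(counts) {
  n1 <- nrow(counts) - 1L; n2 <- ncol(counts) - 1L
  out <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    m <- counts[i + 1, j + 1]
    if (m == 0) next
    if (i + j < (n1 + n2) / 2) {
      out[i + 1, j + 1] <- out[i + 1, j + 1] + m
    } else if (i + j > (n1 + n2) / 2) {
      out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + m
    } else {
      out[i + 1, j + 1] <- out[i + 1, j + 1] + m / 2
      out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + m / 2
    }
  }
  out
}

# Poisson theta profile by 1-D ternary search. Direct lnL values go flat at
# sqrt(machine-eps) near the optimum, so candidates are compared through the
# cancellation-free difference lnL(a) - lnL(b) =
# sum(O) * log1p((a - b) / b) - (a - b) * sum(F).
oracleThetaGrid <- function(O, FF) {
  sO <- sum(O); sF <- sum(FF)
  better <- function(a, b) sO * log1p((a - b) / b) - (a - b) * sF > 0
  lo <- 1e-6; hi <- sO / sF * 10 + 1
  for (pass in 1:200) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    if (better(m1, m2)) hi <- m2 else lo <- m1
  }
  (lo + hi) / 2
}

# exact accumulation expectation by exhaustive subset enumeration
oracleAccumExhaustive <- function(carry, N) {
  n <- nrow(carry)
  subsets <- utils::combn(n, N)
  vals <- apply(subsets, 2, function(ix)
    mean(colSums(carry[ix, , drop = FALSE]) > 0))
  mean(vals)
}

# exact Mantel p-value by full enumeration of row/column permutations
oracleMantelExact <- function(A, B) {
  n <- nrow(A)
  lt <- lower.tri(A)
  obs <- cor(A[lt], B[lt])
  perms <- gtoolsPermutations(n)
  ge <- 0
  for (k in seq_len(nrow(perms))) {
    ix <- perms[k, ]
    if (cor(A[lt], B[ix, ix][lt]) >= obs - 1e-12) ge <- ge + 1
  }
  list(r = obs, p = ge / nrow(perms))
}

# all permutations of 1..n (tiny n)
gtoolsPermutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtoolsPermutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- (1:n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
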