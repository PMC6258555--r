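#' @include AllClasses.R constructors.R simdata.R
NULL

# free parameters per model id
.freeParams <- function(modelId) {
  mi <- parseModelId(modelId)
  if (is.null(mi)) stop("unknown model id: ", modelId)
  fp <- c("nu1", "nu2", "tS")
  if (mi$base != "SI") fp <- c(fp, "M12", "M21")
  if (mi$base == "SC") fp <- c(fp, "tSC")
  if (mi$twoM) fp <- c(fp, "MI12", "MI21", "P")
  if (mi$hrf) fp <- c(fp, "hrf", "Q")
  fp
}

# default optimization box, on the natural scale
.defaultBounds <- function(free) {
  lower <- c(nu1 = 0.01, nu2 = 0.01, tS = 0.01, tSC = 1e-3, M12 = 1e-3,
             M21 = 1e-3, MI12 = 1e-5, MI21 = 1e-5, P = 0.01, Q = 0.01,
             hrf = 0.02)
  upper <- c(nu1 = 100, nu2 = 100, tS = 20, tSC = 20, M12 = 50, M21 = 50,
             MI12 = 50, MI21 = 50, P = 0.99, Q = 0.99, hrf = 1)
  list(lower = lower[free], upper = upper[free])
}

# run the RNG-isolated engine: evaluates fn() under a fixed seed and restores
# the caller's RNG state afterwards
.withEngineSeed <- function(engineSeed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(engineSeed)
  fn()
}

#' Expected joint allele frequency spectrum (per unit theta)
#'
#' Monte-Carlo structured-coalescent engine: for each locus class the expected
#' spectrum is estimated by accumulating branch lengths by frequency class over
#' replicate genealogies (`E[sites in class (i,j)] = theta/2 * E[length]`),
#' and the model spectrum is the mixture
#' `(1-P)(1-Q) F(M, nu) + P(1-Q) F(MI, nu) + (1-P)Q F(M, hrf nu) + PQ F(MI, hrf nu)`.
#' The engine is deterministic given `engineSeed` (common random numbers), so
#' likelihood surfaces built on it are optimizable; precision is controlled by
#' `reps`. The caller's RNG state is left untouched.
#'
#' @param params a [DemographyParams-class].
#' @param modelId model identifier; heterogeneity terms are only active when
#'   the id carries the `2M` / `_hrf` flags.
#' @param n1,n2 haploid sample sizes of the spectrum.
#' @param reps Monte-Carlo replicate genealogies per mixture component.
#' @param engineSeed fixed engine seed.
#' @return a [Jafs-class] holding the expected spectrum per unit theta.
#' @examples
#' F <- expectedJafs(DemographyParams(M12 = 1, M21 = 1), "IM", 4, 4,
#'                   reps = 200)
#' @export
expectedJafs <- function(params, modelId, n1, n2, reps = 2000L,
                         engineSeed = 1L) {
  mi <- parseModelId(modelId)
  if (is.null(mi)) stop("unknown model id: ", modelId)
  validObject(params)
  p <- if (mi$twoM) params@P else 0
  q <- if (mi$hrf) params@Q else 0
  w <- setNames(c((1 - p) * (1 - q), p * (1 - q), (1 - p) * q, p * q),
                .lociClassNames)
  FF <- .withEngineSeed(engineSeed, function() {
    acc <- matrix(0, n1 + 1, n2 + 1)
    for (cls in .lociClassNames) {
      if (w[[cls]] <= 0) next
      a <- .kernelArgs(params, modelId, cls)
      acc <- acc + w[[cls]] *
        cpp_branch_jafs(n1, n2, a$nu1, a$nu2, a$m12, a$m21,
                        a$tSplit, a$migStop, a$nuAnc, as.integer(reps))
    }
    acc
  })
  if (any(!is.finite(FF))) stop("non-finite entries in expected spectrum")
  j <- Jafs(FF)
  if (jafsSum(j) <= 0) stop("expected spectrum has zero total mass")
  j
}

#' Poisson composite log-likelihood with profiled theta
#'
#' Treats each unmasked cell of the observed spectrum as an independent
#' Poisson count with mean `theta * F[i, j]`. The scale is profiled out
#' analytically: `theta_hat = sum(O) / sum(F)` over unmasked cells, and
#' `lnL = sum(O log(theta_hat F) - theta_hat F - log O!)`.
#'
#' @param observed,model [Jafs-class] objects of identical shape and mask;
#'   `model` is the expected spectrum per unit theta.
#' @return list with `lnL` and `thetaHat`.
#' @export
jafsLogLik <- function(observed, model) {
  if (!identical(dim(observed@counts), dim(model@counts)))
    stop("observed and model spectra have different shapes")
  if (!identical(observed@mask, model@mask))
    stop("observed and model masks differ")
  O <- observed@counts[!observed@mask]
  FF <- model@counts[!model@mask]
  if (any(FF == 0 & O > 0))
    stop("model spectrum is zero where data are observed; ",
         "increase engine precision (reps)")
  th <- sum(O) / sum(FF)
  pos <- FF > 0
  lnL <- sum(O[pos] * log(th * FF[pos]) - th * FF[pos] - lgamma(O[pos] + 1))
  list(lnL = lnL, thetaHat = th)
}

# full parameter vector from free values + fixed overrides, on top of nulls
.assembleParams <- function(free_vals, fixed, symmetricM = FALSE) {
  v <- c(nu1 = 1, nu2 = 1, tS = 1, tSC = 0, M12 = 0, M21 = 0, MI12 = 0,
         MI21 = 0, P = 0, Q = 0, hrf = 1)
  v[names(fixed)] <- fixed
  v[names(free_vals)] <- free_vals
  if (symmetricM) { v[["M21"]] <- v[["M12"]]; v[["MI21"]] <- v[["MI12"]] }
  if (v[["tSC"]] > v[["tS"]]) v[["tSC"]] <- v[["tS"]]
  paramsFromVector(v)
}

# evaluate the Poisson composite likelihood at one parameter point
.objectiveAt <- function(freev, fixedv, symmetricM, modelId, observed, n,
                         reps, engineSeed) {
  p <- .assembleParams(freev, fixedv, symmetricM)
  FF <- expectedJafs(p, modelId, n[[1]], n[[2]], reps = reps,
                     engineSeed = engineSeed)
  jafsLogLik(observed, FF)
}

# step-robust compass (pattern) search on log10 coordinates, clipped to the
# box. The Monte-Carlo objective carries noise that stalls simplex methods;
# coordinate steps that start large and shrink geometrically ride the
# macro-scale gradient through it.
.compassSearch <- function(x0, fn, lo, hi, step = 0.5, shrink = 0.6,
                           minStep = 0.03, maxIter = 150L) {
  x <- pmin(pmax(x0, lo), hi)
  fx <- fn(x)
  for (it in seq_len(maxIter)) {
    improved <- FALSE
    for (k in seq_along(x)) for (s in c(1, -1)) {
      y <- x
      y[k] <- min(max(y[k] + s * step, lo[k]), hi[k])
      if (y[k] == x[k]) next
      fy <- fn(y)
      if (fy < fx) { x <- y; fx <- fy; improved <- TRUE }
    }
    if (!improved) {
      step <- step * shrink
      if (step < minStep) break
    }
  }
  list(par = x, value = fx)
}

#' Fit a divergence model to an observed spectrum
#'
#' Replicated derivative-free optimization of the Poisson composite
#' likelihood on log10-transformed parameters. Each of the `nStarts` runs is
#' a two-stage compass (pattern) search: a coarse descent at engine precision
#' `reps` followed by a refinement at `4 * reps` with smaller steps. The
#' first start sits at the geometric midpoint of the bounds; each subsequent
#' start perturbs the best parameters found so far by a factor `U(1/3, 3)`
#' per coordinate. The Monte-Carlo engine runs under a fixed `engineSeed`
#' for every evaluation, making the objective deterministic; the whole fit
#' is reproducible given `seed`. Runs whose optimum sits on a bound are
#' flagged `"bound-pinned"`.
#'
#' @param observed a [Jafs-class] of counts.
#' @param modelId model identifier.
#' @param bounds optional list with named numeric `lower` and `upper` on the
#'   natural scale (defaults cover all parameters).
#' @param nStarts number of replicated optimization runs.
#' @param fixed named numeric vector of parameters to hold fixed (removed from
#'   the free set; with all parameters fixed, `k = 0` and the likelihood is
#'   evaluated at that point).
#' @param symmetricM constrain migration to be symmetric (`M21 = M12`,
#'   `MI21 = MI12`), halving the migration dimensions.
#' @param reps,engineSeed engine precision and common-random-numbers seed.
#' @param maxit iteration cap per search stage.
#' @param seed master seed for start perturbations.
#' @return a [FitResult-class].
#' @export
fitDemography <- function(observed, modelId, bounds = NULL, nStarts = 20L,
                          fixed = NULL, symmetricM = FALSE, reps = 1000L,
                          engineSeed = 1L, maxit = 150L, seed = 1L) {
  n <- sampleSizes(observed)
  free <- .freeParams(modelId)
  if (symmetricM) free <- setdiff(free, c("M21", "MI21"))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), c(free, "theta"))
    if (length(bad)) stop("fixed parameters not in model: ",
                          paste(bad, collapse = ", "))
    free <- setdiff(free, names(fixed))
  }
  fixedv <- if (is.null(fixed)) numeric(0) else fixed
  k <- length(free)

  objective <- function(freev)
    .objectiveAt(freev, fixedv, symmetricM, modelId, observed, n,
                 4L * as.integer(reps), engineSeed)

  if (k == 0L) {
    ll <- objective(numeric(0))
    pars <- paramVector(.assembleParams(numeric(0), fixedv, symmetricM))
    return(new("FitResult", modelId = modelId, params = pars, lnL = ll$lnL,
               k = 0L, AIC = -2 * ll$lnL, thetaHat = ll$thetaHat,
               replicates = data.frame(run = 1L, lnL = ll$lnL,
                                       AIC = -2 * ll$lnL,
                                       converged = TRUE, bestFive = TRUE),
               status = "ok"))
  }

  b <- .defaultBounds(free)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <-
        bounds$lower[intersect(names(bounds$lower), free)]
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <-
        bounds$upper[intersect(names(bounds$upper), free)]
  }
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)) ||
      any(b$lower <= 0 & names(b$lower) != "tSC") || any(b$lower > b$upper))
    stop("bounds must be finite, positive and ordered")
  lo <- log10(b$lower); hi <- log10(b$upper)

  negLnL <- function(lx, nrep) {
    x <- setNames(10^lx, free)
    ll <- try(.objectiveAt(x, fixedv, symmetricM, modelId, observed,
                           n, nrep, engineSeed), silent = TRUE)
    if (inherits(ll, "try-error")) return(1e12)
    -ll$lnL
  }

  set.seed(seed)
  runs <- vector("list", nStarts)
  bestPar <- 10^((lo + hi) / 2)
  bestVal <- Inf
  for (r in seq_len(nStarts)) {
    start <- if (r == 1L) bestPar else {
      pmin(pmax(bestPar * runif(k, 1 / 3, 3), b$lower), b$upper)
    }
    coarse <- .compassSearch(log10(start), function(lx) negLnL(lx, reps),
                             lo, hi, step = 0.5, minStep = 0.03,
                             maxIter = maxit)
    fine <- .compassSearch(coarse$par,
                           function(lx) negLnL(lx, 4L * as.integer(reps)),
                           lo, hi, step = 0.12, minStep = 0.02,
                           maxIter = maxit)
    lx <- fine$par
    x <- setNames(10^lx, free)
    ll <- try(objective(x), silent = TRUE)
    if (inherits(ll, "try-error") || fine$value >= 1e12) {
      runs[[r]] <- list(ok = FALSE, start = start)
      next
    }
    pinned <- any(abs(lx - lo) < 1e-6 | abs(lx - hi) < 1e-6)
    runs[[r]] <- list(ok = TRUE, start = start, end = x, lnL = ll$lnL,
                      thetaHat = ll$thetaHat, pinned = pinned,
                      converged = TRUE)
    if (-ll$lnL < bestVal) { bestVal <- -ll$lnL; bestPar <- x }
  }

  okruns <- Filter(function(r) isTRUE(r$ok), runs)
  if (!length(okruns)) stop("all optimization runs failed for model ", modelId)

  tab <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (!isTRUE(r$ok))
      return(data.frame(run = i, lnL = NA_real_, AIC = NA_real_,
                        converged = FALSE, pinned = NA,
                        t(setNames(rep(NA_real_, k), paste0("start_", free))),
                        t(setNames(rep(NA_real_, k), free))))
    data.frame(run = i, lnL = r$lnL, AIC = 2 * k - 2 * r$lnL,
               converged = r$converged, pinned = r$pinned,
               t(setNames(r$start, paste0("start_", free))),
               t(setNames(r$end, free)))
  }))
  tab <- tab[order(tab$AIC, na.last = TRUE), ]
  tab$bestFive <- seq_len(nrow(tab)) <= 5L
  rownames(tab) <- NULL

  best <- okruns[[which.max(vapply(okruns, function(r) r$lnL, numeric(1)))]]
  pars <- paramVector(.assembleParams(best$end, fixedv, symmetricM))
  status <- if (isTRUE(best$pinned)) "bound-pinned" else "ok"
  new("FitResult", modelId = modelId, params = pars, lnL = best$lnL,
      k = as.integer(k), AIC = 2 * k - 2 * best$lnL,
      thetaHat = best$thetaHat, replicates = tab, status = status)
}

#' Compare divergence models by AIC
#'
#' Fits each model to the observed spectrum (propagating fit errors as NA
#' rows) and returns the ranked table.
#'
#' @param observed a [Jafs-class] of counts.
#' @param models character vector of at least two model identifiers.
#' @param ... passed to [fitDemography()].
#' @return data.frame with columns `model`, `k`, `lnL`, `AIC`, `dAIC` and
#'   `error`, sorted by AIC; the fitted [FitResult-class] objects are attached
#'   as attribute `"fits"`.
#' @export
compareModels <- function(observed, models, ...) {
  if (length(models) < 2L) stop("need at least two models to compare")
  fits <- lapply(models, function(m)
    tryCatch(fitDemography(observed, m, ...), error = function(e) e))
  rows <- lapply(seq_along(models), function(i) {
    f <- fits[[i]]
    if (inherits(f, "error"))
      data.frame(model = models[i], k = NA_integer_, lnL = NA_real_,
                 AIC = NA_real_, error = conditionMessage(f))
    else
      data.frame(model = models[i], k = f@k, lnL = f@lnL, AIC = f@AIC,
                 error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, na.last = TRUE), ]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- setNames(fits, models)
  tab
}
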