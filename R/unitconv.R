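#' @include AllClasses.R
NULL

#' Estimate the per-year mutation rate from outgroup divergence
#'
#' `mu = (d_out / 2) / T_div_years`: half the per-site divergence to the
#' outgroup (one lineage's share) divided by the divergence time in years.
#' With the beetle calibration (per-site divergence 0.03587, outgroup split
#' 620,000 years) this gives 2.89e-8 mutations/site/year.
#'
#' @param dOut average per-site nucleotide difference to the outgroup.
#' @param TDivYears outgroup divergence time in years.
#' @return mutation rate per site per year.
#' @examples
#' estimateMu(0.03587, 620000)
#' @export
estimateMu <- function(dOut, TDivYears) {
  if (!is.finite(dOut) || dOut <= 0) stop("dOut must be > 0")
  if (!is.finite(TDivYears) || TDivYears <= 0) stop("TDivYears must be > 0")
  (dOut / 2) / TDivYears
}

#' Calibration inputs for unit conversion
#'
#' @param dOut per-site divergence to the outgroup.
#' @param TDivYears outgroup divergence time (years).
#' @param L total callable sequence length (bp).
#' @param genPerYear generations per year (default 1; the beetle is treated
#'   as annual).
#' @return list of validated calibration inputs with the derived `mu`.
#' @export
calibrationInputs <- function(dOut, TDivYears, L, genPerYear = 1) {
  if (!is.finite(L) || L <= 0) stop("L must be > 0")
  if (!is.finite(genPerYear) || genPerYear <= 0)
    stop("genPerYear must be > 0")
  list(dOut = dOut, TDivYears = TDivYears, L = L, genPerYear = genPerYear,
       mu = estimateMu(dOut, TDivYears))
}

#' Convert mutation-scaled estimates to biological units
#'
#' Uses `N_A = theta / (4 mu_gen L)` with `mu_gen = mu / genPerYear`,
#' `N_i = nu_i N_A`, times in generations `T = 2 N_A t` (divided by
#' `genPerYear` for years), migrant fractions `m_{i<-j} = M_{i<-j} / (2 N_A)`
#' and effective migrant gene copies per generation `nu_i M_{i<-j}`.
#'
#' @param params a [DemographyParams-class] with `theta` set (e.g. the
#'   profiled `thetaHat` of a fit), or a [FitResult-class].
#' @param calib output of [calibrationInputs()].
#' @return list of biological estimates: `mu`, `NA_` (ancestral size), `N1`,
#'   `N2`, `TS_years`, `TSC_years`, `m12`, `m21`, `mI12`, `mI21`,
#'   `migrants12`, `migrants21`.
#' @examples
#' p <- DemographyParams(nu1 = 0.5, nu2 = 2, tS = 1, M12 = 3, theta = 4)
#' convertToBiological(p, calibrationInputs(0.02, 1e6, 1e6))
#' @export
convertToBiological <- function(params, calib) {
  if (is(params, "FitResult")) {
    th <- params@thetaHat
    params <- paramsFromVector(params@params, theta = th)
  }
  theta <- params@theta
  if (is.na(theta)) stop("theta is not set on the parameters")
  muGen <- calib$mu / calib$genPerYear
  NAnc <- theta / (4 * muGen * calib$L)
  TS_gen <- 2 * NAnc * params@tS
  TSC_gen <- 2 * NAnc * params@tSC
  list(mu = calib$mu,
       NA_ = NAnc,
       N1 = params@nu1 * NAnc,
       N2 = params@nu2 * NAnc,
       TS_gen = TS_gen, TSC_gen = TSC_gen,
       TS_years = TS_gen / calib$genPerYear,
       TSC_years = TSC_gen / calib$genPerYear,
       m12 = params@M12 / (2 * NAnc), m21 = params@M21 / (2 * NAnc),
       mI12 = params@MI12 / (2 * NAnc), mI21 = params@MI21 / (2 * NAnc),
       migrants12 = params@nu1 * params@M12,
       migrants21 = params@nu2 * params@M21)
}

#' Invert a biological-units conversion
#'
#' Recovers the mutation-scaled `(theta, t, M)` from biological estimates;
#' algebraic inverse of [convertToBiological()], useful for round-trip
#' checking.
#'
#' @param est output of [convertToBiological()].
#' @param calib output of [calibrationInputs()].
#' @return named list with `theta`, `tS`, `tSC`, `M12`, `M21`.
#' @export
rescaleFromBiological <- function(est, calib) {
  muGen <- calib$mu / calib$genPerYear
  NAnc <- est$NA_
  list(theta = 4 * NAnc * muGen * calib$L,
       tS = est$TS_gen / (2 * NAnc),
       tSC = est$TSC_gen / (2 * NAnc),
       M12 = est$m12 * 2 * NAnc,
       M21 = est$m21 * 2 * NAnc)
}
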