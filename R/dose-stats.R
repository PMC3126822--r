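## Exposure-dose arithmetic, paired nonparametric statistics, and the
## rheology phase-angle helper.

#' Inhaled-exposure scenario
#'
#' Parameters for estimating the particle concentration accumulating in the
#' tracheobronchial mucus layer under a sustained airborne exposure.
#' Defaults follow a permissible-exposure-limit scenario for airborne
#' particulates: 10 mg/m^3 over an 8 hr shift at a heavy-activity breathing
#' rate of 3.2 m^3/hr, a 5-10% tracheobronchial deposition fraction for
#' 0.1-1 um particles, a tracheobronchial surface area of 2741 cm^2 and a
#' 30 um mucus layer.
#'
#' @param airborneConcentration mg/m^3.
#' @param breathingRate m^3/hr.
#' @param exposureDuration hr.
#' @param depositionFraction dimensionless in [0, 1].
#' @param airwaySurfaceArea cm^2.
#' @param mucusThickness um.
#' @return validated named list of class `"exposureScenario"`.
#' @export
exposureScenario <- function(airborneConcentration = 10,
                             breathingRate = 3.2, exposureDuration = 8,
                             depositionFraction = 0.05,
                             airwaySurfaceArea = 2741,
                             mucusThickness = 30) {
  vals <- list(airborneConcentration = airborneConcentration,
               breathingRate = breathingRate,
               exposureDuration = exposureDuration,
               depositionFraction = depositionFraction,
               airwaySurfaceArea = airwaySurfaceArea,
               mucusThickness = mucusThickness)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        is.na(vals[[nm]]) || vals[[nm]] < 0)
      stop("invalid scenario: '", nm, "' must be a single non-negative number")
  for (nm in setdiff(names(vals), "airborneConcentration"))
    if (vals[[nm]] == 0)
      stop("invalid scenario: '", nm, "' must be positive")
  if (depositionFraction > 1)
    stop("invalid scenario: 'depositionFraction' must be <= 1")
  structure(vals, class = "exposureScenario")
}

#' Particle concentration deposited in the mucus layer
#'
#' Deposited mass = airborne concentration x breathing rate x duration x
#' deposition fraction; mucus volume = airway surface area x layer
#' thickness. The result is expressed as % w/v (grams per 100 mL); mucus
#' density is not involved because mass is divided by volume directly.
#' Linear in concentration, duration and deposition fraction, and
#' inverse-linear in layer thickness.
#'
#' @param scenario an [exposureScenario()].
#' @return concentration, % w/v.
#' @export
mucusDoseConcentration <- function(scenario = exposureScenario()) {
  if (!inherits(scenario, "exposureScenario"))
    scenario <- do.call(exposureScenario, as.list(scenario))
  mass_g <- scenario$airborneConcentration * scenario$breathingRate *
    scenario$exposureDuration * scenario$depositionFraction / 1000
  volume_mL <- scenario$airwaySurfaceArea * scenario$mucusThickness * 1e-4
  100 * mass_g / volume_mL
}

#' Final concentration after volumetric dilution
#'
#' A stock added to mucus at a small volume fraction yields a final
#' concentration of `stock * addedVolumeFraction` (e.g. an 8% w/v stock at
#' 3% v/v gives 0.24% w/v).
#'
#' @param stock stock concentration, % w/v.
#' @param addedVolumeFraction volume fraction in [0, 1].
#' @return final concentration, % w/v.
#' @export
dilutionConcentration <- function(stock, addedVolumeFraction) {
  if (any(stock < 0)) stop("'stock' must be >= 0")
  if (any(addedVolumeFraction < 0) || any(addedVolumeFraction > 1))
    stop("'addedVolumeFraction' must lie in [0, 1]")
  stock * addedVolumeFraction
}

#' Exact one-tailed Wilcoxon signed-rank test for paired samples
#'
#' Exact p-value by enumeration of all `2^n` sign assignments, valid for
#' the tiny sample sizes (n = 6 donors) where the normal approximation is
#' not. Ties in |differences| receive mid-ranks; zero differences are
#' dropped (standard signed-rank convention). `alternative = "greater"`
#' tests whether `treated` exceeds `control`.
#'
#' @param treated,control paired numeric vectors (same samples, same
#'   order). Alternatively pass precomputed differences as `treated` and
#'   omit `control`.
#' @param alternative `"greater"` or `"less"`.
#' @return list with `p.value`, `statistic` (W+, sum of positive ranks),
#'   `n` (non-zero pairs).
#' @export
wilcoxonSignedRankExact <- function(treated, control = NULL,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(control)) as.numeric(treated)
       else as.numeric(treated) - as.numeric(control)
  if (!length(d)) stop("need at least one pair")
  if (alternative == "less") d <- -d
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1")
    return(list(p.value = 1, statistic = 0, n = 0L))
  }
  d <- d[nz]
  n <- length(d)
  if (n > 20L)
    stop("exact enumeration supported for n <= 20 non-zero pairs (got ",
         n, ")")
  r <- rank(abs(d))                       # mid-ranks for ties
  wObs <- sum(r[d > 0])
  # all 2^n sign patterns, in chunks to bound memory
  total <- 0
  nPat <- 2^n
  chunk <- 2^min(n, 14L)
  for (start in seq(0, nPat - 1, by = chunk)) {
    ids <- start + seq_len(min(chunk, nPat - start)) - 1
    # bit j of each pattern says whether pair j is positive
    m <- outer(ids, 2^(seq_len(n) - 1L),
               function(a, b) (a %/% b) %% 2)
    total <- total + sum(as.vector(m %*% r) >= wObs - 1e-9)
  }
  list(p.value = total / nPat, statistic = wObs, n = n)
}

#' Rheological phase angle
#'
#' `delta = arctan(G'' / G')` in degrees: 0 deg is an elastic (Hookean)
#' solid, 90 deg a purely viscous liquid.
#'
#' @param gPrime elastic (storage) modulus G', Pa.
#' @param gDoublePrime viscous (loss) modulus G'', Pa.
#' @return phase angle, degrees.
#' @export
phaseAngle <- function(gPrime, gDoublePrime) {
  if (any(gPrime < 0) || any(gDoublePrime < 0))
    stop("moduli must be >= 0")
  if (any(gPrime == 0 & gDoublePrime == 0))
    stop("phase angle undefined when both moduli are zero")
  atan2(gDoublePrime, gPrime) * 180 / pi
}
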