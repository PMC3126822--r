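## First-passage Monte Carlo across a uniform mucus slab.
##
## One-dimensional model: each particle starts at x = 0 (the luminal surface
## of a slab of thickness L) and takes Gaussian steps of variance 2*D*dt.
## A particle counts as penetrated from the first recorded step at which its
## position reaches L. The far boundary is absorbing (counting only); the
## entry side is unbounded, so particles may diffuse to negative x and
## return. Under these semantics the crossing probability for constant D has
## the closed form erfc(L / sqrt(4 D t)), which serves as the analytic
## oracle. Crossing is detected at the discrete step times only, so the
## simulation slightly undercounts relative to the continuous-time oracle;
## an optional Brownian-bridge correction samples the between-step crossing
## probability.

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
.erfcinv <- function(y) stats::qnorm(y / 2, lower.tail = FALSE) / sqrt(2)

#' Analytic first-passage fraction
#'
#' Probability that a 1-D Brownian particle with diffusivity `D`, starting
#' at 0 with no entry-side boundary, reaches level `L` by time `t`:
#' `erfc(L / sqrt(4 D t))`; 0 when `D = 0`.
#'
#' @param D diffusivity, um^2/s (vectorized).
#' @param L slab thickness, um.
#' @param t elapsed time, s.
#' @return crossing probability in [0, 1).
#' @export
analyticFirstPassage <- function(D, L, t) {
  if (any(D < 0)) stop("'D' must be >= 0")
  if (L <= 0 || t <= 0) stop("'L' and 't' must be positive")
  out <- numeric(length(D))
  pos <- D > 0
  out[pos] <- .erfc(L / sqrt(4 * D[pos] * t))
  out
}

#' Calibrate a diffusivity to a target crossing fraction
#'
#' Solves `analyticFirstPassage(D, L, t) = targetFraction` for `D`. The
#' closed form is `D = L^2 / (4 t erfcinv(target)^2)`; a monotone bisection
#' fallback is available and agrees to 1e-6 relative.
#'
#' @param targetFraction target crossing fraction in (0, 1).
#' @param L slab thickness, um.
#' @param t elapsed time, s.
#' @param method `"closed-form"` (default) or `"bisection"`.
#' @return diffusivity, um^2/s.
#' @export
calibrateDiffusivity <- function(targetFraction, L, t,
                                 method = c("closed-form", "bisection")) {
  method <- match.arg(method)
  if (targetFraction <= 0 || targetFraction >= 1)
    stop("'targetFraction' must lie strictly between 0 and 1")
  if (L <= 0 || t <= 0) stop("'L' and 't' must be positive")
  closed <- L^2 / (4 * t * .erfcinv(targetFraction)^2)
  if (method == "closed-form") return(closed)
  f <- function(D) analyticFirstPassage(D, L, t) - targetFraction
  lo <- closed / 100
  hi <- closed * 100
  stats::uniroot(f, c(lo, hi), tol = closed * 1e-9)$root
}

#' Monte Carlo slab penetration of a diffusivity ensemble
#'
#' Simulates `replicates` independent 1-D random walks for every entry of
#' `diffusivities` and records the fraction that has reached the opposite
#' face of the slab at each step. Zero diffusivities (immobile probes) are
#' legal and never penetrate. With the reference study's several hundred
#' measured diffusivities per condition and the default 30 replicates each,
#' the ensemble totals ~20,000 particles.
#'
#' @param diffusivities vector of measured effective diffusivities, um^2/s.
#' @param thickness slab thickness L, um.
#' @param duration simulated time, s (default 1 hr).
#' @param timeStep step, s.
#' @param replicates walkers per diffusivity.
#' @param seed integer RNG seed.
#' @param bridgeCorrection if `TRUE`, also count between-step crossings by
#'   sampling the Brownian-bridge excursion probability
#'   `exp(-(L - x0)(L - x1) / (D dt))`, removing the discrete-monitoring
#'   undercount.
#' @return a [SlabPenetrationResult-class].
#' @export
simulateSlabPenetration <- function(diffusivities, thickness,
                                    duration = 3600, timeStep = 1,
                                    replicates = 30L, seed = 1L,
                                    bridgeCorrection = FALSE) {
  if (!length(diffusivities)) stop("empty diffusivity list")
  if (any(diffusivities < 0)) stop("diffusivities must be >= 0")
  if (thickness <= 0) stop("'thickness' must be positive")
  if (timeStep <= 0 || duration < timeStep)
    stop("need duration >= timeStep > 0")
  nSteps <- floor(duration / timeStep + 1e-9)
  D <- rep(as.numeric(diffusivities), each = replicates)
  nTot <- length(D)
  # immobile walkers never move; exclude them from the walk entirely
  mobile <- which(D > 0)
  stepSd <- sqrt(2 * D[mobile] * timeStep)
  set.seed(as.integer(seed))
  pos <- numeric(length(mobile))
  active <- seq_along(mobile)   # indices into `mobile` still short of L
  sdAct <- stepSd
  crossedAt <- integer(0)       # step index of each crossing
  for (s in seq_len(nSteps)) {
    if (!length(active)) break
    prev <- pos
    pos <- pos + stats::rnorm(length(active), sd = sdAct)
    hit <- pos >= thickness
    if (bridgeCorrection && any(!hit)) {
      pBridge <- exp(-2 * (thickness - prev[!hit]) *
                       (thickness - pos[!hit]) / sdAct[!hit]^2)
      hit[!hit] <- stats::runif(sum(!hit)) < pBridge
    }
    if (any(hit)) {
      crossedAt <- c(crossedAt, rep.int(s, sum(hit)))
      active <- active[!hit]
      pos <- pos[!hit]
      sdAct <- sdAct[!hit]
    }
  }
  counts <- tabulate(crossedAt, nbins = nSteps)
  frac <- cumsum(counts) / nTot
  new("SlabPenetrationResult",
      time = seq_len(nSteps) * timeStep, fraction = frac,
      nParticles = as.integer(nTot), thickness = thickness,
      timeStep = timeStep, seed = as.integer(seed))
}

#' Condition-comparison penetration table
#'
#' Simulates slab penetration for two measured diffusivity ensembles over a
#' grid of slab thicknesses and tabulates the fractions penetrated at the
#' stated duration together with the treated/control fold ratio.
#'
#' @param controlD,treatedD diffusivity vectors, um^2/s.
#' @param thicknesses slab thicknesses, um (default the large-airway range).
#' @param duration simulated time, s.
#' @param timeStep step, s.
#' @param replicates walkers per diffusivity.
#' @param seed integer RNG seed.
#' @return data.frame with columns `L_um`, `fraction_control`,
#'   `fraction_treated`, `fold_ratio`.
#' @export
penetrationTable <- function(controlD, treatedD,
                             thicknesses = c(10, 30, 55), duration = 3600,
                             timeStep = 1, replicates = 30L, seed = 1L) {
  if (!length(controlD) || !length(treatedD))
    stop("both diffusivity lists must be non-empty")
  rows <- lapply(seq_along(thicknesses), function(i) {
    L <- thicknesses[i]
    fc <- penetratedFraction(simulateSlabPenetration(
      controlD, L, duration, timeStep, replicates, seed = seed + 2L * i))
    ft <- penetratedFraction(simulateSlabPenetration(
      treatedD, L, duration, timeStep, replicates, seed = seed + 2L * i + 1L))
    data.frame(L_um = L, fraction_control = fc, fraction_treated = ft,
               fold_ratio = if (fc > 0) ft / fc else NA_real_)
  })
  do.call(rbind, rows)
}

#' Penetration fraction curves for multiple thicknesses
#'
#' Long-form fraction-vs-time curves per condition per thickness, matching
#' the delimited output format (`condition, L_um, t_s, fraction`).
#'
#' @param diffusivityList named list of diffusivity vectors (one per
#'   condition).
#' @param thicknesses slab thicknesses, um.
#' @param duration simulated time, s.
#' @param timeStep step, s.
#' @param replicates walkers per diffusivity.
#' @param seed integer RNG seed.
#' @param recordEvery thin the curve to every this-many steps.
#' @return data.frame with columns `condition`, `L_um`, `t_s`, `fraction`.
#' @export
penetrationCurves <- function(diffusivityList, thicknesses = c(10, 30, 55),
                              duration = 3600, timeStep = 1,
                              replicates = 30L, seed = 1L,
                              recordEvery = 60L) {
  stopifnot(is.list(diffusivityList), length(names(diffusivityList)) > 0)
  out <- list()
  sOff <- 0L
  for (cond in names(diffusivityList)) {
    for (L in thicknesses) {
      sOff <- sOff + 1L
      res <- simulateSlabPenetration(diffusivityList[[cond]], L, duration,
                                     timeStep, replicates,
                                     seed = seed + sOff)
      keep <- seq(recordEvery, length(res@time), by = recordEvery)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, L_um = L, t_s = res@time[keep],
        fraction = res@fraction[keep])
    }
  }
  do.call(rbind, out)
}
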