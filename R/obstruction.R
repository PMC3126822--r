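## Obstruction-scaling model for hydrogel mesh size.
##
## For a probe of radius r_s in a fiber gel of fiber radius r_f, the hindered
## diffusivity relative to water follows
##   D_g / D_o = exp( -(pi/4) * ((r_s + r_f) / (r_g + r_f))^2 )
## where r_g is the effective pore radius. The model assumes no chemical
## interaction between probe and mesh, so the probe experiences the viscous
## drag of water inside the pores. Inverting the relation converts measured
## diffusivity ratios into pore radii; "pore size" and "mesh spacing" are
## reported on the diameter scale 2 * r_g.

#' Obstruction model parameters
#'
#' @param rs probe (particle) radius, nm. Default 500 nm: 1 um probes.
#' @param rf gel fiber radius, nm. Default 3.5 nm, the accepted estimate for
#'   individual mucin fibers.
#' @param do unobstructed (water) diffusivity of the probe, um^2/s; default
#'   from Stokes-Einstein via [waterDiffusivity()].
#' @return named list of validated parameters.
#' @export
obstructionParams <- function(rs = 500, rf = 3.5,
                              do = waterDiffusivity(rs)) {
  stopifnot(rs > 0, rf >= 0, do > 0)
  list(rs = rs, rf = rf, do = do)
}

#' Forward obstruction ratio
#'
#' Evaluates `D_g/D_o = exp(-(pi/4) ((rs+rf)/(rg+rf))^2)` for pore radius
#' `rg`. Strictly increasing in `rg`, with limits 0 (vanishing pore) and 1
#' (no obstruction).
#'
#' @param rg effective pore radius, nm (vectorized).
#' @param params from [obstructionParams()].
#' @param log if `TRUE`, return `log(D_g/D_o)`. For pores much smaller than
#'   the probe the ratio underflows double precision (below about 13 nm for
#'   a 500 nm probe); the log scale stays exact there.
#' @return diffusivity ratio in (0, 1), or its natural log.
#' @export
forwardRatio <- function(rg, params = obstructionParams(), log = FALSE) {
  if (any(rg <= 0)) stop("'rg' must be positive")
  lr <- -(pi / 4) * ((params$rs + params$rf) / (rg + params$rf))^2
  if (log) lr else exp(lr)
}

#' Invert the obstruction model for pore radius
#'
#' Solves the obstruction relation for `r_g` given a measured ratio
#' `D_g/D_o`:
#' `r_g = (rs + rf) * sqrt((pi/4) / (-log(ratio))) - rf`.
#' Ratios at or above 1 (probe apparently faster than water - measurement
#' noise) cannot be inverted and are flagged censored rather than clamped;
#' censored estimates belong to the open "spacing at least as large as any
#' threshold" class.
#'
#' @param ratio measured diffusivity ratio `D_g/D_o` (vectorized, > 0), or
#'   its natural log when `log = TRUE`.
#' @param params from [obstructionParams()].
#' @param log if `TRUE`, `ratio` is given as `log(D_g/D_o)`, which permits
#'   inversion of ratios too small to represent directly.
#' @return data.frame with columns `ratio`, `r_g_nm`, `spacing_nm`
#'   (`= 2 * r_g_nm`), `censored`.
#' @export
invertPoreRadius <- function(ratio, params = obstructionParams(),
                             log = FALSE) {
  lr <- if (log) ratio else base::log(ratio)
  if (!log && any(ratio <= 0)) stop("'ratio' must be positive")
  censored <- lr >= 0
  rg <- rep(NA_real_, length(lr))
  ok <- !censored
  rg[ok] <- (params$rs + params$rf) * sqrt((pi / 4) / (-lr[ok])) - params$rf
  data.frame(ratio = exp(lr), r_g_nm = rg, spacing_nm = 2 * rg,
             censored = censored)
}

#' Pore estimates for a per-particle summary table
#'
#' Converts per-particle effective diffusivities into pore estimates: each
#' particle's `D_g` is its `deff_1s_um2_s`, and `D_o` is the water
#' diffusivity in `params`.
#'
#' @param summaries data.frame from [particleSummaries()].
#' @param params from [obstructionParams()].
#' @return the summary key columns bound to the [invertPoreRadius()] output.
#' @export
poreEstimates <- function(summaries, params = obstructionParams()) {
  ratio <- summaries$deff_1s_um2_s / params$do
  # a zero measured diffusivity (exactly static probe) maps to a zero-width
  # pore rather than an inversion error
  ratio <- pmax(ratio, .Machine$double.xmin)
  cbind(summaries[c("sample_id", "condition", "particle_id")],
        invertPoreRadius(ratio, params))
}

#' Pore-population statistics
#'
#' Headline statistics of a pore-estimate table: mean spacing with its
#' standard error computed over per-sample means (matching a per-donor
#' experimental structure), and the fraction of pores with spacings at or
#' above given thresholds. Censored estimates (ratio >= 1, spacing
#' effectively unbounded) are excluded from the mean but count toward every
#' threshold fraction.
#'
#' @param estimates data.frame from [poreEstimates()] (needs `sample_id`,
#'   `spacing_nm`, `censored`).
#' @param thresholds spacing thresholds, nm.
#' @return list with `mean_spacing_nm`, `sem_spacing_nm`, `n_samples`,
#'   `fraction_ge` (named vector), `n_censored`.
#' @export
poreStatistics <- function(estimates, thresholds = c(500, 1000)) {
  if (!nrow(estimates)) stop("empty pore-estimate table")
  unc <- estimates[!estimates$censored, , drop = FALSE]
  if (nrow(unc)) {
    perSample <- tapply(unc$spacing_nm, unc$sample_id, mean)
    meanSpacing <- mean(perSample)
    sem <- if (length(perSample) > 1L)
      stats::sd(perSample) / sqrt(length(perSample)) else NA_real_
  } else {
    perSample <- numeric(0)
    meanSpacing <- NA_real_
    sem <- NA_real_
  }
  fr <- vapply(thresholds, function(th)
    mean(estimates$censored | estimates$spacing_nm >= th), numeric(1))
  names(fr) <- paste0("ge_", thresholds, "_nm")
  list(mean_spacing_nm = meanSpacing, sem_spacing_nm = sem,
       n_samples = length(perSample), fraction_ge = fr,
       n_censored = sum(estimates$censored))
}

#' Stokes-Einstein water diffusivity
#'
#' `D = kB * T / (6 * pi * eta * r)` for a sphere of radius `r` in a fluid
#' of viscosity `eta`.
#'
#' @param radiusNm particle radius, nm.
#' @param temperatureK absolute temperature, K (default 25 C).
#' @param viscosityPaS dynamic viscosity, Pa s (default water at 25 C).
#' @return diffusivity, um^2/s.
#' @export
waterDiffusivity <- function(radiusNm, temperatureK = 298.15,
                             viscosityPaS = 8.9e-4) {
  stopifnot(radiusNm > 0, temperatureK > 0, viscosityPaS > 0)
  kB <- 1.380649e-23  # J/K
  d_m2s <- kB * temperatureK / (6 * pi * viscosityPaS * radiusNm * 1e-9)
  d_m2s * 1e12  # m^2/s -> um^2/s
}
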