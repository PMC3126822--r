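## Synthetic trajectory generation.
##
## Mobile particles follow two-dimensional fractional Brownian motion with
## Hurst index H = alpha/2, so the ensemble-expected time-averaged MSD obeys
## MSD(tau) = 4 * deff1s * tau^alpha, anchored at the 1 s reference lag used
## throughout the package (MSD(1 s) = 4 * D_eff). Immobile particles are a
## fixed point plus localization noise. All randomness is driven by explicit
## seeds; per-particle substreams are derived deterministically from a master
## seed and the (sample, condition, particle) index.

# cache for Cholesky factors of the fractional Gaussian noise covariance,
# keyed by (alpha, nSteps); the dt and diffusivity scale factor out
.fgnCache <- new.env(parent = emptyenv())

# lower-triangular Cholesky factor of the unit-scale fGn autocovariance
# gamma(k) = ((k+1)^alpha - 2 k^alpha + |k-1|^alpha) / 2
.fgnChol <- function(alpha, nSteps) {
  key <- sprintf("%.12g|%d", alpha, nSteps)
  hit <- .fgnCache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:(nSteps - 1L)
  gam <- ((k + 1)^alpha - 2 * k^alpha + abs(k - 1)^alpha) / 2
  L <- t(chol(stats::toeplitz(gam)))
  .fgnCache[[key]] <- L
  L
}

#' Specify one synthetic particle
#'
#' Bundles the parameters of a single synthetic trajectory: motion class,
#' effective diffusivity at the 1 s reference lag, anomalous exponent,
#' localization noise, and sampling parameters. Defaults mirror a typical
#' MPT movie: 300 frames at 66.7 ms (20 s).
#'
#' @param motionClass one of `"immobile"`, `"subdiffusive"`, `"brownian"`.
#' @param deff1s effective diffusivity at tau = 1 s, um^2/s (ignored for
#'   immobile particles).
#' @param alpha anomalous exponent in (0, 1]; forced to 1 for
#'   `motionClass = "brownian"`.
#' @param noiseSd localization noise per coordinate per frame, um. The
#'   default 0.0025 um keeps the apparent MSD of a static particle
#'   (4 * noiseSd^2 = 2.5e-5 um^2) well below the immobile-classification
#'   floor of (10 nm)^2 = 1e-4 um^2 set by the stated tracking resolution.
#' @param nFrames number of frames (>= 2).
#' @param frameInterval frame interval, s.
#' @return a validated list of class `"particleSpec"`.
#' @export
particleSpec <- function(motionClass = c("subdiffusive", "brownian", "immobile"),
                         deff1s = 0.005, alpha = 0.5, noiseSd = 0.0025,
                         nFrames = 300L, frameInterval = 0.0667) {
  motionClass <- match.arg(motionClass)
  if (motionClass == "brownian") alpha <- 1
  if (!is.numeric(deff1s) || length(deff1s) != 1L || is.na(deff1s) ||
      deff1s < 0)
    stop("invalid particle spec: 'deff1s' must be a single number >= 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("invalid particle spec: 'alpha' must lie in (0, 1]")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || is.na(noiseSd) ||
      noiseSd < 0)
    stop("invalid particle spec: 'noiseSd' must be a single number >= 0")
  if (!is.numeric(nFrames) || length(nFrames) != 1L || is.na(nFrames) ||
      nFrames < 2)
    stop("invalid particle spec: 'nFrames' must be >= 2")
  if (!is.numeric(frameInterval) || length(frameInterval) != 1L ||
      is.na(frameInterval) || frameInterval <= 0)
    stop("invalid particle spec: 'frameInterval' must be > 0")
  structure(list(motionClass = motionClass, deff1s = deff1s, alpha = alpha,
                 noiseSd = noiseSd, nFrames = as.integer(nFrames),
                 frameInterval = frameInterval),
            class = "particleSpec")
}

#' Generate one synthetic trajectory
#'
#' Draws a single 2-D trajectory according to a [particleSpec()]. For
#' subdiffusive particles each coordinate is fractional Brownian motion with
#' Hurst index `alpha/2`, scaled so the expected time-averaged MSD at
#' tau = 1 s equals `4 * deff1s`; `"brownian"` is the `alpha = 1` special
#' case (independent Gaussian increments). Immobile particles sit at the
#' origin. Independent Gaussian localization noise of sd `noiseSd` is added
#' to each coordinate of each frame.
#'
#' @param spec a [particleSpec()].
#' @param seed integer seed; the trajectory is a pure function of
#'   `(spec, seed)`.
#' @return data.frame with columns `frame` (0-based), `t_s`, `x_um`, `y_um`.
#' @export
generateTrajectory <- function(spec, seed = 1L) {
  if (!inherits(spec, "particleSpec"))
    spec <- do.call(particleSpec, as.list(spec))
  n <- spec$nFrames
  dt <- spec$frameInterval
  set.seed(as.integer(seed))
  xy <- if (spec$motionClass == "immobile") {
    cbind(numeric(n), numeric(n))
  } else if (spec$alpha == 1) {
    stepSd <- sqrt(2 * spec$deff1s * dt)
    cbind(c(0, cumsum(stats::rnorm(n - 1L, sd = stepSd))),
          c(0, cumsum(stats::rnorm(n - 1L, sd = stepSd))))
  } else {
    # per-coordinate one-step increment variance: 2 * deff1s * dt^alpha
    L <- .fgnChol(spec$alpha, n - 1L)
    scale <- sqrt(2 * spec$deff1s * dt^spec$alpha)
    z <- matrix(stats::rnorm(2L * (n - 1L)), ncol = 2L)
    incr <- scale * (L %*% z)
    cbind(c(0, cumsum(incr[, 1L])), c(0, cumsum(incr[, 2L])))
  }
  if (spec$noiseSd > 0)
    xy <- xy + matrix(stats::rnorm(2L * n, sd = spec$noiseSd), ncol = 2L)
  data.frame(frame = 0:(n - 1L), t_s = (0:(n - 1L)) * dt,
             x_um = xy[, 1L], y_um = xy[, 2L])
}

#' Specify a paired-condition tracking study
#'
#' Describes a paired design: `nSamples` donor samples, each measured under
#' both conditions, with `nParticlesPerSample` probe particles per sample and
#' condition. Per-condition parameters give the immobile fraction, the
#' target ensemble-level anomalous exponent, and the log-normal law of
#' mobile-particle effective diffusivities. A log-normal per-sample
#' multiplicative effect (shared between the two conditions of a sample)
#' makes the pairing real.
#'
#' Within a condition, mobile particles all carry the same anomalous
#' exponent, set to `alphaEnsemble / (1 - immobileFraction)` (capped at 1)
#' so that the slope of the ensemble geometric-mean MSD curve - which
#' averages, in log space, power-law mobile curves with flat immobile
#' noise-floor curves - recovers `alphaEnsemble`.
#'
#' Defaults encode the reference study conditions: 6 donor samples with at
#' least 100 particles each; immobile fractions 0.33 (control) and 0.20
#' (treated); ensemble exponents 0.36 and 0.68; and a diffusivity shift
#' chosen so the mean effective diffusivity (immobile particles included)
#' increases 10-fold, with the absolute control level and the common
#' log-spread (sdlog 1.5) calibrated against the reported barrier
#' penetration statistics of 1 um probes in cervicovaginal mucus.
#'
#' @param nSamples number of paired donor samples.
#' @param nParticlesPerSample particles per sample per condition.
#' @param conditions named list of per-condition parameter lists with
#'   entries `immobileFraction`, `alphaEnsemble`, `deffLogMean`,
#'   `deffLogSd` (natural-log scale, um^2/s).
#' @param perSampleEffectSd sdlog of the shared per-sample multiplicative
#'   diffusivity effect.
#' @param noiseSd,nFrames,frameInterval per-trajectory sampling parameters,
#'   as in [particleSpec()].
#' @param seed master integer seed.
#' @return a validated list of class `"studyDesign"`.
#' @export
studyDesign <- function(nSamples = 6L, nParticlesPerSample = 100L,
                        conditions = list(
                          control = list(immobileFraction = 0.33,
                                         alphaEnsemble = 0.36,
                                         deffLogMean = log(0.005),
                                         deffLogSd = 1.5),
                          treated = list(immobileFraction = 0.20,
                                         alphaEnsemble = 0.68,
                                         deffLogMean = log(0.005 * 8.375),
                                         deffLogSd = 1.5)),
                        perSampleEffectSd = 0.5,
                        noiseSd = 0.0025, nFrames = 300L,
                        frameInterval = 0.0667, seed = 1L) {
  if (nSamples < 1) stop("invalid design: 'nSamples' must be >= 1")
  if (nParticlesPerSample < 1)
    stop("invalid design: 'nParticlesPerSample' must be >= 1")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("invalid design: 'conditions' must be a named list")
  for (nm in names(conditions)) {
    p <- conditions[[nm]]
    need <- c("immobileFraction", "alphaEnsemble", "deffLogMean", "deffLogSd")
    if (!all(need %in% names(p)))
      stop("invalid design: condition '", nm, "' must define ",
           paste(need, collapse = ", "))
    if (p$immobileFraction < 0 || p$immobileFraction > 1)
      stop("invalid design: 'immobileFraction' must lie in [0, 1]")
    if (p$alphaEnsemble <= 0 || p$alphaEnsemble > 1)
      stop("invalid design: 'alphaEnsemble' must lie in (0, 1]")
    if (p$deffLogSd < 0)
      stop("invalid design: 'deffLogSd' must be >= 0")
  }
  if (perSampleEffectSd < 0)
    stop("invalid design: 'perSampleEffectSd' must be >= 0")
  structure(list(nSamples = as.integer(nSamples),
                 nParticlesPerSample = as.integer(nParticlesPerSample),
                 conditions = conditions,
                 perSampleEffectSd = perSampleEffectSd,
                 noiseSd = noiseSd, nFrames = as.integer(nFrames),
                 frameInterval = frameInterval, seed = as.integer(seed)),
            class = "studyDesign")
}

# deterministic 31-bit substream seed from the master seed and indices
.substreamSeed <- function(master, i, j, k) {
  h <- (as.double(master) * 2654435761 + i * 97561 + j * 1009 + k) %%
    2147483629
  as.integer(h)
}

#' Generate a paired-condition synthetic study
#'
#' Draws a full paired tracking study from a [studyDesign()]. For each
#' sample a shared log-normal diffusivity multiplier is drawn once and
#' applied to both conditions, so per-sample fold changes are centered on
#' the planted condition contrast. Within each (sample, condition) group,
#' each particle is immobile with the condition's immobile probability;
#' mobile particles draw their diffusivity from the condition's log-normal
#' law and move as fractional Brownian motion. Fully reproducible: the
#' output is a pure function of the design (including its seed).
#'
#' @param design a [studyDesign()].
#' @return a [TrackingExperiment-class] with one group per
#'   (sample, condition).
#' @export
generateStudy <- function(design = studyDesign()) {
  if (!inherits(design, "studyDesign"))
    stop("'design' must be created by studyDesign()")
  condNames <- names(design$conditions)
  pieces <- vector("list", design$nSamples * length(condNames) *
                     design$nParticlesPerSample)
  idx <- 0L
  for (i in seq_len(design$nSamples)) {
    sampleId <- sprintf("S%02d", i)
    # shared per-sample effect: same multiplier in both conditions
    set.seed(.substreamSeed(design$seed, i, 0L, 0L))
    sampleEffect <- stats::rnorm(1L, sd = design$perSampleEffectSd)
    for (j in seq_along(condNames)) {
      p <- design$conditions[[j]]
      alphaMobile <- min(1, p$alphaEnsemble / max(1 - p$immobileFraction,
                                                  .Machine$double.eps))
      set.seed(.substreamSeed(design$seed, i, j, 0L) + 1L)
      nP <- design$nParticlesPerSample
      isImmobile <- stats::runif(nP) < p$immobileFraction
      logD <- stats::rnorm(nP, mean = p$deffLogMean + sampleEffect,
                           sd = p$deffLogSd)
      for (k in seq_len(nP)) {
        spec <- if (isImmobile[k]) {
          particleSpec("immobile", noiseSd = design$noiseSd,
                       nFrames = design$nFrames,
                       frameInterval = design$frameInterval)
        } else {
          particleSpec("subdiffusive", deff1s = exp(logD[k]),
                       alpha = alphaMobile, noiseSd = design$noiseSd,
                       nFrames = design$nFrames,
                       frameInterval = design$frameInterval)
        }
        tr <- generateTrajectory(spec, seed = .substreamSeed(design$seed,
                                                             i, j, k))
        idx <- idx + 1L
        pieces[[idx]] <- data.frame(sample_id = sampleId,
                                    condition = condNames[j],
                                    particle_id = sprintf("P%03d", k),
                                    tr)
      }
    }
  }
  df <- do.call(rbind, pieces[seq_len(idx)])
  TrackingExperiment(df, frameInterval = design$frameInterval)
}
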