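## Time-averaged MSD analysis.
##
## For a trajectory sampled at uniform interval dt, the time-averaged MSD at
## lag tau = k*dt is the mean over all n-k overlapping start frames of the
## squared 2-D displacement
##   <dr^2(tau)> = mean_t [ (x(t+tau)-x(t))^2 + (y(t+tau)-y(t))^2 ].
## The effective diffusivity at a reference lag is D_eff = MSD/(4*tau) (2-D
## tracking), the anomalous exponent alpha is the least-squares slope of
## log MSD vs log tau, and particles whose MSD at 1 s falls below the square
## of the tracking resolution are classified immobile.

#' Time-averaged mean squared displacement of one trajectory
#'
#' @param x,y coordinate vectors, um. Alternatively `x` may be a trajectory
#'   data.frame with columns `t_s`, `x_um`, `y_um` (and `y` omitted).
#' @param frameInterval frame interval, s; inferred from `t_s` when a
#'   trajectory data.frame is given.
#' @param maxTau largest lag to report, s; defaults to a quarter of the
#'   trajectory duration, beyond which few displacement pairs remain and the
#'   time average is statistically unreliable.
#' @return data.frame with columns `tau_s`, `msd_um2`, `n_pairs`.
#' @export
timeAveragedMSD <- function(x, y = NULL, frameInterval = NULL,
                            maxTau = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x_um", "y_um") %in% colnames(x)))
    if (is.null(frameInterval)) {
      stopifnot("t_s" %in% colnames(x))
      frameInterval <- mean(diff(x$t_s))
    }
    y <- x$y_um
    x <- x$x_um
  }
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L, is.numeric(frameInterval),
            frameInterval > 0)
  duration <- (n - 1L) * frameInterval
  if (is.null(maxTau)) maxTau <- duration / 4
  if (maxTau < frameInterval)
    stop("'maxTau' must be at least one frame interval (",
         signif(frameInterval, 4), " s)")
  maxTau <- min(maxTau, duration)
  kmax <- floor(maxTau / frameInterval + 1e-9)
  k <- seq_len(kmax)
  msd <- vapply(k, function(kk) {
    dx <- x[(kk + 1L):n] - x[1L:(n - kk)]
    dy <- y[(kk + 1L):n] - y[1L:(n - kk)]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  data.frame(tau_s = k * frameInterval, msd_um2 = msd, n_pairs = n - k)
}

# index of the grid lag nearest tau_ref; errors if tau_ref is outside the
# profile range by more than half a lag
.nearestLag <- function(tau, tauRef) {
  if (tauRef < tau[1L] - tau[1L] / 2 || tauRef > tau[length(tau)] + tau[1L] / 2)
    stop("reference lag ", tauRef, " s is outside the MSD profile range [",
         signif(tau[1L], 4), ", ", signif(tau[length(tau)], 4), "] s")
  which.min(abs(tau - tauRef))
}

#' Effective diffusivity at a reference lag
#'
#' `D_eff = MSD(tau_ref) / (4 * tau_ref)` for 2-D tracking. When `tauRef`
#' does not fall exactly on the lag grid the nearest grid lag is used (with
#' a 66.7 ms frame interval, lag 15 at 1.0005 s represents 1 s).
#'
#' @param profile MSD profile from [timeAveragedMSD()].
#' @param tauRef reference lag, s.
#' @return effective diffusivity, um^2/s.
#' @export
effectiveDiffusivity <- function(profile, tauRef = 1) {
  i <- .nearestLag(profile$tau_s, tauRef)
  profile$msd_um2[i] / (4 * profile$tau_s[i])
}

#' Anomalous diffusion exponent
#'
#' Least-squares slope of `log(MSD)` versus `log(tau)` over a lag window.
#' `alpha = 1` is unconstrained Brownian motion; decreasing values indicate
#' increasing obstruction; a flat (noise-floor) profile gives 0.
#'
#' @param tau lag vector, s (or an MSD profile data.frame, with `msd`
#'   omitted).
#' @param msd MSD vector, um^2.
#' @param tauRange two-element window of lags to fit, s.
#' @return fitted exponent (dimensionless).
#' @export
fitAlpha <- function(tau, msd = NULL, tauRange = c(0.2, 2)) {
  if (is.data.frame(tau)) {
    msd <- tau$msd_um2
    tau <- tau$tau_s
  }
  keep <- tau >= tauRange[1L] & tau <= tauRange[2L]
  if (sum(keep) < 3L)
    stop("need at least 3 lags inside the fit range [",
         tauRange[1L], ", ", tauRange[2L], "] s")
  if (any(msd[keep] <= 0))
    stop("MSD is zero inside the fit range; floor the profile at the ",
         "noise floor (resolution^2) before fitting alpha")
  stats::coef(stats::lm(log(msd[keep]) ~ log(tau[keep])))[[2L]]
}

#' Immobile-particle classification
#'
#' A particle is immobile when its time-averaged MSD at the reference lag
#' falls below the square of the tracking resolution (default 0.01 um =
#' 10 nm, giving a floor of 1e-4 um^2 at tau = 1 s).
#'
#' @param profile MSD profile from [timeAveragedMSD()].
#' @param resolution tracking resolution, um.
#' @param tauRef reference lag, s.
#' @return logical flag.
#' @export
classifyImmobile <- function(profile, resolution = 0.01, tauRef = 1) {
  i <- .nearestLag(profile$tau_s, tauRef)
  profile$msd_um2[i] < resolution^2
}

#' Per-particle summaries for a tracking experiment
#'
#' Computes, for every particle, the effective diffusivity at the reference
#' lag, the per-particle anomalous exponent (fitted on the profile floored
#' at `resolution^2`, so immobile particles report a slope near 0 instead of
#' failing), and the immobile flag.
#'
#' @param experiment a [TrackingExperiment-class].
#' @param tauRef reference lag, s.
#' @param alphaRange lag window for the per-particle alpha fit, s.
#' @param resolution tracking resolution, um.
#' @param maxTau largest lag retained, s (default: quarter of the movie).
#' @return data.frame with columns `sample_id`, `condition`, `particle_id`,
#'   `deff_1s_um2_s`, `alpha`, `immobile`.
#' @export
particleSummaries <- function(experiment, tauRef = 1, alphaRange = c(0.2, 2),
                              resolution = 0.01, maxTau = NULL) {
  prof <- .msdProfiles(experiment, maxTau = maxTau)
  floor2 <- resolution^2
  out <- prof$keys
  tau <- prof$tau
  iRef <- .nearestLag(tau, tauRef)
  out$deff_1s_um2_s <- prof$msd[, iRef] / (4 * tau[iRef])
  out$alpha <- apply(prof$msd, 1L, function(m)
    fitAlpha(tau, pmax(m, floor2), tauRange = alphaRange))
  out$immobile <- prof$msd[, iRef] < floor2
  rownames(out) <- NULL
  out
}

# all per-particle MSD profiles of an experiment on the shared lag grid;
# returns list(keys = data.frame, tau = vector, msd = particles x lags)
.msdProfiles <- function(experiment, maxTau = NULL) {
  stopifnot(is(experiment, "TrackingExperiment"))
  df <- trajectoryData(experiment)
  if (!nrow(df)) stop("experiment contains no trajectories")
  dt <- frameInterval(experiment)
  key <- paste(df$sample_id, df$condition, df$particle_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)
  nFrames <- lengths(idx)
  if (is.null(maxTau)) maxTau <- (min(nFrames) - 1L) * dt / 4
  profs <- lapply(idx, function(ii)
    timeAveragedMSD(df$x_um[ii], df$y_um[ii], frameInterval = dt,
                    maxTau = maxTau))
  kmax <- min(vapply(profs, nrow, integer(1)))
  msd <- do.call(rbind, lapply(profs, function(p) p$msd_um2[seq_len(kmax)]))
  first <- vapply(idx, `[`, integer(1), 1L)
  keys <- df[first, c("sample_id", "condition", "particle_id")]
  list(keys = keys, tau = profs[[1L]]$tau_s[seq_len(kmax)], msd = msd)
}

#' Ensemble summary of a particle group
#'
#' Summarizes one (sample, condition) group - or any set of particles - by
#' the ensemble geometric-mean MSD curve, the ensemble anomalous exponent
#' fitted on that curve, the arithmetic-mean effective diffusivity, and the
#' immobile fraction. Before log-averaging, per-particle MSD values are
#' floored at `resolution^2`: the tracking resolution is the measurement
#' floor, and the floor keeps immobile particles (true MSD 0) from
#' contributing `-Inf`. Immobile particles are included in the curve, in
#' the exponent fit and in the diffusivity mean.
#'
#' @inheritParams particleSummaries
#' @return list of data.frame `curve` (`tau_s`, `gm_msd_um2`) and scalars
#'   `alpha`, `meanDeff`, `immobileFraction`, `nParticles`.
#' @export
summarizeEnsemble <- function(experiment, tauRef = 1, alphaRange = c(0.2, 2),
                              resolution = 0.01, maxTau = NULL) {
  prof <- .msdProfiles(experiment, maxTau = maxTau)
  floor2 <- resolution^2
  gm <- exp(colMeans(log(pmax(prof$msd, floor2))))
  tau <- prof$tau
  iRef <- .nearestLag(tau, tauRef)
  deff <- prof$msd[, iRef] / (4 * tau[iRef])
  list(curve = data.frame(tau_s = tau, gm_msd_um2 = gm),
       alpha = fitAlpha(tau, gm, tauRange = alphaRange),
       meanDeff = mean(deff),
       immobileFraction = mean(prof$msd[, iRef] < floor2),
       nParticles = nrow(prof$msd))
}

#' Per-group ensemble summaries
#'
#' Applies [summarizeEnsemble()] to every (sample, condition) group of an
#' experiment.
#'
#' @inheritParams particleSummaries
#' @return list of `groups` (data.frame of per-group scalars) and `curves`
#'   (long data.frame of per-group geometric-mean MSD curves).
#' @export
ensembleSummaries <- function(experiment, tauRef = 1, alphaRange = c(0.2, 2),
                              resolution = 0.01, maxTau = NULL) {
  df <- trajectoryData(experiment)
  groups <- unique(df[c("sample_id", "condition")])
  rownames(groups) <- NULL
  res <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- df[df$sample_id == groups$sample_id[g] &
                df$condition == groups$condition[g], , drop = FALSE]
    summarizeEnsemble(TrackingExperiment(sub, frameInterval(experiment)),
                      tauRef = tauRef, alphaRange = alphaRange,
                      resolution = resolution, maxTau = maxTau)
  })
  groups$alpha <- vapply(res, `[[`, numeric(1), "alpha")
  groups$mean_deff_um2_s <- vapply(res, `[[`, numeric(1), "meanDeff")
  groups$immobile_fraction <- vapply(res, `[[`, numeric(1),
                                     "immobileFraction")
  groups$n_particles <- vapply(res, `[[`, numeric(1), "nParticles")
  curves <- do.call(rbind, lapply(seq_along(res), function(g)
    data.frame(sample_id = groups$sample_id[g],
               condition = groups$condition[g], res[[g]]$curve)))
  list(groups = groups, curves = curves)
}
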