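#' @import methods
NULL

# canonical column order of the trajectory table; the header is part of the
# on-disk format and must not drift
.TRAJ_COLS <- c("sample_id", "condition", "particle_id", "frame",
                "t_s", "x_um", "y_um")

#' TrackingExperiment: a set of particle trajectories grouped by sample and
#' condition
#'
#' Container for a multiple particle tracking experiment. Holds the long-form
#' trajectory table (one row per particle per frame) together with the frame
#' interval shared by all movies. Positions are in micrometers, times in
#' seconds; the time column is authoritative and the frame index advisory.
#'
#' @slot trajectories a `data.frame` with columns `sample_id`, `condition`,
#'   `particle_id`, `frame`, `t_s`, `x_um`, `y_um`, sorted by
#'   (sample_id, condition, particle_id, t_s).
#' @slot frameInterval frame interval in seconds, shared by all trajectories.
#'
#' @seealso [readTrajectories()], [writeTrajectories()], [generateStudy()]
#' @export
setClass("TrackingExperiment",
         representation(trajectories = "data.frame",
                        frameInterval = "numeric"))

setValidity("TrackingExperiment", function(object) {
  df <- object@trajectories
  msgs <- character()
  if (!identical(colnames(df), .TRAJ_COLS))
    msgs <- c(msgs, sprintf("trajectory table must have columns %s",
                            paste(.TRAJ_COLS, collapse = ", ")))
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msgs <- c(msgs, "frameInterval must be a single positive number")
  if (length(msgs)) return(msgs)
  if (nrow(df)) {
    if (anyNA(df[c("t_s", "x_um", "y_um")]))
      msgs <- c(msgs, "trajectory table contains missing coordinates or times")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TrackingExperiment number of trajectories (particles) held
#' @param object,x a `TrackingExperiment`
#' @export
setGeneric("nTrajectories", function(object) standardGeneric("nTrajectories"))

#' @export
setMethod("nTrajectories", "TrackingExperiment", function(object) {
  df <- object@trajectories
  if (!nrow(df)) return(0L)
  nrow(unique(df[c("sample_id", "condition", "particle_id")]))
})

#' @describeIn TrackingExperiment the long-form trajectory table
#' @export
setGeneric("trajectoryData", function(object) standardGeneric("trajectoryData"))

#' @export
setMethod("trajectoryData", "TrackingExperiment",
          function(object) object@trajectories)

#' @describeIn TrackingExperiment frame interval in seconds
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @export
setMethod("frameInterval", "TrackingExperiment",
          function(object) object@frameInterval)

setMethod("show", "TrackingExperiment", function(object) {
  df <- object@trajectories
  groups <- unique(df[c("sample_id", "condition")])
  cat("TrackingExperiment\n")
  cat(sprintf("  %d trajectories in %d (sample, condition) groups\n",
              nTrajectories(object), nrow(groups)))
  cat(sprintf("  frame interval: %.4g s", object@frameInterval))
  if (nrow(df)) {
    dur <- max(df$t_s) - min(df$t_s)
    cat(sprintf("; duration: %.4g s", dur))
  }
  cat("\n")
  if (nrow(groups)) {
    cnt <- table(paste(df$sample_id, df$condition, sep = " / ")[
      !duplicated(df[c("sample_id", "condition", "particle_id")])])
    cat("  particles per group:\n")
    for (nm in names(cnt)) cat(sprintf("    %s: %d\n", nm, cnt[[nm]]))
  }
  invisible(NULL)
})

#' Construct a TrackingExperiment from a trajectory table
#'
#' Validates per-particle time grids (at least two points, strictly
#' increasing, uniform spacing to relative jitter below `1e-6`) and sorts
#' rows canonically.
#'
#' @param trajectories data.frame with the trajectory-table columns.
#' @param frameInterval frame interval in seconds; inferred from the data
#'   when `NULL`.
#' @return a validated [TrackingExperiment-class] object.
#' @export
TrackingExperiment <- function(trajectories, frameInterval = NULL) {
  df <- as.data.frame(trajectories)
  missing_cols <- setdiff(.TRAJ_COLS, colnames(df))
  if (length(missing_cols))
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[.TRAJ_COLS]
  for (col in c("sample_id", "condition", "particle_id"))
    df[[col]] <- as.character(df[[col]])
  df <- df[order(df$sample_id, df$condition, df$particle_id, df$t_s), ,
           drop = FALSE]
  rownames(df) <- NULL
  dt <- .validateTimeGrids(df)
  if (is.null(frameInterval)) frameInterval <- dt
  new("TrackingExperiment", trajectories = df,
      frameInterval = as.numeric(frameInterval))
}

# checks each particle's time grid and returns the common frame interval
.validateTimeGrids <- function(df) {
  if (!nrow(df)) return(NA_real_)
  key <- paste(df$sample_id, df$condition, df$particle_id, sep = "\r")
  steps <- vapply(split(df$t_s, key), function(t) {
    if (length(t) < 2L)
      return(NA_real_)
    d <- diff(t)
    if (any(d <= 0)) return(-1)
    if ((max(d) - min(d)) / mean(d) > 1e-6) return(-2)
    mean(d)
  }, numeric(1))
  bad <- names(steps)[is.na(steps)]
  if (length(bad))
    stop("trajectory for particle '", gsub("\r", "/", bad[1L]),
         "' has fewer than 2 points")
  bad <- names(steps)[steps == -1]
  if (length(bad))
    stop("times not strictly increasing (duplicate or out-of-order rows) ",
         "for particle '", gsub("\r", "/", bad[1L]), "'")
  bad <- names(steps)[steps == -2]
  if (length(bad))
    stop("non-uniform time steps (gap or jitter) for particle '",
         gsub("\r", "/", bad[1L]), "'")
  dts <- unique(signif(steps, 9))
  if (length(dts) > 1L)
    stop("trajectories do not share a common frame interval: found ",
         paste(signif(dts, 6), collapse = ", "), " s")
  unname(steps[1L])
}

#' SlabPenetrationResult: outcome of a slab first-passage simulation
#'
#' Fraction of a diffusivity ensemble that has reached the far side of a
#' mucus slab as a function of time, from the Monte Carlo simulation in
#' [simulateSlabPenetration()].
#'
#' @slot time times at which the fraction was recorded, s.
#' @slot fraction fraction of particles that have crossed by each time.
#' @slot nParticles total number of simulated particles.
#' @slot thickness slab thickness, um.
#' @slot timeStep simulation step, s.
#' @slot seed RNG seed used.
#' @export
setClass("SlabPenetrationResult",
         representation(time = "numeric", fraction = "numeric",
                        nParticles = "integer", thickness = "numeric",
                        timeStep = "numeric", seed = "integer"))

setValidity("SlabPenetrationResult", function(object) {
  msgs <- character()
  if (length(object@time) != length(object@fraction))
    msgs <- c(msgs, "time and fraction must have equal length")
  if (length(object@fraction) &&
      (any(object@fraction < 0) || any(object@fraction > 1)))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (length(object@fraction) && is.unsorted(object@fraction))
    msgs <- c(msgs, "fraction curve must be non-decreasing in time")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SlabPenetrationResult fraction-vs-time curve as a data.frame
#' @param object a `SlabPenetrationResult`
#' @export
setGeneric("fractionCurve", function(object) standardGeneric("fractionCurve"))

#' @export
setMethod("fractionCurve", "SlabPenetrationResult", function(object) {
  data.frame(t_s = object@time, fraction = object@fraction)
})

#' @describeIn SlabPenetrationResult final penetrated fraction
#' @export
setGeneric("penetratedFraction",
           function(object) standardGeneric("penetratedFraction"))

#' @export
setMethod("penetratedFraction", "SlabPenetrationResult", function(object) {
  if (!length(object@fraction)) return(0)
  object@fraction[length(object@fraction)]
})

setMethod("show", "SlabPenetrationResult", function(object) {
  cat("SlabPenetrationResult\n")
  cat(sprintf("  %d particles, slab thickness %.4g um, step %.4g s\n",
              object@nParticles, object@thickness, object@timeStep))
  cat(sprintf("  fraction penetrated by t = %.4g s: %.4f\n",
              max(object@time), penetratedFraction(object)))
  invisible(NULL)
})
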