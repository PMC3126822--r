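## End-to-end orchestration: synthesize -> analyze -> penetrate -> report.
##
## A single flat configuration (R list or YAML file) drives all stages; all
## randomness flows from one seed, and every output table carries the seed
## and a configuration hash in '#' comment lines.

#' Default pipeline configuration
#'
#' Flat named list of every tunable parameter, suitable for writing to /
#' reading from a YAML file. Analysis parameters: `tau_ref` (s),
#' `alpha_fit_min`/`alpha_fit_max` (s), `resolution` (um). Obstruction
#' parameters: `probe_radius_nm`, `fiber_radius_nm`, `temperature_K`,
#' `viscosity_Pa_s`. Slab parameters: `thicknesses_um`, `duration_s`,
#' `time_step_s`, `replicates`. Study-design parameters mirror
#' [studyDesign()].
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(seed = 1L,
       # analysis
       tau_ref = 1, alpha_fit_min = 0.2, alpha_fit_max = 2,
       resolution = 0.01,
       # obstruction model
       probe_radius_nm = 500, fiber_radius_nm = 3.5,
       temperature_K = 298.15, viscosity_Pa_s = 8.9e-4,
       # slab simulation
       thicknesses_um = c(10, 30, 55), duration_s = 3600,
       time_step_s = 1, replicates = 30L,
       # study design
       n_samples = 6L, n_particles_per_sample = 100L,
       control_immobile_fraction = 0.33, control_alpha = 0.36,
       control_deff_log_mean = log(0.005), control_deff_log_sd = 1.5,
       treated_immobile_fraction = 0.20, treated_alpha = 0.68,
       treated_deff_log_mean = log(0.005 * 8.375),
       treated_deff_log_sd = 1.5,
       per_sample_effect_sd = 0.5, noise_sd = 0.0025,
       n_frames = 300L, frame_interval = 0.0667)
}

#' Read a pipeline configuration file
#'
#' Reads a flat YAML key-value file and overlays it on
#' [defaultPipelineConfig()]; unknown keys are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# tiny polynomial rolling hash over the deparsed configuration; enough to
# fingerprint output files against the configuration that produced them
.configHash <- function(cfg) {
  bytes <- utils::head(charToRaw(paste(deparse(cfg[order(names(cfg))]),
                                       collapse = "")), 1e5)
  h <- 5381
  for (b in as.integer(bytes))
    h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.studyDesignFromConfig <- function(cfg) {
  studyDesign(
    nSamples = cfg$n_samples,
    nParticlesPerSample = cfg$n_particles_per_sample,
    conditions = list(
      control = list(immobileFraction = cfg$control_immobile_fraction,
                     alphaEnsemble = cfg$control_alpha,
                     deffLogMean = cfg$control_deff_log_mean,
                     deffLogSd = cfg$control_deff_log_sd),
      treated = list(immobileFraction = cfg$treated_immobile_fraction,
                     alphaEnsemble = cfg$treated_alpha,
                     deffLogMean = cfg$treated_deff_log_mean,
                     deffLogSd = cfg$treated_deff_log_sd)),
    perSampleEffectSd = cfg$per_sample_effect_sd,
    noiseSd = cfg$noise_sd, nFrames = cfg$n_frames,
    frameInterval = cfg$frame_interval, seed = cfg$seed)
}

#' Synthesize a study to a trajectory table file
#'
#' Generates the configured paired study and writes the trajectory table
#' (with seed and configuration hash in the header comments).
#'
#' @param config list from [readPipelineConfig()].
#' @param path output trajectory table path.
#' @return `invisible(path)`.
#' @export
runSynth <- function(config = defaultPipelineConfig(), path) {
  exp <- generateStudy(.studyDesignFromConfig(config))
  writeTrajectories(exp, path,
                    meta = c(seed = config$seed,
                             config_hash = .configHash(config)))
  message(sprintf("wrote %d trajectories to %s", nTrajectories(exp), path))
  invisible(path)
}

#' Analyze a tracking experiment
#'
#' Runs the full analysis stage on a [TrackingExperiment-class]:
#' per-particle summaries, per-group ensemble summaries, obstruction-model
#' pore statistics per condition, the paired one-tailed Wilcoxon
#' signed-rank comparison of per-sample mean effective diffusivities
#' (treated > control), and the mean-diffusivity fold change. When only one
#' condition is present the comparison is skipped.
#'
#' @param experiment a `TrackingExperiment` (e.g. from
#'   [readTrajectories()]).
#' @param config list from [readPipelineConfig()].
#' @return list with `particles`, `ensembles`, `curves`, `poreTables`,
#'   `poreStats`, `wilcoxon`, `foldChange`.
#' @export
analyzeStudy <- function(experiment, config = defaultPipelineConfig()) {
  alphaRange <- c(config$alpha_fit_min, config$alpha_fit_max)
  particles <- particleSummaries(experiment, tauRef = config$tau_ref,
                                 alphaRange = alphaRange,
                                 resolution = config$resolution)
  ens <- ensembleSummaries(experiment, tauRef = config$tau_ref,
                           alphaRange = alphaRange,
                           resolution = config$resolution)
  params <- obstructionParams(
    rs = config$probe_radius_nm, rf = config$fiber_radius_nm,
    do = waterDiffusivity(config$probe_radius_nm, config$temperature_K,
                          config$viscosity_Pa_s))
  conds <- sort(unique(particles$condition))
  poreTables <- lapply(stats::setNames(conds, conds), function(cc)
    poreEstimates(particles[particles$condition == cc, , drop = FALSE],
                  params))
  poreStats <- lapply(poreTables, poreStatistics)
  wilcoxon <- NULL
  foldChange <- NA_real_
  if (all(c("control", "treated") %in% conds)) {
    perSample <- tapply(particles$deff_1s_um2_s,
                        particles[c("sample_id", "condition")], mean)
    ctl <- perSample[, "control"]
    trt <- perSample[, "treated"]
    wilcoxon <- wilcoxonSignedRankExact(trt, ctl, alternative = "greater")
    foldChange <- mean(trt) / mean(ctl)
  }
  n_imm <- sum(particles$immobile)
  message(sprintf(
    "analyzed %d particles (%d immobile); conditions: %s",
    nrow(particles), n_imm, paste(conds, collapse = ", ")))
  list(particles = particles, ensembles = ens$groups, curves = ens$curves,
       poreTables = poreTables, poreStats = poreStats,
       wilcoxon = wilcoxon, foldChange = foldChange)
}

#' Analysis stage from and to files
#'
#' File-level wrapper for [analyzeStudy()]: reads a trajectory table and
#' writes the per-particle summary, ensemble curve and pore tables next to
#' `outPrefix`.
#'
#' @param trajectoryPath input trajectory table.
#' @param outPrefix prefix for output files (`<prefix>_particles.csv`,
#'   `<prefix>_ensembles.csv`, `<prefix>_curves.csv`,
#'   `<prefix>_pores.csv`).
#' @param config list from [readPipelineConfig()].
#' @return the [analyzeStudy()] result, invisibly.
#' @export
runAnalyze <- function(trajectoryPath, outPrefix,
                       config = defaultPipelineConfig()) {
  experiment <- readTrajectories(trajectoryPath)
  res <- analyzeStudy(experiment, config)
  meta <- c(seed = config$seed, config_hash = .configHash(config))
  writeParticleSummaries(res$particles, paste0(outPrefix, "_particles.csv"),
                         meta = meta)
  .writeCsvWithMeta(res$ensembles, paste0(outPrefix, "_ensembles.csv"), meta)
  .writeCsvWithMeta(res$curves, paste0(outPrefix, "_curves.csv"), meta)
  pores <- do.call(rbind, res$poreTables)
  .writeCsvWithMeta(pores, paste0(outPrefix, "_pores.csv"), meta)
  invisible(res)
}

#' Penetration stage from a per-particle summary
#'
#' Builds per-condition diffusivity lists from a per-particle summary table
#' (immobile particles included, with their near-zero diffusivities) and
#' simulates slab penetration over the configured thickness grid. An
#' optional water-reference curve uses a diffusivity calibrated with
#' [calibrateDiffusivity()].
#'
#' @param particles data.frame from [particleSummaries()] (or a file path
#'   readable by [readParticleSummaries()]).
#' @param config list from [readPipelineConfig()].
#' @param waterFraction optional crossing fraction at
#'   `(thicknesses_um[1], duration_s)` used to calibrate a water-reference
#'   diffusivity; `NULL` for none.
#' @return list with `curves` (long data.frame) and `table`
#'   (per-thickness fractions and fold ratios when both conditions exist).
#' @export
penetrationAnalysis <- function(particles,
                                config = defaultPipelineConfig(),
                                waterFraction = NULL) {
  if (is.character(particles)) particles <- readParticleSummaries(particles)
  dlist <- split(particles$deff_1s_um2_s, particles$condition)
  if (!is.null(waterFraction)) {
    dWater <- calibrateDiffusivity(waterFraction, config$thicknesses_um[1L],
                                   config$duration_s)
    dlist$water <- dWater
  }
  curves <- penetrationCurves(dlist, thicknesses = config$thicknesses_um,
                              duration = config$duration_s,
                              timeStep = config$time_step_s,
                              replicates = config$replicates,
                              seed = config$seed)
  tab <- NULL
  if (all(c("control", "treated") %in% names(dlist)))
    tab <- penetrationTable(dlist$control, dlist$treated,
                            thicknesses = config$thicknesses_um,
                            duration = config$duration_s,
                            timeStep = config$time_step_s,
                            replicates = config$replicates,
                            seed = config$seed)
  list(curves = curves, table = tab)
}

.writeCsvWithMeta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
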