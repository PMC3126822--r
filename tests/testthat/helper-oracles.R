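# Independent oracles used across the suite. Deliberately naive
# implementations: correctness over speed, sharing no code with the package.

# brute-force time-averaged MSD: explicit double loop over lags and starts
bruteMSD <- function(x, y, dt, kmax) {
  n <- length(x)
  vapply(seq_len(kmax), function(k) {
    acc <- 0
    for (t in seq_len(n - k))
      acc <- acc + (x[t + k] - x[t])^2 + (y[t + k] - y[t])^2
    acc / (n - k)
  }, numeric(1))
}

# brute-force exact one-tailed signed-rank p-value: every sign pattern via
# expand.grid (n <= 12)
bruteSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- signs %*% r
  mean(w >= wObs - 1e-9)
}

# reference trajectory-table writer used for read/write cross-checks
refTrajectoryFile <- function(df, path) {
  cols <- c("sample_id", "condition", "particle_id", "frame",
            "t_s", "x_um", "y_um")
  write.csv(df[cols], path, row.names = FALSE, quote = FALSE)
  path
}

# small standard trajectory data.frame builder
makeTraj <- function(x, y, sample = "S1", cond = "control", particle = "P1",
                     dt = 1) {
  n <- length(x)
  data.frame(sample_id = sample, condition = cond, particle_id = particle,
             frame = 0:(n - 1), t_s = (0:(n - 1)) * dt, x_um = x, y_um = y)
}

# compact paired study used where the full-size default would be slow
smallStudy <- function(seed, nParticles = 15L, nFrames = 80L,
                       conditions = NULL, perSampleEffectSd = 0.3) {
  args <- list(nSamples = 6L, nParticlesPerSample = nParticles,
               perSampleEffectSd = perSampleEffectSd, nFrames = nFrames,
               seed = seed)
  if (!is.null(conditions)) args$conditions <- conditions
  generateStudy(do.call(studyDesign, args))
}
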