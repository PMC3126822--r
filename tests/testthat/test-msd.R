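test_that("MSD matches the brute-force double-loop oracle exactly", {
  set.seed(101)
  for (i in 1:20) {
    x <- cumsum(rnorm(50))
    y <- cumsum(rnorm(50))
    prof <- timeAveragedMSD(x, y, frameInterval = 0.5, maxTau = 24.5)
    expect_equal(prof$msd_um2, bruteMSD(x, y, 0.5, 49), tolerance = 1e-12)
    expect_equal(prof$n_pairs, 50 - seq_len(49))
  }
})

test_that("unit-square path gives MSD (1, 2, 1) at lags 1-3 s", {
  prof <- timeAveragedMSD(c(0, 1, 1, 0), c(0, 0, 1, 1), frameInterval = 1,
                          maxTau = 3)
  expect_equal(prof$msd_um2, c(1, 2, 1))
})

test_that("pure drift gives the ballistic closed form v^2 tau^2", {
  v <- 0.37
  t <- (0:99) * 0.1
  prof <- timeAveragedMSD(v * t, rep(0, 100), frameInterval = 0.1,
                          maxTau = 5)
  expect_equal(prof$msd_um2, v^2 * prof$tau_s^2, tolerance = 1e-12)
})

test_that("effective diffusivity is MSD/(4 tau) at the nearest grid lag", {
  prof <- data.frame(tau_s = c(0.5, 1.0, 1.5), msd_um2 = c(0.5, 1.0, 1.5),
                     n_pairs = c(10, 9, 8))
  expect_equal(effectiveDiffusivity(prof, 1), 0.25)
  prof$msd_um2 <- c(0, 0, 0)
  expect_equal(effectiveDiffusivity(prof, 1), 0)
  # 66.7 ms grid: lag 15 (1.0005 s) represents 1 s
  prof2 <- data.frame(tau_s = (1:30) * 0.0667, msd_um2 = (1:30) * 0.0667)
  expect_equal(effectiveDiffusivity(prof2, 1), (15 * 0.0667) / (4 * 15 * 0.0667))
  expect_error(effectiveDiffusivity(prof, 9), "outside")
})

test_that("alpha fit recovers closed-form slopes", {
  tau <- (1:30) * 0.0667
  expect_equal(fitAlpha(tau, 4 * 0.3 * tau), 1, tolerance = 1e-12)
  expect_equal(fitAlpha(tau, rep(2.5, 30)), 0, tolerance = 1e-12)
  expect_equal(fitAlpha(tau, 0.8 * tau^0.42), 0.42, tolerance = 1e-10)
  expect_error(fitAlpha(tau[1:3], c(1, 2, 3)), "at least 3 lags")
  expect_error(fitAlpha(tau, rep(0, 30)), "noise floor")
})

test_that("immobile classification thresholds MSD at resolution squared", {
  static <- timeAveragedMSD(rep(0, 40), rep(0, 40), frameInterval = 0.1)
  expect_true(classifyImmobile(static, tauRef = 0.5))
  mobile <- data.frame(tau_s = c(0.5, 1), msd_um2 = c(0.5, 1.0),
                       n_pairs = c(2, 1))
  expect_false(classifyImmobile(mobile))
  edge <- data.frame(tau_s = 1, msd_um2 = 1e-4, n_pairs = 1)
  expect_false(classifyImmobile(edge))   # strictly below the floor
  expect_true(classifyImmobile(edge, resolution = 0.011))
})

test_that("planted immobile mixtures are recovered within binomial error", {
  design <- studyDesign(nSamples = 1L, nParticlesPerSample = 300L,
                        seed = 77L)
  exp <- generateStudy(design)
  parts <- particleSummaries(exp)
  fc <- mean(parts$immobile[parts$condition == "control"])
  ft <- mean(parts$immobile[parts$condition == "treated"])
  expect_lt(abs(fc - 0.33), 0.07)
  expect_lt(abs(ft - 0.20), 0.07)
})

test_that("geometric-mean ensemble curve behaves as documented", {
  df <- rbind(makeTraj(c(0, 1, 0, 1), c(0, 0, 0, 0), particle = "A"),
              makeTraj(c(0, 2, 0, 2), c(0, 0, 0, 0), particle = "B"))
  exp <- TrackingExperiment(df)
  ens <- summarizeEnsemble(exp, tauRef = 1, alphaRange = c(0.5, 3),
                           maxTau = 3)
  # per-particle MSD at lag 1: 1 and 4; geometric mean 2
  expect_equal(ens$curve$gm_msd_um2[1], 2)
  expect_equal(ens$nParticles, 2)
  # single particle: curve equals its own profile
  one <- summarizeEnsemble(TrackingExperiment(df[df$particle_id == "A", ]),
                           alphaRange = c(0.5, 3), maxTau = 3)
  raw <- timeAveragedMSD(df[df$particle_id == "A", ], maxTau = 3)$msd_um2
  # single particle: curve is its own profile, floored at resolution^2
  expect_equal(one$curve$gm_msd_um2, pmax(raw, 1e-4))
})

test_that("geometric mean never exceeds arithmetic mean (AM-GM)", {
  exp <- smallStudy(seed = 31, nParticles = 12L)
  prof <- mptbarrier:::.msdProfiles(exp)
  gm <- exp(colMeans(log(pmax(prof$msd, 1e-4))))
  am <- colMeans(pmax(prof$msd, 1e-4))
  expect_true(all(gm <= am + 1e-12))
})

test_that("D_eff is invariant under translation and rotation", {
  set.seed(9)
  x <- cumsum(rnorm(60, sd = 0.3))
  y <- cumsum(rnorm(60, sd = 0.3))
  d0 <- effectiveDiffusivity(timeAveragedMSD(x, y, frameInterval = 0.1),
                             tauRef = 1)
  th <- 0.83
  xr <- cos(th) * x - sin(th) * y + 5.2
  yr <- sin(th) * x + cos(th) * y - 1.7
  dr <- effectiveDiffusivity(timeAveragedMSD(xr, yr, frameInterval = 0.1),
                             tauRef = 1)
  expect_equal(dr, d0, tolerance = 1e-12)
})

test_that("ensemble MSD of generated stationary ensembles is non-decreasing", {
  spec <- particleSpec("subdiffusive", deff1s = 0.05, alpha = 0.5,
                       noiseSd = 0, nFrames = 100L)
  profs <- lapply(1:100, function(i)
    timeAveragedMSD(generateTrajectory(spec, seed = 900 + i)))
  ens <- rowMeans(vapply(profs, `[[`, numeric(nrow(profs[[1]])), "msd_um2"))
  expect_true(all(diff(ens) > -1e-6))
})
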