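test_that("analytic first passage has the erfc closed form and limits", {
  expect_equal(analyticFirstPassage(0, 10, 3600), 0)
  expect_equal(analyticFirstPassage(0.5, 10, 3600),
               2 * pnorm(10 / sqrt(4 * 0.5 * 3600) * sqrt(2),
                         lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(analyticFirstPassage(0.5, 10, 3600), 0.868, tolerance = 1e-3)
  # level recurrence: fraction -> 1 as t -> Inf
  expect_gt(analyticFirstPassage(0.5, 10, 1e12), 1 - 1e-4)
  expect_error(analyticFirstPassage(0.5, -1, 10), "positive")
})

test_that("diffusivity calibration inverts the analytic fraction", {
  target <- analyticFirstPassage(0.5, 10, 3600)
  expect_equal(calibrateDiffusivity(target, 10, 3600), 0.5,
               tolerance = 1e-6)
  # closed form agrees with monotone bisection
  for (tf in c(0.05, 0.17, 0.64, 0.9)) {
    dc <- calibrateDiffusivity(tf, 30, 3600)
    db <- calibrateDiffusivity(tf, 30, 3600, method = "bisection")
    expect_lt(abs(dc - db) / dc, 1e-6)
  }
  expect_error(calibrateDiffusivity(1, 10, 3600), "between 0 and 1")
  expect_error(calibrateDiffusivity(0, 10, 3600), "between 0 and 1")
})

test_that("zero-diffusivity ensembles never penetrate", {
  res <- simulateSlabPenetration(rep(0, 5), thickness = 10, duration = 60,
                                 replicates = 10)
  expect_equal(penetratedFraction(res), 0)
  expect_equal(res@nParticles, 50L)
  expect_error(simulateSlabPenetration(numeric(0), 10), "empty")
})

test_that("Monte Carlo agrees with the analytic oracle for constant D", {
  for (cfg in list(c(D = 0.5, L = 10), c(D = 0.05, L = 30))) {
    n <- 6000L
    res <- simulateSlabPenetration(cfg[["D"]], cfg[["L"]], duration = 3600,
                                   timeStep = 1, replicates = n,
                                   seed = 13L)
    p <- analyticFirstPassage(cfg[["D"]], cfg[["L"]], 3600)
    tol <- 3 * sqrt(p * (1 - p) / n) + 0.015
    expect_lt(abs(penetratedFraction(res) - p), tol)
  }
})

test_that("a half immobile mixture penetrates at half the mobile rate", {
  n <- 4000L
  res <- simulateSlabPenetration(c(0, 0.5), 10, duration = 3600,
                                 replicates = n, seed = 23L)
  p <- analyticFirstPassage(0.5, 10, 3600) / 2
  expect_lt(abs(penetratedFraction(res) - p),
            3 * sqrt(p * (1 - p) / (2 * n)) + 0.015)
})

test_that("the Brownian-bridge correction removes the discretization bias", {
  n <- 20000L
  res <- simulateSlabPenetration(0.5, 10, duration = 3600, timeStep = 1,
                                 replicates = n, seed = 29L,
                                 bridgeCorrection = TRUE)
  p <- analyticFirstPassage(0.5, 10, 3600)
  expect_lt(abs(penetratedFraction(res) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("fraction curves are monotone in time, thickness and diffusivity", {
  d <- c(0.01, 0.1, 1)
  r10 <- simulateSlabPenetration(d, 10, duration = 600, replicates = 200,
                                 seed = 5L)
  expect_true(all(diff(r10@fraction) >= 0))
  r30 <- simulateSlabPenetration(d, 30, duration = 600, replicates = 200,
                                 seed = 5L)
  expect_lte(penetratedFraction(r30), penetratedFraction(r10))
  rUp <- simulateSlabPenetration(3 * d, 10, duration = 600,
                                 replicates = 200, seed = 5L)
  expect_gte(penetratedFraction(rUp), penetratedFraction(r10))
})

test_that("simultaneous scaling L -> cL, D -> c^2 D is exact at fixed seed", {
  d <- c(0.02, 0.3)
  a <- simulateSlabPenetration(d, 10, duration = 900, replicates = 500,
                               seed = 17L)
  b <- simulateSlabPenetration(9 * d, 30, duration = 900, replicates = 500,
                               seed = 17L)
  expect_identical(a@fraction, b@fraction)
})

test_that("fixed seeds give identical fraction curves", {
  d <- runif(20, 0, 0.2)
  a <- simulateSlabPenetration(d, 10, duration = 300, replicates = 50,
                               seed = 99L)
  b <- simulateSlabPenetration(d, 10, duration = 300, replicates = 50,
                               seed = 99L)
  expect_identical(fractionCurve(a), fractionCurve(b))
})

test_that("penetration table reports fold ratios with the right trends", {
  d <- c(0.005, 0.05, 0.5)
  same <- penetrationTable(d, d, thicknesses = 10, duration = 1200,
                           replicates = 400, seed = 3L)
  expect_lt(abs(same$fold_ratio - 1), 0.35)
  up <- penetrationTable(0.02, 0.2, thicknesses = 15, duration = 1200,
                         replicates = 2000, seed = 3L)
  expect_gt(up$fold_ratio, 1)
  expect_error(penetrationTable(numeric(0), d), "non-empty")
})

test_that("penetration curves cover every condition and thickness", {
  curves <- penetrationCurves(list(control = c(0, 0.1), treated = c(0.2)),
                              thicknesses = c(10, 30, 55), duration = 120,
                              replicates = 20, seed = 2L, recordEvery = 30)
  expect_equal(nrow(unique(curves[c("condition", "L_um")])), 6L)
  expect_true(all(curves$fraction >= 0 & curves$fraction <= 1))
})
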