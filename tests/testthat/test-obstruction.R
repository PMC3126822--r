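test_that("forward ratio reproduces closed-form values", {
  p <- obstructionParams(rs = 500, rf = 3.5)
  # pore radius equal to probe radius: exponent exactly -pi/4 when rf = 0
  expect_equal(forwardRatio(500, obstructionParams(rs = 500, rf = 0)),
               exp(-pi / 4), tolerance = 1e-12)
  # with the mucin fiber radius the symmetric case is unchanged:
  # (rs+rf)/(rg+rf) = 1
  expect_equal(forwardRatio(500, p), exp(-pi / 4), tolerance = 1e-12)
  expect_equal(forwardRatio(190, p),
               exp(-(pi / 4) * (503.5 / 193.5)^2), tolerance = 1e-12)
  expect_equal(forwardRatio(190, p), 4.9e-3, tolerance = 5e-3)
  # no-obstruction limit
  expect_gt(forwardRatio(1e9, p), 1 - 1e-6)
  expect_error(forwardRatio(-5, p), "positive")
})

test_that("inversion is the exact inverse over a wide pore-radius range", {
  p <- obstructionParams()
  # log scale spans pores far below the double-precision ratio underflow
  rg <- 10^seq(1, 5, length.out = 200)
  back <- invertPoreRadius(forwardRatio(rg, p, log = TRUE), p, log = TRUE)
  expect_false(any(back$censored))
  expect_true(all(abs(back$r_g_nm - rg) / rg < 1e-9))
  expect_equal(back$spacing_nm, 2 * back$r_g_nm)
  # plain-ratio route agrees wherever the ratio is representable
  rg2 <- 10^seq(log10(15), 5, length.out = 100)
  back2 <- invertPoreRadius(forwardRatio(rg2, p), p)
  expect_true(all(abs(back2$r_g_nm - rg2) / rg2 < 1e-9))
})

test_that("inversion recovers the hindered-mucus scale", {
  p <- obstructionParams()
  est <- invertPoreRadius(4.9e-3, p)
  expect_equal(est$r_g_nm, 190, tolerance = 5e-3)
  expect_equal(est$spacing_nm, 380, tolerance = 5e-3)
  expect_equal(invertPoreRadius(exp(-pi / 4),
                                obstructionParams(rf = 0))$r_g_nm,
               500, tolerance = 1e-9)
})

test_that("ratios at or above one are censored, never clamped", {
  est <- invertPoreRadius(c(0.5, 1.0, 1.2))
  expect_equal(est$censored, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(est$r_g_nm[est$censored])))
  expect_error(invertPoreRadius(0), "positive")
})

test_that("forward and inverse maps are strictly monotone", {
  p <- obstructionParams()
  rg <- seq(20, 5000, length.out = 500)
  r <- forwardRatio(rg, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(invertPoreRadius(seq(0.01, 0.99, 0.01), p)$r_g_nm) > 0))
})

test_that("pore statistics follow the documented arithmetic", {
  est <- data.frame(sample_id = "S1",
                    spacing_nm = c(380, 520, 1100, 300),
                    censored = FALSE)
  st <- poreStatistics(est)
  expect_equal(st$mean_spacing_nm, mean(c(380, 520, 1100, 300)))
  expect_equal(unname(st$fraction_ge["ge_500_nm"]), 0.5)
  expect_equal(unname(st$fraction_ge["ge_1000_nm"]), 0.25)

  allCens <- data.frame(sample_id = "S1", spacing_nm = NA_real_,
                        censored = c(TRUE, TRUE))
  stc <- poreStatistics(allCens)
  expect_true(is.na(stc$mean_spacing_nm))
  expect_equal(unname(stc$fraction_ge), c(1, 1))
  expect_error(poreStatistics(est[0, ]), "empty")
})

test_that("pore statistics average per-sample means first", {
  est <- data.frame(sample_id = c("S1", "S1", "S2"),
                    spacing_nm = c(100, 300, 1000), censored = FALSE)
  st <- poreStatistics(est)
  expect_equal(st$mean_spacing_nm, mean(c(200, 1000)))
  expect_equal(st$n_samples, 2)
})

test_that("planted spacing distributions survive the analysis round trip", {
  p <- obstructionParams()
  set.seed(14)
  spacing <- exp(rnorm(400, log(400), 0.3))
  ratios <- forwardRatio(spacing / 2, p)
  summ <- data.frame(sample_id = rep(c("S1", "S2"), each = 200),
                     condition = "control",
                     particle_id = sprintf("P%03d", 1:400),
                     deff_1s_um2_s = ratios * p$do,
                     alpha = 0.5, immobile = FALSE)
  est <- poreEstimates(summ, p)
  st <- poreStatistics(est)
  expect_lt(abs(st$mean_spacing_nm - mean(spacing)) / mean(spacing), 0.1)
})

test_that("Stokes-Einstein diffusivity has the right value and scalings", {
  d <- waterDiffusivity(500, 298.15, 8.9e-4)
  expect_equal(d, 0.490, tolerance = 2e-3)
  expect_equal(waterDiffusivity(1000) * 2, waterDiffusivity(500))
  expect_equal(waterDiffusivity(500, viscosityPaS = 2 * 8.9e-4) * 2,
               waterDiffusivity(500))
  expect_error(waterDiffusivity(-1), "radiusNm")
})
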