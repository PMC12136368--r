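test_that("incoming shortwave follows the transmissivity product", {
  # latitude equal to the solar declination at noon puts the sun overhead
  d <- as.Date("2020-06-01")
  geom <- solarGeometry(d, 12, 0)
  latOverhead <- geom$declination * 180 / pi
  rs <- shortwaveDown(d, 12, latOverhead, 0)
  expect_equal(rs, 1367 * 0.75 * geom$dr)
  # elevation raises transmissivity: 0.80 at 2500 m
  expect_equal(shortwaveDown(d, 12, latOverhead, 2500) / rs, 0.80 / 0.75)
  # night clamps to zero
  expect_warning(rs0 <- shortwaveDown(d, 0, 40, 0), "horizon")
  expect_equal(rs0, 0)
})

test_that("net radiation assembles the four components", {
  sig <- 5.67e-8
  # alpha = 1, eps = 1: only the longwave difference survives
  r <- netRadiation(1, 800, 305, 298, 1, 0.75)
  expect_equal(r$rn, r$rl_down - r$rl_up)
  # Ts = Ta with eps = eps_a = 1 would cancel longwave; verify via components
  full <- netRadiation(0.2, 800, 305, 298, 0.97, 0.75)
  epsA <- 0.85 * (-log(0.75))^0.09
  rlDown <- epsA * sig * 298^4
  rlUp <- 0.97 * sig * 305^4
  expect_equal(full$rn, 0.8 * 800 + rlDown - rlUp - 0.03 * rlDown)
  expect_error(netRadiation(0.2, 800, 305, NULL, 0.97), "required")
})

test_that("soil heat flux matches the hand-evaluated parameterization", {
  expect_equal(soilHeatFlux(273.15, 0.2, 0.5, 500), 0)
  g <- soilHeatFlux(293.15, 0.2, 0.5, 500)
  expect_equal(g, 20 / 0.2 * (0.0038 * 0.2 + 0.0074 * 0.2^2) *
                 (1 - 0.98 * 0.5^4) * 500)
  expect_equal(g, 49.566, tolerance = 1e-3)
  # full vegetation factorization: (1 - 0.98) survives
  g1 <- soilHeatFlux(293.15, 0.2, 1, 500)
  expect_equal(g1, 0.02 * (20 / 0.2) * (0.0038 * 0.2 + 0.0074 * 0.04) * 500)
  # clipped into [0, Rn/2]
  expect_gte(soilHeatFlux(263.15, 0.2, 0.5, 500), 0)
})

test_that("anchor selection honours pools, planted extremes and tie-breaks", {
  cfg <- synthConfig(rows = 30, cols = 30, seed = 11,
                     noiseSd = list(reflectance = 0, thermal = 0))
  gen <- generateScene(cfg)
  sf <- surfaceFields(gen$scene)
  an <- selectAnchorPixels(sf@lst, sf@ndvi, landMask(sf))
  expect_equal(c(an$cold$row, an$cold$col),
               unname(gen$truth$anchor_cold_index))
  expect_equal(c(an$hot$row, an$hot$col), unname(gen$truth$anchor_hot_index))

  # uniform NDVI: pools degenerate to the whole scene, cold = global Ts min
  ts <- matrix(runif(400, 290, 320), 20)
  nd <- matrix(0.5, 20, 20)
  an2 <- selectAnchorPixels(ts, nd, matrix(TRUE, 20, 20))
  expect_equal(an2$cold$ts, min(ts))
  expect_equal(an2$hot$ts, max(ts))

  # deterministic (row, col) tie-break between equal-minimum pixels
  ts[5, 5] <- ts[2, 9] <- min(ts) - 1
  an3 <- selectAnchorPixels(ts, nd, matrix(TRUE, 20, 20))
  expect_equal(c(an3$cold$row, an3$cold$col), c(2, 9))

  expect_error(selectAnchorPixels(ts[1:5, 1:5], nd[1:5, 1:5],
                                  matrix(TRUE, 5, 5)), "100")
})

test_that("neutral sensible heat equals the scalar log-profile computation", {
  cfg <- synthConfig(rows = 25, cols = 25, seed = 5,
                     noiseSd = list(reflectance = 0, thermal = 0))
  gen <- generateScene(cfg)
  res <- sebalScene(gen$scene, gen$dem, gen$met, stability = FALSE)
  ap <- res$anchors
  # independent scalar recomputation at an arbitrary interior pixel
  i <- 13; j <- 17
  sf <- res$surface
  u200 <- gen$met$wind_2m_ms * log(200 / 0.03) / log(2 / 0.03)
  ustar <- 0.41 * u200 / log(200 / sf@z0m[i, j])
  rah <- log(2 / 0.1) / (0.41 * ustar)
  taK <- gen$met$ta_c + 273.15
  p <- 101.3 * ((293 - 0.0065 * gen$dem[i, j]) / 293)^5.26
  rho <- 1000 * p / (287.05 * (taK - 0.0065 * (gen$dem[i, j] - gen$met$elev_m)))
  dT <- ap@a + ap@b * sf@lst[i, j]
  expect_equal(res$flux@h[i, j], rho * 1004 * dT / rah, tolerance = 1e-12)
})

test_that("latent heat residual and evaporative fraction follow definitions", {
  lh <- latentHeat(500, 100, 100)
  expect_equal(lh$le, 300)
  expect_equal(lh$lambda, 0.75)
  expect_equal(latentHeat(500, 100, 0)$lambda, 1)     # cold-pixel limit
  expect_equal(latentHeat(500, 100, 450)$lambda, 0)   # clipped below 0
  expect_true(is.na(latentHeat(100, 150, 10)$lambda)) # Rn - G <= 0 masked
  # raising H strictly lowers the (unclipped-range) fraction
  hs <- seq(0, 350, by = 50)
  lams <- vapply(hs, function(h) latentHeat(500, 100, h)$lambda, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("daily ET scales the evaporative fraction by available radiation", {
  expect_equal(86400 * 0.75 * 150 / 2.45e6, 3.967, tolerance = 5e-4)
  expect_equal(latentHeatVaporization(293.96), 2.45188e6, tolerance = 1e1)
  ts245 <- (2.501 - 2.45) / 0.002361 + 273.15   # Ts giving lambda = 2.45e6
  expect_equal(dailyET(0.75, 150, ts245), 3.967, tolerance = 5e-4)
  expect_equal(dailyET(0, 150, 300), 0)
  expect_gte(dailyET(0.5, -50, 300), 0)          # negative floored
})

test_that("ET24 preserves the sign of a northeast-to-southwest truth gradient", {
  cfg <- synthConfig(rows = 40, cols = 40, seed = 21, nBumps = 0,
                     lambdaGradient = c(0.5, -0.5))
  gen <- generateScene(cfg)
  res <- sebalScene(gen$scene, gen$dem, gen$met, rn24 = gen$truth$rn24)
  et <- res$et24
  sw <- mean(et[21:40, 1:20])   # southwest quadrant: high rows, low cols
  ne <- mean(et[1:20, 21:40])
  expect_gt(sw, ne)
  expect_gt(mean(gen$truth$et24_true[21:40, 1:20]),
            mean(gen$truth$et24_true[1:20, 21:40]))
})
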