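test_that("identical configuration and seed give bit-identical output", {
  cfg <- synthConfig(rows = 15, cols = 15, seed = 99)
  g1 <- generateScene(cfg)
  g2 <- generateScene(cfg)
  expect_identical(g1$scene@bands, g2$scene@bands)
  expect_identical(g1$scene@bt, g2$scene@bt)
  expect_identical(g1$truth$lambda_true, g2$truth$lambda_true)
  expect_identical(g1$dem, g2$dem)
  m1 <- generateMet(cfg); m2 <- generateMet(cfg)
  expect_identical(m1, m2)
})

test_that("a prescribed constant field survives the generator unchanged", {
  cfg <- synthConfig(rows = 12, cols = 12, seed = 1, lambdaField = 0.5,
                     plantAnchors = FALSE,
                     noiseSd = list(reflectance = 0, thermal = 0))
  gen <- generateScene(cfg)
  expect_true(all(gen$truth$lambda_true == 0.5))
})

test_that("scenes always contain exactly one strict anchor of each kind", {
  for (s in c(2, 13, 77)) {
    cfg <- synthConfig(rows = 20, cols = 20, seed = s,
                       noiseSd = list(reflectance = 0, thermal = 0))
    gen <- generateScene(cfg)
    nd <- gen$truth$ndvi_true; ts <- gen$truth$ts_true
    expect_equal(sum(nd == max(nd)), 1)
    expect_equal(sum(nd == min(nd)), 1)
    expect_equal(sum(ts == min(ts)), 1)
    expect_equal(sum(ts == max(ts)), 1)
    ci <- gen$truth$anchor_cold_index; hi <- gen$truth$anchor_hot_index
    expect_equal(which(nd == max(nd)), (ci[2] - 1) * 20 + ci[1],
                 ignore_attr = TRUE)
    expect_equal(which(ts == max(ts)), (hi[2] - 1) * 20 + hi[1],
                 ignore_attr = TRUE)
    expect_equal(gen$truth$lambda_true[ci[1], ci[2]], 1)
    expect_equal(gen$truth$lambda_true[hi[1], hi[2]], 0)
    # daily-ET truth vanishes exactly where the fraction is zero
    expect_true(all(gen$truth$et24_true[gen$truth$lambda_true == 0] == 0))
  }
})

test_that("the generator rejects invalid configurations", {
  expect_error(synthConfig(rows = 5), "grid too small")
  expect_error(synthConfig(tsRange = c(200, 330)), "250")
  expect_error(synthConfig(ndviRange = c(0.9, 0.1)), "increasing")
  expect_error(synthConfig(metMeans = list(tmax_c = 10, tmin_c = 20,
                                           rh_pct = 60, wind_2m_ms = 2,
                                           sunshine_h = 7, precip_mm = 1)),
               "Tmax below Tmin")
  expect_error(synthConfig(nStations = 0), "station")
})

test_that("zero-noise met series are constant at the configured means", {
  cfg <- synthConfig(rows = 12, cols = 12, seed = 4, nStations = 1,
                     metNoise = list(temp_c = 0, rh_pct = 0, wind_ms = 0,
                                     sunshine_h = 0, precip_mm = 0))
  met <- generateMet(cfg)
  expect_true(all(met$daily$tmax_c == cfg$metMeans$tmax_c))
  expect_true(all(met$daily$tmin_c == cfg$metMeans$tmin_c))
  expect_true(all(met$daily$rh_pct == cfg$metMeans$rh_pct))
  expect_true(all(met$daily$wind_2m_ms == cfg$metMeans$wind_2m_ms))
  expect_true(all(met$daily$sunshine_h == cfg$metMeans$sunshine_h))
  expect_true(all(met$daily$precip_mm == cfg$metMeans$precip_mm))
})

test_that("met series satisfy the physical-range invariants", {
  cfg <- synthConfig(rows = 12, cols = 12, seed = 8, nStations = 4)
  met <- generateMet(cfg)
  d <- met$daily
  expect_true(all(d$tmin_c <= d$tmean_c & d$tmean_c <= d$tmax_c))
  expect_true(all(d$rh_pct >= 0 & d$rh_pct <= 100))
  expect_true(all(d$wind_2m_ms >= 0))
  nlen <- extraterrestrialRadiation(d$date, d$lat)$daylength
  expect_true(all(d$sunshine_h <= nlen + 1e-9 & d$sunshine_h >= 0))
  expect_true(all(d$precip_mm >= 0))
})

test_that("zone yields are seeded, clamped and honour a degenerate draw", {
  cfg <- synthConfig(rows = 12, cols = 12, seed = 6)
  zones <- generateZones(cfg, 5)
  y <- generateYield(zones, cfg)
  expect_equal(nrow(y), 5)
  expect_identical(y, generateYield(zones, cfg))
  expect_true(all(y$yield_kg_per_mu >= 386.794 &
                    y$yield_kg_per_mu <= 754.896))
  cfg0 <- synthConfig(rows = 12, cols = 12, seed = 6, yieldSd = 0)
  y0 <- generateYield(matrix(1L, 3, 3), cfg0)
  expect_equal(y0$yield_kg_per_mu, 577.046)
  expect_error(generateYield(matrix(NA_integer_, 2, 2), cfg), "empty")
})

test_that("the flux chain evaluated at tight tolerance returns the truth", {
  cfg <- synthConfig(rows = 30, cols = 30, seed = 23,
                     noiseSd = list(reflectance = 0, thermal = 0))
  gen <- generateScene(cfg)
  res <- sebalScene(gen$scene, gen$dem, gen$met, tol = 1e-10, maxIter = 60)
  err <- lambdaInst(res$flux) - gen$truth$lambda_true
  expect_lt(max(abs(err), na.rm = TRUE), 1e-6)
})
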