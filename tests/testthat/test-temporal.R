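test_that("evaporative-fraction interpolation is exact at overpasses", {
  l1 <- matrix(runif(100), 10); l2 <- matrix(runif(100), 10)
  dates <- as.Date(c("2020-04-08", "2020-08-10"))
  expect_identical(interpolateLambda(list(l1, l2), dates, dates[1]), l1)
  expect_identical(interpolateLambda(list(l1, l2), dates, dates[2]), l2)
  # midpoint of 0.2 and 0.8 is 0.5
  a <- matrix(0.2, 3, 3); b <- matrix(0.8, 3, 3)
  d2 <- as.Date(c("2020-05-01", "2020-05-11"))
  expect_equal(interpolateLambda(list(a, b), d2, as.Date("2020-05-06")),
               matrix(0.5, 3, 3))
  # boundary hold outside the overpass window
  expect_identical(interpolateLambda(list(a, b), d2, as.Date("2020-04-01")), a)
  expect_identical(interpolateLambda(list(a, b), d2, as.Date("2020-06-01")), b)
})

test_that("monthly totals sum hand-computable constant-lambda ET", {
  lam <- matrix(0.5, 4, 4)
  ts <- matrix((2.501 - 2.45) / 0.002361 + 273.15, 4, 4)  # lambda_vap 2.45e6
  dates <- seq(as.Date("2020-06-01"), as.Date("2020-06-30"), by = "day")
  out <- interpolateDailyET(list(lam), as.Date("2020-06-15"), dates, 100, ts)
  expect_equal(out$monthly[["2020-06"]][1, 1],
               30 * 86400 * 0.5 * 100 / 2.45e6, tolerance = 1e-10)
  expect_equal(out$monthly[["2020-06"]][1, 1], 52.9, tolerance = 1e-2)
  # zero fraction gives zero seasonal ET
  out0 <- interpolateDailyET(list(lam * 0), as.Date("2020-06-15"), dates,
                             100, ts)
  expect_true(all(out0$seasonal == 0))
})

test_that("seasonal ET equals the sum of its monthly totals exactly", {
  cfg <- synthConfig(rows = 10, cols = 10, seed = 31)
  gen <- generateScene(cfg)
  dates <- seq(as.Date("2020-05-01"), as.Date("2020-07-31"), by = "day")
  out <- interpolateDailyET(list(gen$truth$lambda_true),
                            cfg$date, dates, 120, gen$truth$ts_true)
  expect_identical(Reduce(`+`, out$monthly), out$seasonal)
  expect_true(all(out$seasonal >= 0))
})

test_that("water productivity honours units and inverse proportionality", {
  wp <- waterProductivity(matrix(600, 2, 2), matrix(450, 2, 2))
  expect_equal(wp$wp[1, 1], 2.0)
  expect_equal(wp$wp[1, 1], 1.5 * 600 / 450)
  # kg/mu over mm agrees with kg/m2 over m to machine precision
  yieldKgM2 <- 600 / (2000 / 3)   # 1 mu = 666.667 m2
  etM <- 0.45
  expect_equal(wp$wp[1, 1], yieldKgM2 / etM, tolerance = 1e-12)
  expect_equal(waterProductivity(matrix(0, 1, 1), matrix(300, 1, 1))$wp[1, 1], 0)
  # doubling ET halves WP
  wp2 <- waterProductivity(matrix(600, 2, 2), matrix(900, 2, 2))
  expect_equal(wp$wp / wp2$wp, matrix(2, 2, 2))
  # zero-ET crop pixels are masked and flagged
  z <- waterProductivity(matrix(500, 1, 2), matrix(c(0, 400), 1, 2))
  expect_true(z$flagged[1, 1])
  expect_true(is.na(z$wp[1, 1]))
})

test_that("zonal statistics are deterministic and omit empty zones", {
  wp <- matrix(1.742, 4, 4)
  zones <- matrix(1L, 4, 4)
  st <- zonalStats(wp, zones)
  expect_equal(st$mean, 1.742)
  expect_equal(st$min, 1.742)
  expect_equal(st$max, 1.742)
  x <- matrix(c(0.824, 2.367), 1, 2)
  st2 <- zonalStats(x, matrix(1L, 1, 2))
  expect_equal(st2$min, 0.824)
  expect_equal(st2$max, 2.367)
  expect_equal(st2$mean, 1.5955)
  x3 <- matrix(c(1, NA), 1, 2)
  expect_warning(st3 <- zonalStats(x3, matrix(c(1L, 2L), 1, 2)), "omitted")
  expect_equal(st3$zone, 1)
})

test_that("correlations recover exact linear relations and affine invariance", {
  set.seed(40)
  dem <- matrix(runif(400, 500, 1500), 20)
  zones <- matrix(1L, 20, 20)
  r1 <- correlateWP(2 * dem + 3, list(dem = dem), zones)
  expect_equal(r1$r, 1)
  expect_true(r1$significant)
  r2 <- correlateWP(-dem, list(dem = dem), zones)
  expect_equal(r2$r, -1)
  # affine rescaling of either variable leaves r unchanged
  wp <- matrix(runif(400), 20)
  rA <- correlateWP(wp, list(dem = dem), zones)$r
  rB <- correlateWP(10 * wp - 4, list(dem = 0.01 * dem + 7), zones)$r
  expect_equal(rA, rB)
  # zero-variance factor flagged
  rz <- correlateWP(wp, list(flat = matrix(1, 20, 20)), zones)
  expect_true(rz$flagged)
  expect_true(is.na(rz$r))
})

test_that("a prescribed positive WP-elevation slope is recovered under noise", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    dem <- matrix(runif(200, 500, 1500), 10)
    wp <- 1 + 0.001 * dem + matrix(rnorm(200, 0, 0.3), 10)
    r <- correlateWP(wp, list(dem = dem), matrix(1L, 10, 20))$r
    if (r > 0) hits <- hits + 1
  }
  expect_gte(hits, 99)
})
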