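.metRec <- function(...) {
  rec <- list(date = as.Date("2020-08-10"), lat = 37.9, tmax_c = 30,
              tmin_c = 18, tmean_c = 24, rh_pct = 60, wind_2m_ms = 2,
              sunshine_h = 8, elev_m = 800)
  utils::modifyList(rec, list(...))
}

test_that("vapor-pressure terms match closed forms", {
  expect_equal(satVaporPressure(0), 0.6108)
  vt <- vaporTerms(.metRec(rh_pct = 100))
  expect_equal(vt$ea, vt$es)                       # saturation
  vt0 <- vaporTerms(.metRec(elev_m = 0))
  expect_equal(vt0$pressure, 101.3)
  expect_equal(vt0$gamma, 0.665e-3 * 101.3)
  expect_equal(vt0$gamma, 0.0674, tolerance = 1e-3)
  expect_error(vaporTerms(.metRec(rh_pct = 120)), "humidity")
  # psychrometric constant decreases with elevation
  gammas <- vapply(seq(0, 3000, by = 500), function(z)
    vaporTerms(.metRec(elev_m = z))$gamma, numeric(1))
  expect_true(all(diff(gammas) < 0))
})

test_that("daily radiation follows the Angstrom endpoints and solar oracle", {
  recN <- .metRec()
  nlen <- extraterrestrialRadiation(recN$date, recN$lat)$daylength
  clear <- pmRadiation(.metRec(sunshine_h = nlen))
  expect_equal(clear$rs, 0.75 * clear$ra)
  overcast <- pmRadiation(.metRec(sunshine_h = 0))
  expect_equal(overcast$rs, 0.25 * overcast$ra)
  expect_error(pmRadiation(.metRec(sunshine_h = nlen + 1)), "daylength")
  # equator at equinox: hand scalar solar-geometry computation
  j <- as.integer(format(as.Date("2020-03-20"), "%j"))
  dec <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  raHand <- 24 * 60 / pi * 0.0820 * dr * cos(dec) * sin(pi / 2)
  eq <- extraterrestrialRadiation(as.Date("2020-03-20"), 0)
  expect_equal(eq$ra, raHand)
  expect_equal(eq$daylength, 12)
})

test_that("reference ET limits collapse as expected", {
  # no wind, no radiation: both terms vanish
  rec <- .metRec(wind_2m_ms = 0)
  vt <- vaporTerms(rec)
  rn <- pmRadiation(rec)$rn
  et0 <- penmanMonteithET0(rec)
  expect_equal(et0, 0.408 * vt$delta * rn / (vt$delta + vt$gamma))
  # ET0 increases with vapor-pressure deficit (drier air)
  ets <- vapply(c(90, 70, 50, 30, 10), function(rh)
    penmanMonteithET0(.metRec(rh_pct = rh)), numeric(1))
  expect_true(all(diff(ets) > 0))
  expect_gte(penmanMonteithET0(.metRec(sunshine_h = 0, tmax_c = 2,
                                       tmin_c = -3, tmean_c = -0.5)), 0)
})

test_that("reference ET matches the independent scalar oracle", {
  set.seed(20)
  for (k in 1:50) {
    rec <- randomMetRecord()
    got <- penmanMonteithET0(rec)
    want <- fao56Oracle(rec$tmax_c, rec$tmin_c, rec$rh_pct, rec$wind_2m_ms,
                        rec$sunshine_h, rec$elev_m, rec$lat, rec$doy)
    expect_equal(got, want, tolerance = 0.01 / max(want, 1))
  }
})

test_that("crop coefficients scale reference ET through the calendar", {
  et0 <- data.frame(date = as.Date("2020-05-01") + 0:9,
                    et0_mm = rep(5.0, 10))
  crop <- list(name = "winter wheat", stages = data.frame(
    start = as.Date(c("2020-05-01", "2020-05-06")),
    end = as.Date(c("2020-05-05", "2020-05-08")),
    kc = c(1.0, 1.15)))
  out <- cropET(et0, crop)
  expect_equal(out$etc_mm[1:5], rep(5.0, 5))          # Kc = 1 identity
  expect_equal(out$etc_mm[6:8], rep(5.75, 3))         # 1.15 * 5.0
  expect_true(all(is.na(out$etc_mm[9:10])))           # outside calendar
  badCrop <- list(stages = data.frame(
    start = as.Date(c("2020-05-01", "2020-05-03")),
    end = as.Date(c("2020-05-05", "2020-05-08")), kc = c(1, 1)))
  expect_error(cropET(et0, badCrop), "overlap")
})

test_that("station validation reproduces the published error cells", {
  tab <- validateDailyET(exampleStationET())
  expect_equal(round(tab$abs_error, 4), c(0.1797, 0.0786, 0.1560))
  expect_equal(round(tab$rel_error, 2), c(4.78, 1.52, 2.08))
  ident <- validateDailyET(data.frame(station = "x", date = Sys.Date(),
                                      et_pm = 3, et_sebal = 3))
  expect_equal(ident$abs_error, 0)
  expect_equal(ident$rel_error, 0)
  zero <- validateDailyET(data.frame(station = "x", date = Sys.Date(),
                                     et_pm = 3, et_sebal = 0))
  expect_true(zero$flagged)
  expect_true(is.na(zero$rel_error))
})
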