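## Seeded synthetic scenes with known evaporative-fraction ground truth.
## The surface temperature field is constructed by inverting the package's
## own energy-balance chain (per-pixel monotone bisection), so the retrieval
## has an exact known answer on zero-noise scenes.

#' Configuration for the synthetic-scene generator
#'
#' Bundles and validates every knob of the generator: grid geometry,
#' acquisition date/time/latitude, the prescribed evaporative-fraction
#' field, value ranges, noise levels, met-station settings and the
#' growing-season window.  All randomness downstream flows from `seed`.
#'
#' @param rows,cols grid shape (both >= 10)
#' @param cellSize cell size, m
#' @param date scene acquisition date
#' @param overpassTime local solar time of overpass, decimal hours
#' @param latitude scene latitude, degrees
#' @param seed integer seed fixing all randomness
#' @param ndviRange NDVI truth range (subset of \[-1, 1\])
#' @param tsRange surface-temperature range, K (subset of \[250, 340\]);
#'   the endpoints are the planted cold/hot anchor temperatures
#' @param albedoRange broadband albedo truth range
#' @param demRange elevation range, m
#' @param noiseSd named list: `reflectance` (per band, reflectance units)
#'   and `thermal` (K) noise standard deviations
#' @param lambdaClip non-anchor evaporative-fraction truth is clipped to
#'   this interval so the planted anchors are strict unique extremes
#' @param lambdaGradient `c(rowSlope, colSlope)` of the linear component of
#'   the truth field (positive rowSlope + negative colSlope = increase from
#'   the northeast towards the southwest)
#' @param nBumps number of Gaussian bumps added to the truth field
#' @param lambdaField optional prescribed truth field (scalar or matrix)
#'   overriding the bumps-plus-gradient construction
#' @param plantAnchors plant strict cold/hot anchor pixels (forces the
#'   truth to 1/0 at two pixels); disable only for degenerate diagnostics
#' @param ndviAnchorMargin NDVI gap between the anchors and all other pixels
#' @param nStations number of met stations (>= 1)
#' @param season `c(start, end)` growing-season window (dates)
#' @param metMeans named list of daily met means: `tmax_c`, `tmin_c`,
#'   `rh_pct`, `wind_2m_ms`, `sunshine_h`, `precip_mm`
#' @param metNoise named list of met noise standard deviations:
#'   `temp_c`, `rh_pct`, `wind_ms`, `sunshine_h`, `precip_mm`
#' @param yieldMean,yieldSd,yieldRange zone yield distribution, kg/mu
#' @return validated `SynthConfig` list
#' @export
synthConfig <- function(rows = 100, cols = 100, cellSize = 30,
                        date = as.Date("2020-08-10"), overpassTime = 10.5,
                        latitude = 37.9, seed = 42,
                        ndviRange = c(0.20, 0.90), tsRange = c(296, 321),
                        albedoRange = c(0.16, 0.26), demRange = c(800, 1400),
                        noiseSd = list(reflectance = 0.005, thermal = 0.2),
                        lambdaClip = c(0.04, 0.96),
                        lambdaGradient = c(0.25, -0.25), nBumps = 4,
                        lambdaField = NULL, plantAnchors = TRUE,
                        ndviAnchorMargin = 0.05, nStations = 9,
                        season = as.Date(c("2020-04-01", "2020-09-30")),
                        metMeans = list(tmax_c = 29, tmin_c = 17, rh_pct = 65,
                                        wind_2m_ms = 2.2, sunshine_h = 8,
                                        precip_mm = 2),
                        metNoise = list(temp_c = 1.5, rh_pct = 8,
                                        wind_ms = 0.5, sunshine_h = 2,
                                        precip_mm = 3),
                        yieldMean = 577.046, yieldSd = 60,
                        yieldRange = c(386.794, 754.896)) {
  cfg <- list(rows = rows, cols = cols, cellSize = cellSize,
              date = as.Date(date), overpassTime = overpassTime,
              latitude = latitude, seed = as.integer(seed),
              ndviRange = ndviRange, tsRange = tsRange,
              albedoRange = albedoRange, demRange = demRange,
              noiseSd = noiseSd, lambdaClip = lambdaClip,
              lambdaGradient = lambdaGradient, nBumps = nBumps,
              lambdaField = lambdaField, plantAnchors = plantAnchors,
              ndviAnchorMargin = ndviAnchorMargin, nStations = nStations,
              season = as.Date(season), metMeans = metMeans,
              metNoise = metNoise, yieldMean = yieldMean, yieldSd = yieldSd,
              yieldRange = yieldRange)
  if (rows < 10 || cols < 10) stop("grid too small: rows and cols must be >= 10")
  if (ndviRange[1] < -1 || ndviRange[2] > 1 || ndviRange[1] >= ndviRange[2])
    stop("ndviRange must be an increasing subset of [-1, 1]")
  if (tsRange[1] < 250 || tsRange[2] > 340 || tsRange[1] >= tsRange[2])
    stop("tsRange must be an increasing subset of [250, 340] K")
  if (metMeans$tmax_c < metMeans$tmin_c) stop("configured Tmax below Tmin")
  if (nStations < 1) stop("at least one met station required")
  if (noiseSd$reflectance < 0 || noiseSd$thermal < 0) stop("negative noise sd")
  class(cfg) <- "SynthConfig"
  cfg
}

.gridCoords <- function(cfg) {
  list(x = (seq_len(cfg$cols) - 0.5) * cfg$cellSize,
       y = rev((seq_len(cfg$rows) - 0.5) * cfg$cellSize))
}

## Smooth field: Gaussian bumps + linear gradient, scaled into [lo, hi].
.smoothField <- function(rows, cols, nBumps, gradient, lo, hi) {
  rr <- matrix(seq_len(rows) / rows, rows, cols)
  cc <- matrix(rep(seq_len(cols) / cols, each = rows), rows, cols)
  f <- gradient[1] * rr + gradient[2] * cc
  for (i in seq_len(nBumps)) {
    cr <- stats::runif(1); cc0 <- stats::runif(1)
    amp <- stats::runif(1, -0.4, 0.4); wid <- stats::runif(1, 0.08, 0.25)
    f <- f + amp * exp(-((rr - cr)^2 + (cc - cc0)^2) / (2 * wid^2))
  }
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix((lo + hi) / 2, rows, cols))
  lo + (hi - lo) * (f - rng[1]) / diff(rng)
}

## Evaluate the package's flux chain at a trial Ts field with a fixed dT
## calibration; returns the evaporative fraction.  Shared by the generator
## (inversion) and its consistency tests.
.lambdaOfTs <- function(ts, ndvi, albedo, z0m, dem, taK, u200, stationElev,
                        aCo, bCo, date, timeHours, latitude,
                        tol = 1e-12, maxIter = 60) {
  eps <- computeEmissivity(ndvi)
  rsDown <- shortwaveDown(date, timeHours, latitude, dem)
  rad <- netRadiation(albedo, rsDown, ts, taK, eps, 0.75 + 2e-5 * dem)
  g <- soilHeatFlux(ts, albedo, ndvi, rad$rn)
  rho <- airDensity(dem, taK, stationElev)$rho
  dT <- aCo + bCo * ts
  h <- ts * 0
  rahPrev <- NULL
  ustar <- NULL
  for (it in seq_len(maxIter)) {
    upd <- .rahUpdate(u200, z0m, rho, ts, h, stability = TRUE, ustar)
    ustar <- upd$ustar
    rah <- if (is.null(rahPrev)) upd$rah else 0.5 * (rahPrev + upd$rah)
    h <- rho * .const$cp * dT / rah
    if (!is.null(rahPrev) &&
        max(abs(rah - rahPrev) / rahPrev, na.rm = TRUE) < tol) break
    rahPrev <- rah
  }
  latentHeat(rad$rn, g, h)$lambda
}

## Fixed-point dT calibration at the planted anchors (scalar), mirroring
## the update order of sensibleHeat().
.anchorCalibration <- function(tsCold, tsHot, hotNdvi, hotAlbedo, hotZ0m,
                               hotDem, taK, u200, stationElev,
                               date, timeHours, latitude,
                               tol = 1e-12, maxIter = 60) {
  eps <- computeEmissivity(hotNdvi)
  rs <- shortwaveDown(date, timeHours, latitude, hotDem)
  rad <- netRadiation(hotAlbedo, rs, tsHot, taK, eps, 0.75 + 2e-5 * hotDem)
  g <- soilHeatFlux(tsHot, hotAlbedo, hotNdvi, rad$rn)
  hHot <- rad$rn - g
  rho <- airDensity(hotDem, taK, stationElev)$rho
  h <- 0; rahPrev <- NULL; aCo <- bCo <- NA_real_
  ustar <- NULL
  for (it in seq_len(maxIter)) {
    upd <- .rahUpdate(u200, hotZ0m, rho, tsHot, h, stability = TRUE, ustar)
    ustar <- upd$ustar
    rah <- if (is.null(rahPrev)) upd$rah else 0.5 * (rahPrev + upd$rah)
    dtHot <- hHot * rah / (rho * .const$cp)
    bCo <- dtHot / (tsHot - tsCold)
    aCo <- -bCo * tsCold
    h <- rho * .const$cp * dtHot / rah
    if (!is.null(rahPrev) && abs(rah - rahPrev) / rahPrev < tol) break
    rahPrev <- rah
  }
  list(a = aCo, b = bCo, hHot = hHot)
}

#' Generate a synthetic scene with known evaporative-fraction truth
#'
#' Builds a smooth evaporative-fraction truth field (Gaussian bumps plus a
#' linear gradient, clipped to the configured interval), plants strict
#' cold (truth = 1, maximum NDVI, minimum Ts) and hot (truth = 0, minimum
#' NDVI, maximum Ts) anchor pixels, derives the surface-temperature field
#' from the truth by inverting the energy-balance chain, synthesizes
#' reflectance bands consistent with the NDVI and albedo truths, and adds
#' seeded sensor noise.  Identical configurations produce bit-identical
#' output.
#'
#' @param config a [synthConfig()] object
#' @return list with `scene` ([SceneStack-class]), `truth` (list:
#'   `lambda_true`, `et24_true`, `anchor_cold_index`, `anchor_hot_index`,
#'   plus the noiseless `ndvi_true`, `albedo_true`, `ts_true`, and the
#'   calibration `a`, `b`), `dem` (elevation matrix), and `met`
#'   (the instantaneous record used in the construction)
#' @export
generateScene <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  cfg <- config
  set.seed(cfg$seed)
  rows <- cfg$rows; cols <- cfg$cols

  # prescribed evaporative-fraction truth
  if (is.null(cfg$lambdaField)) {
    lam <- .smoothField(rows, cols, cfg$nBumps, cfg$lambdaGradient, 0, 1)
  } else if (length(cfg$lambdaField) == 1) {
    lam <- matrix(cfg$lambdaField, rows, cols)
  } else {
    lam <- cfg$lambdaField
    stopifnot(identical(dim(lam), c(rows, cols)))
  }
  lam <- pmin(pmax(lam, cfg$lambdaClip[1]), cfg$lambdaClip[2])

  # supporting smooth fields
  dem <- .smoothField(rows, cols, 3, c(0.4, -0.4), cfg$demRange[1], cfg$demRange[2])
  albedo <- .smoothField(rows, cols, 3, c(-0.1, 0.2),
                         cfg$albedoRange[1], cfg$albedoRange[2])

  # NDVI truth tracks the evaporative fraction; anchors sit strictly outside
  dm <- cfg$ndviAnchorMargin
  ndvi <- cfg$ndviRange[1] + dm + (diff(cfg$ndviRange) - 2 * dm) *
    (lam - cfg$lambdaClip[1]) / diff(cfg$lambdaClip)

  # plant the anchors at the extremes of the truth field
  coldIdx <- hotIdx <- NULL
  if (cfg$plantAnchors) {
    coldIdx <- which(lam == max(lam), arr.ind = TRUE)[1, ]
    hotIdx <- which(lam == min(lam), arr.ind = TRUE)[1, ]
    if (all(coldIdx == hotIdx))
      hotIdx <- if (coldIdx[1] == 1) c(rows, cols) else c(1L, 1L)
    lam[coldIdx[1], coldIdx[2]] <- 1
    lam[hotIdx[1], hotIdx[2]] <- 0
    ndvi[coldIdx[1], coldIdx[2]] <- cfg$ndviRange[2]
    ndvi[hotIdx[1], hotIdx[2]] <- cfg$ndviRange[1]
  }

  # met driving the construction (same record the retrieval will use)
  met <- generateMet(cfg)
  inst <- as.list(met$instant[1, ])
  taK <- inst$ta_c + 273.15
  z0mRef <- 0.03
  u200 <- inst$wind_2m_ms * log(200 / z0mRef) / log(2 / z0mRef)
  z0m <- suppressWarnings(computeRoughness(ndvi, albedo))

  tsCold <- cfg$tsRange[1]; tsHot <- cfg$tsRange[2]
  if (cfg$plantAnchors) {
    hotCell <- function(m) m[hotIdx[1], hotIdx[2]]
    cal <- .anchorCalibration(tsCold, tsHot, hotCell(ndvi), hotCell(albedo),
                              hotCell(z0m), hotCell(dem), taK, u200,
                              inst$elev_m, cfg$date, cfg$overpassTime,
                              cfg$latitude)
  } else {
    # virtual anchors at representative surface values
    cal <- .anchorCalibration(tsCold, tsHot, stats::median(ndvi),
                              stats::median(albedo), stats::median(z0m),
                              stats::median(dem), taK, u200, inst$elev_m,
                              cfg$date, cfg$overpassTime, cfg$latitude)
  }

  # invert lambda(Ts) per pixel by monotone bisection
  lo <- matrix(tsCold, rows, cols); hi <- matrix(tsHot, rows, cols)
  for (i in seq_len(48)) {
    mid <- (lo + hi) / 2
    lamMid <- .lambdaOfTs(mid, ndvi, albedo, z0m, dem, taK, u200,
                          inst$elev_m, cal$a, cal$b, cfg$date,
                          cfg$overpassTime, cfg$latitude)
    up <- lamMid > lam          # lambda decreases with Ts
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  ts <- (lo + hi) / 2
  if (cfg$plantAnchors) {
    ts[coldIdx[1], coldIdx[2]] <- tsCold
    ts[hotIdx[1], hotIdx[2]] <- tsHot
  }

  # reflectance bands consistent with the NDVI and albedo truths
  s <- 0.4
  red <- s * (1 - ndvi) / 2
  nir <- s * (1 + ndvi) / 2
  blue <- 0.5 * red
  green <- 0.6 * red
  swir <- (albedo + 0.0018 - 0.356 * blue - 0.130 * red - 0.373 * nir) /
    (0.085 + 0.072)
  if (any(swir < 0 | swir > 1))
    warning("albedo truth clipped: SWIR reflectance left [0, 1]")
  swir <- pmin(pmax(swir, 0), 1)

  # thermal: brightness temperature whose emissivity correction returns Ts
  eps <- computeEmissivity(ndvi)
  cc <- .const$lam_eff * log(eps) / .const$rho_c
  bt <- ts / (1 - cc * ts)

  addNoise <- function(m, sd, lim) {
    if (sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
    pmin(pmax(m, lim[1]), lim[2])
  }
  bands <- list(blue = addNoise(blue, cfg$noiseSd$reflectance, c(0, 1)),
                green = addNoise(green, cfg$noiseSd$reflectance, c(0, 1)),
                red = addNoise(red, cfg$noiseSd$reflectance, c(0, 1)),
                nir = addNoise(nir, cfg$noiseSd$reflectance, c(0, 1)),
                swir1 = addNoise(swir, cfg$noiseSd$reflectance, c(0, 1)),
                swir2 = addNoise(swir, cfg$noiseSd$reflectance, c(0, 1)))
  bt <- addNoise(bt, cfg$noiseSd$thermal, c(200, 350))

  scene <- new("SceneStack", bands = bands, bt = bt,
               mask = matrix(TRUE, rows, cols), date = cfg$date,
               overpassTime = cfg$overpassTime, latitude = cfg$latitude,
               cellSize = cfg$cellSize, origin = c(0, 0))

  # daily net radiation on the scene date -> daily-ET truth
  dayRow <- met$daily[met$daily$station_id == met$daily$station_id[1] &
                        met$daily$date == cfg$date, ]
  rn24 <- pmRadiation(as.list(dayRow))$rn * 1e6 / 86400   # MJ/m2/d -> W/m2
  et24 <- dailyET(lam, rn24, ts)

  truth <- list(lambda_true = lam, et24_true = et24,
                anchor_cold_index = coldIdx, anchor_hot_index = hotIdx,
                ndvi_true = ndvi, albedo_true = albedo, ts_true = ts,
                a = cal$a, b = cal$b, rn24 = rn24)
  class(truth) <- "SceneTruth"
  list(scene = scene, truth = truth, dem = dem, met = inst)
}

#' Generate station meteorology
#'
#' Daily records over the configured growing season plus an instantaneous
#' overpass-time record per station, with seeded noise around the
#' configured means.  Physical ranges are enforced (Tmin <= Tmean <= Tmax,
#' RH in \[0, 100\], sunshine within the astronomical daylength).
#'
#' @param config a [synthConfig()] object
#' @return list with `daily` and `instant` data frames (columns
#'   `station_id`, `date`, `tmax_c`, `tmin_c`, `tmean_c`, `rh_pct`,
#'   `wind_2m_ms`, `sunshine_h`, `precip_mm`, `elev_m`, `lat`, `lon`;
#'   `instant` has `ta_c` instead of the daily temperature triplet)
#' @export
generateMet <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  dates <- seq(cfg$season[1], cfg$season[2], by = "day")
  mm <- cfg$metMeans; ns <- cfg$metNoise

  ext <- cfg$cellSize * c(cfg$rows, cfg$cols)
  st <- data.frame(
    station_id = sprintf("S%02d", seq_len(cfg$nStations)),
    lat = cfg$latitude + stats::runif(cfg$nStations, -0.2, 0.2),
    lon = 112 + stats::runif(cfg$nStations, -0.3, 0.3),
    x = stats::runif(cfg$nStations, 0, ext[2]),
    y = stats::runif(cfg$nStations, 0, ext[1]),
    elev_m = stats::runif(cfg$nStations, cfg$demRange[1], cfg$demRange[2]))

  daily <- do.call(rbind, lapply(seq_len(cfg$nStations), function(i) {
    n <- length(dates)
    tmax <- mm$tmax_c + stats::rnorm(n, 0, ns$temp_c)
    tmin <- pmin(mm$tmin_c + stats::rnorm(n, 0, ns$temp_c), tmax - 0.5)
    if (ns$temp_c == 0) tmin <- rep(mm$tmin_c, n)
    nlen <- extraterrestrialRadiation(dates, st$lat[i])$daylength
    data.frame(
      station_id = st$station_id[i], date = dates,
      tmax_c = tmax, tmin_c = tmin, tmean_c = (tmax + tmin) / 2,
      rh_pct = pmin(pmax(mm$rh_pct + stats::rnorm(n, 0, ns$rh_pct), 0), 100),
      wind_2m_ms = pmax(mm$wind_2m_ms + stats::rnorm(n, 0, ns$wind_ms), 0.1),
      sunshine_h = pmin(pmax(mm$sunshine_h +
                               stats::rnorm(n, 0, ns$sunshine_h), 0), nlen),
      precip_mm = pmax(mm$precip_mm + stats::rnorm(n, 0, ns$precip_mm), 0),
      elev_m = st$elev_m[i], lat = st$lat[i], lon = st$lon[i],
      x = st$x[i], y = st$y[i])
  }))

  instant <- data.frame(
    station_id = st$station_id, date = cfg$date,
    ta_c = mm$tmax_c - 2 + stats::rnorm(cfg$nStations, 0, ns$temp_c),
    rh_pct = pmin(pmax(mm$rh_pct + stats::rnorm(cfg$nStations, 0, ns$rh_pct), 0), 100),
    wind_2m_ms = pmax(mm$wind_2m_ms + stats::rnorm(cfg$nStations, 0, ns$wind_ms), 0.3),
    elev_m = st$elev_m, lat = st$lat, lon = st$lon, x = st$x, y = st$y)

  list(daily = daily, instant = instant)
}

#' Generate a zone raster
#'
#' Splits the grid into contiguous vertical zone bands (a stand-in for an
#' administrative-region raster).
#'
#' @param config a [synthConfig()] object
#' @param nZones number of zones
#' @return integer matrix of zone ids
#' @export
generateZones <- function(config, nZones = 5) {
  stopifnot(inherits(config, "SynthConfig"), nZones >= 1)
  matrix(rep(as.integer(cut(seq_len(config$cols), nZones, labels = FALSE)),
             each = config$rows), config$rows, config$cols)
}

#' Generate zone-wise crop yields
#'
#' Draws one yield per zone from a normal distribution around the
#' configured mean, clamped to the configured range (kg/mu).
#'
#' @param zones integer zone raster
#' @param config a [synthConfig()] object
#' @return data.frame with `zone_id` and `yield_kg_per_mu`
#' @export
generateYield <- function(zones, config) {
  stopifnot(inherits(config, "SynthConfig"))
  ids <- sort(unique(as.integer(zones[!is.na(zones)])))
  if (length(ids) == 0) stop("empty zone raster")
  set.seed(config$seed + 2L)
  y <- stats::rnorm(length(ids), config$yieldMean, config$yieldSd)
  y <- pmin(pmax(y, config$yieldRange[1]), config$yieldRange[2])
  data.frame(zone_id = ids, yield_kg_per_mu = y)
}
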