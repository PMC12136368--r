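## Instantaneous surface energy balance: Rn, G, anchor-calibrated H with
## Monin-Obukhov stability iteration, latent heat as the residual,
## evaporative fraction and daily ET.

#' Solar geometry for a date, time and latitude
#'
#' Declination, inverse relative earth-sun distance and the cosine of the
#' solar zenith angle for a horizontal surface at local solar time.
#'
#' @param date a `Date`
#' @param timeHours local solar time, decimal hours
#' @param latitude degrees
#' @return list with `declination` (rad), `dr`, `cosTheta`, `hourAngle` (rad)
#' @export
solarGeometry <- function(date, timeHours, latitude) {
  j <- as.integer(format(as.Date(date), "%j"))
  decl <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  phi <- latitude * pi / 180
  omega <- pi / 12 * (timeHours - 12)
  cosTheta <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(omega)
  list(declination = decl, dr = dr, cosTheta = cosTheta, hourAngle = omega)
}

#' Instantaneous incoming shortwave radiation
#'
#' `Rs = Gsc * cos(theta) * dr * tau_sw` with a one-way transmissivity
#' `tau_sw = 0.75 + 2e-5 * z`.  Returns 0 (with a warning) when the sun is
#' below the horizon.
#'
#' @param date acquisition date
#' @param timeHours local solar time, decimal hours
#' @param latitude degrees
#' @param elevation elevation raster or scalar, m
#' @return incoming shortwave, W m-2 (same shape as `elevation`)
#' @export
shortwaveDown <- function(date, timeHours, latitude, elevation = 0) {
  geom <- solarGeometry(date, timeHours, latitude)
  tau <- 0.75 + 2e-5 * elevation
  if (geom$cosTheta <= 0) {
    warning("sun below horizon at requested time; shortwave set to 0")
    return(elevation * 0)
  }
  .const$gsc * geom$cosTheta * geom$dr * tau
}

#' Instantaneous net radiation
#'
#' Assembles `Rn = (1 - albedo) Rs_down + RL_down - RL_up - (1 - eps) RL_down`
#' with `RL_up = eps * sigma * Ts^4` and
#' `RL_down = eps_a * sigma * Ta^4`, `eps_a = 0.85 * (-ln tau_sw)^0.09`.
#'
#' @param albedo surface albedo raster
#' @param rsDown incoming shortwave, W m-2
#' @param ts surface temperature, K
#' @param ta near-surface air temperature at overpass, K (scalar or raster)
#' @param emissivity surface emissivity
#' @param tauSw shortwave transmissivity used for the atmospheric emissivity
#'   (scalar or raster)
#' @return list with `rs_down`, `rl_down`, `rl_up`, `rn` rasters
#' @export
netRadiation <- function(albedo, rsDown, ts, ta, emissivity, tauSw = 0.75) {
  if (missing(ta) || is.null(ta)) stop("air temperature ta is required")
  sig <- .const$sigma
  rlUp <- emissivity * sig * ts^4
  epsA <- 0.85 * (-log(tauSw))^0.09
  rlDown <- epsA * sig * ta^4 + 0 * ts   # broadcast to raster shape
  rn <- (1 - albedo) * rsDown + rlDown - rlUp - (1 - emissivity) * rlDown
  list(rs_down = rsDown + 0 * ts, rl_down = rlDown, rl_up = rlUp, rn = rn)
}

#' Soil heat flux
#'
#' `G = (Ts - 273.15)/albedo * (0.0038 albedo + 0.0074 albedo^2)
#'  * (1 - 0.98 NDVI^4) * Rn`, clipped to \[0, 0.5 Rn\] where Rn > 0.
#' Zero-albedo pixels are masked.
#'
#' @param ts surface temperature, K
#' @param albedo,ndvi surface rasters
#' @param rn net radiation, W m-2
#' @return soil heat flux raster, W m-2
#' @export
soilHeatFlux <- function(ts, albedo, ndvi, rn) {
  g <- (ts - 273.15) / albedo * (0.0038 * albedo + 0.0074 * albedo^2) *
    (1 - 0.98 * ndvi^4) * rn
  g[!is.na(albedo) & albedo == 0] <- NA_real_
  pos <- !is.na(rn) & rn > 0 & !is.na(g)
  g[pos] <- pmin(pmax(g[pos], 0), 0.5 * rn[pos])
  g
}

#' Select cold and hot anchor pixels
#'
#' The cold anchor is the coolest pixel among the highest-NDVI candidates
#' (top `coldNdviFrac` of the NDVI distribution); the hot anchor is the
#' hottest pixel among the lowest-NDVI land candidates (bottom
#' `hotNdviFrac`).  Ties are broken deterministically by (row, col)
#' lexicographic order.
#'
#' @param ts surface temperature raster, K
#' @param ndvi NDVI raster
#' @param mask logical land mask (see [landMask()])
#' @param coldNdviFrac fraction of top NDVI pixels forming the cold pool
#' @param hotNdviFrac fraction of bottom NDVI pixels forming the hot pool
#' @return list with `cold` and `hot`, each `list(row, col, ts)`
#' @export
selectAnchorPixels <- function(ts, ndvi, mask, coldNdviFrac = 0.05,
                               hotNdviFrac = 0.10) {
  valid <- mask & is.finite(ts) & is.finite(ndvi)
  if (sum(valid) < 100)
    stop("anchor selection needs at least 100 valid land pixels, got ", sum(valid))
  nv <- ndvi[valid]
  coldThr <- stats::quantile(nv, 1 - coldNdviFrac, names = FALSE)
  hotThr <- stats::quantile(nv, hotNdviFrac, names = FALSE)

  pick <- function(pool, stat, decreasing) {
    idx <- which(pool, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    vals <- stat[pool]
    best <- if (decreasing) max(vals) else min(vals)
    cand <- idx[vals == best, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    list(row = unname(cand[1, 1]), col = unname(cand[1, 2]),
         ts = ts[cand[1, 1], cand[1, 2]])
  }

  cold <- pick(valid & ndvi >= coldThr, ts, decreasing = FALSE)
  hot <- pick(valid & ndvi <= hotThr, ts, decreasing = TRUE)
  if (is.null(cold) || is.null(hot))
    stop("anchor candidate pool empty after masking")
  if (cold$ts >= hot$ts)
    stop(sprintf(
      "degenerate anchors: cold Ts %.2f K not below hot Ts %.2f K", cold$ts, hot$ts))
  list(cold = cold, hot = hot)
}

## Businger-Dyer stability correction functions of z/L.
.psiM <- function(zl) {
  out <- numeric(length(zl))
  un <- is.finite(zl) & zl < 0
  st <- is.finite(zl) & zl > 0
  x <- (1 - 16 * zl[un])^0.25
  out[un] <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
  out[st] <- -5 * zl[st]
  out
}

.psiH <- function(zl) {
  out <- numeric(length(zl))
  un <- is.finite(zl) & zl < 0
  st <- is.finite(zl) & zl > 0
  x2 <- sqrt(1 - 16 * zl[un])
  out[un] <- 2 * log((1 + x2) / 2)
  out[st] <- -5 * zl[st]
  out
}

#' Air pressure and density from elevation
#'
#' `P = 101.3 ((293 - 0.0065 z)/293)^5.26` kPa; density from the ideal gas
#' law at the lapse-adjusted air temperature.
#'
#' @param elevation m
#' @param taK air temperature at a reference elevation, K
#' @param refElevation elevation of the temperature reference, m
#' @return list with `pressure` (kPa) and `rho` (kg m-3)
#' @export
airDensity <- function(elevation, taK, refElevation = 0) {
  p <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  taz <- taK - 0.0065 * (elevation - refElevation)
  list(pressure = p, rho = 1000 * p / (.const$r_dry * taz))
}

## One aerodynamic-resistance update given the current sensible heat flux
## and the friction velocity of the previous iterate (the Obukhov length
## uses the corrected ustar, as in the canonical scheme).  z1/z2 are the dT
## heights; u200 the blending-height wind.  Returns the corrected (or
## neutral, stability = FALSE) ustar and rah.
.rahUpdate <- function(u200, z0m, rho, ts, h, stability, ustarPrev = NULL,
                       z1 = 0.1, z2 = 2) {
  k <- .const$k_vk
  lnBlend <- log(200 / z0m)
  ustarN <- k * u200 / lnBlend
  if (!stability)
    return(list(ustar = ustarN, rah = log(z2 / z1) / (k * ustarN)))
  if (is.null(ustarPrev)) ustarPrev <- ustarN
  mol <- rep(Inf, length(h))
  act <- is.finite(h) & abs(h) > 0.1
  mol[act] <- -rho[act] * .const$cp * ustarPrev[act]^3 * ts[act] /
    (k * .const$grav * h[act])
  psiM200 <- .psiM(200 / mol)
  denom <- pmax(lnBlend - psiM200, 0.1 * lnBlend)
  ustar <- k * u200 / denom
  rah <- pmax((log(z2 / z1) - .psiH(z2 / mol) + .psiH(z1 / mol)) / (k * ustar), 1)
  list(ustar = ustar, rah = rah)
}

#' Sensible heat flux with anchor calibration and stability iteration
#'
#' Calibrates the linear near-surface temperature difference `dT = a + b Ts`
#' so that `H = 0` at the cold anchor and `H = Rn - G` at the hot anchor,
#' computes `H = rho_air * Cp * dT / rah` per pixel, and iterates the
#' Monin-Obukhov stability correction of the aerodynamic resistance `rah`
#' (log profile between 0.1 m and 2 m; friction velocity from the station
#' wind extrapolated to a 200 m blending height) until the maximum relative
#' change in `rah` drops below `tol` or `maxIter` is reached.  The returned
#' `H` is always computed from the final calibration on the final `rah`, so
#' the anchor constraints hold exactly at convergence.
#'
#' @param surface a [SurfaceFields-class]
#' @param anchors anchor list from [selectAnchorPixels()]
#' @param rn,g net radiation and soil heat flux rasters, W m-2
#' @param windSpeed station wind speed at 2 m, m/s (must be positive)
#' @param taK station air temperature at overpass, K
#' @param dem elevation raster, m
#' @param stationElevation station elevation, m
#' @param stability apply Monin-Obukhov corrections (`FALSE` = neutral)
#' @param tol relative rah convergence tolerance
#' @param maxIter iteration cap
#' @return list with `h` raster and `anchors` ([AnchorPair-class])
#' @export
sensibleHeat <- function(surface, anchors, rn, g, windSpeed, taK, dem,
                         stationElevation = 0, stability = TRUE,
                         tol = 1e-3, maxIter = 20) {
  if (windSpeed <= 0) stop("wind speed must be positive")
  k <- .const$k_vk
  z0mRef <- 0.03   # reference (grass) roughness at the met station
  u200 <- windSpeed * log(200 / z0mRef) / log(2 / z0mRef)

  rho <- airDensity(dem, taK, stationElevation)$rho
  ci <- c(anchors$cold$row, anchors$cold$col)
  hi <- c(anchors$hot$row, anchors$hot$col)
  tsCold <- surface@lst[ci[1], ci[2]]
  tsHot <- surface@lst[hi[1], hi[2]]
  hHot <- rn[hi[1], hi[2]] - g[hi[1], hi[2]]

  ts <- surface@lst
  z0m <- surface@z0m
  hCur <- ts * 0   # neutral start
  rahPrev <- NULL
  aCo <- bCo <- NA_real_
  iterations <- 0L
  converged <- FALSE
  rah <- NULL

  ustar <- NULL
  for (it in seq_len(maxIter)) {
    iterations <- it
    upd <- .rahUpdate(u200, z0m, rho, ts, hCur, stability, ustar)
    ustar <- upd$ustar
    # damped update: same fixed point, suppresses oscillation in strongly
    # stable/unstable pixels
    rah <- if (is.null(rahPrev)) upd$rah else 0.5 * (rahPrev + upd$rah)
    # calibrate dT = a + b * Ts on the current rah at the anchors
    dtHot <- hHot * rah[hi[1], hi[2]] / (rho[hi[1], hi[2]] * .const$cp)
    bCo <- dtHot / (tsHot - tsCold)
    aCo <- -bCo * tsCold
    dT <- aCo + bCo * ts
    hCur <- rho * .const$cp * dT / rah
    if (!stability) { converged <- TRUE; break }
    if (!is.null(rahPrev) &&
        max(abs(rah - rahPrev) / rahPrev, na.rm = TRUE) < tol) {
      converged <- TRUE
      break
    }
    rahPrev <- rah
  }
  if (!converged && stability)
    warning("stability iteration did not converge in ", maxIter, " iterations")

  ap <- new("AnchorPair",
            cold = c(row = ci[1], col = ci[2], ts = tsCold),
            hot = c(row = hi[1], col = hi[2], ts = tsHot),
            a = aCo, b = bCo, iterations = as.numeric(iterations),
            converged = converged,
            rahCold = rah[ci[1], ci[2]], rahHot = rah[hi[1], hi[2]])
  list(h = hCur, anchors = ap)
}

#' Latent heat flux and evaporative fraction
#'
#' `lambdaET = Rn - G - H` (the energy-balance residual) and
#' `Lambda = lambdaET / (Rn - G)` clipped to \[0, 1\]; pixels with
#' `Rn - G <= 0` are masked.
#'
#' @param rn,g,h flux rasters, W m-2
#' @return list with `le` and `lambda` rasters
#' @export
latentHeat <- function(rn, g, h) {
  le <- rn - g - h
  avail <- rn - g
  lam <- le / avail
  lam[!is.na(avail) & avail <= 0] <- NA_real_
  lam <- pmin(pmax(lam, 0), 1)
  list(le = le, lambda = lam)
}

#' Latent heat of vaporization of water
#'
#' `lambda = (2.501 - 0.002361 * (Ts - 273.15)) * 1e6` J/kg.
#'
#' @param tsK temperature, K
#' @return J/kg
#' @export
latentHeatVaporization <- function(tsK) {
  (2.501 - 0.002361 * (tsK - 273.15)) * 1e6
}

#' Daily ET from the evaporative fraction
#'
#' `ET24 = 86400 * Lambda24 * Rn24 / lambda` (mm/d), with the evaporative
#' fraction assumed constant over the day, and negative values floored at 0.
#'
#' @param lambda24 daily evaporative fraction raster, \[0, 1\]
#' @param rn24 daily mean net radiation, W m-2 (scalar or raster)
#' @param ts surface temperature, K, used for the vaporization heat
#' @return daily ET raster, mm/d
#' @export
dailyET <- function(lambda24, rn24, ts) {
  lam <- latentHeatVaporization(ts)
  if (any(lam <= 0, na.rm = TRUE)) stop("nonphysical surface temperature: lambda <= 0")
  pmax(86400 * lambda24 * rn24 / lam, 0)
}

#' Run the full instantaneous energy balance on one scene
#'
#' Chains surface parameters, shortwave and net radiation, soil heat flux,
#' anchor selection (unless `anchors` are supplied), calibrated sensible
#' heat, the latent heat residual and the evaporative fraction; optionally
#' converts to daily ET when a daily net radiation is supplied.
#'
#' @param scene a [SceneStack-class]
#' @param dem elevation raster, m
#' @param met list with instantaneous met: `ta_c` (air temperature, deg C),
#'   `wind_2m_ms`, `elev_m` (station elevation)
#' @param rn24 optional daily mean net radiation (W m-2, scalar or raster)
#'   to produce `et24`
#' @param anchors optional anchor list (from [selectAnchorPixels()]) to use
#'   instead of searching
#' @param stability,tol,maxIter passed to [sensibleHeat()]
#' @param coldNdviFrac,hotNdviFrac passed to [selectAnchorPixels()]
#' @return list with `surface` ([SurfaceFields-class]), `radiation`,
#'   `flux` ([FluxFields-class]), `anchors` ([AnchorPair-class]) and, when
#'   `rn24` is given, `et24` (mm/d)
#' @export
sebalScene <- function(scene, dem, met, rn24 = NULL, anchors = NULL,
                       stability = TRUE, tol = 1e-3, maxIter = 20,
                       coldNdviFrac = 0.05, hotNdviFrac = 0.10) {
  surf <- surfaceFields(scene)
  taK <- met$ta_c + 273.15
  rsDown <- shortwaveDown(scene@date, scene@overpassTime, scene@latitude, dem)
  tauSw <- 0.75 + 2e-5 * dem
  rad <- netRadiation(surf@albedo, rsDown, surf@lst, taK, surf@emissivity, tauSw)
  g <- soilHeatFlux(surf@lst, surf@albedo, surf@ndvi, rad$rn)
  if (is.null(anchors))
    anchors <- selectAnchorPixels(surf@lst, surf@ndvi, landMask(surf),
                                  coldNdviFrac, hotNdviFrac)
  sh <- sensibleHeat(surf, anchors, rad$rn, g, met$wind_2m_ms, taK, dem,
                     stationElevation = met$elev_m, stability = stability,
                     tol = tol, maxIter = maxIter)
  lh <- latentHeat(rad$rn, g, sh$h)
  msk <- surf@mask & is.finite(lh$lambda)
  flux <- new("FluxFields", rn = rad$rn, g = g, h = sh$h, le = lh$le,
              lambdaInst = lh$lambda, mask = msk)
  out <- list(surface = surf, radiation = rad, flux = flux, anchors = sh$anchors)
  if (!is.null(rn24))
    out$et24 <- dailyET(lh$lambda, rn24, surf@lst)
  out
}
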