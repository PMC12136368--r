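## FAO-56 Penman-Monteith reference ET, crop-coefficient ET and the
## station-level validation of SEBAL daily ET.

#' Saturation vapor pressure at a temperature
#'
#' `e0(T) = 0.6108 exp(17.27 T / (T + 237.3))` kPa, T in deg C.
#'
#' @param tC temperature, deg C
#' @return kPa
#' @export
satVaporPressure <- function(tC) 0.6108 * exp(17.27 * tC / (tC + 237.3))

#' Vapor-pressure terms of the Penman-Monteith equation
#'
#' Saturation vapor pressure (mean of the Tmax and Tmin values), actual
#' vapor pressure from relative humidity, the slope of the saturation curve
#' at Tmean, and the psychrometric constant from elevation-dependent
#' pressure.
#'
#' @param met one daily met record: list/row with `tmax_c`, `tmin_c`,
#'   `tmean_c`, `rh_pct`, `elev_m`
#' @return list with `es`, `ea` (kPa), `delta`, `gamma` (kPa/degC),
#'   `pressure` (kPa)
#' @export
vaporTerms <- function(met) {
  if (met$rh_pct < 0 || met$rh_pct > 100)
    stop("relative humidity outside [0, 100]")
  es <- (satVaporPressure(met$tmax_c) + satVaporPressure(met$tmin_c)) / 2
  ea <- es * met$rh_pct / 100
  delta <- 4098 * satVaporPressure(met$tmean_c) / (met$tmean_c + 237.3)^2
  p <- 101.3 * ((293 - 0.0065 * met$elev_m) / 293)^5.26
  gamma <- 0.665e-3 * p
  list(es = es, ea = ea, delta = delta, gamma = gamma, pressure = p)
}

#' Extraterrestrial radiation and daylength
#'
#' Daily extraterrestrial radiation `Ra` (MJ m-2 d-1) and maximum possible
#' sunshine duration `N` (h) for a date and latitude.
#'
#' @param date a `Date`
#' @param latitude degrees
#' @return list with `ra` and `daylength`
#' @export
extraterrestrialRadiation <- function(date, latitude) {
  j <- as.integer(format(as.Date(date), "%j"))
  decl <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  phi <- latitude * pi / 180
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  ra <- (24 * 60 / pi) * .const$gsc_mj * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  list(ra = ra, daylength = 24 * ws / pi)
}

#' Daily net radiation for the Penman-Monteith equation
#'
#' FAO-56 daily radiation balance: Angstrom solar radiation
#' `Rs = (0.25 + 0.50 n/N) Ra`, net shortwave `Rns = 0.77 Rs`, net longwave
#' `Rnl` from the Tmax/Tmin fourth powers, humidity and relative cloudiness,
#' `Rn = Rns - Rnl`.  Soil heat flux is taken as zero at the daily step.
#'
#' @param met one daily met record: needs `date`, `lat`, `tmax_c`, `tmin_c`,
#'   `rh_pct`, `sunshine_h`, `elev_m`
#' @param angstrom `c(as, bs)` Angstrom coefficients
#' @return list with `ra`, `daylength`, `rs`, `rso`, `rns`, `rnl`, `rn`
#'   (all MJ m-2 d-1 except `daylength` in h)
#' @export
pmRadiation <- function(met, angstrom = c(0.25, 0.50)) {
  ext <- extraterrestrialRadiation(met$date, met$lat)
  if (met$sunshine_h > ext$daylength + 1e-9)
    stop("sunshine hours exceed daylength")
  rs <- (angstrom[1] + angstrom[2] * met$sunshine_h / ext$daylength) * ext$ra
  rso <- (0.75 + 2e-5 * met$elev_m) * ext$ra
  rns <- 0.77 * rs
  ea <- vaporTerms(met)$ea
  sigD <- 4.903e-9   # Stefan-Boltzmann, MJ K-4 m-2 d-1
  rnl <- sigD * ((met$tmax_c + 273.16)^4 + (met$tmin_c + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * pmin(rs / rso, 1) - 0.35)
  list(ra = ext$ra, daylength = ext$daylength, rs = rs, rso = rso,
       rns = rns, rnl = rnl, rn = rns - rnl)
}

#' FAO-56 Penman-Monteith reference ET
#'
#' `ET0 = (0.408 Delta (Rn - G) + gamma 900/(T + 273) U2 (es - ea)) /
#'        (Delta + gamma (1 + 0.34 U2))` in mm/d, floored at 0.
#'
#' @param met one daily met record: `date`, `lat`, `tmax_c`, `tmin_c`,
#'   `tmean_c`, `rh_pct`, `wind_2m_ms`, `sunshine_h`, `elev_m`
#' @return ET0, mm/d
#' @export
penmanMonteithET0 <- function(met) {
  vt <- vaporTerms(met)
  rn <- pmRadiation(met)$rn
  gday <- 0
  den <- vt$delta + vt$gamma * (1 + 0.34 * met$wind_2m_ms)
  stopifnot(den > 0)
  et0 <- (0.408 * vt$delta * (rn - gday) +
            vt$gamma * 900 / (met$tmean_c + 273) * met$wind_2m_ms *
            (vt$es - vt$ea)) / den
  max(et0, 0)
}

#' Reference ET for a daily met table
#'
#' @param metDaily data.frame of daily records (columns as in
#'   [penmanMonteithET0()], one row per station-day)
#' @return the input with an `et0_mm` column appended
#' @export
penmanMonteithSeries <- function(metDaily) {
  metDaily$et0_mm <- vapply(seq_len(nrow(metDaily)), function(i)
    penmanMonteithET0(as.list(metDaily[i, ])), numeric(1))
  metDaily
}

#' Crop ET from a crop-coefficient schedule
#'
#' `ETc = Kc(stage(date)) * ET0`.  Dates outside the crop calendar get `NA`.
#'
#' @param et0 data.frame with `date` and `et0_mm`
#' @param crop list with `name`, and `stages`: data.frame with `start`,
#'   `end` (Dates) and `kc`
#' @return input with `kc` and `etc_mm` columns
#' @export
cropET <- function(et0, crop) {
  st <- crop$stages
  stopifnot(all(st$kc > 0), all(st$kc <= 1.5), all(st$start <= st$end))
  if (nrow(st) > 1) {
    o <- order(st$start)
    st <- st[o, ]
    if (any(st$start[-1] <= st$end[-nrow(st)]))
      stop("crop stages must be ordered and non-overlapping")
  }
  kc <- rep(NA_real_, nrow(et0))
  for (i in seq_len(nrow(st))) {
    inStage <- et0$date >= st$start[i] & et0$date <= st$end[i]
    kc[inStage] <- st$kc[i]
  }
  et0$kc <- kc
  et0$etc_mm <- kc * et0$et0_mm
  et0
}

#' Validate SEBAL daily ET against Penman-Monteith at stations
#'
#' Builds the station comparison table: absolute error
#' `|et_sebal - et_pm|` and relative error `100 |et_sebal - et_pm| /
#' et_sebal` (the energy-balance value in the denominator).
#'
#' @param stations data.frame with `station`, `date`, `et_pm` and
#'   `et_sebal` (mm/d)
#' @return data.frame with `abs_error` (mm/d), `rel_error` (%) and a
#'   `flagged` column marking rows where `et_sebal = 0` leaves the relative
#'   error undefined
#' @export
validateDailyET <- function(stations) {
  stopifnot(all(c("station", "date", "et_pm", "et_sebal") %in% names(stations)))
  out <- stations
  out$abs_error <- abs(out$et_sebal - out$et_pm)
  out$rel_error <- ifelse(out$et_sebal == 0, NA_real_,
                          100 * out$abs_error / out$et_sebal)
  out$flagged <- out$et_sebal == 0
  out
}
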