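# Independent scalar FAO-56 reference-ET oracle, written directly from the
# textbook chain and kept separate from the package implementation.  Used
# only as the comparison target in tests.

fao56Oracle <- function(tmax, tmin, rh, u2, sunshine, elev, lat, doy) {
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  tmean <- (tmax + tmin) / 2
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh / 100 * es
  slope <- 4098 * e0(tmean) / (tmean + 237.3)^2
  pres <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  psy <- 0.000665 * pres
  # solar
  phi <- pi * lat / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(max(min(-tan(phi) * tan(dec), 1), -1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  nmax <- 24 / pi * ws
  rs <- (0.25 + 0.5 * sunshine / nmax) * ra
  rso <- (0.75 + 2e-5 * elev) * ra
  rns <- (1 - 0.23) * rs
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(rs / rso, 1) - 0.35)
  rn <- rns - rnl
  num <- 0.408 * slope * rn + psy * 900 / (tmean + 273) * u2 * (es - ea)
  max(num / (slope + psy * (1 + 0.34 * u2)), 0)
}

# one random physically valid daily met record
randomMetRecord <- function() {
  tmin <- runif(1, -5, 22)
  tmax <- tmin + runif(1, 2, 15)
  lat <- runif(1, 20, 55)
  date <- as.Date("2020-01-01") + sample.int(365, 1) - 1
  doy <- as.integer(format(date, "%j"))
  nmax <- 24 / pi * acos(max(min(
    -tan(pi * lat / 180) * tan(0.409 * sin(2 * pi * doy / 365 - 1.39)), 1), -1))
  list(date = date, lat = lat,
       tmax_c = tmax, tmin_c = tmin, tmean_c = (tmax + tmin) / 2,
       rh_pct = runif(1, 20, 100), wind_2m_ms = runif(1, 0.2, 6),
       sunshine_h = runif(1, 0, nmax * 0.99), elev_m = runif(1, 0, 2500),
       doy = doy)
}
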