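## Evaporative-fraction interpolation between overpasses, seasonal ET,
## water productivity, zonal statistics and the WP-environment correlation.

#' Interpolate the evaporative fraction to an arbitrary date
#'
#' Per-pixel linear interpolation between consecutive overpass dates, held
#' constant before the first and after the last overpass.  At an overpass
#' date the overpass field is returned bit-for-bit.
#'
#' @param lambdas list of evaporative-fraction matrices, one per overpass
#' @param overpassDates `Date` vector, same length as `lambdas`
#' @param date target `Date`
#' @return evaporative-fraction matrix
#' @export
interpolateLambda <- function(lambdas, overpassDates, date) {
  stopifnot(length(lambdas) == length(overpassDates), length(lambdas) >= 1)
  o <- order(overpassDates)
  overpassDates <- overpassDates[o]; lambdas <- lambdas[o]
  t <- as.numeric(date)
  tt <- as.numeric(overpassDates)
  hit <- match(t, tt)
  if (!is.na(hit)) return(lambdas[[hit]])
  if (t <= tt[1]) return(lambdas[[1]])
  n <- length(tt)
  if (t >= tt[n]) return(lambdas[[n]])
  i <- findInterval(t, tt)
  w <- (t - tt[i]) / (tt[i + 1] - tt[i])
  (1 - w) * lambdas[[i]] + w * lambdas[[i + 1]]
}

#' Daily, monthly and seasonal ET from overpass evaporative fractions
#'
#' Interpolates the daily evaporative fraction per pixel between overpasses
#' (boundary hold), converts each day to ET with the day's net radiation
#' (`ET = 86400 Lambda Rn24 / lambda_vap`) and accumulates monthly and
#' seasonal totals.
#'
#' @param lambdas list of evaporative-fraction matrices at overpass dates
#' @param overpassDates `Date` vector
#' @param dates daily `Date` sequence covering the season
#' @param rn24 daily net radiation: numeric vector (scalar per day) or list
#'   of matrices, aligned with `dates`
#' @param ts surface temperature matrix (K) for the vaporization heat
#' @return list with `dates`, `monthly` (named list of ET matrices, mm) and
#'   `seasonal` (ET matrix, mm)
#' @export
interpolateDailyET <- function(lambdas, overpassDates, dates, rn24, ts) {
  if (length(lambdas) < 1) stop("at least one overpass required")
  if (is.numeric(rn24) && length(rn24) == 1) rn24 <- rep(rn24, length(dates))
  if (is.numeric(rn24)) stopifnot(length(rn24) == length(dates))
  months <- format(dates, "%Y-%m")
  monthly <- list()
  for (k in seq_along(dates)) {
    lam <- interpolateLambda(lambdas, overpassDates, dates[k])
    r <- if (is.list(rn24)) rn24[[k]] else rn24[k]
    et <- dailyET(lam, r, ts)
    m <- months[k]
    monthly[[m]] <- if (is.null(monthly[[m]])) et else monthly[[m]] + et
  }
  # seasonal total is the sum of the monthly totals by construction
  list(dates = dates, monthly = monthly, seasonal = Reduce(`+`, monthly))
}

#' Per-pixel yield raster from a zone yield table
#'
#' @param zones integer zone raster
#' @param yieldTable data.frame with `zone_id`, `yield_kg_per_mu`
#' @return yield matrix, kg/mu
#' @export
yieldRaster <- function(zones, yieldTable) {
  idx <- match(as.integer(zones), yieldTable$zone_id)
  matrix(yieldTable$yield_kg_per_mu[idx], nrow(zones), ncol(zones))
}

#' Crop water productivity
#'
#' `WP = yield / water consumed` in kg per cubic metre.  With the yield in
#' kg/mu (1 mu = 666.667 m2) and seasonal ET as a depth in mm this reduces
#' to `WP = 1.5 * yield / ET_mm`.  Pixels with zero ET are masked and
#' flagged.
#'
#' @param yield yield raster, kg/mu (see [yieldRaster()])
#' @param etMm seasonal ET raster, mm
#' @return list with `wp` (kg/m3 matrix) and `flagged` (logical matrix of
#'   zero-ET crop pixels)
#' @export
waterProductivity <- function(yield, etMm) {
  stopifnot(identical(dim(yield), dim(etMm)))
  flagged <- !is.na(etMm) & etMm == 0 & !is.na(yield) & yield > 0
  wp <- (yield / .const$mu_m2) / (etMm / 1000)
  wp[flagged] <- NA_real_
  wp[!is.na(yield) & yield == 0] <- 0
  list(wp = wp, flagged = flagged)
}

#' Zonal statistics
#'
#' Mean, minimum, maximum and valid-pixel count of a raster per zone.
#' Empty zones (no valid pixels) are omitted with a warning.
#'
#' @param x value raster
#' @param zones integer zone raster, aligned with `x`
#' @return data.frame with `zone`, `mean`, `min`, `max`, `count`, ordered
#'   by zone id
#' @export
zonalStats <- function(x, zones) {
  stopifnot(identical(dim(x), dim(zones)))
  ids <- sort(unique(as.integer(zones[!is.na(zones)])))
  rows <- lapply(ids, function(z) {
    v <- x[!is.na(zones) & zones == z]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    data.frame(zone = z, mean = mean(v), min = min(v), max = max(v),
               count = length(v))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("zone(s) with no valid pixels omitted: ",
                          paste(ids[empty], collapse = ", "))
  do.call(rbind, rows[!empty])
}

#' Correlation of water productivity with environmental factors
#'
#' Pearson correlation of the WP raster with each factor raster, per zone,
#' with a two-tailed t-test and a significance flag at the chosen level.
#' Zones with fewer than 10 valid pixel pairs or a zero-variance variable
#' yield an undefined correlation and are flagged.
#'
#' @param wp water-productivity raster
#' @param factors named list of factor rasters (e.g. `dem`, `temperature`,
#'   `precipitation`)
#' @param zones integer zone raster
#' @param alpha significance level (default 0.01, two-tailed)
#' @return data.frame with `region`, `factor`, `r`, `p`, `significant`,
#'   `n`, `flagged`
#' @export
correlateWP <- function(wp, factors, zones, alpha = 0.01) {
  stopifnot(is.list(factors), length(names(factors)) == length(factors))
  for (f in factors) stopifnot(identical(dim(f), dim(wp)))
  ids <- sort(unique(as.integer(zones[!is.na(zones)])))
  out <- list()
  for (z in ids) {
    inz <- !is.na(zones) & zones == z
    for (nm in names(factors)) {
      a <- wp[inz]; b <- factors[[nm]][inz]
      ok <- is.finite(a) & is.finite(b)
      a <- a[ok]; b <- b[ok]
      n <- length(a)
      if (n < 10 || stats::sd(a) == 0 || stats::sd(b) == 0) {
        out[[length(out) + 1]] <- data.frame(
          region = z, factor = nm, r = NA_real_, p = NA_real_,
          significant = FALSE, n = n, flagged = TRUE)
        next
      }
      ct <- stats::cor.test(a, b, alternative = "two.sided")
      out[[length(out) + 1]] <- data.frame(
        region = z, factor = nm, r = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < alpha, n = n, flagged = FALSE)
    }
  }
  do.call(rbind, out)
}
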