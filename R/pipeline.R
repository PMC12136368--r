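## End-to-end driver: synthetic scene bundle -> surface parameters ->
## energy balance per scene -> temporal upscaling -> water productivity ->
## reference-ET validation, with a run manifest.

#' Pipeline configuration
#'
#' Collects every algorithm switch and constant of the pipeline with
#' documented defaults.  Unknown arguments are errors; the configuration
#' round-trips losslessly through JSON ([saveConfig()] / [loadConfig()]).
#'
#' @param synth a [synthConfig()] for the scene generator
#' @param sceneDates overpass dates to simulate
#' @param outDir output directory
#' @param nZones number of yield/administrative zones
#' @param stability apply Monin-Obukhov stability corrections
#' @param tol,maxIter stability-iteration control
#' @param coldNdviFrac,hotNdviFrac anchor-pool percentile fractions
#' @param gFormula soil-heat-flux formulation tag (only `"bastiaanssen"`,
#'   the albedo-normalized form, is implemented)
#' @param cropNdviMin minimum scene-mean NDVI for a pixel to count as
#'   cropland; water productivity is only defined on crop pixels
#' @param interpolation evaporative-fraction interpolation between
#'   overpasses (only `"linear"` with boundary hold is implemented)
#' @param seed run seed (overrides the generator seed)
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(synth = synthConfig(), sceneDates =
                             as.Date(c("2020-04-08", "2020-08-10")),
                           outDir = tempfile("sebalwp_run_"), nZones = 5,
                           stability = TRUE, tol = 1e-3, maxIter = 20,
                           coldNdviFrac = 0.05, hotNdviFrac = 0.10,
                           gFormula = "bastiaanssen", cropNdviMin = 0.35,
                           interpolation = "linear", seed = NULL) {
  gFormula <- match.arg(gFormula)
  interpolation <- match.arg(interpolation)
  if (!is.null(seed)) synth$seed <- as.integer(seed)
  cfg <- list(synth = synth, sceneDates = as.Date(sceneDates),
              outDir = outDir, nZones = nZones, stability = stability,
              tol = tol, maxIter = maxIter, coldNdviFrac = coldNdviFrac,
              hotNdviFrac = hotNdviFrac, gFormula = gFormula,
              cropNdviMin = cropNdviMin,
              interpolation = interpolation, seed = synth$seed,
              constants = list(cp = .const$cp, sigma = .const$sigma,
                               gsc = .const$gsc, mu_m2 = .const$mu_m2))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipelineConfig()] object
#' @param path JSON file
#' @export
saveConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$synth <- unclass(cfg$synth)
  cfg$synth$date <- format(cfg$synth$date)
  cfg$synth$season <- format(cfg$synth$season)
  cfg$sceneDates <- format(cfg$sceneDates)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(raw), c(known, "constants", "seed"))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  sRaw <- raw$synth
  sKnown <- names(formals(synthConfig))
  sExtra <- setdiff(names(sRaw), sKnown)
  if (length(sExtra)) stop("unknown synth key(s): ", paste(sExtra, collapse = ", "))
  sRaw$lambdaField <- if (is.null(sRaw$lambdaField)) NULL else sRaw$lambdaField
  synth <- do.call(synthConfig, sRaw)
  pipelineConfig(synth = synth, sceneDates = as.Date(raw$sceneDates),
                 outDir = raw$outDir, nZones = raw$nZones,
                 stability = raw$stability, tol = raw$tol,
                 maxIter = raw$maxIter, coldNdviFrac = raw$coldNdviFrac,
                 hotNdviFrac = raw$hotNdviFrac, gFormula = raw$gFormula,
                 cropNdviMin = raw$cropNdviMin,
                 interpolation = raw$interpolation)
}

## Map station grid coordinates to a (row, col) cell.
.stationCell <- function(x, y, rows, cols, cellSize) {
  col <- pmin(pmax(ceiling(x / cellSize), 1), cols)
  row <- pmin(pmax(rows - ceiling(y / cellSize) + 1, 1), rows)
  cbind(row = row, col = col)
}

#' Run the full pipeline on a synthetic scene bundle
#'
#' Generates the scenes, DEM, meteorology, zones and yields; runs the
#' energy balance per scene; interpolates the evaporative fraction to daily
#' ET over the growing season (daily net radiation gridded from the
#' stations via thin-plate spline with elevation covariate); maps water
#' productivity and zonal statistics; correlates WP with elevation,
#' temperature and precipitation; and validates the retrieved daily ET
#' against Penman-Monteith at the stations.  All outputs are written under
#' `config$outDir` and listed, with checksums, in the returned manifest.
#'
#' @param config a [pipelineConfig()] object
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  warningsLog <- character()
  stamp <- function(name, start)
    timings[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(start), 3)

  # --- scenes + energy balance per overpass -------------------------------
  tA <- Sys.time()
  scfg <- config$synth
  lambdas <- list(); ndvis <- list(); anchorsLog <- list()
  dem <- NULL; met <- NULL; tsLast <- NULL
  for (i in seq_along(config$sceneDates)) {
    ci <- scfg
    ci$date <- config$sceneDates[i]
    gen <- generateScene(ci)
    if (is.null(dem)) { dem <- gen$dem; met <- generateMet(ci) }
    res <- sebalScene(gen$scene, gen$dem, gen$met,
                      stability = config$stability, tol = config$tol,
                      maxIter = config$maxIter,
                      coldNdviFrac = config$coldNdviFrac,
                      hotNdviFrac = config$hotNdviFrac)
    lambdas[[i]] <- lambdaInst(res$flux)
    ndvis[[i]] <- getLayer(res$surface, "ndvi")
    tsLast <- res$surface@lst
    ap <- res$anchors
    anchorsLog[[i]] <- list(
      date = format(config$sceneDates[i]),
      cold = as.list(ap@cold), hot = as.list(ap@hot),
      a = ap@a, b = ap@b, iterations = ap@iterations,
      converged = ap@converged, rahCold = ap@rahCold, rahHot = ap@rahHot)
    writeAsciiGrid(lambdas[[i]],
                   file.path(config$outDir,
                             sprintf("lambda_%s.asc", format(ci$date))),
                   scfg$cellSize)
  }
  stamp("energy_balance", tA)

  # --- daily net radiation grids and temporal upscaling -------------------
  tB <- Sys.time()
  dates <- seq(scfg$season[1], scfg$season[2], by = "day")
  daily <- met$daily
  daily$rn24_wm2 <- vapply(seq_len(nrow(daily)), function(k)
    pmRadiation(as.list(daily[k, ]))$rn * 1e6 / 86400, numeric(1))
  rn24 <- lapply(seq_along(dates), function(k) {
    d <- daily[daily$date == dates[k], ]
    gridMet(d, "rn24_wm2", dem, scfg$cellSize, temperature = FALSE)
  })
  ets <- interpolateDailyET(lambdas, config$sceneDates, dates, rn24, tsLast)
  writeAsciiGrid(ets$seasonal, file.path(config$outDir, "seasonal_et.asc"),
                 scfg$cellSize)
  stamp("temporal_upscaling", tB)

  # --- water productivity -------------------------------------------------
  tC <- Sys.time()
  zones <- generateZones(scfg, config$nZones)
  yields <- generateYield(zones, scfg)
  # water productivity is only defined over cropland
  cropMask <- Reduce(`+`, ndvis) / length(ndvis) >= config$cropNdviMin
  cropZones <- zones
  cropZones[!cropMask] <- NA_integer_
  wp <- waterProductivity(yieldRaster(cropZones, yields), ets$seasonal)
  wpStats <- zonalStats(wp$wp, cropZones)
  tempGrid <- gridMet(stats::aggregate(tmean_c ~ station_id + x + y + elev_m,
                                       daily, mean),
                      "tmean_c", dem, scfg$cellSize)
  precGrid <- gridMet(stats::aggregate(precip_mm ~ station_id + x + y + elev_m,
                                       daily, sum),
                      "precip_mm", dem, scfg$cellSize, temperature = FALSE)
  corr <- correlateWP(wp$wp, list(dem = dem, temperature = tempGrid,
                                  precipitation = precGrid), cropZones)
  writeAsciiGrid(wp$wp, file.path(config$outDir, "wp.asc"), scfg$cellSize)
  utils::write.csv(yields, file.path(config$outDir, "yields.csv"),
                   row.names = FALSE)
  utils::write.csv(wpStats, file.path(config$outDir, "wp_zonal.csv"),
                   row.names = FALSE)
  utils::write.csv(corr, file.path(config$outDir, "wp_correlation.csv"),
                   row.names = FALSE)
  stamp("water_productivity", tC)

  # --- Penman-Monteith validation at stations -----------------------------
  tD <- Sys.time()
  cells <- .stationCell(met$instant$x, met$instant$y, scfg$rows, scfg$cols,
                        scfg$cellSize)
  val <- do.call(rbind, lapply(seq_along(config$sceneDates), function(i) {
    d <- config$sceneDates[i]
    rows <- daily[daily$date == d, ]
    etPm <- vapply(seq_len(nrow(rows)), function(k)
      penmanMonteithET0(as.list(rows[k, ])), numeric(1))
    lam <- lambdas[[i]]
    etSe <- vapply(seq_len(nrow(rows)), function(k) {
      rc <- cells[k, ]
      dailyET(lam[rc[1], rc[2]], rn24[[match(d, dates)]][rc[1], rc[2]],
              tsLast[rc[1], rc[2]])
    }, numeric(1))
    data.frame(station = rows$station_id, date = d, et_pm = etPm,
               et_sebal = etSe)
  }))
  valTab <- validateDailyET(val)
  utils::write.csv(valTab, file.path(config$outDir, "validation.csv"),
                   row.names = FALSE)
  stamp("validation", tD)

  # --- manifest -----------------------------------------------------------
  cfgPath <- file.path(config$outDir, "config.json")
  saveConfig(config, cfgPath)
  outFiles <- setdiff(list.files(config$outDir, full.names = TRUE),
                      file.path(config$outDir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sebalwp")),
    config = cfgPath,
    seed = config$seed,
    timings_s = timings,
    anchors = anchorsLog,
    warnings = warningsLog,
    outputs = lapply(outFiles, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    total_s = round(as.numeric(Sys.time()) - as.numeric(t0), 3))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Bundled station daily-ET comparison pairs
#'
#' Published daily ET (mm/d) at three Shanxi meteorological stations on
#' 2020-08-10: the FAO-56 Penman-Monteith value and the satellite
#' energy-balance retrieval.  Used as reference input for the validation
#' examples and tests.
#'
#' @return data.frame with `station`, `date`, `et_pm`, `et_sebal`
#' @export
exampleStationET <- function() {
  data.frame(
    station = c("Mount Wutai", "Taigu", "Lishi"),
    date = as.Date("2020-08-10"),
    et_pm = c(3.5812, 5.0843, 7.3481),
    et_sebal = c(3.7609, 5.1629, 7.5041))
}
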