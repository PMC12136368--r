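## Plain-text raster and table I/O plus station-to-grid met interpolation.

#' Write a matrix as an ESRI ASCII grid
#'
#' Rows are written from the northern edge; `NA` becomes the nodata value.
#'
#' @param x numeric matrix
#' @param path output file (conventionally `.asc`)
#' @param cellSize cell size, m
#' @param origin x/y of the lower-left corner
#' @param nodata nodata sentinel
#' @export
writeAsciiGrid <- function(x, path, cellSize = 30, origin = c(0, 0),
                           nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(x)),
               sprintf("nrows %d", nrow(x)),
               sprintf("xllcorner %.10g", origin[1]),
               sprintf("yllcorner %.10g", origin[2]),
               sprintf("cellsize %.10g", cellSize),
               sprintf("NODATA_value %.10g", nodata)), con)
  xx <- x
  xx[is.na(xx)] <- nodata
  utils::write.table(format(xx, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file
#' @return list with `data` matrix (`NA` at nodata), `cellSize`, `origin`
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == h[["nrows"]], ncol(m) == h[["ncols"]])
  m[m == h[["nodata_value"]]] <- NA_real_
  list(data = m, cellSize = h[["cellsize"]],
       origin = c(h[["xllcorner"]], h[["yllcorner"]]))
}

#' Write a scene to a directory of ASCII grids plus JSON metadata
#'
#' @param scene a [SceneStack-class]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(scene@bands))
    writeAsciiGrid(.maskNA(scene@bands[[b]], scene@mask),
                   file.path(dir, paste0(b, ".asc")),
                   scene@cellSize, scene@origin)
  writeAsciiGrid(.maskNA(scene@bt, scene@mask), file.path(dir, "bt.asc"),
                 scene@cellSize, scene@origin)
  meta <- list(date = format(scene@date), overpassTime = scene@overpassTime,
               latitude = scene@latitude)
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scene written by [writeScene()]
#'
#' Rejects directories with missing bands or metadata, naming the missing
#' piece; nodata pixels become the scene mask.
#'
#' @param dir scene directory
#' @return a [SceneStack-class]
#' @export
readScene <- function(dir) {
  metaPath <- file.path(dir, "scene.json")
  if (!file.exists(metaPath)) stop("missing scene metadata: scene.json")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (f in c("date", "overpassTime", "latitude"))
    if (is.null(meta[[f]])) stop("scene metadata missing field: ", f)
  need <- c(.bandNames, "bt")
  paths <- file.path(dir, paste0(need, ".asc"))
  miss <- need[!file.exists(paths)]
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  grids <- lapply(paths, readAsciiGrid)
  names(grids) <- need
  mask <- Reduce(`&`, lapply(grids, function(g) !is.na(g$data)))
  fill <- function(m, v) { m[is.na(m)] <- v; m }
  bands <- lapply(grids[.bandNames], function(g) fill(g$data, 0))
  new("SceneStack", bands = bands, bt = fill(grids$bt$data, 273.15),
      mask = mask, date = as.Date(meta$date),
      overpassTime = meta$overpassTime, latitude = meta$latitude,
      cellSize = grids[[1]]$cellSize, origin = grids[[1]]$origin)
}

#' Write / read station meteorology CSV
#'
#' @param met data.frame of met records
#' @param path CSV path
#' @export
writeMetCSV <- function(met, path) {
  utils::write.csv(met, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetCSV
#' @export
readMetCSV <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(m)) m$date <- as.Date(m$date)
  m
}

.phiTPS <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Interpolate station values to the model grid
#'
#' Thin-plate-spline surface with an elevation covariate when at least five
#' stations are available (exact at the stations), otherwise
#' inverse-distance-squared weighting with a -6.5 K/km lapse adjustment for
#' temperature-like variables.
#'
#' @param stations data.frame with `x`, `y` (m, grid coordinates), `elev_m`
#'   and the value column named by `variable`
#' @param variable name of the value column
#' @param dem elevation matrix, m
#' @param cellSize grid cell size, m
#' @param temperature apply the elevation lapse in the inverse-distance
#'   fallback (default: guessed from the variable name)
#' @return interpolated matrix on the DEM grid
#' @export
gridMet <- function(stations, variable, dem, cellSize,
                    temperature = grepl("^t|temp", variable)) {
  if (nrow(stations) == 0) stop("no stations to interpolate")
  v <- stations[[variable]]
  if (is.null(v)) stop("no column named ", variable)
  rows <- nrow(dem); cols <- ncol(dem)
  gx <- matrix(rep((seq_len(cols) - 0.5) * cellSize, each = rows), rows, cols)
  gy <- matrix(rev(seq_len(rows) - 0.5) * cellSize, rows, cols)

  if (nrow(stations) >= 5) {
    fit <- tpsFit(stations$x, stations$y, stations$elev_m, v)
    if (!is.null(fit))
      return(tpsPredict(fit, as.vector(gx), as.vector(gy), as.vector(dem),
                        rows, cols))
  }
  # inverse-distance-squared fallback
  lapse <- if (temperature) 0.0065 else 0
  vsl <- v + lapse * stations$elev_m
  num <- matrix(0, rows, cols); den <- matrix(0, rows, cols)
  exact <- matrix(NA_real_, rows, cols)
  for (i in seq_len(nrow(stations))) {
    d2 <- (gx - stations$x[i])^2 + (gy - stations$y[i])^2
    hit <- d2 == 0
    exact[hit] <- vsl[i]
    w <- 1 / pmax(d2, 1e-12)
    num <- num + w * vsl[i]
    den <- den + w
  }
  out <- num / den
  out[!is.na(exact)] <- exact[!is.na(exact)]
  out - lapse * dem
}

#' Fit a thin-plate spline with an elevation covariate
#'
#' Exact interpolation (no smoothing): radial basis `r^2 log r` plus an
#' affine polynomial in x, y and elevation.  Returns `NULL` when the system
#' is singular (e.g. collinear stations).
#'
#' @param x,y station coordinates, m
#' @param elev station elevations, m
#' @param v station values
#' @return fit object for [tpsPredict()], or `NULL`
#' @export
tpsFit <- function(x, y, elev, v) {
  n <- length(v)
  sc <- 1000   # coordinates in km for conditioning
  xs <- x / sc; ys <- y / sc
  d <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
  K <- .phiTPS(d)
  P <- cbind(1, xs, ys, elev / 1000)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(v, rep(0, 4))
  coefs <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(coefs)) return(NULL)
  list(xs = xs, ys = ys, w = coefs[1:n], poly = coefs[(n + 1):(n + 4)],
       sc = sc)
}

#' @rdname tpsFit
#' @param fit a [tpsFit()] object
#' @param gx,gy,gelev prediction coordinates and elevations (vectors)
#' @param rows,cols output matrix shape
#' @export
tpsPredict <- function(fit, gx, gy, gelev, rows, cols) {
  xs <- gx / fit$sc; ys <- gy / fit$sc
  out <- fit$poly[1] + fit$poly[2] * xs + fit$poly[3] * ys +
    fit$poly[4] * gelev / 1000
  for (i in seq_along(fit$w)) {
    r <- sqrt((xs - fit$xs[i])^2 + (ys - fit$ys[i])^2)
    out <- out + fit$w[i] * .phiTPS(r)
  }
  matrix(out, rows, cols)
}
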