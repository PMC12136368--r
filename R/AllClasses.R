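#' @import methods
NULL

# Physical constants used across the energy-balance chain.
.const <- list(
  sigma   = 5.67e-8,   # Stefan-Boltzmann, W m-2 K-4
  gsc     = 1367,      # solar constant, W m-2
  gsc_mj  = 0.0820,    # solar constant, MJ m-2 min-1 (daily radiation chain)
  cp      = 1004,      # specific heat of air at constant pressure, J kg-1 K-1
  k_vk    = 0.41,      # von Karman constant
  grav    = 9.81,      # m s-2
  r_dry   = 287.05,    # gas constant of dry air, J kg-1 K-1
  mu_m2   = 2000 / 3,  # area of 1 mu in m2 (666.667, 1/15 ha)
  k1_l8   = 774.8853,  # Planck calibration, 10.6-11.2 um band
  k2_l8   = 1321.0789,
  lam_eff = 10.9e-6,   # effective thermal wavelength, m
  rho_c   = 1.438e-2   # h*c/k_B, m K
)

.sameDim <- function(a, b) identical(dim(a), dim(b))

#' SceneStack: one satellite acquisition
#'
#' Holds the six reflectance bands, the thermal band (brightness temperature,
#' K), the valid-pixel mask and the acquisition geometry of a Landsat-like
#' scene.  All bands are row/col matrices on a single shared grid;
#' geographic coordinates refer to pixel centres, rows count from the
#' northern edge.
#'
#' @slot bands named list of reflectance matrices
#'   (`blue`, `green`, `red`, `nir`, `swir1`, `swir2`), each in \[0, 1\]
#' @slot bt brightness-temperature matrix (K)
#' @slot mask logical matrix, `TRUE` on valid pixels
#' @slot date acquisition `Date`
#' @slot overpassTime local solar time of overpass, decimal hours
#' @slot latitude scene-centre latitude, degrees
#' @slot cellSize grid cell size, m
#' @slot origin numeric length-2, x/y of the lower-left pixel centre
#'
#' @exportClass SceneStack
setClass("SceneStack", representation(
  bands = "list", bt = "matrix", mask = "matrix",
  date = "Date", overpassTime = "numeric", latitude = "numeric",
  cellSize = "numeric", origin = "numeric"
))

.bandNames <- c("blue", "green", "red", "nir", "swir1", "swir2")

setValidity("SceneStack", function(object) {
  msg <- character()
  if (!all(.bandNames %in% names(object@bands)))
    msg <- c(msg, paste("missing band(s):",
                        paste(setdiff(.bandNames, names(object@bands)), collapse = ", ")))
  for (b in intersect(.bandNames, names(object@bands))) {
    m <- object@bands[[b]]
    if (!.sameDim(m, object@mask)) msg <- c(msg, paste("band", b, "shape mismatch"))
    v <- m[object@mask]
    if (any(is.finite(v) & (v < 0 | v > 1)))
      msg <- c(msg, paste("band", b, "outside [0,1] on valid pixels"))
  }
  if (!.sameDim(object@bt, object@mask)) msg <- c(msg, "thermal band shape mismatch")
  btv <- object@bt[object@mask]
  if (any(is.finite(btv) & (btv < 200 | btv > 350)))
    msg <- c(msg, "brightness temperature outside [200, 350] K")
  if (object@latitude < -90 || object@latitude > 90) msg <- c(msg, "invalid latitude")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
  if (length(msg)) msg else TRUE
})

#' SurfaceFields: per-pixel surface parameters
#'
#' NDVI, broadband albedo, emissivity, emissivity-corrected land surface
#' temperature and momentum roughness length derived from a
#' [SceneStack-class], all masked identically to the input scene.
#'
#' @slot ndvi normalized difference vegetation index, \[-1, 1\]
#' @slot albedo broadband surface albedo, \[0, 1\]
#' @slot emissivity surface emissivity, clipped to \[0.90, 0.99\]
#' @slot lst land surface temperature, K
#' @slot z0m momentum roughness length, m (floored at 0.001)
#' @slot mask logical validity matrix
#'
#' @exportClass SurfaceFields
setClass("SurfaceFields", representation(
  ndvi = "matrix", albedo = "matrix", emissivity = "matrix",
  lst = "matrix", z0m = "matrix", mask = "matrix"
))

setValidity("SurfaceFields", function(object) {
  msg <- character()
  for (s in c("ndvi", "albedo", "emissivity", "lst", "z0m"))
    if (!.sameDim(slot(object, s), object@mask)) msg <- c(msg, paste(s, "shape mismatch"))
  ev <- object@emissivity[object@mask]
  if (any(is.finite(ev) & (ev < 0.90 - 1e-12 | ev > 0.99 + 1e-12)))
    msg <- c(msg, "emissivity outside [0.90, 0.99]")
  zv <- object@z0m[object@mask]
  if (any(is.finite(zv) & zv <= 0)) msg <- c(msg, "z0m must be positive on land")
  if (length(msg)) msg else TRUE
})

#' FluxFields: instantaneous surface energy-balance components
#'
#' Net radiation, soil heat flux, sensible heat flux, the latent heat flux
#' obtained as the residual of the balance, and the evaporative fraction.
#' Closure `le = rn - g - h` holds exactly by construction.
#'
#' @slot rn net radiation, W m-2
#' @slot g soil heat flux, W m-2
#' @slot h sensible heat flux, W m-2
#' @slot le latent heat flux, W m-2
#' @slot lambdaInst evaporative fraction, clipped to \[0, 1\]
#' @slot mask logical validity matrix
#'
#' @exportClass FluxFields
setClass("FluxFields", representation(
  rn = "matrix", g = "matrix", h = "matrix", le = "matrix",
  lambdaInst = "matrix", mask = "matrix"
))

setValidity("FluxFields", function(object) {
  msg <- character()
  for (s in c("rn", "g", "h", "le", "lambdaInst"))
    if (!.sameDim(slot(object, s), object@mask)) msg <- c(msg, paste(s, "shape mismatch"))
  ok <- object@mask & is.finite(object@le)
  resid <- object@rn[ok] - object@g[ok] - object@h[ok] - object@le[ok]
  if (length(resid) && max(abs(resid)) > 0)
    msg <- c(msg, "energy balance closure violated (le != rn - g - h)")
  lv <- object@lambdaInst[object@mask & is.finite(object@lambdaInst)]
  if (length(lv) && (min(lv) < 0 || max(lv) > 1))
    msg <- c(msg, "lambdaInst outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' AnchorPair: calibrated cold/hot anchor pixels
#'
#' The cold (well-watered, H = 0) and hot (dry, latent heat = 0) pixels used
#' to calibrate the linear near-surface temperature difference
#' `dT = a + b * Ts`, together with the Monin-Obukhov convergence trace.
#'
#' @slot cold named numeric: `row`, `col`, `ts` of the cold pixel
#' @slot hot named numeric: `row`, `col`, `ts` of the hot pixel
#' @slot a intercept of the dT-Ts line, K
#' @slot b slope of the dT-Ts line, K/K
#' @slot iterations stability iterations used
#' @slot converged logical
#' @slot rahCold aerodynamic resistance at the cold anchor, s m-1
#' @slot rahHot aerodynamic resistance at the hot anchor, s m-1
#'
#' @exportClass AnchorPair
setClass("AnchorPair", representation(
  cold = "numeric", hot = "numeric", a = "numeric", b = "numeric",
  iterations = "numeric", converged = "logical",
  rahCold = "numeric", rahHot = "numeric"
))

setValidity("AnchorPair", function(object) {
  if (object@cold[["ts"]] >= object@hot[["ts"]])
    "cold anchor must be cooler than hot anchor" else TRUE
})

#' @describeIn SceneStack-class dimensions of the scene grid
#' @param x a `SceneStack`
#' @export
setMethod("dim", "SceneStack", function(x) dim(x@mask))

setMethod("show", "SceneStack", function(object) {
  d <- dim(object)
  cat(sprintf("SceneStack %d x %d (%g m cells), %s %.2fh solar, lat %.3f\n",
              d[1], d[2], object@cellSize, format(object@date),
              object@overpassTime, object@latitude))
  cat(sprintf("  bands: %s + thermal; %d/%d valid pixels\n",
              paste(names(object@bands), collapse = ","),
              sum(object@mask), length(object@mask)))
})

setMethod("show", "SurfaceFields", function(object) {
  rng <- function(m) {
    v <- m[object@mask & is.finite(m)]
    if (!length(v)) return("all masked")
    sprintf("[%.3f, %.3f]", min(v), max(v))
  }
  cat("SurfaceFields", paste(dim(object@mask), collapse = " x "), "\n")
  cat("  ndvi", rng(object@ndvi), " albedo", rng(object@albedo),
      " lst", rng(object@lst), "K\n")
})

setMethod("show", "FluxFields", function(object) {
  v <- object@lambdaInst[object@mask & is.finite(object@lambdaInst)]
  cat("FluxFields", paste(dim(object@mask), collapse = " x "),
      sprintf("| mean Rn %.1f W/m2, mean evaporative fraction %.3f\n",
              mean(object@rn[object@mask], na.rm = TRUE), mean(v)))
})

setMethod("show", "AnchorPair", function(object) {
  cat(sprintf("AnchorPair: cold (%d,%d) Ts=%.2fK | hot (%d,%d) Ts=%.2fK\n",
              object@cold[["row"]], object@cold[["col"]], object@cold[["ts"]],
              object@hot[["row"]], object@hot[["col"]], object@hot[["ts"]]))
  cat(sprintf("  dT = %.4f + %.5f * Ts;  %d iterations, converged: %s\n",
              object@a, object@b, object@iterations, object@converged))
})

#' Extract a named layer from a scene, surface or flux object
#'
#' @param x a [SceneStack-class], [SurfaceFields-class] or [FluxFields-class]
#' @param name layer name (a band name, `"bt"`, or a slot such as `"ndvi"`,
#'   `"rn"`, `"lambdaInst"`)
#' @return a numeric matrix with masked pixels set to `NA`
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

.maskNA <- function(m, mask) { m[!mask] <- NA_real_; m }

setMethod("getLayer", "SceneStack", function(x, name) {
  m <- if (name == "bt") x@bt
  else if (name %in% names(x@bands)) x@bands[[name]]
  else stop("unknown layer: ", name)
  .maskNA(m, x@mask)
})

setMethod("getLayer", "SurfaceFields", function(x, name) {
  if (!name %in% c("ndvi", "albedo", "emissivity", "lst", "z0m"))
    stop("unknown layer: ", name)
  .maskNA(slot(x, name), x@mask)
})

setMethod("getLayer", "FluxFields", function(x, name) {
  if (!name %in% c("rn", "g", "h", "le", "lambdaInst"))
    stop("unknown layer: ", name)
  .maskNA(slot(x, name), x@mask)
})

#' @rdname getLayer
#' @export
lambdaInst <- function(x) getLayer(x, "lambdaInst")

#' @rdname getLayer
#' @export
landSurfaceTemperature <- function(x) getLayer(x, "lst")
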