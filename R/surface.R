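#' Normalized difference vegetation index
#'
#' `NDVI = (nir - red) / (nir + red)`.  Pixels where the denominator is zero
#' are masked (`NA`) rather than propagated as `NaN`.
#'
#' @param red,nir reflectance matrices (or vectors) on the same grid
#' @return matrix (or vector) of NDVI values in \[-1, 1\]
#' @export
computeNDVI <- function(red, nir) {
  if (!identical(dim(red), dim(nir)) || length(red) != length(nir))
    stop("red and nir must share shape")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Broadband surface albedo from narrowband reflectances
#'
#' Liang-type narrow-to-broadband weighting of the six shortwave bands,
#' clipped to \[0, 1\]:
#' `0.356 b + 0.130 r + 0.373 n + 0.085 s1 + 0.072 s2 - 0.0018`.
#'
#' @param blue,red,nir,swir1,swir2 reflectance matrices
#' @param coef named coefficient vector; override to swap the weighting
#' @return albedo matrix in \[0, 1\]
#' @export
computeAlbedo <- function(blue, red, nir, swir1, swir2,
                          coef = c(blue = 0.356, red = 0.130, nir = 0.373,
                                   swir1 = 0.085, swir2 = 0.072,
                                   intercept = -0.0018)) {
  for (b in list(red, nir, swir1, swir2))
    if (!identical(dim(blue), dim(b))) stop("albedo bands must share shape")
  a <- coef[["blue"]] * blue + coef[["red"]] * red + coef[["nir"]] * nir +
    coef[["swir1"]] * swir1 + coef[["swir2"]] * swir2 + coef[["intercept"]]
  pmin(pmax(a, 0), 1)
}

#' Surface emissivity from NDVI
#'
#' Log-NDVI parameterization: `1.009 + 0.047 ln(NDVI)` for NDVI > 0.157,
#' 0.955 for sparse cover (0 < NDVI <= 0.157), 0.985 for water (NDVI <= 0);
#' clipped to \[0.90, 0.99\].
#'
#' @param ndvi NDVI matrix
#' @return emissivity matrix
#' @export
computeEmissivity <- function(ndvi) {
  eps <- ifelse(ndvi <= 0, 0.985,
                ifelse(ndvi <= 0.157, 0.955,
                       1.009 + 0.047 * log(pmax(ndvi, 1e-12))))
  eps[is.na(ndvi)] <- NA_real_
  pmin(pmax(eps, 0.90), 0.99)
}

#' Brightness temperature from thermal radiance
#'
#' Planck inversion `BT = K2 / ln(K1 / L + 1)` with band calibration
#' constants (defaults for the 10.6-11.2 um band).
#'
#' @param radiance spectral radiance, W m-2 sr-1 um-1
#' @param k1,k2 Planck calibration constants
#' @return brightness temperature, K
#' @export
brightnessTemperature <- function(radiance, k1 = .const$k1_l8, k2 = .const$k2_l8) {
  if (any(radiance <= 0, na.rm = TRUE)) stop("radiance must be positive")
  k2 / log(k1 / radiance + 1)
}

#' Land surface temperature with single-channel emissivity correction
#'
#' `Ts = BT / (1 + (lambda_eff * BT / rho_c) * ln(eps))` with
#' `lambda_eff = 10.9 um` and `rho_c = 1.438e-2 m K`.  Since `ln(eps) < 0`
#' for `eps < 1`, the corrected Ts is never below BT.
#'
#' @param bt brightness temperature, K (or radiance via
#'   [brightnessTemperature()] first)
#' @param emissivity surface emissivity, must be positive
#' @return surface temperature matrix, K
#' @export
computeLST <- function(bt, emissivity) {
  if (any(emissivity <= 0, na.rm = TRUE)) stop("emissivity must be positive")
  bt / (1 + (.const$lam_eff * bt / .const$rho_c) * log(emissivity))
}

#' Momentum roughness length from NDVI and albedo
#'
#' Exponential parameterization `z0m = exp(a * NDVI / albedo + b)` with
#' defaults a = 1.096, b = -5.307, floored at 0.001 m and capped at 0.5 m
#' (the parameterization diverges for dense canopies over dark surfaces;
#' the cap keeps the log wind profile valid between the 0.1 m and 2 m
#' reference heights).  Zero albedo pixels fall back to the floor with a
#' warning.
#'
#' @param ndvi,albedo matrices on the same grid
#' @param a,b parameterization coefficients
#' @param floor minimum roughness, m
#' @param cap maximum roughness, m
#' @return roughness matrix, m
#' @export
computeRoughness <- function(ndvi, albedo, a = 1.096, b = -5.307,
                             floor = 0.001, cap = 0.5) {
  if (!identical(dim(ndvi), dim(albedo))) stop("ndvi and albedo must share shape")
  bad <- !is.na(albedo) & albedo == 0
  if (any(bad)) warning("zero albedo at ", sum(bad), " pixel(s); roughness floored")
  z <- exp(a * ndvi / albedo + b)
  z[bad] <- floor
  pmin(pmax(z, floor), cap)
}

#' Derive all surface parameters from a scene
#'
#' Runs the NDVI, albedo, emissivity, LST and roughness chain on a
#' [SceneStack-class] and returns a [SurfaceFields-class] carrying the
#' scene's mask unchanged.
#'
#' @param scene a [SceneStack-class]
#' @return a [SurfaceFields-class]
#' @export
surfaceFields <- function(scene) {
  stopifnot(is(scene, "SceneStack"))
  msk <- scene@mask
  nd <- computeNDVI(scene@bands$red, scene@bands$nir)
  al <- computeAlbedo(scene@bands$blue, scene@bands$red, scene@bands$nir,
                      scene@bands$swir1, scene@bands$swir2)
  em <- computeEmissivity(nd)
  ts <- computeLST(scene@bt, em)
  z0 <- suppressWarnings(computeRoughness(nd, al))
  msk <- msk & !is.na(nd)   # degenerate-denominator pixels drop out
  new("SurfaceFields", ndvi = nd, albedo = al, emissivity = em,
      lst = ts, z0m = z0, mask = msk)
}

#' Land mask for anchor search
#'
#' Excludes water and snow-like pixels (NDVI <= 0 or albedo > 0.45) from the
#' anchor candidate pool.
#'
#' @param surface a [SurfaceFields-class]
#' @return logical matrix
#' @export
landMask <- function(surface) {
  surface@mask & !is.na(surface@ndvi) & surface@ndvi > 0 &
    !is.na(surface@albedo) & surface@albedo <= 0.45
}
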