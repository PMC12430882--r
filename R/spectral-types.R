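#' Wavelength grid
#'
#' A strictly increasing vector of band-centre wavelengths in nanometres.
#' All spectral containers in the package carry one of these so that
#' operations can refuse to mix cubes sampled on different grids.
#'
#' @param band_centers numeric vector of band centres in nm, strictly
#'   increasing, within 380--1004 nm, length >= 2. Alternatively supply
#'   `n`, `from`, `to` to build a uniform grid.
#' @param n,from,to build `n` uniformly spaced bands spanning `[from, to]` nm
#'   (used when `band_centers` is missing).
#' @return a numeric vector of class `"wavelength_grid"`.
#' @examples
#' wavelength_grid(n = 32, from = 400, to = 700)
#' @export
wavelength_grid <- function(band_centers, n = 32, from = 400, to = 700) {
  if (missing(band_centers)) band_centers <- seq(from, to, length.out = n)
  band_centers <- as.numeric(band_centers)
  if (length(band_centers) < 2) stop("a wavelength grid needs at least 2 bands")
  if (any(diff(band_centers) <= 0)) stop("band centres must be strictly increasing")
  if (any(band_centers < 380) || any(band_centers > 1004))
    stop("band centres must lie within [380, 1004] nm")
  structure(band_centers, class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n",
              length(x), min(x), max(x)))
  invisible(x)
}

grids_match <- function(a, b) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) < 1e-9)
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  stop(sprintf("wavelength grids of %s do not match (%d vs %d bands)",
               what, length(a), length(b)), call. = FALSE)
}

check_nonneg_finite <- function(values, what) {
  if (!all(is.finite(values))) stop(sprintf("%s contains non-finite values", what))
  if (any(values < 0)) stop(sprintf("%s contains negative values", what))
  invisible(TRUE)
}

#' Spectral cube
#'
#' A rank-3 array `H x W x B` with two spatial axes and one spectral axis.
#' The `kind` records the physical quantity: `"reflectance"` (dimensionless
#' ratio S(x,y,lambda)), `"radiance"` (relative scene radiance
#' I(lambda) S(x,y,lambda)), or `"illuminant"` (spatially resolved spectral
#' power of the light source). Values must be nonnegative and finite;
#' reflectance is deliberately not clipped at 1 (glossy pixels can exceed a
#' diffuse reference).
#'
#' @param values numeric array `H x W x B`.
#' @param grid a [wavelength_grid()] with `B` entries.
#' @param kind one of `"reflectance"`, `"radiance"`, `"illuminant"`.
#' @return an object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(values, grid,
                          kind = c("reflectance", "radiance", "illuminant")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("spectral cube values must be a rank-3 array")
  if (dim(values)[3] != length(grid))
    stop(sprintf("cube has %d bands but grid has %d", dim(values)[3], length(grid)))
  check_nonneg_finite(values, sprintf("%s cube", kind))
  structure(list(values = values, grid = grid, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube:%s> %dx%d pixels, %d bands (%.0f-%.0f nm), range [%.4g, %.4g]\n",
              x$kind, d[1], d[2], d[3], min(x$grid), max(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Illuminant spectrum
#'
#' The spectral power distribution I(lambda) of a light source, relative
#' units, sampled on a wavelength grid. Must be nonnegative with at least
#' one strictly positive entry.
#'
#' @param power numeric vector, length matching `grid`.
#' @param grid a [wavelength_grid()].
#' @export
illuminant_spectrum <- function(power, grid) {
  power <- as.numeric(power)
  if (length(power) != length(grid))
    stop(sprintf("power has %d entries but grid has %d bands",
                 length(power), length(grid)))
  check_nonneg_finite(power, "illuminant power")
  if (all(power == 0)) stop("illuminant must have at least one positive band")
  structure(list(power = power, grid = grid), class = "illuminant_spectrum")
}

#' @export
print.illuminant_spectrum <- function(x, ...) {
  cat(sprintf("<illuminant_spectrum> %d bands, peak %.3g at %.0f nm\n",
              length(x$grid), max(x$power), x$grid[which.max(x$power)]))
  invisible(x)
}

#' Broadcast an illuminant spectrum to a spatially constant cube
#'
#' Models the whiteboard measurement: with unit reflectance everywhere, the
#' measured cube is the illuminant itself at every pixel.
#'
#' @param illum an [illuminant_spectrum()].
#' @param h,w spatial size of the cube.
#' @export
broadcast_illuminant <- function(illum, h, w) {
  vals <- aperm(array(illum$power, c(length(illum$grid), h, w)), c(2, 3, 1))
  spectral_cube(vals, illum$grid, kind = "illuminant")
}

#' Camera spectral response
#'
#' Per-channel sensitivity curves C_k(lambda), k in {R, G, B}, as a 3 x B
#' matrix of nonnegative weights on a wavelength grid. Each row must have at
#' least one positive entry.
#'
#' @param sensitivities 3 x B nonnegative matrix, rows ordered R, G, B.
#' @param grid a [wavelength_grid()] with B entries.
#' @export
camera_response <- function(sensitivities, grid) {
  sensitivities <- as.matrix(sensitivities)
  if (nrow(sensitivities) != 3)
    stop("camera response needs exactly 3 rows (R, G, B)")
  if (ncol(sensitivities) != length(grid))
    stop(sprintf("response has %d bands but grid has %d",
                 ncol(sensitivities), length(grid)))
  check_nonneg_finite(sensitivities, "camera response")
  if (any(rowSums(sensitivities) == 0))
    stop("every channel must have at least one positive sensitivity")
  rownames(sensitivities) <- c("R", "G", "B")
  structure(list(sensitivities = sensitivities, grid = grid),
            class = "camera_response")
}

#' RGB image
#'
#' A linear-light `H x W x 3` array, channel order R, G, B, nonnegative and
#' finite. No gamma encoding anywhere in the package.
#'
#' @param values numeric array `H x W x 3`.
#' @export
rgb_image <- function(values) {
  values <- as.array(values)
  if (length(dim(values)) != 3 || dim(values)[3] != 3)
    stop("an RGB image must be an H x W x 3 array")
  check_nonneg_finite(values, "RGB image")
  structure(list(values = values), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rgb_image> %dx%d, range [%.4g, %.4g]\n",
              d[1], d[2], min(x$values), max(x$values)))
  invisible(x)
}
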