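#' Project a spectral cube onto RGB through a camera response
#'
#' Discrete image formation: for a radiance cube the result is
#' `G1[x,y,k] = sum_lambda I(lambda) S(x,y,lambda) C_k(lambda)`, and for a
#' (spatially resolved) illuminant cube it is the whiteboard measurement
#' `G2[x,y,k] = sum_lambda I(lambda) C_k(lambda)`. The projection is linear
#' in the cube.
#'
#' @param cube a [spectral_cube()] of kind `"radiance"` or `"illuminant"`.
#' @param response a [camera_response()] on the same wavelength grid.
#' @return an [rgb_image()].
#' @export
render_rgb <- function(cube, response) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(response, "camera_response"))
  if (!grids_match(cube$grid, response$grid))
    stop_grid_mismatch(cube$grid, response$grid, "cube and camera response")
  d <- dim(cube$values)
  m <- matrix(cube$values, d[1] * d[2], d[3])
  out <- m %*% t(response$sensitivities)
  rgb_image(array(out, c(d[1], d[2], 3)))
}

#' Combine reflectance and illumination into scene radiance
#'
#' Elementwise product `I(lambda) * S(x,y,lambda)`. A spatially constant
#' illuminant spectrum is broadcast across all pixels; a spatially resolved
#' illuminant cube is multiplied per pixel.
#'
#' @param reflectance a reflectance [spectral_cube()].
#' @param illum an [illuminant_spectrum()] or an illuminant [spectral_cube()].
#' @return a radiance [spectral_cube()].
#' @export
make_radiance <- function(reflectance, illum) {
  stopifnot(inherits(reflectance, "spectral_cube"))
  d <- dim(reflectance$values)
  if (inherits(illum, "illuminant_spectrum")) {
    if (!grids_match(reflectance$grid, illum$grid))
      stop_grid_mismatch(reflectance$grid, illum$grid, "reflectance and illuminant")
    vals <- reflectance$values * rep(illum$power, each = d[1] * d[2])
  } else if (inherits(illum, "spectral_cube")) {
    if (!grids_match(reflectance$grid, illum$grid))
      stop_grid_mismatch(reflectance$grid, illum$grid, "reflectance and illuminant")
    if (!all(dim(illum$values)[1:2] == d[1:2]))
      stop("reflectance and illuminant cubes have different spatial sizes")
    vals <- reflectance$values * illum$values
  } else stop("illum must be an illuminant_spectrum or spectral_cube")
  spectral_cube(vals, reflectance$grid, kind = "radiance")
}

#' Wavelength-wise reflectance ratio
#'
#' Ground-truth reflectance generation: the ratio of the sample cube to the
#' illumination cube band by band, `S = sample / max(illum, floor)`. Bands
#' whose illumination does not exceed `floor` are clamped (never divided by
#' zero) and flagged in the `"clamped"` attribute, a logical `H x W x B`
#' mask. Wherever illumination exceeds the floor this exactly inverts
#' [make_radiance()].
#'
#' @param sample a radiance [spectral_cube()] of the object.
#' @param illum an illuminant [spectral_cube()] (or [illuminant_spectrum()],
#'   broadcast) measured off the whiteboard.
#' @param floor small positive divisor floor; applied to the illuminant as
#'   given, so pass illuminants on a unit-max scale for the default to mean
#'   "one millionth of peak power".
#' @return a reflectance [spectral_cube()] with attribute `"clamped"`.
#' @export
compute_reflectance <- function(sample, illum, floor = 1e-6) {
  stopifnot(inherits(sample, "spectral_cube"))
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    stop("floor must be a single positive number")
  d <- dim(sample$values)
  if (inherits(illum, "illuminant_spectrum"))
    illum <- broadcast_illuminant(illum, d[1], d[2])
  if (!grids_match(sample$grid, illum$grid))
    stop_grid_mismatch(sample$grid, illum$grid, "sample and illumination")
  if (!all(dim(illum$values)[1:2] == d[1:2]))
    stop("sample and illumination cubes have different spatial sizes")
  clamped <- illum$values <= floor
  denom <- pmax(illum$values, floor)
  out <- spectral_cube(sample$values / denom, sample$grid, kind = "reflectance")
  attr(out, "clamped") <- clamped
  out
}

#' Normalize to unit maximum
#'
#' Divides every value by the global maximum so the output peaks at exactly
#' 1 while all ratios are preserved; idempotent and invariant to positive
#' rescaling. Errors on an all-zero input.
#'
#' @param x an [rgb_image()], [spectral_cube()], [illuminant_spectrum()], or
#'   a bare numeric array.
#' @return the same type, scaled to maximum 1.
#' @export
normalize_unit_max <- function(x) {
  if (inherits(x, "rgb_image")) {
    m <- max(x$values)
    if (m <= 0) stop("cannot normalize an all-zero image")
    return(rgb_image(x$values / m))
  }
  if (inherits(x, "spectral_cube")) {
    m <- max(x$values)
    if (m <= 0) stop("cannot normalize an all-zero cube")
    return(spectral_cube(x$values / m, x$grid, kind = x$kind))
  }
  if (inherits(x, "illuminant_spectrum")) {
    m <- max(x$power)
    return(illuminant_spectrum(x$power / m, x$grid))
  }
  m <- max(x)
  if (m <= 0) stop("cannot normalize an all-zero array")
  x / m
}

#' Resample a spectrum or cube onto a different wavelength grid
#'
#' Linear interpolation between source band centres; target bands outside
#' the source range take the nearest endpoint value (constant extension).
#' Needed to map finely sampled sources (e.g. 204-band imagers spanning
#' roughly 397-1004 nm) onto the coarser working grid. Errors when the
#' grids do not overlap at all.
#'
#' @param x an [illuminant_spectrum()] or [spectral_cube()].
#' @param target a [wavelength_grid()].
#' @return the same kind of object on `target`.
#' @export
resample_spectrum <- function(x, target) {
  check_overlap <- function(src) {
    if (min(src) > max(target) || max(src) < min(target))
      stop("source and target wavelength grids are disjoint")
  }
  if (inherits(x, "illuminant_spectrum")) {
    check_overlap(x$grid)
    p <- stats::approx(as.numeric(x$grid), x$power, xout = as.numeric(target),
                       rule = 2)$y
    return(illuminant_spectrum(pmax(p, 0), target))
  }
  if (inherits(x, "spectral_cube")) {
    check_overlap(x$grid)
    d <- dim(x$values)
    m <- matrix(x$values, d[1] * d[2], d[3])
    out <- apply(m, 1, function(row)
      stats::approx(as.numeric(x$grid), row, xout = as.numeric(target),
                    rule = 2)$y)
    out <- array(t(out), c(d[1], d[2], length(target)))
    return(spectral_cube(pmax(out, 0), target, kind = x$kind))
  }
  stop("resample_spectrum expects an illuminant_spectrum or spectral_cube")
}
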