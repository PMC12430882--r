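#' Write a spectral cube as an ENVI header + band-sequential binary
#'
#' Writes `path` (raw band-sequential doubles, little-endian, samples
#' fastest within each band) and the matching `.hdr` text header with the
#' wavelength list (nanometres) always populated. Doubles round-trip
#' bit-exactly.
#'
#' @param cube a [spectral_cube()].
#' @param path data-file path; the header is written next to it with the
#'   extension replaced by `.hdr`.
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  hdr_path <- paste0(sub("\\.[^./]*$", "", path), ".hdr")
  hdr <- c(
    "ENVI",
    sprintf("description = {%s cube written by specfusion}", cube$kind),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.12g", as.numeric(cube$grid)), collapse = ", "))
  )
  writeLines(hdr, hdr_path)
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube$values[, , b])), con, size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", key, "\\s*=\\s*\\S+"), txt,
                                 perl = TRUE))
    if (!length(m)) stop("malformed ENVI header: missing '", key, "'")
    as.numeric(sub(".*=\\s*", "", m))
  }
  m <- regmatches(txt, regexpr("(?si)wavelength\\s*=\\s*\\{[^}]*\\}", txt,
                               perl = TRUE))
  if (!length(m)) stop("malformed ENVI header: missing wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       byte_order = get_num("byte order"), wavelength = wl)
}

#' Read an ENVI spectral cube
#'
#' Counterpart of [write_cube_envi()]. Errors on a missing or malformed
#' header and when the header's band count, wavelength list and binary
#' file size disagree.
#'
#' @param path data-file path (header expected at the `.hdr` sibling).
#' @param kind cube kind to tag the result with.
#' @export
read_cube_envi <- function(path, kind = "reflectance") {
  hdr_path <- paste0(sub("\\.[^./]*$", "", path), ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  if (!file.exists(path)) stop("missing ENVI data file: ", path)
  h <- parse_envi_header(hdr_path)
  if (length(h$wavelength) != h$bands)
    stop(sprintf("header lists %d wavelengths but %d bands",
                 length(h$wavelength), h$bands))
  if (h$data_type != 5) stop("only data type 5 (float64) is supported")
  n_expect <- h$samples * h$lines * h$bands
  n_bytes <- file.info(path)$size
  if (n_bytes != 8 * n_expect)
    stop(sprintf("data file holds %g values but header promises %g",
                 n_bytes / 8, n_expect))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
  vals <- array(0, c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands))
    vals[, , b] <- matrix(raw_vals[(b - 1) * per_band + seq_len(per_band)],
                          h$lines, h$samples, byrow = TRUE)
  spectral_cube(vals, wavelength_grid(h$wavelength), kind = kind)
}

#' Single-file compressed cube container with JSON sidecar
#'
#' Gzip-compressed little-endian doubles in `path`, with a `path.json`
#' sidecar recording dimensions, the wavelength grid (nm), the cube kind
#' and a provenance note. Lossless for doubles.
#'
#' @param cube a [spectral_cube()].
#' @param path output path (conventional extension `.sfz`).
#' @export
write_cube_container <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  con <- gzfile(path, "wb")
  writeBin(as.vector(cube$values), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dims = dim(cube$values), wavelength_nm = as.numeric(cube$grid),
         kind = cube$kind, layout = "column-major H x W x B, 0-based pixel indices",
         writer = "specfusion"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube_container
#' @export
read_cube_container <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing container sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- gzfile(path, "rb")
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(vals) != n)
    stop(sprintf("container holds %d values but sidecar promises %d",
                 length(vals), n))
  spectral_cube(array(vals, meta$dims), wavelength_grid(meta$wavelength_nm),
                kind = meta$kind)
}

#' Write a linear RGB image as 16-bit TIFF
#'
#' Values are scaled by `scale` (default: the image maximum, i.e. the
#' unit-max convention) onto the 16-bit range; the scale is recorded in a
#' JSON sidecar so loading restores absolute values to 16-bit precision.
#'
#' @param image an [rgb_image()].
#' @param path output path (`.tif`/`.tiff`).
#' @param scale value mapped to the 16-bit maximum.
#' @export
write_rgb <- function(image, path, scale = max(image$values)) {
  stopifnot(inherits(image, "rgb_image"))
  if (scale <= 0) stop("cannot write an all-zero image with an implicit scale")
  tiff::writeTIFF(pmin(image$values / scale, 1), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(scale = scale, colorspace = "linear RGB"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear RGB image (16-bit TIFF or PNG)
#'
#' Values are mapped back through the sidecar scale when present,
#' otherwise returned on the \[0, 1\] scale of the file.
#'
#' @param path image path.
#' @export
read_rgb <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  vals <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    png::readPNG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(vals)) != 3 || dim(vals)[3] < 3)
    stop("expected a 3-channel image")
  vals <- vals[, , 1:3, drop = FALSE]
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    vals <- vals * meta$scale
  }
  rgb_image(vals)
}

#' Save / load a fitted model checkpoint
#'
#' Serializes the fitted object (parameters with embedded configs, control
#' and history) to a single file.
#'
#' @param fit a fitted `"srnet"`.
#' @param path checkpoint path.
#' @export
save_srnet <- function(fit, path) {
  stopifnot(inherits(fit, "srnet"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_srnet
#' @export
load_srnet <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "srnet"))
  fit
}
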