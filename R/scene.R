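#' Scene generator parameters
#'
#' Controls for the synthetic spectral-scene simulator that emulates the
#' paired acquisition geometry: smooth tooth/ceramic-like reflectance blobs
#' on a dark background, imaged under a mixed-LED illuminant with a generic
#' RGB camera, plus additive sensor noise on the RGB images only.
#'
#' @param image_size spatial size H = W in pixels.
#' @param bands number of spectral bands on the working grid.
#' @param n_blobs number of elliptical specimen blobs per scene.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   rendered RGB images (on the unit-max-normalized scale of the light
#'   image); ground-truth cubes stay noise-free.
#' @param augment_ops character vector of geometric augmentations applied
#'   while building a dataset, subset of `c("rotate", "shift", "crop")`.
#' @param grid_from,grid_to wavelength range of the working grid in nm.
#' @return a list of class `"scene_params"` including the working
#'   [wavelength_grid()].
#' @export
scene_params <- function(image_size = 64, bands = 32, n_blobs = 3,
                         noise_sigma = 0.01, augment_ops = character(0),
                         grid_from = 400, grid_to = 700) {
  stopifnot(image_size >= 4, bands >= 2, n_blobs >= 1, noise_sigma >= 0)
  bad <- setdiff(augment_ops, c("rotate", "shift", "crop"))
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  structure(list(image_size = as.integer(image_size), bands = as.integer(bands),
                 n_blobs = as.integer(n_blobs), noise_sigma = noise_sigma,
                 augment_ops = augment_ops,
                 grid = wavelength_grid(n = bands, from = grid_from, to = grid_to)),
            class = "scene_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-item sub-seed, kept below 2^31
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
                as.numeric(salt) * 7 + 12345) %% 2147483647)
}

#' Default camera spectral response
#'
#' Three Gaussian sensitivities centred at 460 (B), 540 (G) and 610 (R) nm
#' with 35 nm standard deviation -- a generic linear RGB camera. Tabulated
#' curves can be substituted by constructing a [camera_response()] directly.
#'
#' @param grid a [wavelength_grid()].
#' @export
default_camera_response <- function(grid) {
  lam <- as.numeric(grid)
  g <- function(mu) exp(-0.5 * ((lam - mu) / 35)^2)
  camera_response(rbind(g(610), g(540), g(460)), grid)
}

# smooth spectral basis on normalized wavelength t in [0, 1]:
# flat term, upward sigmoid toward long wavelengths (the tooth/ceramic
# signature), and two broad Gaussian lobes
spectral_basis <- function(grid) {
  t <- (as.numeric(grid) - min(grid)) / diff(range(grid))
  cbind(flat = rep(1, length(t)),
        rise = 1 / (1 + exp(-6 * (t - 0.45))),
        lobe1 = exp(-0.5 * ((t - 0.35) / 0.18)^2),
        lobe2 = exp(-0.5 * ((t - 0.75) / 0.20)^2))
}

#' Sample a synthetic reflectance field
#'
#' Draws a piecewise-smooth reflectance scene: elliptical specimen blobs
#' with soft edges on a dark, spectrally flat background. Each blob's
#' spectrum is a nonnegative combination of four smooth basis functions
#' dominated by an upward slope toward long wavelengths (tooth-like);
#' values stay within \[0, 1.2\]. Deterministic given `seed`.
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return a reflectance [spectral_cube()] on the working grid.
#' @export
sample_reflectance_field <- function(params, seed) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$image_size
  grid <- params$grid
  B <- length(grid)
  basis <- spectral_basis(grid)
  with_seed(seed, {
    # per-scene background level and tint: constant and low within a scene,
    # but never the same across scenes (a fixed background would act as an
    # embedded calibration target and leak the illuminant)
    bg_level <- stats::runif(1, 0.03, 0.10)
    bg_tint <- stats::runif(1, 0.01, 0.04)
    bg <- bg_level * basis[, "flat"] + bg_tint * basis[, "rise"]
    vals <- array(rep(bg, each = n * n), c(n, n, B))
    xg <- matrix(seq_len(n), n, n)
    yg <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (b in seq_len(params$n_blobs)) {
      cx <- stats::runif(1, 0.25 * n, 0.75 * n)
      cy <- stats::runif(1, 0.25 * n, 0.75 * n)
      ax <- stats::runif(1, 0.14 * n, 0.30 * n)
      ay <- stats::runif(1, 0.14 * n, 0.30 * n)
      th <- stats::runif(1, 0, pi)
      base <- stats::runif(1, 0.10, 0.25)
      rise <- stats::runif(1, 0.45, 0.85)
      a3 <- stats::runif(1, 0, 0.12)
      a4 <- stats::runif(1, 0, 0.12)
      spec <- base * basis[, "flat"] + rise * basis[, "rise"] +
        a3 * basis[, "lobe1"] + a4 * basis[, "lobe2"]
      if (max(spec) > 1.15) spec <- spec * (1.15 / max(spec))
      u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      r <- sqrt((u / ax)^2 + (v / ay)^2)
      m <- pmin(pmax((1.15 - r) / 0.3, 0), 1)  # soft elliptical edge
      for (k in seq_len(B))
        vals[, , k] <- vals[, , k] * (1 - m) + m * spec[k]
    }
    spectral_cube(vals, grid, kind = "reflectance")
  })
}

#' Render a paired training sample
#'
#' Composes the forward model for one scene: broadcasts the condition's SPD
#' into a spatially constant illuminant cube, forms the radiance cube, and
#' projects both through the camera response into the two RGB images.
#' Seeded Gaussian sensor noise (`noise_sigma`) is added to the RGB images
#' only; all three ground-truth cubes remain noise-free. The stored
#' reflectance ground truth is the wavelength-wise ratio of the two cubes
#' ([compute_reflectance()]), which here equals the generating reflectance
#' field exactly because every built-in illuminant is strictly positive.
#'
#' @param reflectance a reflectance [spectral_cube()].
#' @param condition a `lighting_condition` from [builtin_conditions()].
#' @param response a [camera_response()] on the same grid.
#' @param noise_sigma RGB noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @param bank LED bank, default [builtin_led_bank()].
#' @return a `paired_sample`: list with `sample_rgb`, `light_rgb`,
#'   `sample_hsi`, `light_hsi`, `reflectance_gt`, `condition`, `seed`.
#' @export
render_pair <- function(reflectance, condition, response, noise_sigma = 0,
                        seed = 1, bank = builtin_led_bank()) {
  stopifnot(inherits(reflectance, "spectral_cube"))
  d <- dim(reflectance$values)
  ispec <- condition_spectrum(condition, reflectance$grid, bank)
  light_hsi <- broadcast_illuminant(ispec, d[1], d[2])
  sample_hsi <- make_radiance(reflectance, ispec)
  sample_rgb <- render_rgb(sample_hsi, response)
  light_rgb <- render_rgb(light_hsi, response)
  if (noise_sigma > 0) {
    scale <- max(light_rgb$values)
    with_seed(seed, {
      sample_rgb <- rgb_image(pmax(
        sample_rgb$values + stats::rnorm(length(sample_rgb$values),
                                         sd = noise_sigma * scale), 0))
      light_rgb <- rgb_image(pmax(
        light_rgb$values + stats::rnorm(length(light_rgb$values),
                                        sd = noise_sigma * scale), 0))
    })
  }
  structure(list(sample_rgb = sample_rgb, light_rgb = light_rgb,
                 sample_hsi = sample_hsi, light_hsi = light_hsi,
                 reflectance_gt = compute_reflectance(sample_hsi, light_hsi),
                 condition = condition, seed = as.integer(seed)),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  d <- dim(x$sample_hsi$values)
  cat(sprintf("<paired_sample> %dx%d px, %d bands, condition '%s'\n",
              d[1], d[2], d[3], x$condition$name))
  invisible(x)
}

#' Check the structural invariants of a paired sample
#'
#' Verifies equal spatial sizes across the five components, the ratio
#' identity between the reflectance ground truth and the two cubes, and
#' (when the rendering noise is zero) agreement of the RGB images with the
#' camera projection of the cubes.
#'
#' @param pair a `paired_sample`.
#' @param response the generating [camera_response()], or `NULL` to skip
#'   the RGB checks.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_paired_sample <- function(pair, response = NULL, tol = 1e-8) {
  d <- dim(pair$sample_hsi$values)
  stopifnot(all(dim(pair$light_hsi$values) == d),
            all(dim(pair$reflectance_gt$values) == d),
            all(dim(pair$sample_rgb$values)[1:2] == d[1:2]),
            all(dim(pair$light_rgb$values)[1:2] == d[1:2]))
  gt <- compute_reflectance(pair$sample_hsi, pair$light_hsi)
  if (max(abs(gt$values - pair$reflectance_gt$values)) > tol)
    stop("reflectance ground truth does not match the cube ratio")
  if (!is.null(response)) {
    if (max(abs(render_rgb(pair$sample_hsi, response)$values -
                  pair$sample_rgb$values)) > tol)
      stop("sample RGB does not match the rendered cube")
  }
  invisible(TRUE)
}

rot90_spatial <- function(a, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(a)
  d <- dim(a)
  out <- a
  for (i in seq_len(k)) {
    d <- dim(out)
    new <- array(0, c(d[2], d[1], d[3]))
    for (c in seq_len(d[3])) new[, , c] <- t(out[, , c])[d[2]:1, ]
    out <- new
  }
  out
}

shift_spatial <- function(a, dx, dy) {
  # dx shifts columns rightward, dy shifts rows downward; zero padding
  d <- dim(a)
  out <- array(0, d)
  rs <- intersect(seq_len(d[1]), seq_len(d[1]) + dy)
  cs <- intersect(seq_len(d[2]), seq_len(d[2]) + dx)
  if (length(rs) && length(cs))
    out[rs, cs, ] <- a[rs - dy, cs - dx, , drop = FALSE]
  out
}

crop_spatial <- function(a, r0, r1, c0, c1) {
  out <- array(0, dim(a))
  out[r0:r1, c0:c1, ] <- a[r0:r1, c0:c1, , drop = FALSE]
  out
}

#' Geometric augmentation of a paired sample
#'
#' Applies one identical geometric transform to the spatial modalities of a
#' pair -- the sample RGB, the sample cube and the reflectance ground truth
#' -- with zero padding and preserved output size. The light image and cube
#' are never touched: illumination is scene-global, so a geometric move of
#' the specimen does not move the illuminant. Rotations are quantized to
#' multiples of 90 degrees so spectra are never interpolated.
#'
#' @param pair a `paired_sample`.
#' @param ops subset of `c("rotate", "shift", "crop")`; an empty vector
#'   returns the input unchanged.
#' @param seed integer seed used to draw the transform parameters.
#' @param rotate,shift,crop optional explicit parameters overriding the
#'   seeded draws: `rotate` in degrees (multiple of 90), `shift = c(dx, dy)`
#'   in pixels, `crop = c(r0, r1, c0, c1)` the kept row/column range.
#' @return a transformed `paired_sample`.
#' @export
augment_pair <- function(pair, ops, seed = 1, rotate = NULL, shift = NULL,
                         crop = NULL) {
  bad <- setdiff(ops, c("rotate", "shift", "crop"))
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  if (!length(ops)) return(pair)
  d <- dim(pair$sample_hsi$values)
  with_seed(seed, {
    if ("rotate" %in% ops && is.null(rotate))
      rotate <- 90 * sample.int(4, 1)
    if ("shift" %in% ops && is.null(shift))
      shift <- c(sample(seq(-(d[2] %/% 4), d[2] %/% 4), 1),
                 sample(seq(-(d[1] %/% 4), d[1] %/% 4), 1))
    if ("crop" %in% ops && is.null(crop)) {
      hh <- sample(seq(d[1] %/% 2, d[1]), 1)
      ww <- sample(seq(d[2] %/% 2, d[2]), 1)
      r0 <- sample(seq_len(d[1] - hh + 1), 1)
      c0 <- sample(seq_len(d[2] - ww + 1), 1)
      crop <- c(r0, r0 + hh - 1, c0, c0 + ww - 1)
    }
  })
  tf <- function(a) {
    if ("rotate" %in% ops) {
      if (rotate %% 90 != 0) stop("rotation must be a multiple of 90 degrees")
      a <- rot90_spatial(a, rotate %/% 90)
    }
    if ("shift" %in% ops) a <- shift_spatial(a, shift[1], shift[2])
    if ("crop" %in% ops) a <- crop_spatial(a, crop[1], crop[2], crop[3], crop[4])
    a
  }
  out <- pair
  out$sample_rgb <- rgb_image(tf(pair$sample_rgb$values))
  out$sample_hsi <- spectral_cube(tf(pair$sample_hsi$values),
                                  pair$sample_hsi$grid, kind = "radiance")
  gt <- spectral_cube(tf(pair$reflectance_gt$values),
                      pair$reflectance_gt$grid, kind = "reflectance")
  out$reflectance_gt <- gt
  out
}

dataset_split <- function(n) {
  if (n > 3300) {
    n_train <- 3000L; n_val <- 300L
  } else {
    n_train <- max(1L, round(n * 30 / 34))
    n_val <- max(1L, round(n * 3 / 34))
    while (n_train + n_val >= n) n_train <- n_train - 1L
  }
  rep(c("train", "val", "test"),
      c(n_train, n_val, n - n_train - n_val))
}

#' Build a synthetic paired dataset
#'
#' Generates `n_pairs` paired samples round-robin over the lighting
#' conditions, each from its own derived seed, and records a manifest with
#' the per-pair seed, condition and train/val/test split (3000/300/rest for
#' large datasets, the same 30:3:1 proportions scaled down otherwise).
#' Bit-reproducible from `(seed, params, conditions)`.
#'
#' @param n_pairs number of pairs to generate.
#' @param params a [scene_params()].
#' @param conditions list of lighting conditions, default
#'   [builtin_conditions()].
#' @param seed master integer seed; per-pair seeds are derived from it.
#' @param bank LED bank.
#' @param response camera response; default [default_camera_response()] on
#'   the working grid.
#' @return a list of class `"paired_dataset"` with `pairs`, `manifest`
#'   (data.frame: pair, seed, condition, split), `params`, `response`.
#' @export
build_dataset <- function(n_pairs, params = scene_params(),
                          conditions = builtin_conditions(), seed = 1,
                          bank = builtin_led_bank(),
                          response = default_camera_response(params$grid)) {
  stopifnot(n_pairs > 0)
  nc <- length(conditions)
  pairs <- vector("list", n_pairs)
  seeds <- integer(n_pairs)
  cnames <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    cond <- conditions[[(i - 1L) %% nc + 1L]]
    s_field <- derive_seed(seed, i, 1L)
    s_noise <- derive_seed(seed, i, 2L)
    refl <- sample_reflectance_field(params, s_field)
    pair <- render_pair(refl, cond, response, noise_sigma = params$noise_sigma,
                        seed = s_noise, bank = bank)
    if (length(params$augment_ops))
      pair <- augment_pair(pair, params$augment_ops,
                           seed = derive_seed(seed, i, 3L))
    pairs[[i]] <- pair
    seeds[i] <- s_field
    cnames[i] <- cond$name
  }
  manifest <- data.frame(pair = seq_len(n_pairs), seed = seeds,
                         condition = cnames, split = dataset_split(n_pairs),
                         stringsAsFactors = FALSE)
  structure(list(pairs = pairs, manifest = manifest, params = params,
                 response = response, seed = as.integer(seed)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d pairs (%s), %dx%d px, %d bands\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$split)),
                            as.integer(table(x$manifest$split))), collapse = ", "),
              x$params$image_size, x$params$image_size, x$params$bands))
  invisible(x)
}

#' Write a dataset manifest as JSON lines
#'
#' One record per pair with its index, seed, condition and split.
#'
#' @param dataset a `paired_dataset`.
#' @param path output file.
#' @export
write_manifest <- function(dataset, path) {
  rows <- lapply(seq_len(nrow(dataset$manifest)), function(i)
    jsonlite::toJSON(as.list(dataset$manifest[i, ]), auto_unbox = TRUE))
  writeLines(unlist(rows), path)
  invisible(path)
}
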