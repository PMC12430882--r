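test_that("wavelength grids and containers enforce their invariants", {
  expect_error(wavelength_grid(c(500, 400)), "increasing")
  expect_error(wavelength_grid(c(100, 500)), "380")
  expect_error(wavelength_grid(500), "at least 2")
  g <- tiny_grid(4)
  expect_error(spectral_cube(array(-1, c(2, 2, 4)), g), "negative")
  expect_error(spectral_cube(array(1, c(2, 2, 3)), g), "bands")
  expect_error(illuminant_spectrum(rep(0, 4), g), "positive")
  expect_error(camera_response(matrix(0, 3, 4), g), "positive")
  expect_error(rgb_image(array(1, c(2, 2, 4))), "H x W x 3")
})

test_that("render_rgb matches the discrete image-formation sum", {
  g <- tiny_grid(2)
  resp <- camera_response(rbind(c(1, 0), c(0, 1), c(1, 1)), g)
  # indicator response picks out one band
  cube <- spectral_cube(array(1, c(2, 2, 2)), g, kind = "radiance")
  out <- render_rgb(cube, resp)
  expect_equal(out$values[, , 1], matrix(1, 2, 2))
  # all-zero cube renders to zero
  zero <- spectral_cube(array(0, c(3, 3, 2)), g, kind = "radiance")
  expect_true(all(render_rgb(zero, resp)$values == 0))
  # random cube against the nested-loop oracle
  cube4 <- random_cube(11, kind = "radiance")
  resp4 <- random_response(12)
  expect_equal(render_rgb(cube4, resp4)$values,
               bruteforce_render(cube4$values, resp4$sensitivities),
               tolerance = 1e-12)
  # grid mismatch is refused with both band counts named
  resp8 <- random_response(13, B = 8)
  expect_error(render_rgb(cube4, resp8), "4.*8|8.*4")
})

test_that("render_rgb is linear in the cube", {
  resp <- random_response(20)
  for (s in 1:10) {
    a <- random_cube(s, kind = "radiance")
    b <- random_cube(s + 100, kind = "radiance")
    lhs <- render_rgb(spectral_cube(2 * a$values + 3 * b$values, a$grid,
                                    kind = "radiance"), resp)$values
    rhs <- 2 * render_rgb(a, resp)$values + 3 * render_rgb(b, resp)$values
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("make_radiance broadcasts and multiplies elementwise", {
  g <- tiny_grid(4)
  S <- random_cube(3)
  illum <- illuminant_spectrum(c(0.2, 1, 0.5, 0.1), g)
  rad <- make_radiance(S, illum)
  # per-element oracle
  for (b in 1:4)
    expect_equal(rad$values[, , b], S$values[, , b] * illum$power[b])
  # whiteboard case: unit reflectance returns the broadcast illuminant
  ones <- spectral_cube(array(1, c(4, 5, 4)), g, kind = "reflectance")
  expect_equal(make_radiance(ones, illum)$values,
               broadcast_illuminant(illum, 4, 5)$values)
  # zero illuminant annihilates
  expect_error(illuminant_spectrum(rep(0, 4), g))
  icube <- spectral_cube(array(0, c(4, 5, 4)), g, kind = "illuminant")
  expect_true(all(make_radiance(S, icube)$values == 0))
})

test_that("compute_reflectance inverts the forward model above the floor", {
  g <- tiny_grid(4)
  for (s in 1:10) {
    set.seed(s)
    S <- random_cube(s)
    illum <- illuminant_spectrum(runif(4, 0.1, 1), g)
    rad <- make_radiance(S, illum)
    rec <- compute_reflectance(rad, broadcast_illuminant(illum, 4, 5))
    expect_lt(max(abs(rec$values - S$values)) / max(S$values, 1e-12), 1e-12)
  }
  # whiteboard self-ratio is exactly one
  illum <- illuminant_spectrum(c(0.3, 1, 0.6, 0.2), g)
  icube <- broadcast_illuminant(illum, 3, 3)
  self <- compute_reflectance(
    spectral_cube(icube$values, g, kind = "radiance"), icube)
  expect_equal(self$values, array(1, c(3, 3, 4)))
  # all-zero sample gives all-zero reflectance
  zero <- spectral_cube(array(0, c(3, 3, 4)), g, kind = "radiance")
  expect_true(all(compute_reflectance(zero, icube)$values == 0))
})

test_that("compute_reflectance clamps dark bands and flags them", {
  g <- tiny_grid(3)
  illum_vals <- array(rep(c(1, 1e-9, 0.5), each = 4), c(2, 2, 3))
  icube <- spectral_cube(illum_vals, g, kind = "illuminant")
  rad <- spectral_cube(array(0.5, c(2, 2, 3)), g, kind = "radiance")
  out <- compute_reflectance(rad, icube, floor = 1e-6)
  mask <- attr(out, "clamped")
  expect_true(all(mask[, , 2]))
  expect_false(any(mask[, , c(1, 3)]))
  expect_true(all(is.finite(out$values)))
  expect_equal(out$values[, , 2], matrix(0.5 / 1e-6, 2, 2))
  expect_error(compute_reflectance(rad, icube, floor = 0), "positive")
})

test_that("normalize_unit_max scales to 1, idempotently and scale-invariantly", {
  img <- rgb_image(array(c(1, 2, 4), c(1, 1, 3)))
  out <- normalize_unit_max(img)
  expect_equal(max(out$values), 1)
  expect_equal(out$values[1, 1, ], c(0.25, 0.5, 1))
  expect_equal(normalize_unit_max(out)$values, out$values)
  for (s in 1:5) {
    cube <- random_cube(s, lo = 0.01)
    n1 <- normalize_unit_max(cube)$values
    scaled <- spectral_cube(cube$values * 7.3, cube$grid, kind = cube$kind)
    expect_equal(normalize_unit_max(scaled)$values, n1, tolerance = 1e-12)
  }
  const <- spectral_cube(array(0.4, c(2, 2, 4)), tiny_grid(4))
  expect_equal(normalize_unit_max(const)$values, array(1, c(2, 2, 4)))
  expect_error(normalize_unit_max(array(0, c(2, 2))), "zero")
})

test_that("resample_spectrum interpolates onto the working grid", {
  src <- wavelength_grid(seq(400, 1000, length.out = 204))
  set.seed(5)
  p <- abs(sin(seq(0, 6, length.out = 204))) + 0.1
  spec <- illuminant_spectrum(p, src)
  tgt <- wavelength_grid(n = 32, from = 400, to = 700)
  out <- resample_spectrum(spec, tgt)
  expect_length(out$power, 32)
  expect_equal(out$power,
               stats::approx(as.numeric(src), p, xout = as.numeric(tgt),
                             rule = 2)$y)
  # cubes resample band-wise and stay nonnegative
  cube <- random_cube(6, B = 8, kind = "radiance")
  g8 <- tiny_grid(8)
  out_c <- resample_spectrum(spectral_cube(cube$values, g8, "radiance"),
                             tiny_grid(4))
  expect_equal(dim(out_c$values), c(4, 5, 4))
  expect_true(all(out_c$values >= 0))
  # disjoint grids are refused
  lo <- wavelength_grid(c(400, 450))
  hi <- wavelength_grid(c(900, 1000))
  expect_error(resample_spectrum(illuminant_spectrum(c(1, 1), lo), hi),
               "disjoint")
})
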