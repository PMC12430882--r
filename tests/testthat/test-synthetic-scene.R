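grid16 <- wavelength_grid(n = 16, from = 400, to = 700)

test_that("the LED bank has 16 members with the documented class structure", {
  bank <- builtin_led_bank()
  expect_length(bank, 16)
  kinds <- vapply(bank, function(l) l$kind, character(1))
  expect_equal(sum(kinds == "warm_white"), 3)
  expect_equal(sum(kinds == "neutral_white"), 3)
  expect_equal(sum(kinds == "cool_white"), 2)
  expect_equal(sum(kinds == "monochromatic"), 8)
  for (led in bank) {
    p <- led_spectrum(led, grid16)$power
    expect_true(all(p >= 0))
    expect_true(any(p > 0))
  }
})

test_that("warm whites carry more long-wavelength energy than cool whites", {
  bank <- builtin_led_bank()
  lam <- as.numeric(grid16)
  ratio <- function(led) {
    p <- led_spectrum(led, grid16)$power
    sum(p[lam > 550]) / sum(p[lam < 550])
  }
  kinds <- vapply(bank, function(l) l$kind, character(1))
  warm <- vapply(bank[kinds == "warm_white"], ratio, numeric(1))
  cool <- vapply(bank[kinds == "cool_white"], ratio, numeric(1))
  expect_gt(min(warm), max(cool))
})

test_that("the 16 lighting conditions match the documented combination plan", {
  conds <- builtin_conditions()
  expect_length(conds, 16)
  sizes <- vapply(conds, function(cn) length(cn$members), integer(1))
  expect_equal(sum(sizes == 1), 8)   # single-white conditions
  expect_equal(sum(sizes == 2), 5)   # binary white mixes
  expect_equal(sum(sizes == 3), 2)   # tricolor mixes
  eleven <- conds[[which(sizes == 11)]]
  expect_equal(eleven$members, c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L, 12L, 14L, 15L))
  for (cn in conds) {
    p <- condition_spectrum(cn, grid16)$power
    expect_gt(min(p), 0)          # strictly positive everywhere
    expect_equal(max(p), 1)       # relative SPD convention
  }
})

test_that("reflectance fields are deterministic, bounded and tooth-like", {
  ps <- scene_params(image_size = 16, bands = 16)
  a <- sample_reflectance_field(ps, 42)
  b <- sample_reflectance_field(ps, 42)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         sample_reflectance_field(ps, 43)$values))
  expect_true(all(a$values >= 0 & a$values <= 1.2))
  # background corner pixel: low, near-flat spectrum
  bgspec <- a$values[1, 1, ]
  expect_lt(max(bgspec), 0.15)
  expect_lt(diff(range(bgspec)), 0.05)
})

test_that("spectra have bounded curvature across bands", {
  # threshold frozen from the seeded-batch maximum of |second difference|
  ps <- scene_params(image_size = 16, bands = 16)
  for (s in 1:10) {
    S <- sample_reflectance_field(ps, s)$values
    d2 <- S[, , 3:16] - 2 * S[, , 2:15] + S[, , 1:14]
    expect_lt(max(abs(d2)), 0.025)
  }
})

test_that("render_pair satisfies the five-component invariants", {
  ps <- scene_params(image_size = 16, bands = 16)
  resp <- default_camera_response(ps$grid)
  refl <- sample_reflectance_field(ps, 1)
  cond <- builtin_conditions()[[9]]
  pair <- render_pair(refl, cond, resp, noise_sigma = 0, seed = 1)
  expect_true(validate_paired_sample(pair, resp))
  # pedestal-backed illuminants keep the ratio exact everywhere
  expect_equal(pair$reflectance_gt$values, refl$values, tolerance = 1e-12)
  # whiteboard scene: unit reflectance makes the two RGB images identical
  ones <- spectral_cube(array(1, c(16, 16, 16)), ps$grid, "reflectance")
  pw <- render_pair(ones, cond, resp, noise_sigma = 0, seed = 1)
  expect_equal(pw$sample_rgb$values, pw$light_rgb$values, tolerance = 1e-12)
})

test_that("RGB noise has the half-normal mean absolute perturbation", {
  ps <- scene_params(image_size = 32, bands = 16)
  resp <- default_camera_response(ps$grid)
  refl <- sample_reflectance_field(ps, 3)
  cond <- builtin_conditions()[[4]]
  clean <- render_pair(refl, cond, resp, noise_sigma = 0, seed = 7)
  sigma <- 0.05
  scale <- max(clean$light_rgb$values)
  # restrict to pixels far from zero so the nonnegativity clamp cannot bias
  # the half-normal statistic
  bright <- clean$sample_rgb$values > 4 * sigma * scale
  devs <- unlist(lapply(1:8, function(s) {
    noisy <- render_pair(refl, cond, resp, noise_sigma = sigma, seed = s)
    (noisy$sample_rgb$values - clean$sample_rgb$values)[bright]
  }))
  expect_equal(mean(abs(devs)), sigma * scale * sqrt(2 / pi), tolerance = 0.03)
})

test_that("augmentation transforms sample modalities jointly, zero-padded", {
  ps <- scene_params(image_size = 16, bands = 8)
  resp <- default_camera_response(ps$grid)
  pair <- render_pair(sample_reflectance_field(ps, 5),
                      builtin_conditions()[[1]], resp, 0, 1)
  # empty op list is the identity
  expect_identical(augment_pair(pair, character(0)), pair)
  # 180-degree rotation is an involution
  r1 <- augment_pair(pair, "rotate", rotate = 180)
  r2 <- augment_pair(r1, "rotate", rotate = 180)
  expect_equal(r2$sample_hsi$values, pair$sample_hsi$values)
  expect_equal(r2$reflectance_gt$values, pair$reflectance_gt$values)
  # shift by (5, 0): column c of the output equals column c - 5 of the input
  sh <- augment_pair(pair, "shift", shift = c(5, 0))
  for (cc in 6:16)
    expect_equal(sh$sample_hsi$values[, cc, ],
                 pair$sample_hsi$values[, cc - 5, ])
  expect_true(all(sh$sample_hsi$values[, 1:5, ] == 0))
  # the light cube and image are never touched
  expect_identical(sh$light_hsi$values, pair$light_hsi$values)
  expect_identical(sh$light_rgb$values, pair$light_rgb$values)
  # size preserved, unknown op refused, seeded draw deterministic
  expect_equal(dim(sh$sample_rgb$values), dim(pair$sample_rgb$values))
  expect_error(augment_pair(pair, "warp"), "unknown")
  a1 <- augment_pair(pair, c("rotate", "shift", "crop"), seed = 9)
  a2 <- augment_pair(pair, c("rotate", "shift", "crop"), seed = 9)
  expect_identical(a1$sample_hsi$values, a2$sample_hsi$values)
})

test_that("datasets are round-robin, reproducible and correctly split", {
  ps <- scene_params(image_size = 8, bands = 4)
  ds <- build_dataset(16, params = ps, seed = 3)
  expect_length(unique(ds$manifest$condition), 16)  # one pair per condition
  expect_true(all(table(ds$manifest$condition) == 1))
  ds2 <- build_dataset(16, params = ps, seed = 3)
  for (i in c(1, 7, 16))
    expect_identical(ds$pairs[[i]]$sample_hsi$values,
                     ds2$pairs[[i]]$sample_hsi$values)
  # split rule: beyond 3300 pairs the reference 3000/300/test split applies
  expect_equal(as.vector(table(sf$dataset_split(3400))[c("train", "val", "test")]),
               c(3000, 300, 100))
  sp <- table(sf$dataset_split(256))
  expect_equal(sum(sp), 256)
  expect_equal(as.vector(sp["train"]), 226)
  # every emitted pair satisfies its invariants
  for (i in c(2, 9)) expect_true(validate_paired_sample(ds$pairs[[i]]))
})

test_that("reflectance ground truth is illumination-independent", {
  ps <- scene_params(image_size = 8, bands = 8)
  resp <- default_camera_response(ps$grid)
  refl <- sample_reflectance_field(ps, 11)
  conds <- builtin_conditions()
  g1 <- render_pair(refl, conds[[2]], resp, 0, 1)$reflectance_gt$values
  g2 <- render_pair(refl, conds[[16]], resp, 0, 1)$reflectance_gt$values
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("the manifest serializes as one JSON record per pair", {
  ps <- scene_params(image_size = 8, bands = 4)
  ds <- build_dataset(4, params = ps, seed = 1)
  path <- tempfile(fileext = ".jsonl")
  write_manifest(ds, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$pair, 2)
  expect_true(all(c("seed", "condition", "split") %in% names(rec)))
})
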