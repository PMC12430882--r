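test_that("mse is the mean of squared differences", {
  a <- array(0, c(3, 3, 2))
  b <- array(0.5, c(3, 3, 2))
  expect_equal(mse(a, a), 0)
  expect_equal(mse(b, a), 0.25)
  set.seed(1)
  x <- array(runif(24), c(4, 3, 2))
  y <- array(runif(24), c(4, 3, 2))
  # explicit double-loop oracle
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(mse(x, y), acc / 24)
  expect_error(mse(x, array(0, c(4, 3, 3))), "shapes")
})

test_that("ssim is exactly 1 on identical bands and symmetric", {
  set.seed(2)
  x <- matrix(runif(16 * 16), 16)
  y <- matrix(runif(16 * 16), 16)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_lt(ssim(x, x + 0.2), 1)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("ssim of constant images follows the closed form", {
  cfg <- loss_config()
  x <- matrix(0, 12, 12)
  y <- matrix(1, 12, 12)
  # both variances zero: contrast term is 1, luminance term C1 / (1 + C1)
  expect_equal(ssim(x, y, cfg), cfg$C1 / (1 + cfg$C1), tolerance = 1e-12)
})

test_that("windowed ssim matches the brute-force sliding-window oracle", {
  for (kind in c("gaussian", "uniform")) {
    cfg <- loss_config(window_size = 7, window_kind = kind)
    for (s in 1:5) {
      set.seed(s)
      x <- matrix(runif(16 * 16), 16)
      y <- matrix(runif(16 * 16), 16)
      expect_equal(ssim(x, y, cfg), bruteforce_ssim(x, y, cfg),
                   tolerance = 1e-10)
    }
  }
})

test_that("loss_overall composes the two oracles and hits its bounds", {
  set.seed(3)
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  t_ <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cfg <- loss_config()
  expect_equal(loss_overall(p, p, cfg), 0)
  # alpha = 1, beta = 0 reduces exactly to mse (the MSE-only training arm)
  expect_equal(loss_overall(p, t_, loss_config(beta = 0)), mse(p, t_))
  # assembled from the two independent pieces
  sv <- vapply(1:3, function(b) ssim(p[, , b], t_[, , b], cfg), numeric(1))
  expect_equal(loss_overall(p, t_, cfg), mse(p, t_) + mean(1 - sv),
               tolerance = 1e-12)
  # bounds for nonnegative image-like inputs with alpha = beta = 1: the
  # structural term lies in [0, 1] whenever band SSIM is nonnegative, which
  # holds for positively correlated content (independent noise can push a
  # window's covariance term slightly negative)
  for (s in 1:5) {
    set.seed(s)
    a <- array(runif(16 * 16 * 2), c(16, 16, 2))
    b <- 0.8 * a + 0.05 + array(runif(16 * 16 * 2, 0, 0.1), c(16, 16, 2))
    lo <- loss_overall(a, b, cfg)
    expect_gte(lo, mse(a, b) - 1e-12)
    expect_lte(lo, mse(a, b) + 1 + 1e-12)
  }
})

test_that("evaluate_bands reports bandwise metrics whose mean is exact", {
  set.seed(4)
  p <- array(runif(16 * 16 * 4), c(16, 16, 4))
  t_ <- array(runif(16 * 16 * 4), c(16, 16, 4))
  bm <- evaluate_bands(p, t_, normalize = FALSE)
  # identical cubes: zero error, unit similarity
  bm0 <- evaluate_bands(t_, t_, normalize = FALSE)
  expect_equal(bm0$bands$mse, rep(0, 4))
  expect_equal(bm0$bands$ssim, rep(1, 4))
  # locality: perturbing one band moves only that band's metrics
  p2 <- t_
  p2[, , 3] <- p2[, , 3] + 0.3
  bm2 <- evaluate_bands(p2, t_, normalize = FALSE)
  expect_equal(bm2$bands$mse[-3], rep(0, 3))
  expect_equal(bm2$bands$ssim[-3], rep(1, 3))
  expect_gt(bm2$bands$mse[3], 0)
  # bandwise loop oracle and exact means
  for (b in 1:4) {
    expect_equal(bm$bands$mse[b], mse(p[, , b], t_[, , b]))
    expect_equal(bm$bands$ssim[b], ssim(p[, , b], t_[, , b]))
  }
  expect_equal(bm$mean_mse, mean(bm$bands$mse))
  expect_equal(bm$mean_ssim, mean(bm$bands$ssim))
})

test_that("band metrics round-trip through the CSV/JSON writers", {
  set.seed(5)
  p <- array(runif(12 * 12 * 3), c(12, 12, 3))
  bm <- evaluate_bands(p, p * 0.9, normalize = FALSE)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_band_metrics(bm, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(tab$ssim, bm$bands$ssim, tolerance = 1e-12)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$mean_ssim, bm$mean_ssim, tolerance = 1e-12)
})

test_that("relative improvement is the plain percent-change formula", {
  expect_equal(relative_improvement(1.5, 1), 50)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_error(relative_improvement(1, 0), "positive")
  expect_error(relative_improvement(1, -2), "positive")
})

test_that("the differentiable ssim loss agrees with the metric and its gradient", {
  cfg <- loss_config(window_size = 5)
  set.seed(6)
  x <- array(runif(10 * 10 * 2), c(10, 10, 2, 1))
  t_ <- array(runif(10 * 10 * 2), c(10, 10, 2, 1))
  tp <- sf$new_tape()
  lid <- sf$op_ssim_loss(tp, sf$op_input(tp, x), t_, cfg)
  sv <- vapply(1:2, function(b) ssim(x[, , b, 1], t_[, , b, 1], cfg), numeric(1))
  expect_equal(sf$tp_val(tp, lid), mean(1 - sv), tolerance = 1e-12)
  err <- tape_gradcheck(function(tp2, xid) sf$op_ssim_loss(tp2, xid, t_, cfg),
                        x, eps = 1e-5)
  expect_lt(err, 1e-5)
})
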