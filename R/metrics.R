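#' Loss configuration
#'
#' Parameters of the composite structure-pixel loss
#' `L = alpha * L_MSE + beta * (1 - SSIM)` and of the SSIM statistics. The
#' stabilizers `C1 = 0.0001` and `C2 = 0.0009` assume inputs on a \[0, 1\]
#' scale. The SSIM window defaults to the de-facto standard 11 x 11
#' Gaussian with sigma 1.5; a uniform window is available for comparison
#' against brute-force oracles.
#'
#' @param alpha,beta nonnegative weights of the MSE and SSIM terms.
#' @param C1,C2 positive SSIM stabilizers.
#' @param window_size odd window edge length >= 3.
#' @param window_kind `"gaussian"` or `"uniform"`.
#' @param window_sigma Gaussian window standard deviation in pixels.
#' @export
loss_config <- function(alpha = 1, beta = 1, C1 = 1e-4, C2 = 9e-4,
                        window_size = 11, window_kind = c("gaussian", "uniform"),
                        window_sigma = 1.5) {
  window_kind <- match.arg(window_kind)
  stopifnot(alpha >= 0, beta >= 0, C1 > 0, C2 > 0,
            window_size >= 3, window_size %% 2 == 1)
  structure(list(alpha = alpha, beta = beta, C1 = C1, C2 = C2,
                 window_size = as.integer(window_size),
                 window_kind = window_kind, window_sigma = window_sigma),
            class = "loss_config")
}

ssim_kernel_1d <- function(cfg) {
  k <- cfg$window_size
  if (cfg$window_kind == "uniform") return(rep(1 / k, k))
  r <- (seq_len(k) - (k + 1) / 2)
  w <- exp(-0.5 * (r / cfg$window_sigma)^2)
  w / sum(w)
}

# (n - k + 1) x n matrix applying a 1-D kernel at every valid position
filt_mat <- function(n, kern) {
  k <- length(kern)
  if (n < k) stop(sprintf("image extent %d is smaller than the %d-pixel window", n, k))
  m <- matrix(0, n - k + 1, n)
  for (i in seq_len(n - k + 1)) m[i, i:(i + k - 1)] <- kern
  m
}

cube_values <- function(x) {
  if (inherits(x, "spectral_cube")) x$values
  else if (inherits(x, "rgb_image")) x$values
  else as.array(x)
}

#' Mean squared error
#'
#' Mean of squared elementwise differences over all pixels and bands.
#'
#' @param pred,truth arrays (or [spectral_cube()]s) of identical shape.
#' @return a nonnegative scalar.
#' @export
mse <- function(pred, truth) {
  p <- cube_values(pred); t_ <- cube_values(truth)
  if (!all(dim(p) == dim(t_)))
    stop("mse: shapes differ (", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(t_), collapse = "x"), ")")
  mean((p - t_)^2)
}

#' Structural similarity of two single-band images
#'
#' Windowed SSIM: local means, variances and covariance are computed over
#' every fully interior window position (separable Gaussian or uniform
#' weighting), combined per Wang et al.'s luminance-contrast-structure
#' form, and averaged over positions. Exactly 1 iff the bands are
#' identical.
#'
#' @param x,y numeric matrices of identical size, at least as large as the
#'   window.
#' @param cfg a [loss_config()].
#' @return a scalar in (-1, 1].
#' @export
ssim <- function(x, y, cfg = loss_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("ssim: images have different sizes")
  kern <- ssim_kernel_1d(cfg)
  Fh <- filt_mat(nrow(x), kern)
  Fw <- filt_mat(ncol(x), kern)
  f <- function(z) Fh %*% z %*% t(Fw)
  u <- f(x); v <- f(y)
  sx <- f(x * x) - u * u
  sy <- f(y * y) - v * v
  sxy <- f(x * y) - u * v
  s <- ((2 * u * v + cfg$C1) * (2 * sxy + cfg$C2)) /
    ((u * u + v * v + cfg$C1) * (sx + sy + cfg$C2))
  mean(s)
}

#' Composite structure-pixel loss
#'
#' `alpha * MSE + beta * mean over bands of (1 - SSIM_band)`. With both
#' weights positive the loss is zero iff the cubes are identical; with
#' `beta = 0` it reduces exactly to the MSE-only training arm.
#'
#' @param pred,truth cubes (arrays or [spectral_cube()]s) of identical
#'   shape `H x W x B`.
#' @param cfg a [loss_config()].
#' @return a nonnegative scalar.
#' @export
loss_overall <- function(pred, truth, cfg = loss_config()) {
  p <- cube_values(pred); t_ <- cube_values(truth)
  if (!all(dim(p) == dim(t_))) stop("loss_overall: shapes differ")
  term_mse <- mean((p - t_)^2)
  term_ssim <- 0
  if (cfg$beta > 0) {
    B <- dim(p)[3]
    s <- vapply(seq_len(B), function(b) ssim(p[, , b], t_[, , b], cfg),
                numeric(1))
    term_ssim <- mean(1 - s)
  }
  cfg$alpha * term_mse + cfg$beta * term_ssim
}

#' Per-band evaluation metrics
#'
#' Per-band MSE and SSIM between two cubes plus their means (the mean is
#' exactly the average of the per-band values). When `normalize` is `TRUE`
#' both cubes are divided by the truth cube's maximum first, mirroring the
#' unit-max preprocessing convention used for all reported metrics.
#'
#' @param pred,truth cubes of identical shape.
#' @param cfg a [loss_config()].
#' @param normalize divide both cubes by `max(truth)` before measuring.
#' @return a `band_metrics` object: data.frame `bands` (band, mse, ssim)
#'   plus `mean_mse` and `mean_ssim`.
#' @export
evaluate_bands <- function(pred, truth, cfg = loss_config(), normalize = TRUE) {
  p <- cube_values(pred); t_ <- cube_values(truth)
  if (!all(dim(p) == dim(t_))) stop("evaluate_bands: shapes differ")
  if (normalize) {
    m <- max(t_)
    if (m <= 0) stop("cannot normalize by an all-zero truth cube")
    p <- p / m; t_ <- t_ / m
  }
  B <- dim(p)[3]
  ms <- vapply(seq_len(B), function(b) mean((p[, , b] - t_[, , b])^2), numeric(1))
  ss <- vapply(seq_len(B), function(b) ssim(p[, , b], t_[, , b], cfg), numeric(1))
  structure(list(bands = data.frame(band = seq_len(B), mse = ms, ssim = ss),
                 mean_mse = mean(ms), mean_ssim = mean(ss)),
            class = "band_metrics")
}

#' @export
print.band_metrics <- function(x, ...) {
  cat(sprintf("<band_metrics> %d bands: mean MSE %.5g, mean SSIM %.4f\n",
              nrow(x$bands), x$mean_mse, x$mean_ssim))
  invisible(x)
}

#' Write per-band metrics to CSV with a JSON summary
#'
#' @param metrics a `band_metrics` object.
#' @param csv_path path for the per-band table (band, mse, ssim).
#' @param json_path optional path for a `{mean_mse, mean_ssim}` summary.
#' @export
write_band_metrics <- function(metrics, csv_path, json_path = NULL) {
  utils::write.csv(metrics$bands, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(mean_mse = metrics$mean_mse,
                              mean_ssim = metrics$mean_ssim),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Relative improvement in percent
#'
#' `100 * (a - b) / b`: how much larger `a` is than the reference `b`.
#'
#' @param a value of interest.
#' @param b positive reference value.
#' @export
relative_improvement <- function(a, b) {
  if (!is.numeric(b) || b <= 0) stop("reference value must be positive")
  100 * (a - b) / b
}

#' Published benchmark metrics used for comparison arithmetic
#'
#' Mean test MSE and SSIM reported for the fusion network, its variants and
#' prior RGB-to-hyperspectral methods on the (private) 4000-pair dental
#' dataset. These printed values are inputs to the relative-improvement
#' arithmetic; they are not reproduced by this package.
#'
#' @return a data.frame with columns `method`, `mse`, `ssim`.
#' @export
reference_benchmarks <- function() {
  data.frame(
    method = c("baseline_unet", "srnet_no_attention", "srnet_mse", "srnet",
               "mstpp", "hscnnp", "awan", "hdnet",
               "srnet_no_dsa", "srnet_p_only", "srnet_const_illumination"),
    mse = c(0.0018, 0.012, 0.0031, 0.0024,
            0.0009, 0.0011, 0.0014, 0.0012,
            0.0032, 0.0024, 0.083),
    ssim = c(0.7631, 0.643, 0.8129, 0.8724,
             0.8409, 0.8085, 0.8152, 0.8245,
             0.8413, 0.8393, 0.3442),
    stringsAsFactors = FALSE
  )
}

# ---- differentiable SSIM loss on [H,W,C,N] feature maps ----

# separable valid-window filtering along the two spatial axes
filt_sep <- function(x, Fh, Fw) {
  d <- dim(x)
  Ho <- nrow(Fh); Wo <- nrow(Fw)
  t1 <- Fh %*% matrix(x, d[1], prod(d[-1]))
  a <- aperm(array(t1, c(Ho, d[2], d[3], d[4])), c(2, 1, 3, 4))
  t2 <- Fw %*% matrix(a, d[2], Ho * d[3] * d[4])
  aperm(array(t2, c(Wo, Ho, d[3], d[4])), c(2, 1, 3, 4))
}

# mean over bands/batch of (1 - SSIM) against a constant target
op_ssim_loss <- function(tp, xid, target, cfg = loss_config()) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- featdim(x)
  kern <- ssim_kernel_1d(cfg)
  Fh <- filt_mat(d[1], kern)
  Fw <- filt_mat(d[2], kern)
  FhT <- t(Fh); FwT <- t(Fw)
  C1 <- cfg$C1; C2 <- cfg$C2
  v <- filt_sep(target, Fh, Fw)
  q <- filt_sep(target * target, Fh, Fw)
  u <- filt_sep(x, Fh, Fw)
  p <- filt_sep(x * x, Fh, Fw)
  r <- filt_sep(x * target, Fh, Fw)
  A1 <- 2 * u * v + C1
  A2 <- 2 * (r - u * v) + C2
  B1 <- u * u + v * v + C1
  B2 <- (p - u * u) + (q - v * v) + C2
  S <- (A1 * A2) / (B1 * B2)
  val <- 1 - mean(S)
  back <- function(dy) {
    dS <- -dy / length(S)
    Gu <- dS * (2 * v * (A2 - A1) / (B1 * B2) - 2 * u * S * (1 / B1 - 1 / B2))
    Gp <- dS * (-S / B2)
    Gr <- dS * (2 * A1 / (B1 * B2))
    dx <- filt_sep(Gu, FhT, FwT) +
      2 * x * filt_sep(Gp, FhT, FwT) +
      target * filt_sep(Gr, FhT, FwT)
    list(dx)
  }
  tp_push(tp, val, parents = xid, back = back)
}
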