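#' Model size presets
#'
#' Two architecture/dataset scales: `"full"` mirrors the reference
#' configuration (64 x 64 images, 32 bands, encoder base width 32,
#' attention-branch width 64 with 3 L-blocks, 4000 pairs, 54 epochs) and
#' `"desk"` is the down-scaled study used by the test suite and worked
#' examples (32 x 32 images, 16 bands, encoder base width 4 with one
#' fusion block per stage, attention-branch width 4 with 2 L-blocks,
#' 256 pairs, 30 epochs) --
#' sized so that a complete multi-seed study runs in minutes
#' on a single laptop CPU core.
#'
#' @param preset `"full"` or `"desk"`.
#' @return a list with `scene` ([scene_params()]), `n_pairs`, `p_base`,
#'   `l_width`, `l_blocks`, and a default [srnet_control()].
#' @export
srnet_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(name = "full", scene = scene_params(image_size = 64, bands = 32),
         n_pairs = 4000L, p_base = 32L, l_width = 64L, l_blocks = 3L,
         lgf_counts = c(2L, 2L, 2L), control = srnet_control(epochs = 54))
  } else {
    list(name = "desk", scene = scene_params(image_size = 32, bands = 16),
         n_pairs = 256L, p_base = 4L, l_width = 4L, l_blocks = 2L,
         lgf_counts = c(1L, 1L, 1L), control = srnet_control(epochs = 30))
  }
}

#' Fit the physics-informed spectral reflectance model
#'
#' Trains the fusion model end to end on a paired dataset: the P branch
#' maps the object RGB to a radiance cube, the light-role L branch maps the
#' white-reference RGB to an illuminant cube, and a decoder-role L branch
#' (independent parameters) maps their channel concatenation to the
#' reflectance cube. Supervision is the composite structure-pixel loss on
#' the reflectance output plus weak auxiliary MSE supervision of the two
#' intermediate cubes. Ablation variants remove one module or input;
#' `"baseline_unet"` trains the attention-free U-Net that predicts
#' reflectance from the object RGB alone.
#'
#' One seed fans out deterministically to weight initialisation and batch
#' order, so identical `(data, variant, control, seed)` reproduce the fit.
#'
#' @param data a `paired_dataset` from [build_dataset()].
#' @param variant one of `"full"`, `"no_dsa"`, `"no_lgf"`, `"p_only"`,
#'   `"l_only"`, `"const_illumination"`, `"baseline_unet"`,
#'   `"mse_loss_only"`.
#' @param preset `"desk"` or `"full"`; sets architecture widths and the
#'   default control. Ignored where explicit arguments override it.
#' @param control an [srnet_control()]; default from the preset.
#' @param seed master integer seed.
#' @param evaluate compute mean test-split metrics after training.
#' @return an object of class `"srnet"` with components `model`, `history`
#'   (per-epoch train/val loss, epoch 0 = initialisation), `test_metrics`,
#'   `variant`, `control`, `grid`, `seed`.
#' @seealso [predict.srnet()], [run_ablation()], [build_dataset()]
#' @export
srnet <- function(data, variant = "full", preset = c("desk", "full"),
                  control = NULL, seed = 1, evaluate = TRUE) {
  stopifnot(inherits(data, "paired_dataset"))
  variant <- match.arg(variant, srnet_variants())
  ps <- srnet_preset(preset)
  if (is.null(control)) control <- ps$control
  if (variant == "mse_loss_only") control$loss$beta <- 0
  bands <- data$params$bands
  model <- build_model(variant, bands, ps$p_base, ps$l_width, ps$l_blocks,
                       derive_seed(seed, 100L), lgf_counts = ps$lgf_counts)
  fitted <- train_model(model, data, control, seed = seed)
  test_idx <- data$manifest$pair[data$manifest$split == "test"]
  metrics <- NULL
  if (evaluate && length(test_idx))
    metrics <- model_evaluate(fitted$model, data$pairs[test_idx],
                              data$params$grid, control$loss)
  structure(list(model = fitted$model, history = fitted$history,
                 test_metrics = metrics, variant = variant,
                 preset = ps$name, control = control,
                 grid = data$params$grid, seed = as.integer(seed),
                 manifest = data$manifest),
            class = "srnet")
}

#' @export
print.srnet <- function(x, ...) {
  h <- x$history
  cat(sprintf("Physics-informed spectral reflectance model (variant '%s', preset '%s')\n",
              x$variant, x$preset))
  cat(sprintf("  %d bands (%.0f-%.0f nm), %s trainable parameters\n",
              length(x$grid), min(x$grid), max(x$grid),
              format(model_param_count(x$model), big.mark = ",")))
  cat(sprintf("  trained %d epochs: val loss %.4f -> %.4f\n",
              max(h$epoch), h$val_loss[1], h$val_loss[nrow(h)]))
  if (!is.null(x$test_metrics))
    cat(sprintf("  test (%d pairs): mean MSE %.5f, mean SSIM %.4f\n",
                nrow(x$test_metrics$per_pair), x$test_metrics$mean_mse,
                x$test_metrics$mean_ssim))
  invisible(x)
}

#' @export
summary.srnet <- function(object, ...) {
  parts <- intersect(names(object$model), c("p", "l_light", "l_decoder", "unet"))
  counts <- vapply(parts, function(p) count_params(object$model[[p]]$params),
                   numeric(1))
  structure(list(fit = object, part_params = counts), class = "summary.srnet")
}

#' @export
print.summary.srnet <- function(x, ...) {
  print(x$fit)
  cat("  parameters by part:\n")
  for (nm in names(x$part_params))
    cat(sprintf("    %-10s %s\n", nm, format(x$part_params[[nm]], big.mark = ",")))
  h <- x$fit$history
  cat("  last epochs:\n")
  print(utils::tail(h, 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.srnet <- function(object, ...) {
  unlist(model_params_flat(object$model))
}

#' Predict reflectance from a trained model
#'
#' Runs the three-step inversion on one image pair: the object RGB through
#' the P branch, the white-reference RGB through the light-role L branch,
#' and their concatenation through the decoder. Inputs are normalized by
#' the light image's maximum (the exposure reference); negative network
#' outputs are clamped to zero so the result is a valid reflectance cube.
#'
#' @param object a fitted `"srnet"`.
#' @param newdata a `paired_sample` (its two RGB images are used), or
#'   `NULL` when `sample_rgb`/`light_rgb` are given.
#' @param sample_rgb,light_rgb [rgb_image()]s or `H x W x 3` arrays with
#'   equal spatial size, divisible by the encoder's downsampling factor.
#' @param ... unused.
#' @return a reflectance [spectral_cube()].
#' @export
predict.srnet <- function(object, newdata = NULL, sample_rgb = NULL,
                          light_rgb = NULL, ...) {
  if (!is.null(newdata)) {
    stopifnot(inherits(newdata, "paired_sample"))
    sample_rgb <- newdata$sample_rgb
    light_rgb <- newdata$light_rgb
  }
  if (is.null(sample_rgb) || is.null(light_rgb))
    stop("supply either newdata or both sample_rgb and light_rgb")
  model_predict(object$model, sample_rgb, light_rgb, object$grid)
}

#' @export
residuals.srnet <- function(object, ...) {
  if (is.null(object$test_metrics))
    stop("fit was run with evaluate = FALSE; no held-out residual metrics")
  object$test_metrics$per_pair
}

#' Plot training history and per-band test metrics
#'
#' Left panel: train/validation loss per epoch. Right panel (when test
#' metrics were computed): per-band SSIM on the test split.
#'
#' @param x a fitted `"srnet"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.srnet <- function(x, ...) {
  h <- x$history
  has_bands <- !is.null(x$test_metrics)
  if (has_bands) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  if (has_bands) {
    pb <- x$test_metrics$per_band
    graphics::plot(pb$band, pb$ssim, type = "b", pch = 16,
                   xlab = "band", ylab = "mean test SSIM")
  }
  invisible(x)
}

#' Train and evaluate one ablation variant
#'
#' Builds the requested variant (gates replaced by identity for
#' `"no_dsa"`, LGF blocks by plain convolutions for `"no_lgf"`, decoder
#' fed a single cube for `"p_only"`/`"l_only"`, light RGB replaced by
#' constant 1 for `"const_illumination"`), trains it with the identical
#' control and seed, and evaluates on the shared test split.
#'
#' @param variant an ablation name, see [srnet()].
#' @param data a `paired_dataset`.
#' @inheritParams srnet
#' @return a list with `fit` (the `"srnet"` object) and `metrics` (its
#'   test-split metrics).
#' @export
run_ablation <- function(variant, data, preset = c("desk", "full"),
                         control = NULL, seed = 1) {
  variant <- match.arg(variant, srnet_variants())
  fit <- srnet(data, variant = variant, preset = preset, control = control,
               seed = seed, evaluate = TRUE)
  list(fit = fit, metrics = fit$test_metrics)
}

#' Reflectance prediction with an untrained or external model bundle
#'
#' Low-level entry mirroring the three-step inversion for a bare model
#' container (as stored in `fit$model`); [predict.srnet()] is the usual
#' interface.
#'
#' @param model a model container (`fit$model`).
#' @param sample_rgb,light_rgb images as in [predict.srnet()].
#' @param grid the working [wavelength_grid()].
#' @export
predict_reflectance <- function(model, sample_rgb, light_rgb, grid) {
  model_predict(model, sample_rgb, light_rgb, grid)
}
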