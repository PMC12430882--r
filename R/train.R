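#' Training control parameters
#'
#' Adam optimizer settings and loss configuration for fitting the fusion
#' model. Defaults follow the reference protocol: Adam with beta1 = 0.9,
#' beta2 = 0.999, zero weight decay, learning rate 4e-4 held constant,
#' batch size 8.
#'
#' @param learning_rate constant Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param beta1,beta2 Adam moment decays.
#' @param weight_decay L2 weight decay (0 in the reference protocol).
#' @param loss a [loss_config()] for the structure-pixel objective on the
#'   reflectance output.
#' @param aux_weight weight of the auxiliary MSE supervision of the
#'   intermediate radiance and illuminant cubes against their ground-truth
#'   counterparts (0 disables).
#' @param verbose print per-epoch losses.
#' @export
srnet_control <- function(learning_rate = 4e-4, batch_size = 8, epochs = 54,
                          beta1 = 0.9, beta2 = 0.999, weight_decay = 0,
                          loss = loss_config(), aux_weight = 0.1,
                          verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, loss = loss,
                 aux_weight = aux_weight, verbose = isTRUE(verbose)),
            class = "srnet_control")
}

srnet_variants <- function() {
  c("full", "no_dsa", "no_lgf", "p_only", "l_only", "const_illumination",
    "baseline_unet", "mse_loss_only")
}

# model container: the three subnetworks (or the baseline U-Net)
build_model <- function(variant, bands, p_base, l_width, l_blocks, seed,
                        lgf_counts = c(2, 2, 2)) {
  variant <- match.arg(variant, srnet_variants())
  if (variant == "baseline_unet") {
    cfg <- unet_config(bands, base_width = p_base)
    return(list(variant = variant, bands = bands,
                unet = list(cfg = cfg, params = unet_init(cfg, seed))))
  }
  use_p <- variant != "l_only"
  use_l <- !(variant %in% "p_only")
  dec_in <- if (variant %in% c("p_only", "l_only")) bands else 2L * bands
  p_cfg <- srp_config(bands, base_width = p_base, lgf_counts = lgf_counts,
                      use_dsa = variant != "no_dsa",
                      use_lgf = variant != "no_lgf")
  l_cfg <- srl_config(3L, bands, width = l_width, n_blocks = l_blocks)
  d_cfg <- srl_config(dec_in, bands, width = l_width, n_blocks = l_blocks)
  model <- list(variant = variant, bands = bands)
  if (use_p) model$p <- list(cfg = p_cfg, params = srp_init(p_cfg, derive_seed(seed, 1L)))
  if (use_l) model$l_light <- list(cfg = l_cfg,
                                   params = srl_init(l_cfg, derive_seed(seed, 2L)))
  model$l_decoder <- list(cfg = d_cfg,
                          params = srl_init(d_cfg, derive_seed(seed, 3L)))
  model
}

model_param_count <- function(model) {
  parts <- intersect(names(model), c("p", "l_light", "l_decoder", "unet"))
  sum(vapply(parts, function(p) count_params(model[[p]]$params), numeric(1)))
}

# normalized training tensors for one pair: both RGBs scaled by the light
# image's max (the white reference defines exposure), cubes by the light
# cube's max; reflectance is a ratio and stays untouched
pair_tensors <- function(pair, variant = "full") {
  s_rgb <- pair$sample_rgb$values
  l_rgb <- pair$light_rgb$values
  if (variant == "const_illumination") l_rgb <- array(1, dim(l_rgb))
  sc_rgb <- max(l_rgb)
  sc_hsi <- max(pair$light_hsi$values)
  list(xs = s_rgb / sc_rgb, xl = l_rgb / sc_rgb,
       rad = pair$sample_hsi$values / sc_hsi,
       ill = pair$light_hsi$values / sc_hsi,
       refl = pair$reflectance_gt$values)
}

stack_batch <- function(tensors, field) {
  d <- dim(tensors[[1]][[field]])
  out <- array(0, c(d, length(tensors)))
  for (i in seq_along(tensors)) out[, , , i] <- tensors[[i]][[field]]
  out
}

# run a subnetwork builder inside its own parameter scope so gradient names
# come back namespaced ("p/head.W", "l_decoder/lb1.conv.W", ...)
scoped_build <- function(tp, scope, builder) {
  old <- tp$scope
  tp$scope <- paste0(scope, "/")
  on.exit(tp$scope <- old)
  builder()
}

# forward + composite loss on the tape; returns list(loss = id, refl = id)
model_loss_build <- function(tp, model, batch, control) {
  variant <- model$variant
  lcfg <- control$loss
  aux_ids <- integer(0)
  aux_w <- numeric(0)
  if (variant == "baseline_unet") {
    xs <- op_input(tp, batch$xs)
    refl_hat <- scoped_build(tp, "unet", function()
      unet_build(tp, model$unet$params, model$unet$cfg, xs))
  } else {
    rad_hat <- ill_hat <- NULL
    if (!is.null(model$p)) {
      xs <- op_input(tp, batch$xs)
      rad_hat <- scoped_build(tp, "p", function()
        srp_build(tp, model$p$params, model$p$cfg, xs))
      if (control$aux_weight > 0) {
        aux_ids <- c(aux_ids, op_mse(tp, rad_hat, batch$rad))
        aux_w <- c(aux_w, control$aux_weight)
      }
    }
    if (!is.null(model$l_light)) {
      xl <- op_input(tp, batch$xl)
      ill_hat <- scoped_build(tp, "l_light", function()
        srl_build(tp, model$l_light$params, model$l_light$cfg, xl))
      if (control$aux_weight > 0) {
        aux_ids <- c(aux_ids, op_mse(tp, ill_hat, batch$ill))
        aux_w <- c(aux_w, control$aux_weight)
      }
    }
    dec_in <- if (is.null(rad_hat)) ill_hat
      else if (is.null(ill_hat)) rad_hat
      else op_concat(tp, c(rad_hat, ill_hat))
    stopifnot(featdim(tp_val(tp, dec_in))[3] == model$l_decoder$cfg$in_channels)
    refl_hat <- scoped_build(tp, "l_decoder", function()
      srl_build(tp, model$l_decoder$params, model$l_decoder$cfg, dec_in))
  }
  ids <- op_mse(tp, refl_hat, batch$refl)
  w <- lcfg$alpha
  if (lcfg$beta > 0) {
    ids <- c(ids, op_ssim_loss(tp, refl_hat, batch$refl, lcfg))
    w <- c(w, lcfg$beta)
  }
  if (length(aux_ids)) {
    ids <- c(ids, aux_ids)
    w <- c(w, aux_w)
  }
  list(loss = op_wsum(tp, ids, w), refl = refl_hat)
}

model_params_flat <- function(model) {
  parts <- intersect(names(model), c("p", "l_light", "l_decoder", "unet"))
  out <- list()
  for (p in parts)
    for (nm in names(model[[p]]$params))
      out[[paste0(p, "/", nm)]] <- model[[p]]$params[[nm]]
  out
}

model_params_unflat <- function(model, flat) {
  for (nm in names(flat)) {
    sp <- regmatches(nm, regexpr("/", nm), invert = TRUE)[[1]]
    model[[sp[1]]]$params[[sp[2]]] <- flat[[nm]]
  }
  model
}

adam_new <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, control) {
  state$t <- state$t + 1L
  b1 <- control$beta1; b2 <- control$beta2
  lr <- control$learning_rate; eps <- 1e-8
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (control$weight_decay > 0) g <- g + control$weight_decay * flat[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(flat = flat, state = state)
}

batch_arrays <- function(tensors, idx) {
  ts <- tensors[idx]
  list(xs = stack_batch(ts, "xs"), xl = stack_batch(ts, "xl"),
       rad = stack_batch(ts, "rad"), ill = stack_batch(ts, "ill"),
       refl = stack_batch(ts, "refl"))
}

eval_loss <- function(model, tensors, idx, control) {
  tot <- 0
  for (b in split(idx, ceiling(seq_along(idx) / control$batch_size))) {
    tp <- new_tape()
    built <- model_loss_build(tp, model, batch_arrays(tensors, b), control)
    tot <- tot + tp_val(tp, built$loss) * length(b)
  }
  tot / length(idx)
}

# supervised training of a model on a paired dataset; fully seeded
train_model <- function(model, dataset, control, seed = 1) {
  man <- dataset$manifest
  idx_train <- man$pair[man$split == "train"]
  idx_val <- man$pair[man$split == "val"]
  if (!length(idx_train)) stop("dataset has no training pairs")
  tensors <- lapply(dataset$pairs, pair_tensors, variant = model$variant)
  flat <- model_params_flat(model)
  state <- adam_new(flat)
  val0 <- eval_loss(model, tensors, idx_val, control)
  history <- data.frame(epoch = 0L, train_loss = NA_real_, val_loss = val0)
  with_seed(derive_seed(seed, 17L), {
    for (ep in seq_len(control$epochs)) {
      ord <- sample(idx_train)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / control$batch_size))) {
        tp <- new_tape()
        built <- model_loss_build(tp, model, batch_arrays(tensors, b), control)
        lv <- tp_val(tp, built$loss)
        if (!is.finite(lv))
          stop(sprintf("loss became non-finite at epoch %d; last finite val loss %.4g",
                       ep, history$val_loss[nrow(history)]))
        ep_loss <- ep_loss + lv * length(b)
        grads <- tp_backward(tp, built$loss)
        upd <- adam_step(flat, grads, state, control)
        flat <- upd$flat
        state <- upd$state
        model <- model_params_unflat(model, flat)
      }
      vl <- if (length(idx_val)) eval_loss(model, tensors, idx_val, control) else NA_real_
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / length(idx_train),
                                           val_loss = vl))
      if (control$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                        ep_loss / length(idx_train), vl))
    }
  })
  list(model = model, history = history)
}

# reflectance prediction from a trained (or freshly initialised) model
model_predict <- function(model, sample_rgb, light_rgb, grid) {
  s <- if (inherits(sample_rgb, "rgb_image")) sample_rgb$values else as.array(sample_rgb)
  l <- if (inherits(light_rgb, "rgb_image")) light_rgb$values else as.array(light_rgb)
  if (!all(dim(s)[1:2] == dim(l)[1:2]))
    stop("sample and light images have different spatial sizes")
  if (model$variant == "const_illumination") l <- array(1, dim(l))
  sc <- max(l)
  if (sc <= 0) stop("light image is all zero")
  s <- s / sc; l <- l / sc
  if (model$variant == "baseline_unet") {
    out <- baseline_unet_forward(model$unet$params, model$unet$cfg, s)
  } else {
    rad <- if (!is.null(model$p)) srp_forward(model$p$params, model$p$cfg, s) else NULL
    ill <- if (!is.null(model$l_light))
      srl_forward(model$l_light$params, model$l_light$cfg, l) else NULL
    dec_in <- if (is.null(rad)) ill else if (is.null(ill)) rad
      else {
        d <- dim(rad)
        comb <- array(0, c(d[1], d[2], 2L * d[3]))
        comb[, , seq_len(d[3])] <- rad
        comb[, , d[3] + seq_len(d[3])] <- ill
        comb
      }
    out <- srl_forward(model$l_decoder$params, model$l_decoder$cfg, dec_in)
  }
  spectral_cube(pmax(out, 0), grid, kind = "reflectance")
}

# mean test metrics of a model over a list of pairs
model_evaluate <- function(model, pairs, grid, cfg = loss_config()) {
  stopifnot(length(pairs) >= 1)
  ms <- ss <- numeric(length(pairs))
  per_band <- NULL
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    pred <- model_predict(model, p$sample_rgb, p$light_rgb, grid)
    bm <- evaluate_bands(pred, p$reflectance_gt, cfg)
    ms[i] <- bm$mean_mse
    ss[i] <- bm$mean_ssim
    per_band <- if (is.null(per_band)) bm$bands[, c("mse", "ssim")]
      else per_band + bm$bands[, c("mse", "ssim")]
  }
  per_band <- per_band / length(pairs)
  list(mean_mse = mean(ms), mean_ssim = mean(ss),
       per_pair = data.frame(pair = seq_along(pairs), mse = ms, ssim = ss),
       per_band = data.frame(band = seq_len(nrow(per_band)), per_band))
}
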