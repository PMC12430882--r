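#' Configuration of the attention network (L branch)
#'
#' The attention-heavy network used twice in the framework: once to
#' reconstruct the illuminant cube from the light RGB (3 input channels)
#' and once, with independent parameters, to decode the channel-
#' concatenated radiance and illuminant cubes into reflectance (2B input
#' channels). Shallow features come from two independently parameterized
#' 3x3 convolution paths, each followed by ReLU, channel attention and
#' spatial attention; 1x1 refinements of each path give two more maps; the
#' four are concatenated (fusion width exactly `4 * width`, asserted at
#' build) and refined by `n_blocks` recursive L-blocks before a 1x1 head.
#'
#' @param in_channels input channel count (3 for the light role, 2B for
#'   the decoder role).
#' @param bands output band count B.
#' @param width per-branch feature width; the fused trunk runs at
#'   `4 * width`.
#' @param n_blocks number of L-blocks N.
#' @param use_attention `FALSE` strips the CA/SA gates (identity), keeping
#'   layer structure otherwise.
#' @export
srl_config <- function(in_channels, bands, width = 64, n_blocks = 3,
                       use_attention = TRUE) {
  stopifnot(in_channels >= 1, bands >= 2, width >= 1, n_blocks >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 bands = as.integer(bands), width = as.integer(width),
                 n_blocks = as.integer(n_blocks),
                 use_attention = isTRUE(use_attention)),
            class = "srl_config")
}

init_srl_branch <- function(st, name, cin, w, k, use_attention) {
  pinit_conv(st, paste0(name, ".conv"), cin, w, k)
  if (use_attention) {
    init_ca(st, paste0(name, ".ca"), w)
    init_sa(st, paste0(name, ".sa"))
  }
}

fwd_srl_branch <- function(tp, P, name, x, k, use_attention) {
  f <- op_relu(tp, fwd_conv(tp, P, paste0(name, ".conv"), x, k))
  if (use_attention) {
    f <- fwd_ca(tp, P, paste0(name, ".ca"), f)
    f <- fwd_sa(tp, P, paste0(name, ".sa"), f)
  }
  f
}

#' Initialise parameters of the L branch
#'
#' @param cfg an [srl_config()].
#' @param seed integer seed.
#' @export
srl_init <- function(cfg, seed = 1) {
  st <- new.env()
  w <- cfg$width
  with_seed(seed, {
    init_srl_branch(st, "b1", cfg$in_channels, w, 3L, cfg$use_attention)
    init_srl_branch(st, "b2", cfg$in_channels, w, 3L, cfg$use_attention)
    init_srl_branch(st, "r1", w, w, 1L, cfg$use_attention)
    init_srl_branch(st, "r2", w, w, 1L, cfg$use_attention)
    for (i in seq_len(cfg$n_blocks)) {
      if (cfg$use_attention) init_lblock(st, sprintf("lb%d", i), 4L * w)
      else {
        pinit_conv(st, sprintf("lb%d.conv", i), 4L * w, 4L * w, 3L)
        pinit_conv(st, sprintf("lb%d.short", i), 4L * w, 4L * w, 1L, gain = 1)
      }
    }
    pinit_conv(st, "headout", 4L * w, cfg$bands, 1L, gain = 1)
  })
  as.list(st)
}

srl_build <- function(tp, P, cfg, xid) {
  d <- featdim(tp_val(tp, xid))
  if (d[3] != cfg$in_channels)
    stop(sprintf("input has %d channels but the network expects %d",
                 d[3], cfg$in_channels))
  f1 <- fwd_srl_branch(tp, P, "b1", xid, 3L, cfg$use_attention)
  f2 <- fwd_srl_branch(tp, P, "b2", xid, 3L, cfg$use_attention)
  f3 <- fwd_srl_branch(tp, P, "r1", f1, 1L, cfg$use_attention)
  f4 <- fwd_srl_branch(tp, P, "r2", f2, 1L, cfg$use_attention)
  fusion <- op_concat(tp, c(f1, f2, f3, f4))
  stopifnot(featdim(tp_val(tp, fusion))[3] == 4L * cfg$width)
  f <- fusion
  for (i in seq_len(cfg$n_blocks)) {
    f <- if (cfg$use_attention) fwd_lblock(tp, P, sprintf("lb%d", i), f)
    else op_add(tp, fwd_conv(tp, P, sprintf("lb%d.short", i), f, 1L),
                op_relu(tp, fwd_conv(tp, P, sprintf("lb%d.conv", i), f, 3L)))
  }
  fwd_conv(tp, P, "headout", f, 1L)
}

#' Forward pass of the L branch
#'
#' @param params from [srl_init()].
#' @param cfg an [srl_config()].
#' @param x `[H,W,in_channels]` or `[H,W,in_channels,N]` array.
#' @return `[H,W,B]` or `[H,W,B,N]` array.
#' @export
srl_forward <- function(params, cfg, x) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- srl_build(tp, params, cfg, op_input(tp, x4))
  val <- tp_val(tp, out)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  val
}

# ---- plain U-Net baseline (sample RGB -> reflectance directly) ----

unet_config <- function(bands, base_width = 16, n_stages = 3, in_channels = 3) {
  structure(list(bands = as.integer(bands), base_width = as.integer(base_width),
                 n_stages = as.integer(n_stages),
                 in_channels = as.integer(in_channels)),
            class = "unet_config")
}

unet_init <- function(cfg, seed = 1) {
  st <- new.env()
  w <- cfg$base_width * 2^(0:cfg$n_stages)
  with_seed(seed, {
    pinit_conv(st, "head", cfg$in_channels, w[1], 3L, gain = 1)
    for (i in seq_len(cfg$n_stages)) {
      pinit_conv(st, sprintf("enc%d.c1", i), w[i], w[i], 3L)
      pinit_conv(st, sprintf("enc%d.c2", i), w[i], w[i], 3L)
      pinit_conv(st, sprintf("enc%d.down", i), w[i], w[i + 1], 3L, gain = 1)
    }
    pinit_conv(st, "mid.c1", w[cfg$n_stages + 1], w[cfg$n_stages + 1], 3L)
    pinit_conv(st, "mid.c2", w[cfg$n_stages + 1], w[cfg$n_stages + 1], 3L)
    for (i in seq_len(cfg$n_stages)) {
      wi <- w[cfg$n_stages + 1 - i]
      pinit_convT2(st, sprintf("dec%d.up", i), 2L * wi, wi)
      pinit_conv(st, sprintf("dec%d.fuse", i), 2L * wi, wi, 1L, gain = 1)
      pinit_conv(st, sprintf("dec%d.c1", i), wi, wi, 3L)
      pinit_conv(st, sprintf("dec%d.c2", i), wi, wi, 3L)
    }
    pinit_conv(st, "tail", w[1], cfg$bands, 3L, gain = 1)
  })
  as.list(st)
}

unet_build <- function(tp, P, cfg, xid) {
  d <- featdim(tp_val(tp, xid))
  if (d[1] %% 2^cfg$n_stages != 0 || d[2] %% 2^cfg$n_stages != 0)
    stop(sprintf("input size %dx%d is not divisible by 2^%d",
                 d[1], d[2], cfg$n_stages))
  f <- fwd_conv(tp, P, "head", xid, 3L)
  skips <- integer(cfg$n_stages)
  for (i in seq_len(cfg$n_stages)) {
    f <- op_relu(tp, fwd_conv(tp, P, sprintf("enc%d.c1", i), f, 3L))
    f <- op_relu(tp, fwd_conv(tp, P, sprintf("enc%d.c2", i), f, 3L))
    skips[i] <- f
    f <- fwd_conv(tp, P, sprintf("enc%d.down", i), f, 3L, stride = 2L, pad = 1L)
  }
  f <- op_relu(tp, fwd_conv(tp, P, "mid.c1", f, 3L))
  f <- op_relu(tp, fwd_conv(tp, P, "mid.c2", f, 3L))
  for (i in seq_len(cfg$n_stages)) {
    f <- fwd_convT2(tp, P, sprintf("dec%d.up", i), f)
    f <- fwd_conv(tp, P, sprintf("dec%d.fuse", i),
                  op_concat(tp, c(f, skips[cfg$n_stages + 1 - i])), 1L)
    f <- op_relu(tp, fwd_conv(tp, P, sprintf("dec%d.c1", i), f, 3L))
    f <- op_relu(tp, fwd_conv(tp, P, sprintf("dec%d.c2", i), f, 3L))
  }
  fwd_conv(tp, P, "tail", f, 3L)
}

#' Plain U-Net baseline forward pass
#'
#' The attention-free encoder-decoder baseline that predicts reflectance
#' from the sample RGB alone (no light input, no attention, no physics
#' fusion).
#'
#' @param params from the baseline initialiser (see [srnet()] with
#'   `variant = "baseline_unet"`).
#' @param cfg a baseline configuration.
#' @param x `[H,W,3]` or `[H,W,3,N]` array.
#' @export
baseline_unet_forward <- function(params, cfg, x) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- unet_build(tp, params, cfg, op_input(tp, x4))
  val <- tp_val(tp, out)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  val
}
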