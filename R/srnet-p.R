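#' Configuration of the spectral upsampling network (P branch)
#'
#' A U-Net-like encoder-decoder that maps an object RGB image to its
#' radiance cube. Each encoder stage applies `lgf_counts[1]` local-global
#' fusion blocks then a stride-2 convolution that doubles the width; the
#' bottleneck applies `lgf_counts[2]` blocks; each decoder stage upsamples
#' with a 2x2 transposed convolution, concatenates the dual-stat-attention
#' gated encoder skip, fuses with a 1x1 convolution and applies
#' `lgf_counts[3]` blocks. A final 3x3 convolution maps back to `bands`
#' channels and the RGB input, lifted to `bands` channels by a fixed linear
#' map, is added as a residual.
#'
#' @param bands number of output spectral bands B.
#' @param base_width encoder width at full resolution; doubles per stage.
#' @param n_stages number N of down/upsampling stages (input size must be
#'   divisible by `2^n_stages`).
#' @param lgf_counts integer triple (K1, K2, K3): blocks per encoder stage,
#'   bottleneck, and decoder stage.
#' @param use_dsa gate skip connections with dual-stat attention; `FALSE`
#'   replaces the gates by the identity (the no-DSA ablation, structurally
#'   identical otherwise).
#' @param use_lgf `FALSE` replaces every LGF block by a plain residual 3x3
#'   convolution (the no-LGF ablation).
#' @param in_channels input channel count (3 for RGB).
#' @export
srp_config <- function(bands, base_width = 32, n_stages = 3,
                       lgf_counts = c(2, 2, 2), use_dsa = TRUE,
                       use_lgf = TRUE, in_channels = 3) {
  stopifnot(n_stages >= 1, base_width >= 1, bands >= 2,
            length(lgf_counts) == 3, all(lgf_counts >= 1))
  structure(list(bands = as.integer(bands), base_width = as.integer(base_width),
                 n_stages = as.integer(n_stages),
                 lgf_counts = as.integer(lgf_counts),
                 use_dsa = isTRUE(use_dsa), use_lgf = isTRUE(use_lgf),
                 in_channels = as.integer(in_channels),
                 lift = make_lift_matrix(as.integer(in_channels),
                                         as.integer(bands))),
            class = "srp_config")
}

# fixed linear lift of the 3-channel input onto B bands: triangular weights
# placing R, G, B influence at long, middle, short wavelengths
make_lift_matrix <- function(cin, bands) {
  t <- if (bands > 1) (seq_len(bands) - 1) / (bands - 1) else 0.5
  centers <- c(0.70, 0.47, 0.20)[seq_len(min(cin, 3))]
  if (cin > 3) centers <- seq(0.8, 0.2, length.out = cin)
  L <- 1 - abs(outer(centers, t, "-")) / 0.3  # cin x bands
  L[L < 0] <- 0
  L
}

srp_widths <- function(cfg) cfg$base_width * 2^(0:cfg$n_stages)

#' Initialise parameters of the P branch
#'
#' @param cfg an [srp_config()].
#' @param seed integer seed pinning every weight draw.
#' @return a named list of parameter arrays.
#' @export
srp_init <- function(cfg, seed = 1) {
  st <- new.env()
  w <- srp_widths(cfg)
  blk_init <- if (cfg$use_lgf) init_lgf else init_plainconv_block
  with_seed(seed, {
    pinit_conv(st, "head", cfg$in_channels, w[1], 3L, gain = 1)
    for (i in seq_len(cfg$n_stages)) {
      for (k in seq_len(cfg$lgf_counts[1]))
        blk_init(st, sprintf("enc%d.blk%d", i, k), w[i])
      pinit_conv(st, sprintf("enc%d.down", i), w[i], w[i + 1], 3L, gain = 1)
    }
    for (k in seq_len(cfg$lgf_counts[2]))
      blk_init(st, sprintf("mid.blk%d", k), w[cfg$n_stages + 1])
    for (i in seq_len(cfg$n_stages)) {
      wi <- w[cfg$n_stages + 1 - i]
      pinit_convT2(st, sprintf("dec%d.up", i), 2L * wi, wi)
      if (cfg$use_dsa) init_dsa(st, sprintf("dec%d.dsa", i), wi)
      pinit_conv(st, sprintf("dec%d.fuse", i), 2L * wi, wi, 1L, gain = 1)
      for (k in seq_len(cfg$lgf_counts[3]))
        blk_init(st, sprintf("dec%d.blk%d", i, k), wi)
    }
    pinit_conv(st, "tail", w[1], cfg$bands, 3L, gain = 1)
  })
  as.list(st)
}

srp_build <- function(tp, P, cfg, xid) {
  d <- featdim(tp_val(tp, xid))
  if (d[1] %% 2^cfg$n_stages != 0 || d[2] %% 2^cfg$n_stages != 0)
    stop(sprintf("input size %dx%d is not divisible by 2^%d",
                 d[1], d[2], cfg$n_stages))
  blk <- if (cfg$use_lgf) fwd_lgf else fwd_plainconv_block
  f <- fwd_conv(tp, P, "head", xid, 3L)
  skips <- integer(cfg$n_stages)
  for (i in seq_len(cfg$n_stages)) {
    for (k in seq_len(cfg$lgf_counts[1]))
      f <- blk(tp, P, sprintf("enc%d.blk%d", i, k), f)
    skips[i] <- f
    f <- fwd_conv(tp, P, sprintf("enc%d.down", i), f, 3L, stride = 2L, pad = 1L)
  }
  for (k in seq_len(cfg$lgf_counts[2]))
    f <- blk(tp, P, sprintf("mid.blk%d", k), f)
  for (i in seq_len(cfg$n_stages)) {
    f <- fwd_convT2(tp, P, sprintf("dec%d.up", i), f)
    sk <- skips[cfg$n_stages + 1 - i]
    if (cfg$use_dsa) sk <- fwd_dsa(tp, P, sprintf("dec%d.dsa", i), sk)
    f <- fwd_conv(tp, P, sprintf("dec%d.fuse", i), op_concat(tp, c(f, sk)), 1L)
    for (k in seq_len(cfg$lgf_counts[3]))
      f <- blk(tp, P, sprintf("dec%d.blk%d", i, k), f)
  }
  out <- fwd_conv(tp, P, "tail", f, 3L)
  op_add(tp, out, op_fixed_lift(tp, xid, cfg$lift))
}

#' Forward pass of the P branch
#'
#' Maps an RGB batch to a radiance cube batch. Deterministic given
#' parameters and input.
#'
#' @param params from [srp_init()].
#' @param cfg an [srp_config()].
#' @param x `[H,W,3]` or `[H,W,3,N]` array; H and W must be divisible by
#'   `2^n_stages`.
#' @return `[H,W,B]` or `[H,W,B,N]` array.
#' @export
srp_forward <- function(params, cfg, x) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- srp_build(tp, params, cfg, op_input(tp, x4))
  val <- tp_val(tp, out)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  val
}
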