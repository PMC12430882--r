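# Parameter initialisation and tape builders for the shared feature blocks.
# Convolution weights are (k*k*Cin) x Cout with He scaling; dense weights
# Cout x Cin. Initialisation order is fixed so a seed pins every draw.

# gain 2 (He) for layers feeding a ReLU, gain 1 (Glorot-like) otherwise so
# untrained activations keep unit scale through deep stacks
pinit_conv <- function(st, name, cin, cout, k, gain = 2) {
  fan <- cin * k * k
  st[[paste0(name, ".W")]] <- matrix(stats::rnorm(fan * cout, sd = sqrt(gain / fan)),
                                     fan, cout)
  st[[paste0(name, ".b")]] <- numeric(cout)
}

pinit_convT2 <- function(st, name, cin, cout, gain = 1) {
  st[[paste0(name, ".W")]] <- matrix(stats::rnorm(cin * 4 * cout,
                                                  sd = sqrt(gain / cin)),
                                     cin, 4 * cout)
  st[[paste0(name, ".b")]] <- numeric(cout)
}

pinit_dense <- function(st, name, cin, cout, gain = 2) {
  st[[paste0(name, ".W")]] <- matrix(stats::rnorm(cout * cin, sd = sqrt(gain / cin)),
                                     cout, cin)
  st[[paste0(name, ".b")]] <- numeric(cout)
}

fwd_conv <- function(tp, P, name, x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  op_conv(tp, x, op_param(tp, P, paste0(name, ".W")),
          op_param(tp, P, paste0(name, ".b")), k, stride, pad)
}

fwd_convT2 <- function(tp, P, name, x) {
  op_convT2(tp, x, op_param(tp, P, paste0(name, ".W")),
            op_param(tp, P, paste0(name, ".b")))
}

fwd_dense <- function(tp, P, name, x) {
  op_dense(tp, x, op_param(tp, P, paste0(name, ".W")),
           op_param(tp, P, paste0(name, ".b")))
}

# ---- channel attention ----
# global average pool, then a small bottleneck shared across channels maps
# each channel's pooled mean to its gate; sharing keeps the gate
# permutation-equivariant (identical channels get identical gates)

init_ca <- function(st, name, C) {
  pinit_dense(st, paste0(name, ".fc1"), 1L, 4L)
  pinit_dense(st, paste0(name, ".fc2"), 4L, 1L, gain = 1)
}

fwd_ca <- function(tp, P, name, x) {
  d <- featdim(tp_val(tp, x))
  g <- op_reshape(tp, op_gap(tp, x), c(1L, d[3] * d[4]))
  h <- op_relu(tp, fwd_dense(tp, P, paste0(name, ".fc1"), g))
  gate <- op_sigmoid(tp, fwd_dense(tp, P, paste0(name, ".fc2"), h))
  op_scale_channels(tp, x, op_reshape(tp, gate, c(d[3], d[4])))
}

# ---- spatial attention: channel mean/max maps -> 3x3 conv -> sigmoid ----

init_sa <- function(st, name) {
  pinit_conv(st, paste0(name, ".conv"), 2L, 1L, 3L, gain = 1)
}

fwd_sa <- function(tp, P, name, x) {
  s <- op_pix_stats(tp, x)
  gate <- op_sigmoid(tp, fwd_conv(tp, P, paste0(name, ".conv"), s, 3L))
  op_scale_spatial(tp, x, gate)
}

# ---- dual-stat attention ----
# each channel's (spatial mean, spatial std) pair goes through a two-layer
# bottleneck shared across channels; sigmoid output gates that channel

init_dsa <- function(st, name, C) {
  pinit_dense(st, paste0(name, ".fc1"), 2L, 4L)
  pinit_dense(st, paste0(name, ".fc2"), 4L, 1L, gain = 1)
}

fwd_dsa <- function(tp, P, name, x) {
  d <- featdim(tp_val(tp, x))
  s <- op_chan_stats(tp, x)
  h <- op_relu(tp, fwd_dense(tp, P, paste0(name, ".fc1"), s))
  gate <- op_sigmoid(tp, fwd_dense(tp, P, paste0(name, ".fc2"), h))
  op_scale_channels(tp, x, op_reshape(tp, gate, c(d[3], d[4])))
}

# ---- local-global fusion block (residual) ----
# local path: 3x3 convolution; global path: pooled context vector through a
# dense layer, broadcast back; fusion: concat + 1x1 convolution; residual add.

init_lgf <- function(st, name, C) {
  pinit_conv(st, paste0(name, ".local"), C, C, 3L)
  pinit_dense(st, paste0(name, ".ctx"), C, C)
  pinit_conv(st, paste0(name, ".fuse"), 2L * C, C, 1L, gain = 1)
}

fwd_lgf <- function(tp, P, name, x) {
  d <- featdim(tp_val(tp, x))
  loc <- op_relu(tp, fwd_conv(tp, P, paste0(name, ".local"), x, 3L))
  ctx <- op_relu(tp, fwd_dense(tp, P, paste0(name, ".ctx"), op_gap(tp, x)))
  glo <- op_chanvec_broadcast(tp, ctx, d[1], d[2])
  fused <- fwd_conv(tp, P, paste0(name, ".fuse"), op_concat(tp, c(loc, glo)), 1L)
  op_add(tp, x, fused)
}

# plain-convolution stand-in used by the no-LGF ablation (same residual form)
init_plainconv_block <- function(st, name, C) {
  pinit_conv(st, paste0(name, ".local"), C, C, 3L)
}

fwd_plainconv_block <- function(tp, P, name, x) {
  op_add(tp, x, op_relu(tp, fwd_conv(tp, P, paste0(name, ".local"), x, 3L)))
}

# ---- L-block: attention path plus projected shortcut ----

init_lblock <- function(st, name, C) {
  pinit_conv(st, paste0(name, ".conv"), C, C, 3L)
  init_ca(st, paste0(name, ".ca"), C)
  init_sa(st, paste0(name, ".sa"))
  pinit_conv(st, paste0(name, ".short"), C, C, 1L, gain = 1)
}

fwd_lblock <- function(tp, P, name, x) {
  att <- op_relu(tp, fwd_conv(tp, P, paste0(name, ".conv"), x, 3L))
  att <- fwd_ca(tp, P, paste0(name, ".ca"), att)
  att <- fwd_sa(tp, P, paste0(name, ".sa"), att)
  short <- fwd_conv(tp, P, paste0(name, ".short"), x, 1L)
  op_add(tp, short, att)
}

# ---- exported single-shot wrappers over the tape builders ----

as_feat4 <- function(x) {
  x <- as.array(x)
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4) stop("expected a [H,W,C] or [H,W,C,N] array")
  x
}

run_block <- function(x, params, builder) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- builder(tp, params, op_input(tp, x4))
  val <- tp_val(tp, out)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  val
}

#' Local-global fusion block
#'
#' Residual feature block combining a local 3x3 convolution path with a
#' globally pooled context vector broadcast back over the image, fused by a
#' 1x1 convolution: `out = x + fuse(local(x), global(x))`. Shape preserving;
#' with the fusion weights set to zero the block is the identity.
#'
#' @param x a `[H,W,C]` or `[H,W,C,N]` feature array.
#' @param params parameters from [lgf_params()] matching `C`.
#' @return an array of the same shape.
#' @export
lgf_block <- function(x, params) {
  run_block(x, params, function(tp, P, xid) fwd_lgf(tp, P, "lgf", xid))
}

#' @rdname lgf_block
#' @param channels feature width C.
#' @param seed integer seed for the weight draw.
#' @export
lgf_params <- function(channels, seed = 1) {
  st <- new.env()
  with_seed(seed, init_lgf(st, "lgf", as.integer(channels)))
  as.list(st)
}

#' Dual-stat attention gate
#'
#' Per-channel multiplicative gate in (0, 1) computed from each channel's
#' spatial mean and standard deviation through a two-layer bottleneck
#' (shared across channels, so identical channels receive identical gates)
#' with sigmoid output; applied to skip-connection features in the spectral
#' upsampling network.
#'
#' @inheritParams lgf_block
#' @return the gated array, with the gate matrix (C x N) in attribute
#'   `"gates"`.
#' @export
dsa_gate <- function(x, params) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- fwd_dsa(tp, params, "dsa", op_input(tp, x4))
  val <- tp_val(tp, out)
  gates <- tp_val(tp, tp$n - 1L)  # sigmoid node precedes the scaling node
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  attr(val, "gates") <- gates
  val
}

#' @rdname dsa_gate
#' @inheritParams lgf_params
#' @export
dsa_params <- function(channels, seed = 1) {
  st <- new.env()
  with_seed(seed, init_dsa(st, "dsa", as.integer(channels)))
  as.list(st)
}

#' Channel attention
#'
#' Squeeze-style gate: global average pooling followed by a channel-shared
#' two-layer bottleneck and a sigmoid produce one weight in (0, 1) per
#' channel, applied multiplicatively.
#'
#' @inheritParams dsa_gate
#' @export
channel_attention <- function(x, params) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- fwd_ca(tp, params, "ca", op_input(tp, x4))
  val <- tp_val(tp, out)
  gates <- tp_val(tp, tp$n - 1L)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  attr(val, "gates") <- gates
  val
}

#' @rdname channel_attention
#' @inheritParams lgf_params
#' @export
ca_params <- function(channels, seed = 1) {
  st <- new.env()
  with_seed(seed, init_ca(st, "ca", as.integer(channels)))
  as.list(st)
}

#' Spatial attention
#'
#' Per-pixel gate in (0, 1) from the channel-pooled mean and max maps
#' through a 3x3 convolution and sigmoid, applied multiplicatively across
#' all channels.
#'
#' @inheritParams dsa_gate
#' @export
spatial_attention <- function(x, params) {
  x4 <- as_feat4(x)
  tp <- new_tape()
  out <- fwd_sa(tp, params, "sa", op_input(tp, x4))
  val <- tp_val(tp, out)
  gates <- tp_val(tp, tp$n - 1L)
  if (length(dim(as.array(x))) == 3) dim(val) <- dim(val)[1:3]
  attr(val, "gates") <- gates
  val
}

#' @rdname spatial_attention
#' @param seed integer seed for the weight draw.
#' @export
sa_params <- function(seed = 1) {
  st <- new.env()
  with_seed(seed, init_sa(st, "sa"))
  as.list(st)
}

#' Residual attention unit (L-block)
#'
#' `out = shortcut_projection(x) + SA(CA(relu(conv3x3(x))))` -- the
#' recursive unit of the attention network, with a 1x1 projected shortcut.
#'
#' @inheritParams lgf_block
#' @export
l_block <- function(x, params) {
  run_block(x, params, function(tp, P, xid) fwd_lblock(tp, P, "lb", xid))
}

#' @rdname l_block
#' @inheritParams lgf_params
#' @export
lblock_params <- function(channels, seed = 1) {
  st <- new.env()
  with_seed(seed, init_lblock(st, "lb", as.integer(channels)))
  as.list(st)
}

#' Count trainable parameters
#'
#' @param params a named list of parameter arrays (any network's).
#' @return total number of scalar parameters.
#' @export
count_params <- function(params) {
  sum(vapply(params, length, numeric(1)))
}
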