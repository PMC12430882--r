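# Reverse-mode tape: the package's compact CNN engine.
#
# Feature maps are column-major arrays [H, W, C, N]. Every op pushes a node
# holding its value and a backward closure that maps the output gradient to
# gradients for its parent nodes. Convolutions go through im2col (C++) and
# BLAS matrix multiplication; layout shuffles and broadcast gates are C++.
# Parameters enter the tape as leaves, registered by name so Adam can match
# gradients back to the parameter list.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$back <- list()
  tp$parents <- list()
  tp$n <- 0L
  tp$param_ids <- list()   # scoped name -> node id
  tp$scope <- ""           # prefix distinguishing subnetwork instances
  tp
}

tp_push <- function(tp, val, parents = NULL, back = NULL) {
  n <- tp$n + 1L
  tp$n <- n
  tp$vals[[n]] <- val
  tp$back[n] <- list(back)
  tp$parents[n] <- list(parents)
  n
}

tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

op_input <- function(tp, val) tp_push(tp, val)

# parameter leaf, deduplicated by scoped name
op_param <- function(tp, params, name) {
  key <- paste0(tp$scope, name)
  id <- tp$param_ids[[key]]
  if (!is.null(id)) return(id)
  if (is.null(params[[name]])) stop("unknown parameter: ", name)
  id <- tp_push(tp, params[[name]])
  tp$param_ids[[key]] <- id
  id
}

# accumulate output gradients backward; returns list name -> gradient array
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    bk <- tp$back[[id]]
    if (is.null(g) || is.null(bk)) next
    gs <- bk(g)
    ps <- tp$parents[[id]]
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  out <- list()
  for (name in names(tp$param_ids)) {
    g <- grads[[tp$param_ids[[name]]]]
    if (!is.null(g)) out[[name]] <- g
  }
  out
}

featdim <- function(v) {
  d <- dim(v)
  if (length(d) != 4) stop("expected a [H,W,C,N] feature map")
  d
}

add_bias_cols <- function(y, b) y + rep(b, each = nrow(y))

# k x k convolution, stride s, zero padding p; weight (k*k*Cin) x Cout.
# Backward recomputes the im2col patches from x inside the fused C++
# kernel (reused scratch) instead of caching them on the tape.
op_conv <- function(tp, xid, wid, bid, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  force(xid); force(wid); force(bid)
  x <- tp$vals[[xid]]; W <- tp$vals[[wid]]; b <- tp$vals[[bid]]
  d <- featdim(x)
  # direct convolution when the GEMM would do little work per im2col byte
  # (narrow output), BLAS-backed im2col otherwise
  direct <- k > 1L && ncol(W) <= 8L
  val <- if (direct) conv_fwd_direct(x, W, b, d[1], d[2], d[3], d[4], k, stride, pad)
    else conv_fwd_gemm(x, W, b, d[1], d[2], d[3], d[4], k, stride, pad)
  back <- function(dy) {
    r <- if (direct) conv_bwd_direct(x, W, dy, d[1], d[2], d[3], d[4], k, stride, pad)
      else conv_bwd_gemm(x, W, dy, d[1], d[2], d[3], d[4], k, stride, pad)
    list(r$dx, r$dW, r$db)
  }
  tp_push(tp, val, parents = c(xid, wid, bid), back = back)
}

# 2x2 stride-2 transposed convolution; weight Cin x (4*Cout), columns
# ordered (dh, dw, cout)
op_convT2 <- function(tp, xid, wid, bid) {
  force(xid); force(wid); force(bid)
  x <- tp$vals[[xid]]; W <- tp$vals[[wid]]; b <- tp$vals[[bid]]
  d <- featdim(x)
  val <- convT2_fwd(x, W, b, d[1], d[2], d[3], d[4])
  back <- function(dy) {
    r <- convT2_bwd(x, W, dy, d[1], d[2], d[3], d[4])
    list(r$dx, r$dW, r$db)
  }
  tp_push(tp, val, parents = c(xid, wid, bid), back = back)
}

op_relu <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  mask <- x > 0
  val <- x * mask
  tp_push(tp, val, parents = xid, back = function(dy) list(dy * mask))
}

op_sigmoid <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  val <- 1 / (1 + exp(-x))
  tp_push(tp, val, parents = xid, back = function(dy) list(dy * val * (1 - val)))
}

op_add <- function(tp, aid, bid) {
  force(aid); force(bid)
  val <- tp$vals[[aid]] + tp$vals[[bid]]
  tp_push(tp, val, parents = c(aid, bid), back = function(dy) list(dy, dy))
}

# concatenate feature maps along the channel axis
op_concat <- function(tp, ids) {
  force(ids)
  xs <- lapply(ids, function(i) tp$vals[[i]])
  ds <- lapply(xs, featdim)
  H <- ds[[1]][1]; W <- ds[[1]][2]; N <- ds[[1]][4]
  Cs <- vapply(ds, function(d) d[3], numeric(1))
  val <- array(0, c(H, W, sum(Cs), N))
  off <- 0L
  for (j in seq_along(xs)) {
    val[, , off + seq_len(Cs[j]), ] <- xs[[j]]
    off <- off + Cs[j]
  }
  back <- function(dy) {
    out <- vector("list", length(ids))
    off <- 0L
    for (j in seq_along(ids)) {
      out[[j]] <- dy[, , off + seq_len(Cs[j]), , drop = FALSE]
      off <- off + Cs[j]
    }
    out
  }
  tp_push(tp, val, parents = ids, back = back)
}

# global average pool -> C x N matrix
op_gap <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- featdim(x)
  val <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  back <- function(dy) {
    dx <- array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
    list(dx)
  }
  tp_push(tp, val, parents = xid, back = back)
}

# per-channel spatial mean and standard deviation, one column per
# (channel, sample): a 2 x (C*N) matrix so channelwise maps can share
# weights across channels
op_chan_stats <- function(tp, xid, eps = 1e-5) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- featdim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3] * d[4])
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  sd_ <- sqrt(pmax(va, 0) + eps)
  val <- rbind(mu, sd_)
  back <- function(dy) {
    dmu <- dy[1, ]
    dsd <- dy[2, ]
    centered <- xm - rep(mu, each = hw)
    dxm <- rep(dmu / hw, each = hw) +
      centered * rep(dsd / (hw * sd_), each = hw)
    list(array(dxm, d))
  }
  tp_push(tp, val, parents = xid, back = back)
}

# metadata-only reshape of a matrix/array node
op_reshape <- function(tp, xid, dims) {
  force(xid)
  x <- tp$vals[[xid]]
  olddim <- dim(x)
  val <- x
  dim(val) <- dims
  back <- function(dy) {
    dim(dy) <- olddim
    list(dy)
  }
  tp_push(tp, val, parents = xid, back = back)
}

# dense layer on a (Cin x N) matrix: W (Cout x Cin), b length Cout
op_dense <- function(tp, xid, wid, bid) {
  force(xid); force(wid); force(bid)
  x <- tp$vals[[xid]]; W <- tp$vals[[wid]]; b <- tp$vals[[bid]]
  val <- W %*% x + b
  back <- function(dy) {
    list(crossprod(W, dy), tcrossprod(dy, x), rowSums(dy))
  }
  tp_push(tp, val, parents = c(xid, wid, bid), back = back)
}

# multiply feature map by per-channel gate (C x N)
op_scale_channels <- function(tp, xid, gid) {
  force(xid); force(gid)
  x <- tp$vals[[xid]]; g <- tp$vals[[gid]]
  d <- featdim(x)
  val <- scale_channels_fwd(x, g, d[1], d[2], d[3], d[4])
  back <- function(dy) {
    r <- scale_channels_bwd(dy, x, g, d[1], d[2], d[3], d[4])
    list(r$dx, r$dg)
  }
  tp_push(tp, val, parents = c(xid, gid), back = back)
}

# broadcast a channel vector (C x N) to a feature map of given spatial size
op_chanvec_broadcast <- function(tp, gid, H, W) {
  force(gid)
  g <- tp$vals[[gid]]
  C <- nrow(g); N <- ncol(g)
  val <- array(rep(as.vector(g), each = H * W), c(H, W, C, N))
  back <- function(dy) {
    list(matrix(colSums(matrix(dy, H * W, C * N)), C, N))
  }
  tp_push(tp, val, parents = gid, back = back)
}

# per-pixel channel mean and max -> [H, W, 2, N]
op_pix_stats <- function(tp, xid) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- featdim(x)
  r <- pix_stats_fwd(x, d[1], d[2], d[3], d[4])
  back <- function(dy) {
    list(pix_stats_bwd(dy, r$amax, d[1], d[2], d[3], d[4]))
  }
  tp_push(tp, r$value, parents = xid, back = back)
}

# multiply feature map by a spatial gate [H, W, 1, N]
op_scale_spatial <- function(tp, xid, sid) {
  force(xid); force(sid)
  x <- tp$vals[[xid]]; s <- tp$vals[[sid]]
  d <- featdim(x)
  val <- scale_spatial_fwd(x, s, d[1], d[2], d[3], d[4])
  back <- function(dy) {
    r <- scale_spatial_bwd(dy, x, s, d[1], d[2], d[3], d[4])
    list(r$dx, r$ds)
  }
  tp_push(tp, val, parents = c(xid, sid), back = back)
}

# fixed (non-trained) linear lift of channels: L is Cin x Cout
op_fixed_lift <- function(tp, xid, L) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- featdim(x)
  xm <- feat_to_mat(x, d[1], d[2], d[3], d[4])
  val <- mat_to_feat(xm %*% L, d[1], d[2], ncol(L), d[4])
  back <- function(dy) {
    dym <- feat_to_mat(dy, d[1], d[2], ncol(L), d[4])
    list(mat_to_feat(tcrossprod(dym, L), d[1], d[2], d[3], d[4]))
  }
  tp_push(tp, val, parents = xid, back = back)
}

# mean squared error against a constant target
op_mse <- function(tp, xid, target) {
  force(xid)
  x <- tp$vals[[xid]]
  diff <- x - target
  m <- length(x)
  val <- sum(diff^2) / m
  back <- function(dy) list(dy * 2 * diff / m)
  tp_push(tp, val, parents = xid, back = back)
}

# weighted sum of scalar nodes
op_wsum <- function(tp, ids, weights) {
  force(ids)
  val <- 0
  for (j in seq_along(ids)) val <- val + weights[j] * tp$vals[[ids[j]]]
  back <- function(dy) as.list(dy * weights)
  tp_push(tp, val, parents = ids, back = back)
}
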