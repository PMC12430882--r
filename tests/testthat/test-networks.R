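set.seed(100)
x432 <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
tgt <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))

test_that("feature blocks preserve shape on arbitrary sizes", {
  for (d in list(c(5, 7, 3, 1), c(8, 4, 6, 2))) {
    set.seed(d[1])
    x <- array(rnorm(prod(d)), d)
    expect_equal(dim(lgf_block(x, lgf_params(d[3]))), d)
    expect_equal(dim(dsa_gate(x, dsa_params(d[3]))), d)
    expect_equal(dim(channel_attention(x, ca_params(d[3]))), d)
    expect_equal(dim(spatial_attention(x, sa_params())), d)
    expect_equal(dim(l_block(x, lblock_params(d[3]))), d)
  }
})

test_that("the LGF block is the identity when its fusion weights are zero", {
  p <- lgf_params(3, seed = 2)
  p$lgf.fuse.W[] <- 0
  p$lgf.fuse.b[] <- 0
  expect_equal(lgf_block(x432, p), x432)
})

test_that("attention gates are sigmoid-bounded and permutation-consistent", {
  # two identical channels receive identical gates
  xeq <- x432
  xeq[, , 2, ] <- xeq[, , 1, ]
  for (fetch in list(function(x) attr(dsa_gate(x, dsa_params(3, 4)), "gates"),
                     function(x) attr(channel_attention(x, ca_params(3, 4)),
                                      "gates"))) {
    g <- fetch(xeq)
    expect_equal(g[1, ], g[2, ])
    expect_true(all(g > 0 & g < 1))
  }
  # spatial gates are bounded and, away from the zero-padded border,
  # uniform on spatially constant input
  xc <- array(rep(c(1, 2, 3), each = 36), c(6, 6, 3, 1))
  gs <- attr(spatial_attention(xc, sa_params(3)), "gates")
  expect_true(all(gs > 0 & gs < 1))
  inner <- gs[2:5, 2:5, 1, 1]
  expect_equal(max(inner) - min(inner), 0, tolerance = 1e-12)
})

test_that("a constant channel (zero spatial std) produces finite DSA output", {
  xc <- array(1, c(4, 4, 3, 2))
  out <- dsa_gate(xc, dsa_params(3, 5))
  expect_true(all(is.finite(out)))
  expect_true(all(attr(out, "gates") > 0 & attr(out, "gates") < 1))
})

test_that("channel and spatial attention are nonlinear in their input scale", {
  set.seed(7)
  x <- array(runif(4 * 4 * 3, 0.5, 1.5), c(4, 4, 3, 1))
  g1 <- attr(channel_attention(x, ca_params(3, 6)), "gates")
  g2 <- attr(channel_attention(2 * x, ca_params(3, 6)), "gates")
  expect_gt(max(abs(g1 - g2)), 1e-6)
  s1 <- attr(spatial_attention(x, sa_params(6)), "gates")
  s2 <- attr(spatial_attention(2 * x, sa_params(6)), "gates")
  expect_gt(max(abs(s1 - s2)), 1e-6)
})

test_that("the L-block reduces to its projected shortcut with a zeroed path", {
  p <- lblock_params(3, seed = 8)
  p$lb.conv.W[] <- 0
  p$lb.conv.b[] <- 0
  out <- l_block(x432, p)
  # attention path is zero (relu of zero), so only the 1x1 shortcut remains
  tp <- sf$new_tape()
  short <- sf$fwd_conv(tp, p, "lb.short", sf$op_input(tp, x432), 1L)
  expect_equal(out, sf$tp_val(tp, short))
})

test_that("analytic gradients of every block match finite differences", {
  blocks <- list(
    lgf = function(tp, xid) {
      y <- sf$fwd_lgf(tp, lgf_params(3, 2), "lgf", xid)
      sf$op_mse(tp, y, tgt)
    },
    dsa = function(tp, xid) {
      y <- sf$fwd_dsa(tp, dsa_params(3, 2), "dsa", xid)
      sf$op_mse(tp, y, tgt)
    },
    ca = function(tp, xid) {
      y <- sf$fwd_ca(tp, ca_params(3, 2), "ca", xid)
      sf$op_mse(tp, y, tgt)
    },
    sa = function(tp, xid) {
      y <- sf$fwd_sa(tp, sa_params(2), "sa", xid)
      sf$op_mse(tp, y, tgt)
    },
    lblock = function(tp, xid) {
      y <- sf$fwd_lblock(tp, lblock_params(3, 2), "lb", xid)
      sf$op_mse(tp, y, tgt)
    })
  for (nm in names(blocks))
    expect_lt(tape_gradcheck(blocks[[nm]], x432), 1e-6)
})

test_that("the P branch meets its shape, determinism and symmetry contracts", {
  cfg <- srp_config(16, base_width = 4, n_stages = 3)
  p <- srp_init(cfg, 1)
  set.seed(9)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y1 <- srp_forward(p, cfg, x)
  expect_equal(dim(y1), c(32, 32, 16, 2))   # decoder restores H x W exactly
  expect_identical(y1, srp_forward(p, cfg, x))  # bit-identical rerun
  expect_true(all(is.finite(y1)))
  # spatial size not divisible by 2^N is refused
  xb <- array(runif(20 * 20 * 3), c(20, 20, 3))
  expect_error(srp_forward(p, cfg, xb), "divisible")
  # single-sample 3D input round-trips without a batch axis
  y3 <- srp_forward(p, cfg, x[, , , 1])
  expect_equal(dim(y3), c(32, 32, 16))
  expect_equal(y3, y1[, , , 1])
})

test_that("disabling DSA keeps the layer structure and drops only the gates", {
  full <- srp_init(srp_config(8, base_width = 4), 3)
  nodsa <- srp_init(srp_config(8, base_width = 4, use_dsa = FALSE), 3)
  expect_setequal(setdiff(names(full), names(nodsa)),
                  grep("\\.dsa\\.", names(full), value = TRUE))
  expect_gt(length(grep("\\.dsa\\.", names(full))), 0)
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- srp_config(16, base_width = 4)
  expect_equal(count_params(srp_init(cfg, 1)), count_params(srp_init(cfg, 99)))
  cfgl <- srl_config(3, 16, width = 4, n_blocks = 2)
  expect_equal(count_params(srl_init(cfgl, 1)), count_params(srl_init(cfgl, 2)))
})

test_that("the L branch honours both roles' channel contracts", {
  g <- 16L
  light_cfg <- srl_config(3, g, width = 4, n_blocks = 2)
  dec_cfg <- srl_config(2L * g, g, width = 4, n_blocks = 2)
  lp <- srl_init(light_cfg, 1)
  dp <- srl_init(dec_cfg, 2)
  set.seed(10)
  x3 <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  x32 <- array(runif(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  y <- srl_forward(lp, light_cfg, x3)
  expect_equal(dim(y), c(16, 16, 16, 2))
  expect_identical(y, srl_forward(lp, light_cfg, x3))
  yd <- srl_forward(dp, dec_cfg, x32)
  expect_equal(dim(yd), c(16, 16, 16, 2))
  # feeding the wrong width is refused
  expect_error(srl_forward(dp, dec_cfg, x3), "channels")
})

test_that("untrained networks stay finite across all built-in conditions", {
  ps <- scene_params(image_size = 16, bands = 8)
  resp <- default_camera_response(ps$grid)
  cfg <- srp_config(8, base_width = 4)
  p <- srp_init(cfg, 11)
  refl <- sample_reflectance_field(ps, 1)
  for (cond in builtin_conditions()) {
    pair <- render_pair(refl, cond, resp, 0, 1)
    y <- srp_forward(p, cfg, pair$sample_rgb$values / max(pair$light_rgb$values))
    expect_true(all(is.finite(y)))
    expect_equal(dim(y), c(16, 16, 8))
  }
})

test_that("the baseline U-Net keeps its shape and determinism contracts", {
  cfg <- sf$unet_config(8, base_width = 4)
  p <- sf$unet_init(cfg, 1)
  set.seed(12)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- baseline_unet_forward(p, cfg, x)
  expect_equal(dim(y), c(16, 16, 8, 2))
  expect_identical(y, baseline_unet_forward(p, cfg, x))
})
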