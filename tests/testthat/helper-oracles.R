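# Independent brute-force oracles and small fixtures shared by the suite.

sf <- asNamespace("specfusion")

# SSIM by explicit sliding-window loops (independent of the filter-matrix path)
bruteforce_ssim <- function(x, y, cfg) {
  k <- cfg$window_size
  kern1 <- if (cfg$window_kind == "uniform") rep(1 / k, k) else {
    r <- seq_len(k) - (k + 1) / 2
    w <- exp(-0.5 * (r / cfg$window_sigma)^2)
    w / sum(w)
  }
  w2 <- outer(kern1, kern1)
  vals <- numeric(0)
  for (i in seq_len(nrow(x) - k + 1)) {
    for (j in seq_len(ncol(x) - k + 1)) {
      wx <- x[i:(i + k - 1), j:(j + k - 1)]
      wy <- y[i:(i + k - 1), j:(j + k - 1)]
      mx <- sum(w2 * wx); my <- sum(w2 * wy)
      vx <- sum(w2 * wx^2) - mx^2
      vy <- sum(w2 * wy^2) - my^2
      cxy <- sum(w2 * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + cfg$C1) * (2 * cxy + cfg$C2)) /
                  ((mx^2 + my^2 + cfg$C1) * (vx + vy + cfg$C2)))
    }
  }
  mean(vals)
}

# camera projection by explicit triple loop
bruteforce_render <- function(cube_vals, sens) {
  d <- dim(cube_vals)
  out <- array(0, c(d[1], d[2], 3))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (ch in 1:3)
        out[i, j, ch] <- sum(cube_vals[i, j, ] * sens[ch, ])
  out
}

# analytic-vs-numeric gradient of a scalar tape program with respect to its
# input array; returns the max relative deviation
tape_gradcheck <- function(build, x, eps = 1e-6) {
  tp <- sf$new_tape()
  xid <- sf$op_input(tp, x)
  lid <- build(tp, xid)
  grads <- vector("list", tp$n)
  grads[[lid]] <- 1
  for (id in seq(tp$n, 1)) {
    gi <- grads[[id]]
    bk <- tp$back[[id]]
    if (is.null(gi) || is.null(bk)) next
    gs <- bk(gi)
    ps <- tp$parents[[id]]
    for (j in seq_along(ps)) {
      if (is.null(gs[[j]])) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) gs[[j]] else grads[[p]] + gs[[j]]
    }
  }
  ana <- grads[[xid]]
  f <- function(xx) {
    tp2 <- sf$new_tape()
    sf$tp_val(tp2, build(tp2, sf$op_input(tp2, xx)))
  }
  num <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  max(abs(ana - num)) / max(1e-8, max(abs(num)))
}

tiny_grid <- function(B = 4) wavelength_grid(n = B, from = 400, to = 700)

random_cube <- function(seed, h = 4, w = 5, B = 4, kind = "reflectance",
                        lo = 0, hi = 1) {
  set.seed(seed)
  spectral_cube(array(runif(h * w * B, lo, hi), c(h, w, B)), tiny_grid(B),
                kind = kind)
}

random_response <- function(seed, B = 4) {
  set.seed(seed)
  camera_response(matrix(runif(3 * B), 3, B), tiny_grid(B))
}

# independent minimal ENVI reader used as the cross-reader oracle
independent_envi_read <- function(path) {
  hdr <- readLines(paste0(sub("\\.[^./]*$", "", path), ".hdr"))
  grab <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    as.numeric(sub(".*= *", "", ln))
  }
  samples <- grab("samples"); lines_ <- grab("lines"); bands <- grab("bands")
  wl_line <- paste(hdr[grep("wavelength *= *\\{", hdr):length(hdr)], collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_line), ",")[[1]])
  vals <- readBin(path, "double", n = samples * lines_ * bands, size = 8,
                  endian = "little")
  arr <- array(0, c(lines_, samples, bands))
  for (b in seq_len(bands))
    arr[, , b] <- matrix(vals[(b - 1) * samples * lines_ + seq_len(samples * lines_)],
                         lines_, samples, byrow = TRUE)
  list(values = arr, wavelength = wl)
}

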