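# Internal 1-D CNN primitives.
#
# Activations are 3-D arrays of dim (L, B, C): signal length x batch x
# channels, so a length-fastest memory layout that lets im2col slices and
# channel matrices map onto BLAS matrix products without aperm() calls.
# Convolution weights are (k*C_in, C_out) matrices with row index
# (tap-1)*C_in + channel; fully connected weights are (in, out).

conv_fwd <- function(a, W, b, k) {
  d <- dim(a); L <- d[1L]; B <- d[2L]; C <- d[3L]
  pad <- (k - 1L) %/% 2L
  padded <- array(0, c(L + 2L * pad, B, C))
  padded[pad + seq_len(L), , ] <- a
  cols <- vector("list", k)
  for (t in seq_len(k)) {
    s <- padded[(t - 1L) + seq_len(L), , , drop = FALSE]
    dim(s) <- c(L * B, C)
    cols[[t]] <- s
  }
  xcol <- do.call(cbind, cols)                   # (L*B, k*C)
  out <- xcol %*% W
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(L, B, ncol(W))
  list(out = out, xcol = xcol, dims = c(L, B, C))
}

conv_bwd <- function(dout, cache, W, k) {
  L <- cache$dims[1L]; B <- cache$dims[2L]; C <- cache$dims[3L]
  pad <- (k - 1L) %/% 2L
  dmat <- dout
  dim(dmat) <- c(L * B, dim(W)[2L])
  dW <- crossprod(cache$xcol, dmat)
  db <- colSums(dmat)
  dxcol <- tcrossprod(dmat, W)                   # (L*B, k*C)
  dpad <- array(0, c(L + 2L * pad, B, C))
  for (t in seq_len(k)) {
    blk <- dxcol[, (t - 1L) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(L, B, C)
    idx <- (t - 1L) + seq_len(L)
    dpad[idx, , ] <- dpad[idx, , , drop = FALSE] + blk
  }
  list(da = dpad[pad + seq_len(L), , , drop = FALSE], dW = dW, db = db)
}

pool_fwd <- function(a, p) {
  d <- dim(a); L <- d[1L]; B <- d[2L]; C <- d[3L]
  Lo <- L %/% p
  M <- matrix(0, Lo * B * C, p)
  for (j in seq_len(p)) M[, j] <- a[seq.int(j, L, by = p), , , drop = FALSE]
  idx <- max.col(M, ties.method = "first")
  out <- M[cbind(seq_len(nrow(M)), idx)]
  dim(out) <- c(Lo, B, C)
  list(out = out, idx = idx, L = L)
}

pool_bwd <- function(dout, cache, p) {
  d <- dim(dout); Lo <- d[1L]; B <- d[2L]; C <- d[3L]
  Z <- matrix(0, Lo * B * C, p)
  Z[cbind(seq_along(cache$idx), cache$idx)] <- dout
  da <- array(0, c(cache$L, B, C))
  for (j in seq_len(p)) {
    blk <- Z[, j]
    dim(blk) <- c(Lo, B, C)
    da[seq.int(j, cache$L, by = p), , ] <- blk
  }
  da
}

# (Lf, B, C) -> (B, Lf*C) feature matrix; order = length index fastest
flatten_fwd <- function(a) {
  d <- dim(a)
  x <- aperm(a, c(1L, 3L, 2L))
  dim(x) <- c(d[1L] * d[3L], d[2L])
  list(out = t(x), dims = d)
}

flatten_bwd <- function(dout, dims) {
  x <- t(dout)
  dim(x) <- c(dims[1L], dims[3L], dims[2L])
  aperm(x, c(1L, 3L, 2L))
}

fc_fwd <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

# softmax cross-entropy over rows of scores; y in {0,1} indexes class y+1
softmax_xent <- function(scores, y) {
  B <- nrow(scores)
  m <- apply(scores, 1L, max)
  z <- exp(scores - m)
  s <- rowSums(z)
  prob <- z / s
  picked <- prob[cbind(seq_len(B), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dscores <- prob
  dscores[cbind(seq_len(B), y + 1L)] <-
    dscores[cbind(seq_len(B), y + 1L)] - 1
  list(loss = loss, dscores = dscores / B, prob = prob)
}

# Xavier/Glorot uniform init, the conventional choice for Tanh networks
init_net <- function(config, init_seed) {
  k <- config$kernel_size
  ch <- c(1L, config$conv_channels)
  flat <- config$conv_channels[4L] * config$input_len %/% config$pool_size^4
  widths <- c(flat, config$fc_widths, config$n_out)
  with_seed(init_seed, {
    conv <- lapply(seq_len(4L), function(i) {
      fan_in <- k * ch[i]; fan_out <- k * ch[i + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * ch[i + 1L], -lim, lim),
                      fan_in, ch[i + 1L]),
           b = numeric(ch[i + 1L]))
    })
    fc <- lapply(seq_len(length(widths) - 1L), function(i) {
      lim <- sqrt(6 / (widths[i] + widths[i + 1L]))
      list(W = matrix(stats::runif(widths[i] * widths[i + 1L], -lim, lim),
                      widths[i], widths[i + 1L]),
           b = numeric(widths[i + 1L]))
    })
    list(conv = conv, fc = fc)
  })
}

net_param_total <- function(net) {
  sum(vapply(c(net$conv, net$fc),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

# Full forward pass. x: (B, input_len) matrix of segments.
# Returns scores (B, n_out) and, if keep_cache, everything backprop needs.
net_forward <- function(net, x, config, keep_cache = FALSE) {
  B <- nrow(x)
  a <- t(x)
  dim(a) <- c(config$input_len, B, 1L)
  k <- config$kernel_size; p <- config$pool_size
  caches <- if (keep_cache) vector("list", 4L)
  for (i in seq_len(4L)) {
    cv <- conv_fwd(a, net$conv[[i]]$W, net$conv[[i]]$b, k)
    h <- tanh(cv$out)
    pl <- pool_fwd(h, p)
    a <- pl$out
    if (keep_cache)
      caches[[i]] <- list(conv = cv, tanh_out = h, pool = pl)
  }
  fl <- flatten_fwd(a)
  z <- fl$out
  nfc <- length(net$fc)
  fc_in <- if (keep_cache) vector("list", nfc)
  fc_act <- if (keep_cache) vector("list", nfc)
  for (i in seq_len(nfc)) {
    if (keep_cache) fc_in[[i]] <- z
    z <- fc_fwd(z, net$fc[[i]]$W, net$fc[[i]]$b)
    if (i < nfc) {
      z <- tanh(z)
      if (keep_cache) fc_act[[i]] <- z
    }
  }
  if (!keep_cache) return(list(scores = z))
  list(scores = z, caches = caches, flatten_dims = fl$dims,
       fc_in = fc_in, fc_act = fc_act)
}

# Backward pass from dscores; returns gradients shaped like the net.
net_backward <- function(net, fwd, dscores, config) {
  k <- config$kernel_size; p <- config$pool_size
  nfc <- length(net$fc)
  gfc <- vector("list", nfc)
  dz <- dscores
  for (i in rev(seq_len(nfc))) {
    gfc[[i]] <- list(W = crossprod(fwd$fc_in[[i]], dz), b = colSums(dz))
    dz <- tcrossprod(dz, net$fc[[i]]$W)
    if (i > 1L) dz <- dz * (1 - fwd$fc_act[[i - 1L]]^2)
  }
  da <- flatten_bwd(dz, fwd$flatten_dims)
  gconv <- vector("list", 4L)
  for (i in rev(seq_len(4L))) {
    ca <- fwd$caches[[i]]
    dh <- pool_bwd(da, ca$pool, p)
    dh <- dh * (1 - ca$tanh_out^2)
    bw <- conv_bwd(dh, ca$conv, net$conv[[i]]$W, k)
    gconv[[i]] <- list(W = bw$dW, b = bw$db)
    da <- bw$da
  }
  list(conv = gconv, fc = gfc)
}
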