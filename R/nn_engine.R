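# Compact CNN engine used by the interaction classifier.
#
# Tensors are R arrays with dims (N, H, W, C), column-major. Convolutions are
# BLAS-backed im2col GEMMs whose gather indices are precomputed at build time
# (input shapes are fixed per model). A "conv layer" here is the composite
# convolution -> batch normalization -> PReLU -> dropout; no conv bias is
# used since batch norm's shift absorbs it.
#
# All functions are pure: layers carrying updated batch-norm running stats
# are returned alongside outputs and must be reassigned by the caller.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- convolution layer -----------------------------------------------------

# Precompute output geometry and im2col gather indices for a fixed input
# shape. Only height padding ("same"-style, needed by the stride-1 in-block
# layers so concatenation shapes align) is supported; first layers and the
# fusion layer run unpadded.
conv_plan <- function(H, W, C, kh, kw, sh, sw, dil, pad_h) {
  eff_kh <- (kh - 1L) * dil + 1L
  eff_kw <- (kw - 1L) * dil + 1L
  if (pad_h) {
    total <- eff_kh - 1L
    pl <- total %/% 2L
    pr <- total - pl
  } else {
    pl <- 0L; pr <- 0L
  }
  Hp <- H + pl + pr
  if (Hp < eff_kh || W < eff_kw) {
    stopf("build error: kernel (%d,%d) with dilation %d does not fit input (%d,%d)",
          kh, kw, dil, H, W)
  }
  oh <- (Hp - eff_kh) %/% sh + 1L
  ow <- (W - eff_kw) %/% sw + 1L
  h_off <- (seq_len(kh) - 1L) * dil
  w_off <- (seq_len(kw) - 1L) * dil
  patchlen <- kh * kw * C
  he <- rep(h_off, times = kw * C)
  we <- rep(rep(w_off, each = kh), times = C)
  ce <- rep(seq_len(C), each = kh * kw)
  h0 <- rep((seq_len(oh) - 1L) * sh, times = ow)
  w0 <- rep((seq_len(ow) - 1L) * sw, each = oh)
  base <- he + 1L + Hp * we + Hp * W * (ce - 1L)
  idx <- outer(base, h0 + Hp * w0, "+")  # patchlen x K
  list(H = H, W = W, C = C, Hp = Hp, pad_left = pl, oh = oh, ow = ow,
       K = oh * ow, patchlen = patchlen, idx = idx, idxv = as.vector(idx),
       kernel = c(kh, kw), stride = c(sh, sw), dilation = dil, pad_h = pad_h)
}

conv_build <- function(H, W, C, filters, kernel, stride, dilation = 1L,
                       pad_h = FALSE, dropout = 0.2, prelu_init = 0.25) {
  plan <- conv_plan(H, W, C, kernel[1], kernel[2], stride[1], stride[2],
                    dilation, pad_h)
  sdW <- sqrt(2 / plan$patchlen)
  list(
    type = "conv", filters = as.integer(filters), plan = plan,
    dropout = dropout,
    W = matrix(rnorm(plan$patchlen * filters, sd = sdW), plan$patchlen, filters),
    gamma = rep(1, filters), beta = rep(0, filters),
    alpha = rep(prelu_init, filters),
    rmean = rep(0, filters), rvar = rep(1, filters)
  )
}

conv_out_shape <- function(layer) c(layer$plan$oh, layer$plan$ow, layer$filters)

rep_each <- function(v, m) rep(v, each = m)

conv_forward <- function(layer, X, train) {
  pl <- layer$plan
  N <- dim(X)[1]
  if (pl$pad_left > 0 || pl$Hp > pl$H) {
    Xp <- array(0, c(N, pl$Hp, pl$W, pl$C))
    Xp[, (pl$pad_left + 1):(pl$pad_left + pl$H), , ] <- X
  } else {
    Xp <- X
  }
  dim(Xp) <- c(N, pl$Hp * pl$W * pl$C)
  A <- Xp[, pl$idxv, drop = FALSE]
  dim(A) <- c(N, pl$patchlen, pl$K)
  B <- aperm(A, c(1, 3, 2))
  dim(B) <- c(N * pl$K, pl$patchlen)
  Z <- B %*% layer$W
  m <- nrow(Z)
  if (train) {
    mu <- colMeans(Z)
    zc <- Z - rep_each(mu, m)
    v <- colMeans(zc * zc)
    sd <- sqrt(v + BN_EPS)
    Zhat <- zc / rep_each(sd, m)
    layer$rmean <- BN_MOMENTUM * layer$rmean + (1 - BN_MOMENTUM) * mu
    layer$rvar <- BN_MOMENTUM * layer$rvar + (1 - BN_MOMENTUM) * v
  } else {
    sd <- sqrt(layer$rvar + BN_EPS)
    Zhat <- (Z - rep_each(layer$rmean, m)) / rep_each(sd, m)
  }
  U <- rep_each(layer$gamma, m) * Zhat + rep_each(layer$beta, m)
  P <- pmax(U, 0) + rep_each(layer$alpha, m) * pmin(U, 0)
  mask <- NULL
  if (train && layer$dropout > 0) {
    mask <- (runif(length(P)) >= layer$dropout) / (1 - layer$dropout)
    P <- P * mask
  }
  out <- array(P, c(N, pl$oh, pl$ow, layer$filters))
  cache <- if (train) list(B = B, Zhat = Zhat, sd = sd, U = U, mask = mask, N = N) else NULL
  list(out = out, cache = cache, layer = layer)
}

conv_backward <- function(layer, cache, dY, need_dx = TRUE) {
  pl <- layer$plan
  N <- cache$N
  m <- N * pl$K
  dP <- dY
  dim(dP) <- c(m, layer$filters)
  if (!is.null(cache$mask)) dP <- dP * cache$mask
  neg <- cache$U < 0
  aU <- rep_each(layer$alpha, m)
  dU <- dP * (1 + (aU - 1) * neg)
  dalpha <- colSums(dP * cache$U * neg)
  dgamma <- colSums(dU * cache$Zhat)
  dbeta <- colSums(dU)
  dZhat <- dU * rep_each(layer$gamma, m)
  dZ <- (dZhat - rep_each(colMeans(dZhat), m) -
           cache$Zhat * rep_each(colMeans(dZhat * cache$Zhat), m)) /
    rep_each(cache$sd, m)
  dW <- crossprod(cache$B, dZ)
  grads <- list(W = dW, gamma = dgamma, beta = dbeta, alpha = dalpha)
  if (!need_dx) return(list(dX = NULL, grads = grads))
  dBm <- tcrossprod(dZ, layer$W)       # (N*K) x patchlen
  dim(dBm) <- c(N, pl$K, pl$patchlen)
  dA <- aperm(dBm, c(1, 3, 2))         # N x patchlen x K
  dXmat <- matrix(0, N, pl$Hp * pl$W * pl$C)
  for (j in seq_len(pl$patchlen)) {
    cols <- pl$idx[j, ]
    dXmat[, cols] <- dXmat[, cols] + dA[, j, ]
  }
  dXp <- array(dXmat, c(N, pl$Hp, pl$W, pl$C))
  dX <- if (pl$Hp > pl$H) {
    dXp[, (pl$pad_left + 1):(pl$pad_left + pl$H), , , drop = FALSE]
  } else {
    dXp
  }
  list(dX = dX, grads = grads)
}

# ---- dense (fully connected) layer ----------------------------------------

dense_build <- function(n_in, n_out, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "dense", activation = activation,
       W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / max(n_in, 1))), n_in, n_out),
       b = rep(0, n_out))
}

dense_forward <- function(layer, X) {
  Z <- X %*% layer$W + rep_each(layer$b, nrow(X))
  out <- if (layer$activation == "relu") pmax(Z, 0) else Z
  list(out = out, cache = list(X = X, Z = Z))
}

dense_backward <- function(layer, cache, dY) {
  dZ <- if (layer$activation == "relu") dY * (cache$Z > 0) else dY
  list(dX = tcrossprod(dZ, layer$W),
       grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
}

# ---- global average pooling ------------------------------------------------

gap_forward <- function(X) {
  d <- dim(X)
  Xr <- X; dim(Xr) <- c(d[1], d[2] * d[3], d[4])
  Xp <- aperm(Xr, c(2, 1, 3))
  dim(Xp) <- c(d[2] * d[3], d[1] * d[4])
  out <- matrix(colMeans(Xp), d[1], d[4])
  list(out = out, dims = d)
}

gap_backward <- function(dY, dims) {
  K <- dims[2] * dims[3]
  tmp <- matrix(rep(as.vector(dY) / K, each = K), K, dims[1] * dims[4])
  dim(tmp) <- c(K, dims[1], dims[4])
  dX <- aperm(tmp, c(2, 1, 3))
  dim(dX) <- dims
  dX
}

# ---- channel concatenation -------------------------------------------------

concat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- array(0, c(d1[1], d1[2], d1[3], sum(cs)))
  off <- 0L
  for (x in xs) {
    k <- dim(x)[4]
    out[, , , (off + 1):(off + k)] <- x
    off <- off + k
  }
  out
}

split_channels <- function(x, sizes) {
  off <- 0L
  lapply(sizes, function(k) {
    sl <- x[, , , (off + 1):(off + k), drop = FALSE]
    off <<- off + k
    sl
  })
}

# ---- dense block (4 conv layers with concatenative skip connections) -------

# Layer 1 is the block's entry transform (modality-specific kernel/stride,
# unpadded). Layers 2-4 run at the entry layer's spatial resolution with
# kernel (3,1), stride (1,1), height-preserving padding, and each receives
# the channel concatenation of all previous layers' outputs. The block
# output concatenates all four layers' outputs.
block_build <- function(H, W, C, kernel1, stride1, filters, dilations,
                        dropout, prelu_init) {
  stopifnot(length(filters) == length(dilations))
  layers <- vector("list", length(filters))
  layers[[1]] <- conv_build(H, W, C, filters[1], kernel1, stride1,
                            dilation = dilations[1], pad_h = FALSE,
                            dropout = dropout, prelu_init = prelu_init)
  os <- conv_out_shape(layers[[1]])
  for (k in seq_along(filters)[-1]) {
    in_ch <- sum(filters[seq_len(k - 1)])
    layers[[k]] <- conv_build(os[1], os[2], in_ch, filters[k],
                              kernel = c(3L, 1L), stride = c(1L, 1L),
                              dilation = dilations[k], pad_h = TRUE,
                              dropout = dropout, prelu_init = prelu_init)
  }
  list(layers = layers, filters = filters,
       out_shape = c(os[1], os[2], sum(filters)))
}

block_forward <- function(block, X, train) {
  nl <- length(block$layers)
  outs <- vector("list", nl)
  caches <- vector("list", nl)
  for (k in seq_len(nl)) {
    input <- if (k == 1) X else if (k == 2) outs[[1]] else {
      concat_channels(outs[seq_len(k - 1)])
    }
    r <- conv_forward(block$layers[[k]], input, train)
    outs[[k]] <- r$out
    caches[[k]] <- r$cache
    block$layers[[k]] <- r$layer
  }
  list(out = concat_channels(outs), caches = caches, block = block)
}

block_backward <- function(block, caches, dOut) {
  nl <- length(block$layers)
  f <- block$filters
  dparts <- split_channels(dOut, f)
  grads <- vector("list", nl)
  for (k in rev(seq_len(nl))) {
    # the gradient w.r.t. the block input is never consumed (inputs are
    # data), so layer 1 skips its input-scatter
    r <- conv_backward(block$layers[[k]], caches[[k]], dparts[[k]],
                       need_dx = k > 1)
    grads[[k]] <- r$grads
    if (k == 1) {
      dX <- r$dX
    } else {
      dIn <- split_channels(r$dX, f[seq_len(k - 1)])
      for (j in seq_len(k - 1)) dparts[[j]] <- dparts[[j]] + dIn[[j]]
    }
  }
  list(dX = dX, grads = grads)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}
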