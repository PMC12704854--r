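# Minimal neural-network layer library with hand-written forward/backward
# passes. All parameters live in flat named lists of numeric arrays; each
# layer's backward consumes the cache produced by its forward. Correctness is
# guarded by finite-difference gradient checks in the test suite.

addrow <- function(X, b) X + rep(b, each = nrow(X))

linear_fwd <- function(X, W, b) {
  list(out = addrow(X %*% W, b), X = X)
}
linear_bwd <- function(G, cache, W) {
  list(dX = G %*% t(W), dW = crossprod(cache$X, G), db = colSums(G))
}

relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_bwd <- function(G, cache) G * cache$mask

# quick-GELU (sigmoid form): x * sigmoid(1.702 x); C++ kernels
gelu_fwd <- function(X) {
  f <- .cpp_gelu_fwd(X)
  list(out = f$out, s = f$s, X = X)
}
gelu_bwd <- function(G, cache) .cpp_gelu_bwd(G, cache$X, cache$s)

sigmoid_fwd <- function(X) {
  s <- 1 / (1 + exp(-X))
  list(out = s, s = s)
}
sigmoid_bwd <- function(G, cache) G * cache$s * (1 - cache$s)

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  list(out = addrow(sweep(xhat, 2, g, `*`), b), xhat = xhat, istd = istd)
}
layernorm_bwd <- function(G, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(G, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dX = dX, dg = colSums(G * xhat), db = colSums(G))
}

# Batch normalisation over rows (training-mode batch statistics); used in
# the contrastive projection head, where per-batch centring is what keeps
# the InfoNCE objective away from its collapsed fixed point.
batchnorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  list(out = addrow(sweep(xhat, 2, g, `*`), b), xhat = xhat, istd = istd)
}
batchnorm_bwd <- function(G, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(G, 2, g, `*`)
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * xhat)
  dX <- sweep(sweep(dxhat, 2, s1) - sweep(xhat, 2, s2, `*`), 2,
              cache$istd, `*`)
  list(dX = dX, dg = colSums(G * xhat), db = colSums(G))
}

softmax_rows <- function(S) {
  E <- exp(S - max(S)) # global shift suffices for stability here
  E / rowSums(E)
}

# ---- convolution via im2col -------------------------------------------------

# Index map for one image: rows = output positions (row-major over Ho x Wo),
# cols = kernel taps x input channels; entries index the zero-padded flat
# array (channel-major: c(Hp, Wp, C)).
conv_index <- function(h, w, cin, k, stride, pad) {
  hp <- h + 2 * pad; wp <- w + 2 * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  orow <- rep(seq_len(ho), times = wo)
  ocol <- rep(seq_len(wo), each = ho)
  base_r <- (orow - 1L) * stride
  base_c <- (ocol - 1L) * stride
  idx <- matrix(0L, ho * wo, k * k * cin)
  j <- 0L
  for (c in seq_len(cin)) {
    off_c <- (c - 1L) * hp * wp
    for (kc in seq_len(k)) {
      for (kr in seq_len(k)) {
        j <- j + 1L
        idx[, j] <- off_c + (base_c + kc - 1L) * hp + base_r + kr
      }
    }
  }
  list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
}

pad_image <- function(x, pad) {
  # x: h x w x c -> padded flat vector, channel-major
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  if (pad == 0) return(as.vector(x))
  out <- array(0, dim = c(h + 2 * pad, w + 2 * pad, cin))
  out[pad + seq_len(h), pad + seq_len(w), ] <- x
  as.vector(out)
}

# X: B x H x W x Cin array; W: (k*k*Cin) x Cout; returns B x Ho x Wo x Cout.
conv_fwd <- function(X, W, b, stride = 1, pad = 1, imap = NULL) {
  dB <- dim(X)[1]; h <- dim(X)[2]; w <- dim(X)[3]; cin <- dim(X)[4]
  k <- as.integer(round(sqrt(nrow(W) / cin)))
  if (is.null(imap)) imap <- conv_index(h, w, cin, k, stride, pad)
  cols <- vector("list", dB)
  for (bi in seq_len(dB)) {
    flat <- pad_image(array(X[bi, , , ], dim = dim(X)[2:4]), pad)
    cols[[bi]] <- matrix(flat[imap$idx], nrow(imap$idx), ncol(imap$idx))
  }
  cols <- do.call(rbind, cols)
  outm <- addrow(cols %*% W, b)
  # rows of outm: position (row-major, row fastest) within image, then image
  out <- aperm(array(outm, dim = c(imap$ho, imap$wo, dB, ncol(W))), c(3, 1, 2, 4))
  list(out = out, cols = cols, imap = imap, in_dim = dim(X),
       stride = stride, pad = pad)
}

conv_bwd <- function(G, cache, W) {
  # G: B x Ho x Wo x Cout
  dB <- dim(G)[1]; cout <- dim(G)[4]
  imap <- cache$imap
  Gm <- matrix(aperm(G, c(2, 3, 1, 4)), ncol = cout) # rows match cols order
  dW <- crossprod(cache$cols, Gm)
  db <- colSums(Gm)
  dcols <- Gm %*% t(W)
  in_dim <- cache$in_dim
  h <- in_dim[2]; w <- in_dim[3]; cin <- in_dim[4]
  pad <- cache$pad
  hp <- imap$hp; wp <- imap$wp
  npos <- nrow(imap$idx)
  dX <- array(0, dim = in_dim)
  for (bi in seq_len(dB)) {
    dflat <- numeric(hp * wp * cin)
    block <- dcols[(bi - 1L) * npos + seq_len(npos), , drop = FALSE]
    for (j in seq_len(ncol(imap$idx))) {
      tgt <- imap$idx[, j]
      dflat[tgt] <- dflat[tgt] + block[, j]
    }
    dpad <- array(dflat, dim = c(hp, wp, cin))
    dX[bi, , , ] <- dpad[pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# Global average pool over spatial dims: B x H x W x C -> B x C.
gap_fwd <- function(X) {
  d <- dim(X)
  list(out = apply(X, c(1, 4), mean), d = d)
}
gap_bwd <- function(G, cache) {
  d <- cache$d
  sc <- 1 / (d[2] * d[3])
  dX <- array(0, dim = d)
  for (ci in seq_len(d[4])) dX[, , , ci] <- G[, ci] * sc
  dX
}

# Nearest-neighbour 2x spatial upsample and its adjoint.
upsample2_fwd <- function(X) {
  d <- dim(X)
  idx_r <- rep(seq_len(d[2]), each = 2)
  idx_c <- rep(seq_len(d[3]), each = 2)
  list(out = X[, idx_r, idx_c, , drop = FALSE], d = d)
}
upsample2_bwd <- function(G, cache) {
  d <- cache$d
  o1 <- seq(1, 2 * d[2], by = 2); o2 <- seq(1, 2 * d[3], by = 2)
  G[, o1, o2, , drop = FALSE] + G[, o1 + 1, o2, , drop = FALSE] +
    G[, o1, o2 + 1, , drop = FALSE] + G[, o1 + 1, o2 + 1, , drop = FALSE]
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params) sum(vapply(params, length, integer(1)))

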