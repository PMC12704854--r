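# Vision transformer trained through time (ViT-CoT family).
#
# The family convention couples width of attention to depth: the 1H model has
# one head and one transformer layer, 3H three of each, and so on. Patches
# are produced by a shared linear projection only — no convolutional layers —
# so no spatial prior beyond patching is hardcoded. Pre-LN blocks; the
# embedding readout is the mean over last-layer patch tokens after the final
# normalisation.

#' ViT-CoT configuration
#'
#' @param n_layers Transformer layers; `n_heads` defaults to the same number
#'   (the 1H/3H/6H/9H convention).
#' @param n_heads Attention heads; `embed_dim` must be divisible by it.
#' @param patch_size Patch side in pixels (default 8).
#' @param image_size Input image side (default 64); must be divisible by
#'   `patch_size`.
#' @param embed_dim Token/embedding width (default 128).
#' @param mlp_ratio Hidden width of the MLP block relative to `embed_dim`.
#' @return A `vit_config` list.
#' @export
vit_config <- function(n_layers = 3, n_heads = n_layers, patch_size = 8,
                       image_size = 64, embed_dim = 128, mlp_ratio = 4) {
  if (image_size %% patch_size != 0) {
    abort("image_size must be divisible by patch_size")
  }
  if (embed_dim %% n_heads != 0) {
    abort("embed_dim must be divisible by n_heads")
  }
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 patch_size = as.integer(patch_size),
                 image_size = as.integer(image_size),
                 embed_dim = as.integer(embed_dim), mlp_ratio = mlp_ratio),
            class = c("vit_config", "encoder_config"))
}

# images: list of H x W x 3 arrays -> (B*T) x (ps*ps*3) patch matrix,
# patches row-major within each image. The gather index is cached per
# (image size, patch size).
patch_index_cache <- new.env(parent = emptyenv())

patch_index <- function(size, ps) {
  key <- paste(size, ps)
  if (!is.null(patch_index_cache[[key]])) return(patch_index_cache[[key]])
  n_side <- size %/% ps
  Tn <- n_side * n_side
  P <- ps * ps * 3
  M <- matrix(0L, Tn, P)
  t <- 0L
  for (pr in seq_len(n_side)) {
    for (pc in seq_len(n_side)) {
      t <- t + 1L
      rows <- (pr - 1L) * ps + seq_len(ps)
      cols <- (pc - 1L) * ps + seq_len(ps)
      # column-major flat indices of img[rows, cols, 1:3]
      M[t, ] <- as.integer(outer(rows, (cols - 1L) * size, `+`)) +
        rep((0:2) * size * size, each = ps * ps)
    }
  }
  patch_index_cache[[key]] <- M
  M
}

patchify <- function(images, patch_size) {
  size <- dim(images[[1]])[1]
  M <- patch_index(size, patch_size)
  do.call(rbind, lapply(images, function(img) {
    matrix(img[M], nrow(M), ncol(M))
  }))
}

vit_init <- function(cfg, seed = 1) {
  D <- cfg$embed_dim
  Tn <- (cfg$image_size %/% cfg$patch_size)^2
  P <- cfg$patch_size^2 * 3
  H <- as.integer(round(cfg$mlp_ratio * D))
  with_seed(derive_seed(seed, "vit-init"), {
    w <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list(W_patch = w(P, D), b_patch = numeric(D), pos = w(Tn, D))
    for (l in seq_len(cfg$n_layers)) {
      p[[paste0("ln1_g_", l)]] <- rep(1, D)
      p[[paste0("ln1_b_", l)]] <- numeric(D)
      p[[paste0("W_qkv_", l)]] <- w(D, 3 * D)
      p[[paste0("b_qkv_", l)]] <- numeric(3 * D)
      p[[paste0("W_o_", l)]] <- w(D, D)
      p[[paste0("b_o_", l)]] <- numeric(D)
      p[[paste0("ln2_g_", l)]] <- rep(1, D)
      p[[paste0("ln2_b_", l)]] <- numeric(D)
      p[[paste0("W_m1_", l)]] <- w(D, H)
      p[[paste0("b_m1_", l)]] <- numeric(H)
      p[[paste0("W_m2_", l)]] <- w(H, D)
      p[[paste0("b_m2_", l)]] <- numeric(D)
    }
    p$lnf_g <- rep(1, D)
    p$lnf_b <- numeric(D)
    p
  })
}

# Multi-head self-attention over per-image token blocks; the per-image
# softmax-attention loops run in C++ (src/attention.cpp).
mha_fwd <- function(X, W_qkv, b_qkv, W_o, b_o, B, Tn, n_heads) {
  D <- ncol(X)
  qkv <- linear_fwd(X, W_qkv, b_qkv)
  Q <- qkv$out[, seq_len(D), drop = FALSE]
  K <- qkv$out[, D + seq_len(D), drop = FALSE]
  V <- qkv$out[, 2 * D + seq_len(D), drop = FALSE]
  at <- .cpp_mha_fwd(Q, K, V, B, Tn, n_heads)
  proj <- linear_fwd(at$O, W_o, b_o)
  list(out = proj$out,
       cache = list(qkv = qkv, Q = Q, K = K, V = V, A = at$A, proj = proj,
                    B = B, Tn = Tn, n_heads = n_heads))
}

mha_bwd <- function(G, cache, W_qkv, W_o) {
  pb <- linear_bwd(G, cache$proj, W_o)
  gr <- .cpp_mha_bwd(pb$dX, cache$Q, cache$K, cache$V, cache$A,
                     cache$B, cache$Tn, cache$n_heads)
  qb <- linear_bwd(cbind(gr$dQ, gr$dK, gr$dV), cache$qkv, W_qkv)
  list(dX = qb$dX, dW_qkv = qb$dW, db_qkv = qb$db, dW_o = pb$dW, db_o = pb$db)
}

vit_forward <- function(params, cfg, images, want_cache = FALSE) {
  B <- length(images)
  Tn <- (cfg$image_size %/% cfg$patch_size)^2
  Xp <- patchify(images, cfg$patch_size)
  emb <- linear_fwd(Xp, params$W_patch, params$b_patch)
  X <- emb$out + params$pos[rep(seq_len(Tn), B), , drop = FALSE]
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    ln1 <- layernorm_fwd(X, params[[paste0("ln1_g_", l)]],
                         params[[paste0("ln1_b_", l)]])
    att <- mha_fwd(ln1$out, params[[paste0("W_qkv_", l)]],
                   params[[paste0("b_qkv_", l)]],
                   params[[paste0("W_o_", l)]], params[[paste0("b_o_", l)]],
                   B, Tn, cfg$n_heads)
    X1 <- X + att$out
    ln2 <- layernorm_fwd(X1, params[[paste0("ln2_g_", l)]],
                         params[[paste0("ln2_b_", l)]])
    m1 <- linear_fwd(ln2$out, params[[paste0("W_m1_", l)]],
                     params[[paste0("b_m1_", l)]])
    ge <- gelu_fwd(m1$out)
    m2 <- linear_fwd(ge$out, params[[paste0("W_m2_", l)]],
                     params[[paste0("b_m2_", l)]])
    X2 <- X1 + m2$out
    if (want_cache) {
      layers[[l]] <- list(ln1 = ln1, att = att$cache, ln2 = ln2, m1 = m1,
                          ge = ge, m2 = m2)
    }
    X <- X2
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  # mean over the image's patch tokens
  grp <- rep(seq_len(B), each = Tn)
  Z <- rowsum(lnf$out, grp) / Tn
  dimnames(Z) <- NULL
  cache <- if (want_cache) {
    list(emb = emb, layers = layers, lnf = lnf, B = B, Tn = Tn)
  }
  list(emb = Z, cache = cache)
}

vit_backward <- function(params, cfg, cache, dZ) {
  B <- cache$B; Tn <- cache$Tn
  grads <- list()
  dX <- (dZ / Tn)[rep(seq_len(B), each = Tn), , drop = FALSE]
  lb <- layernorm_bwd(dX, cache$lnf, params$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    m2b <- linear_bwd(dX, lc$m2, params[[paste0("W_m2_", l)]])
    geb <- gelu_bwd(m2b$dX, lc$ge)
    m1b <- linear_bwd(geb, lc$m1, params[[paste0("W_m1_", l)]])
    ln2b <- layernorm_bwd(m1b$dX, lc$ln2, params[[paste0("ln2_g_", l)]])
    dX1 <- dX + ln2b$dX
    attb <- mha_bwd(dX1, lc$att, params[[paste0("W_qkv_", l)]],
                    params[[paste0("W_o_", l)]])
    ln1b <- layernorm_bwd(attb$dX, lc$ln1, params[[paste0("ln1_g_", l)]])
    grads[[paste0("W_m2_", l)]] <- m2b$dW
    grads[[paste0("b_m2_", l)]] <- m2b$db
    grads[[paste0("W_m1_", l)]] <- m1b$dW
    grads[[paste0("b_m1_", l)]] <- m1b$db
    grads[[paste0("ln2_g_", l)]] <- ln2b$dg
    grads[[paste0("ln2_b_", l)]] <- ln2b$db
    grads[[paste0("W_qkv_", l)]] <- attb$dW_qkv
    grads[[paste0("b_qkv_", l)]] <- attb$db_qkv
    grads[[paste0("W_o_", l)]] <- attb$dW_o
    grads[[paste0("b_o_", l)]] <- attb$db_o
    grads[[paste0("ln1_g_", l)]] <- ln1b$dg
    grads[[paste0("ln1_b_", l)]] <- ln1b$db
    dX <- dX1 + ln1b$dX
  }
  grads$pos <- rowsum(dX, rep(seq_len(Tn), B))
  pe <- linear_bwd(dX, cache$emb, params$W_patch)
  grads$W_patch <- pe$dW
  grads$b_patch <- pe$db
  grads
}
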