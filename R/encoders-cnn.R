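# ResNet-10 trunk and the encoder families built on it: the contrastive CNN
# (SimCLR-CLTT), the convolutional autoencoder (encoder + mirrored upsampling
# decoder), and the gradient-isolated GreedyInfoMax CNN.
#
# The trunk has 10 trainable layers: a stem convolution, two stages of two
# residual basic blocks (two 3x3 convolutions each), and a linear embedding
# head; stage 2 halves resolution with a 1x1 bridge connection on its first
# block, mirroring the ResNet-18 family at reduced depth. The desk-scale
# variant is norm-free: residual branches are initialised small instead of
# batch-normalised, which keeps evaluation purely functional.

#' ResNet-10 configuration
#'
#' @param channels Stage widths, length 2 (default `c(64, 128)`).
#' @param embed_dim Embedding width (default 128).
#' @param image_size Input side in pixels (default 64).
#' @param bridge_connections Keep the 1x1 projection skip on the
#'   downsampling block (default TRUE).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(channels = c(64, 128), embed_dim = 128, image_size = 64,
                       bridge_connections = TRUE) {
  structure(list(depth = 10L, n_residual_blocks = 2L,
                 channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim),
                 image_size = as.integer(image_size),
                 bridge_connections = isTRUE(bridge_connections)),
            class = c("cnn_config", "encoder_config"))
}

#' Autoencoder configuration
#'
#' A ResNet-10 encoder with a mirrored nearest-neighbour-upsampling decoder;
#' after training the decoder is dropped and only encoder embeddings are
#' evaluated.
#'
#' @param encoder A [cnn_config()].
#' @return An `ae_config` list.
#' @export
ae_config <- function(encoder = cnn_config()) {
  structure(list(encoder = encoder), class = c("ae_config", "encoder_config"))
}

#' GreedyInfoMax configuration
#'
#' The 10-layer trunk split into gradient-isolated modules, each trained with
#' its own local contrastive loss on augmentation pairs (no temporal
#' learning); a gradient blocker stops backpropagation between modules.
#'
#' @param channels,embed_dim,image_size As in [cnn_config()].
#' @param module_partition List of layer spans; the default splits the trunk
#'   into two five-layer modules.
#' @param gradient_blocker Keep the blocker on (default TRUE; turning it off
#'   exists for negative-control testing).
#' @return A `gim_config` list.
#' @export
gim_config <- function(channels = c(64, 128), embed_dim = 128, image_size = 64,
                       module_partition = list(1:5, 6:10),
                       gradient_blocker = TRUE) {
  spans <- sort(unlist(module_partition))
  if (!identical(as.integer(spans), 1:10)) {
    abort("module_partition must cover layers 1..10 exactly once")
  }
  structure(list(depth = 10L, channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim),
                 image_size = as.integer(image_size),
                 module_partition = module_partition,
                 gradient_blocker = isTRUE(gradient_blocker)),
            class = c("gim_config", "encoder_config"))
}

conv_w <- function(k, cin, cout, gain = 1) {
  matrix(rnorm(k * k * cin * cout, sd = gain * sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

resnet_init <- function(cfg, seed = 1) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  with_seed(derive_seed(seed, "resnet-init"), {
    p <- list(
      stem_W = conv_w(3, 3, c1), stem_b = numeric(c1),
      b1a_W1 = conv_w(3, c1, c1), b1a_b1 = numeric(c1),
      b1a_W2 = conv_w(3, c1, c1, gain = 0.2), b1a_b2 = numeric(c1),
      b1b_W1 = conv_w(3, c1, c1), b1b_b1 = numeric(c1),
      b1b_W2 = conv_w(3, c1, c1, gain = 0.2), b1b_b2 = numeric(c1),
      b2a_W1 = conv_w(3, c1, c2), b2a_b1 = numeric(c2),
      b2a_W2 = conv_w(3, c2, c2, gain = 0.2), b2a_b2 = numeric(c2),
      bridge_W = conv_w(1, c1, c2), bridge_b = numeric(c2),
      b2b_W1 = conv_w(3, c2, c2), b2b_b1 = numeric(c2),
      b2b_W2 = conv_w(3, c2, c2, gain = 0.2), b2b_b2 = numeric(c2),
      fc_W = matrix(rnorm(c2 * cfg$embed_dim, sd = 0.05), c2, cfg$embed_dim),
      fc_b = numeric(cfg$embed_dim)
    )
    if (!cfg$bridge_connections) p$bridge_W <- NULL
    p
  })
}

basic_block_fwd <- function(X, W1, b1, W2, b2, stride = 1, bridge = NULL,
                            bridge_b = NULL) {
  c1 <- conv_fwd(X, W1, b1, stride = stride, pad = 1)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, W2, b2, stride = 1, pad = 1)
  skip <- if (!is.null(bridge)) {
    conv_fwd(X, bridge, bridge_b, stride = stride, pad = 0)
  }
  pre <- c2$out + if (is.null(skip)) X else skip$out
  r2 <- relu_fwd(pre)
  list(out = r2$out, cache = list(c1 = c1, r1 = r1, c2 = c2, skip = skip,
                                  r2 = r2))
}

basic_block_bwd <- function(G, cache, W1, W2, bridge = NULL) {
  dpre <- relu_bwd(G, cache$r2)
  cb2 <- conv_bwd(dpre, cache$c2, W2)
  dr1 <- relu_bwd(cb2$dX, cache$r1)
  cb1 <- conv_bwd(dr1, cache$c1, W1)
  out <- list(dW1 = cb1$dW, db1 = cb1$db, dW2 = cb2$dW, db2 = cb2$db)
  if (!is.null(cache$skip)) {
    sb <- conv_bwd(dpre, cache$skip, bridge)
    out$dbridge_W <- sb$dW; out$dbridge_b <- sb$db
    out$dX <- cb1$dX + sb$dX
  } else {
    out$dX <- cb1$dX + dpre
  }
  out
}

# First half of the trunk (layers 1-5): stem + stage 1.
resnet_half1_fwd <- function(params, X) {
  st <- conv_fwd(X, params$stem_W, params$stem_b, stride = 2, pad = 1)
  sr <- relu_fwd(st$out)
  bl1 <- basic_block_fwd(sr$out, params$b1a_W1, params$b1a_b1,
                         params$b1a_W2, params$b1a_b2)
  bl2 <- basic_block_fwd(bl1$out, params$b1b_W1, params$b1b_b1,
                         params$b1b_W2, params$b1b_b2)
  list(out = bl2$out, cache = list(st = st, sr = sr, bl1 = bl1, bl2 = bl2))
}

resnet_half1_bwd <- function(params, cache, dF) {
  g2 <- basic_block_bwd(dF, cache$bl2$cache, params$b1b_W1, params$b1b_W2)
  g1 <- basic_block_bwd(g2$dX, cache$bl1$cache, params$b1a_W1, params$b1a_W2)
  dsr <- relu_bwd(g1$dX, cache$sr)
  sb <- conv_bwd(dsr, cache$st, params$stem_W)
  list(stem_W = sb$dW, stem_b = sb$db,
       b1a_W1 = g1$dW1, b1a_b1 = g1$db1, b1a_W2 = g1$dW2, b1a_b2 = g1$db2,
       b1b_W1 = g2$dW1, b1b_b1 = g2$db1, b1b_W2 = g2$dW2, b1b_b2 = g2$db2)
}

# Second half (layers 6-10): stage 2 + embedding head.
resnet_half2_fwd <- function(params, F1) {
  bl3 <- basic_block_fwd(F1, params$b2a_W1, params$b2a_b1,
                         params$b2a_W2, params$b2a_b2, stride = 2,
                         bridge = params$bridge_W, bridge_b = params$bridge_b)
  bl4 <- basic_block_fwd(bl3$out, params$b2b_W1, params$b2b_b1,
                         params$b2b_W2, params$b2b_b2)
  gp <- gap_fwd(bl4$out)
  fc <- linear_fwd(gp$out, params$fc_W, params$fc_b)
  list(emb = fc$out, cache = list(bl3 = bl3, bl4 = bl4, gp = gp, fc = fc))
}

resnet_half2_bwd <- function(params, cache, dZ) {
  fb <- linear_bwd(dZ, cache$fc, params$fc_W)
  dmap <- gap_bwd(fb$dX, cache$gp)
  g4 <- basic_block_bwd(dmap, cache$bl4$cache, params$b2b_W1, params$b2b_W2)
  g3 <- basic_block_bwd(g4$dX, cache$bl3$cache, params$b2a_W1, params$b2a_W2,
                        bridge = params$bridge_W)
  grads <- list(fc_W = fb$dW, fc_b = fb$db,
                b2b_W1 = g4$dW1, b2b_b1 = g4$db1,
                b2b_W2 = g4$dW2, b2b_b2 = g4$db2,
                b2a_W1 = g3$dW1, b2a_b1 = g3$db1,
                b2a_W2 = g3$dW2, b2a_b2 = g3$db2,
                bridge_W = g3$dbridge_W, bridge_b = g3$dbridge_b)
  list(grads = grads, dF1 = g3$dX)
}

resnet_forward <- function(params, images, want_cache = FALSE) {
  X <- images_to_batch(images)
  h1 <- resnet_half1_fwd(params, X)
  h2 <- resnet_half2_fwd(params, h1$out)
  cache <- if (want_cache) list(h1 = h1$cache, h2 = h2$cache)
  list(emb = h2$emb, cache = cache)
}

resnet_backward <- function(params, cache, dZ) {
  b2 <- resnet_half2_bwd(params, cache$h2, dZ)
  g1 <- resnet_half1_bwd(params, cache$h1, b2$dF1)
  c(b2$grads, g1)
}

images_to_batch <- function(images) {
  d <- dim(images[[1]])
  X <- array(0, dim = c(length(images), d))
  for (i in seq_along(images)) X[i, , , ] <- images[[i]]
  X
}

# ---- autoencoder decoder ----------------------------------------------------

ae_init <- function(cfg, seed = 1) {
  enc <- resnet_init(cfg$encoder, seed)
  c1 <- cfg$encoder$channels[1]; c2 <- cfg$encoder$channels[2]
  D <- cfg$encoder$embed_dim
  s0 <- cfg$encoder$image_size %/% 8 # three 2x upsamplings back to full size
  dec <- with_seed(derive_seed(seed, "ae-dec-init"), {
    list(dec_fc_W = matrix(rnorm(D * s0 * s0 * c2, sd = 0.05), D, s0 * s0 * c2),
         dec_fc_b = numeric(s0 * s0 * c2),
         dec_W1 = conv_w(3, c2, c1), dec_b1 = numeric(c1),
         dec_W2 = conv_w(3, c1, c1), dec_b2 = numeric(c1),
         dec_W3 = conv_w(3, c1, 3), dec_b3 = numeric(3))
  })
  c(enc, dec)
}

ae_decode_fwd <- function(params, Z, cfg) {
  c1 <- cfg$encoder$channels[1]; c2 <- cfg$encoder$channels[2]
  s0 <- cfg$encoder$image_size %/% 8
  fc <- linear_fwd(Z, params$dec_fc_W, params$dec_fc_b)
  X0 <- array(fc$out, dim = c(nrow(Z), s0, s0, c2))
  u1 <- upsample2_fwd(X0)
  cv1 <- conv_fwd(u1$out, params$dec_W1, params$dec_b1, pad = 1)
  r1 <- relu_fwd(cv1$out)
  u2 <- upsample2_fwd(r1$out)
  cv2 <- conv_fwd(u2$out, params$dec_W2, params$dec_b2, pad = 1)
  r2 <- relu_fwd(cv2$out)
  u3 <- upsample2_fwd(r2$out)
  cv3 <- conv_fwd(u3$out, params$dec_W3, params$dec_b3, pad = 1)
  sg <- sigmoid_fwd(cv3$out)
  list(out = sg$out,
       cache = list(fc = fc, u1 = u1, cv1 = cv1, r1 = r1, u2 = u2, cv2 = cv2,
                    r2 = r2, u3 = u3, cv3 = cv3, sg = sg, n = nrow(Z)))
}

ae_decode_bwd <- function(params, cache, dOut) {
  dsg <- sigmoid_bwd(dOut, cache$sg)
  c3 <- conv_bwd(dsg, cache$cv3, params$dec_W3)
  du3 <- upsample2_bwd(c3$dX, cache$u3)
  dr2 <- relu_bwd(du3, cache$r2)
  c2b <- conv_bwd(dr2, cache$cv2, params$dec_W2)
  du2 <- upsample2_bwd(c2b$dX, cache$u2)
  dr1 <- relu_bwd(du2, cache$r1)
  c1b <- conv_bwd(dr1, cache$cv1, params$dec_W1)
  du1 <- upsample2_bwd(c1b$dX, cache$u1)
  fb <- linear_bwd(matrix(du1, cache$n), cache$fc, params$dec_fc_W)
  list(grads = list(dec_W3 = c3$dW, dec_b3 = c3$db,
                    dec_W2 = c2b$dW, dec_b2 = c2b$db,
                    dec_W1 = c1b$dW, dec_b1 = c1b$db,
                    dec_fc_W = fb$dW, dec_fc_b = fb$db),
       dZ = fb$dX)
}
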