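# Encoder construction, embedding extraction, analytic gradients and
# gradient isolation.

test_that("ViT configuration enforces divisibility and scales with depth", {
  expect_error(vit_config(patch_size = 7), "divisible")
  expect_error(vit_config(n_heads = 5, embed_dim = 32), "divisible")

  # parameter count strictly increases with depth at fixed width
  n <- vapply(c(1, 3, 6, 9), function(l) {
    build_encoder(vit_config(n_layers = l, n_heads = 1, embed_dim = 32),
                  seed = 1)$n_params
  }, numeric(1))
  expect_true(all(diff(n) > 0))

  # 64 px / patch 8 = 64 patch tokens
  enc <- fx_tiny_vit()
  imgs <- list(fx_seeded_image(1), fx_seeded_image(2))
  fw <- rearviews:::vit_forward(enc$params, enc$config, imgs,
                                want_cache = TRUE)
  expect_equal(nrow(fw$cache$lnf$xhat) / 2, (64 / 8)^2)

  # patch embedding is a single shared linear projection (no convolution):
  # one weight matrix of size (patch pixels) x embed_dim serves all positions
  expect_equal(dim(enc$params$W_patch), c(8 * 8 * 3, 16L))
})

test_that("embeddings are deterministic, order-preserving and duplicate-consistent", {
  enc <- fx_tiny_vit()
  imgs <- lapply(1:4, fx_seeded_image)
  Z <- embed(enc, imgs)
  expect_equal(dim(Z), c(4L, 16L))
  expect_identical(Z, embed(enc, imgs))

  # duplicated image gives identical rows
  Zd <- embed(enc, list(imgs[[1]], imgs[[1]], imgs[[3]]))
  expect_equal(Zd[1, ], Zd[2, ])

  # permuted batch permutes rows correspondingly
  perm <- c(3, 1, 4, 2)
  Zp <- embed(enc, imgs[perm])
  expect_equal(Zp, Z[perm, ], tolerance = 1e-12)

  expect_error(embed(enc, list(fx_seeded_image(1, 32))), "64 x 64")

  # CNN and AE embed through the same surface
  cnn <- build_encoder(cnn_config(channels = c(4, 6), embed_dim = 8,
                                  image_size = 32), seed = 2)
  imgs32 <- lapply(1:3, function(i) fx_seeded_image(i, 32))
  expect_equal(dim(embed(cnn, imgs32)), c(3L, 8L))
  ae <- build_encoder(ae_config(cnn_config(channels = c(4, 6), embed_dim = 8,
                                           image_size = 32)), seed = 2)
  expect_equal(dim(embed(ae, imgs32)), c(3L, 8L))
})

test_that("hand-written ViT gradients agree with finite differences", {
  cfg <- vit_config(n_layers = 2, n_heads = 2, patch_size = 8,
                    image_size = 16, embed_dim = 8, mlp_ratio = 2)
  enc <- build_encoder(cfg, seed = 7)
  imgs <- lapply(1:3, function(i) fx_seeded_image(i, 16))
  Wfix <- rearviews:::with_seed(1, matrix(rnorm(3 * 8), 3, 8))
  lossf <- function(p) sum(rearviews:::vit_forward(p, cfg, imgs)$emb * Wfix)
  fw <- rearviews:::vit_forward(enc$params, cfg, imgs, want_cache = TRUE)
  gr <- rearviews:::vit_backward(enc$params, cfg, fw$cache, Wfix)
  eps <- 1e-5
  rels <- c()
  for (nm in names(enc$params)) {
    p <- enc$params
    k <- rearviews:::with_seed(nchar(nm), sample(length(p[[nm]]), 1))
    p[[nm]][k] <- enc$params[[nm]][k] + eps; lp <- lossf(p)
    p[[nm]][k] <- enc$params[[nm]][k] - eps; lm <- lossf(p)
    fd <- (lp - lm) / (2 * eps)
    rels <- c(rels, abs(fd - gr[[nm]][k]) /
                max(1e-8, abs(fd) + abs(gr[[nm]][k])))
  }
  expect_lt(max(rels), 1e-4)
})

test_that("hand-written ResNet-10 gradients agree with finite differences", {
  cfg <- cnn_config(channels = c(4, 6), embed_dim = 5, image_size = 16)
  enc <- build_encoder(cfg, seed = 3)
  imgs <- lapply(1:2, function(i) fx_seeded_image(i, 16))
  Wfix <- rearviews:::with_seed(2, matrix(rnorm(2 * 5), 2, 5))
  lossf <- function(p) sum(rearviews:::resnet_forward(p, imgs)$emb * Wfix)
  fw <- rearviews:::resnet_forward(enc$params, imgs, want_cache = TRUE)
  gr <- rearviews:::resnet_backward(enc$params, fw$cache, Wfix)
  eps <- 1e-6
  rels <- c()
  for (nm in names(enc$params)) {
    p <- enc$params
    k <- rearviews:::with_seed(nchar(nm) + 7, sample(length(p[[nm]]), 1))
    p[[nm]][k] <- enc$params[[nm]][k] + eps; lp <- lossf(p)
    p[[nm]][k] <- enc$params[[nm]][k] - eps; lm <- lossf(p)
    fd <- (lp - lm) / (2 * eps)
    rels <- c(rels, abs(fd - gr[[nm]][k]) /
                max(1e-8, abs(fd) + abs(gr[[nm]][k])))
  }
  # median guards against finite differences straddling a ReLU kink
  expect_lt(stats::median(rels), 1e-5)
  expect_lt(max(rels), 0.05)
})

test_that("autoencoder decodes to input shape and its gradients check out", {
  cfg <- ae_config(cnn_config(channels = c(4, 6), embed_dim = 5,
                              image_size = 16))
  ae <- build_encoder(cfg, seed = 5)
  imgs <- lapply(1:2, function(i) fx_seeded_image(i, 16))
  fe <- rearviews:::resnet_forward(ae$params, imgs, want_cache = TRUE)
  dec <- rearviews:::ae_decode_fwd(ae$params, fe$emb, cfg)
  expect_equal(dim(dec$out), c(2L, 16L, 16L, 3L)) # decode preserves shape

  tgt <- rearviews:::images_to_batch(imgs)
  dOut <- 2 * (dec$out - tgt) / length(tgt)
  db <- rearviews:::ae_decode_bwd(ae$params, dec$cache, dOut)
  gall <- c(db$grads, rearviews:::resnet_backward(ae$params, fe$cache, db$dZ))
  lossf <- function(p) {
    f <- rearviews:::resnet_forward(p, imgs)
    d <- rearviews:::ae_decode_fwd(p, f$emb, cfg)
    mean((d$out - tgt)^2)
  }
  eps <- 1e-6
  rels <- c()
  for (nm in names(ae$params)) {
    p <- ae$params
    k <- rearviews:::with_seed(nchar(nm) + 11, sample(length(p[[nm]]), 1))
    p[[nm]][k] <- ae$params[[nm]][k] + eps; lp <- lossf(p)
    p[[nm]][k] <- ae$params[[nm]][k] - eps; lm <- lossf(p)
    fd <- (lp - lm) / (2 * eps)
    rels <- c(rels, abs(fd - gall[[nm]][k]) /
                max(1e-8, abs(fd) + abs(gall[[nm]][k])))
  }
  expect_lt(stats::median(rels), 1e-4)
})

test_that("gradient isolation blocks backpropagation between GIM modules", {
  cfg <- gim_config(channels = c(4, 6), embed_dim = 5, image_size = 16)
  g <- build_encoder(cfg, seed = 2)
  expect_true(gradient_isolation_check(g))

  # negative control: same weights, blocker removed
  cfg_off <- gim_config(channels = c(4, 6), embed_dim = 5, image_size = 16,
                        gradient_blocker = FALSE)
  g_off <- build_encoder(cfg_off, seed = 2)
  expect_false(gradient_isolation_check(g_off))

  # single-module partition: vacuously isolated
  cfg1 <- gim_config(channels = c(4, 6), embed_dim = 5, image_size = 16,
                     module_partition = list(1:10))
  expect_true(gradient_isolation_check(build_encoder(cfg1, seed = 2)))

  expect_error(gim_config(module_partition = list(1:4, 6:10)), "exactly once")
})
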