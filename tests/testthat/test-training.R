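# Augmentations, temporal pairing, losses, shuffling and the training loop.

test_that("augmentations preserve shape, respect probabilities 0/1, and flip is an involution", {
  img <- fx_seeded_image(1)

  # every probability 0 (all ops disabled): identity
  out <- rearviews:::with_seed(1, apply_augmentations(img, augment_none()))
  expect_equal(unclass(out), unclass(img), ignore_attr = TRUE)

  # forced flip applied twice recovers the input
  flip_cfg <- augment_config(p_flip = 1, enabled_ops = "flip")
  f1 <- rearviews:::with_seed(1, apply_augmentations(img, flip_cfg))
  f2 <- rearviews:::with_seed(2, apply_augmentations(f1, flip_cfg))
  expect_equal(unclass(f2), unclass(img), ignore_attr = TRUE)

  # shape and value range always conserved
  full <- augment_config()
  for (s in 1:5) {
    a <- rearviews:::with_seed(s, apply_augmentations(img, full))
    expect_equal(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("empirical augmentation rates match their configured probabilities", {
  img <- fx_seeded_image(2, 16) # small image: rate test needs many draws
  cfg <- augment_config()
  n <- 2000
  ops <- rearviews:::with_seed(99, {
    replicate(n, attr(apply_augmentations(img, cfg), "ops_applied"),
              simplify = FALSE)
  })
  rate <- function(op) mean(vapply(ops, function(o) op %in% o, logical(1)))
  tol3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(rate("blur") - 0.5), tol3(0.5))
  expect_lt(abs(rate("jitter") - 0.8), tol3(0.8))
  expect_lt(abs(rate("grayscale") - 0.2), tol3(0.2))
  expect_lt(abs(rate("flip") - 0.5), tol3(0.5))
  expect_equal(rate("crop"), 1)
})

test_that("temporal positive pairs enumerate the window correctly", {
  # brute-force enumeration oracle for (5, 3)
  p <- temporal_positive_pairs(5, 3)
  brute <- 0
  for (i in 1:5) for (j in 1:5) if (i != j && abs(i - j) <= 2) brute <- brute + 1
  expect_equal(nrow(p), brute)
  expect_true(all(abs(p$anchor - p$positive) < 3 & p$anchor != p$positive))
  # symmetry
  expect_true(all(paste(p$positive, p$anchor) %in% paste(p$anchor, p$positive)))

  # window 1: no temporal positives (augmented self-views only)
  expect_equal(nrow(temporal_positive_pairs(5, 1)), 0)

  # saturated window: all ordered pairs
  expect_equal(nrow(temporal_positive_pairs(4, 10)), 4 * 3)
})

test_that("the contrastive loss matches closed forms and is monotone in alignment", {
  D <- 8
  a <- rearviews:::with_seed(3, matrix(rnorm(D), 1))
  negs <- matrix(0, 7, D)
  negs_raw <- rearviews:::with_seed(4, matrix(rnorm(7 * D), 7, D))
  for (i in 1:7) {
    v <- negs_raw[i, ]
    negs[i, ] <- v - sum(v * a) / sum(a * a) * a # orthogonal to the anchor
  }
  # anchor identical to positive, orthogonal negatives, tau = 0.5, 7 negatives
  expect_equal(cltt_loss(a, a, negs, 0.5), -log(exp(2) / (exp(2) + 7)),
               tolerance = 1e-12)

  # uniform similarities over K = 8 candidates
  u <- matrix(1, 1, D)
  expect_equal(cltt_loss(u, u, matrix(1, 7, D), 0.5), log(8),
               tolerance = 1e-12)

  # positivity and the uniform upper start
  expect_gte(cltt_loss(a, a, negs, 0.5), 0)

  # numeric monotonicity sweep: loss falls as anchor-positive cosine rises
  aa <- matrix(c(1, rep(0, D - 1)), 1)
  losses <- vapply(seq(0, 1, by = 0.2), function(cs) {
    pos <- matrix(c(cs, sqrt(1 - cs^2), rep(0, D - 2)), 1)
    cltt_loss(aa, pos, negs, 0.5)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))

  expect_error(cltt_loss(a, a, negs, 0), "> 0")
})

test_that("batched CLTT gradients match finite differences", {
  B <- 5
  Za <- rearviews:::with_seed(5, matrix(rnorm(B * 4), B))
  Zb <- rearviews:::with_seed(6, matrix(rnorm(B * 4), B))
  g <- rearviews:::cltt_batch_loss_grad(Za, Zb, 2L, 0.5)
  lf <- function(x, y) rearviews:::cltt_batch_loss_grad(x, y, 2L, 0.5)$loss
  eps <- 1e-6
  worst <- 0
  for (k in seq_len(length(Za))) {
    Zp <- Za; Zp[k] <- Za[k] + eps
    Zm <- Za; Zm[k] <- Za[k] - eps
    fd <- (lf(Zp, Zb) - lf(Zm, Zb)) / (2 * eps)
    worst <- max(worst, abs(fd - g$dZa[k]) /
                   max(1e-8, abs(fd) + abs(g$dZa[k])))
    Zp <- Zb; Zp[k] <- Zb[k] + eps
    Zm <- Zb; Zm[k] <- Zb[k] - eps
    fd <- (lf(Za, Zp) - lf(Za, Zm)) / (2 * eps)
    worst <- max(worst, abs(fd - g$dZb[k]) /
                   max(1e-8, abs(fd) + abs(g$dZb[k])))
  }
  expect_lt(worst, 1e-4)
})

test_that("reconstruction loss equals the per-pixel MSE oracle", {
  a <- fx_seeded_image(7, 8)
  b <- fx_seeded_image(8, 8)
  expect_equal(reconstruction_loss(a, a), 0)
  black <- array(0, dim = c(8, 8, 3)); white <- array(1, dim = c(8, 8, 3))
  expect_equal(reconstruction_loss(black, white), 1)
  # explicit loop oracle
  acc <- 0
  for (i in 1:8) for (j in 1:8) for (c in 1:3) {
    acc <- acc + (a[i, j, c] - b[i, j, c])^2
  }
  expect_equal(reconstruction_loss(a, b), acc / (8 * 8 * 3), tolerance = 1e-12)
  expect_error(reconstruction_loss(a, white[1:4, 1:4, ]), "match")
})

test_that("within-batch shuffling conserves frames and reseeds per epoch", {
  ds <- tibble::tibble(index = 1:20, v = rnorm(20))
  s1 <- shuffle_within_batches(ds, 1, epoch = 1, seed = 3)
  expect_identical(s1, ds) # singleton batches cannot move

  s8a <- shuffle_within_batches(ds, 8, epoch = 1, seed = 3)
  expect_equal(sort(s8a$index), 1:20)       # conservation
  # rows stay within their original batch
  expect_true(all((s8a$index[1:8] - 1) %/% 8 == 0))
  s8b <- shuffle_within_batches(ds, 8, epoch = 2, seed = 3)
  expect_false(identical(s8a$index, s8b$index)) # fresh permutation per epoch
  expect_identical(s8a, shuffle_within_batches(ds, 8, epoch = 1, seed = 3))
})

test_that("training reduces the loss, is seed-reproducible, and honours the shuffled condition", {
  ds <- fx_stream(48, seed = 5)
  enc <- fx_tiny_vit()
  cfg <- train_config("cltt", epochs = 3, batch_size = 16, lr = 1e-3)
  fit <- train(enc, ds, cfg, seed = 1)
  expect_s3_class(fit, "rv_fit")
  expect_equal(nrow(fit$trace), 3)
  fit2 <- train(enc, ds, cfg, seed = 1)
  expect_identical(fit$trace, fit2$trace) # bit-identical traces
  expect_identical(fit$encoder$params, fit2$encoder$params)
  fit3 <- train(enc, ds, cfg, seed = 2)
  expect_false(identical(fit$trace, fit3$trace))

  # shuffled control runs and differs from the ordered run
  cfg_sh <- train_config("cltt", epochs = 2, batch_size = 16, lr = 1e-3,
                         shuffled_condition = TRUE)
  fit_sh <- train(enc, ds, cfg_sh, seed = 1)
  cfg_or <- train_config("cltt", epochs = 2, batch_size = 16, lr = 1e-3)
  fit_or <- train(enc, ds, cfg_or, seed = 1)
  expect_false(identical(fit_sh$trace, fit_or$trace))

  expect_error(train(enc, tibble::tibble(image = list()), cfg),
               class = "empty_input")
})

test_that("a smoke-scale fit drives the training loss downward", {
  ds <- fx_stream(96, seed = 9)
  enc <- fx_tiny_vit(seed = 2)
  fit <- train(enc, ds, train_config("cltt", epochs = 5, batch_size = 24,
                                     lr = 2e-3), seed = 3)
  expect_lt(fit$trace$loss[5], fit$trace$loss[1])

  # autoencoder objective trains through the same surface
  imgs16 <- lapply(1:24, function(i) fx_seeded_image(i, 16))
  ae <- build_encoder(ae_config(cnn_config(channels = c(4, 6), embed_dim = 8,
                                           image_size = 16)), seed = 1)
  fa <- train(ae, imgs16, train_config("reconstruction", epochs = 4,
                                       batch_size = 12, lr = 3e-3), seed = 1)
  expect_lt(fa$trace$loss[4], fa$trace$loss[1])

  # GIM trains with gradient isolation intact throughout
  gim <- build_encoder(gim_config(channels = c(4, 6), embed_dim = 8,
                                  image_size = 16), seed = 1)
  fg <- train(gim, imgs16, train_config("gim", epochs = 2, batch_size = 12,
                                        lr = 1e-3), seed = 1)
  expect_true(gradient_isolation_check(fg$encoder))
  expect_true(all(is.finite(fg$trace$loss)))
})

test_that("temporal structure makes the contrastive task learnable: ordered beats shuffled loss", {
  # On a temporally continuous stream the within-window positives are real
  # neighbours, so ordered training reaches a lower contrastive loss than
  # within-batch-shuffled training at matched steps (sign test, 3 seeds).
  wins <- vapply(1:3, function(s) {
    ds <- fx_stream(128, seed = s + 20)
    enc <- build_encoder(vit_config(n_layers = 1, n_heads = 1,
                                    embed_dim = 24), seed = s)
    ord <- train(enc, ds, train_config("cltt", epochs = 3, batch_size = 32,
                                       lr = 3e-3), seed = s)
    shf <- train(enc, ds, train_config("cltt", epochs = 3, batch_size = 32,
                                       lr = 3e-3, shuffled_condition = TRUE),
                 seed = s)
    mean(ord$trace$loss) < mean(shf$trace$loss)
  }, logical(1))
  expect_gte(sum(wins), 2)
})

test_that("learning-rate schedule warms up then decays", {
  cfg <- train_config("cltt", epochs = 10, lr = 1e-3,
                      lr_schedule = "warmup_cosine", warmup_epochs = 5)
  lrs <- vapply(1:10, function(e) rearviews:::epoch_lr(cfg, e), numeric(1))
  expect_true(all(diff(lrs[1:5]) > 0))   # linear warmup
  expect_equal(lrs[5], 1e-3)             # reaches base at end of warmup
  expect_true(all(diff(lrs[5:10]) < 0))  # cosine decay
  cc <- train_config("cltt", epochs = 10, lr = 1e-4)
  expect_equal(vapply(1:10, function(e) rearviews:::epoch_lr(cc, e),
                      numeric(1)), rep(1e-4, 10))
})
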