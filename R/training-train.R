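# The seeded training loop for all four encoder families.

#' Training configuration
#'
#' Defaults mirror the canonical recipe: Adam, temporal window of 3 frames,
#' two augmented views per frame per step, and a constant learning rate for
#' ViTs (the contrastive CNN uses a 5-epoch linear warmup followed by cosine
#' decay). The full-scale recipe trains 100 epochs at learning rate 1e-4 on
#' 80,000-frame streams; desk-scale presets shrink the stream, the model and
#' the epoch count (see [desk_preset()]).
#'
#' @param objective `"cltt"` (temporal contrastive; ViT and CNN),
#'   `"reconstruction"` (autoencoder) or `"gim"` (per-module local
#'   contrastive loss on augmentation pairs, no temporal learning).
#' @param epochs Training epochs.
#' @param batch_size Frames per batch (>= 2 for contrastive objectives).
#' @param lr Base learning rate.
#' @param lr_schedule `"constant"` or `"warmup_cosine"`.
#' @param warmup_epochs Warmup length for `"warmup_cosine"` (default 5).
#' @param temporal_window Temporal window in frames (default 3).
#' @param temperature InfoNCE temperature (default 0.5).
#' @param shuffled_condition If `TRUE`, frames are re-shuffled within batches
#'   every epoch so temporal neighbours are arbitrary (the shuffled-views
#'   control).
#' @param augment An [augment_config()]; use [augment_none()] to disable.
#' @return A `train_config` list.
#' @export
train_config <- function(objective = c("cltt", "reconstruction", "gim"),
                         epochs = 10, batch_size = 64, lr = 1e-4,
                         lr_schedule = c("constant", "warmup_cosine"),
                         warmup_epochs = 5, temporal_window = 3,
                         temperature = 0.5, shuffled_condition = FALSE,
                         augment = augment_config()) {
  objective <- match.arg(objective)
  lr_schedule <- match.arg(lr_schedule)
  if (temporal_window < 1) abort("temporal_window must be >= 1")
  if (temperature <= 0) abort("temperature must be > 0")
  if (objective != "reconstruction" && batch_size < 2) {
    abort("batch_size must be >= 2 for contrastive objectives")
  }
  structure(list(objective = objective, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = lr_schedule,
                 warmup_epochs = as.integer(warmup_epochs),
                 temporal_window = as.integer(temporal_window),
                 temperature = temperature,
                 shuffled_condition = isTRUE(shuffled_condition),
                 augment = augment),
            class = "train_config")
}

epoch_lr <- function(cfg, epoch) {
  if (cfg$lr_schedule == "constant") return(cfg$lr)
  if (epoch <= cfg$warmup_epochs) return(cfg$lr * epoch / cfg$warmup_epochs)
  frac <- (epoch - cfg$warmup_epochs) /
    max(1, cfg$epochs - cfg$warmup_epochs)
  cfg$lr * 0.5 * (1 + cos(pi * min(frac, 1)))
}

encoder_backward_any <- function(encoder, cache, dZ) {
  switch(encoder$kind,
    vit = vit_backward(encoder$params, encoder$config, cache, dZ),
    cnn = resnet_backward(encoder$params, cache, dZ),
    ae = resnet_backward(encoder$params, cache, dZ)
  )
}

# SimCLR-style MLP projection head: the contrastive loss is computed on the
# head output while evaluation always uses the trunk embedding. The head
# absorbs the collapse pressure of the InfoNCE objective (without it, the
# fully collapsed embedding is a fixed point of the dynamics).
ph_names <- function(prefix) {
  paste0(prefix, c("_W1", "_b1", "_g", "_beta", "_W2", "_b2"))
}

proj_head_init <- function(dim, seed, prefix = "ph") {
  with_seed(derive_seed(seed, paste0("proj-head-", prefix)), {
    p <- list(matrix(rnorm(dim^2, sd = sqrt(2 / dim)), dim, dim),
              numeric(dim), rep(1, dim), numeric(dim),
              matrix(rnorm(dim^2, sd = sqrt(2 / dim)), dim, dim),
              numeric(dim))
    names(p) <- ph_names(prefix)
    p
  })
}

proj_head_fwd <- function(params, Z, prefix = "ph") {
  nm <- ph_names(prefix)
  l1 <- linear_fwd(Z, params[[nm[1]]], params[[nm[2]]])
  bn <- batchnorm_fwd(l1$out, params[[nm[3]]], params[[nm[4]]])
  r1 <- relu_fwd(bn$out)
  l2 <- linear_fwd(r1$out, params[[nm[5]]], params[[nm[6]]])
  list(out = l2$out, cache = list(l1 = l1, bn = bn, r1 = r1, l2 = l2))
}

proj_head_bwd <- function(params, cache, dP, prefix = "ph") {
  nm <- ph_names(prefix)
  b2 <- linear_bwd(dP, cache$l2, params[[nm[5]]])
  dr <- relu_bwd(b2$dX, cache$r1)
  bb <- batchnorm_bwd(dr, cache$bn, params[[nm[3]]])
  b1 <- linear_bwd(bb$dX, cache$l1, params[[nm[1]]])
  grads <- list(b1$dW, b1$db, bb$dg, bb$db, b2$dW, b2$db)
  names(grads) <- nm
  list(dZ = b1$dX, grads = grads)
}

#' Train an encoder on a frame stream
#'
#' Runs the configured objective with Adam under a single seed; identical
#' seeds and configurations give identical loss traces. For the temporal
#' contrastive objective each batch of consecutive frames is augmented into
#' two views; embeddings of frames within the temporal window are pulled
#' together (cross-view) while all other in-batch frames are pushed apart.
#' The shuffled-views control permutes frames within batches afresh every
#' epoch before pairing. The autoencoder minimises pixel MSE; GreedyInfoMax
#' trains each gradient-isolated module with its own local contrastive loss
#' on augmentation pairs only.
#'
#' @param encoder An `rv_encoder` from [build_encoder()].
#' @param dataset Frame-stream tibble (temporally ordered) or list of images.
#' @param config A [train_config()].
#' @param seed Integer seed controlling augmentation and batching randomness.
#' @param verbose Print per-epoch losses.
#' @return An `rv_fit`: the trained encoder (`$encoder`), the per-epoch loss
#'   trace (`$trace`), the config and seed.
#' @export
train <- function(encoder, dataset, config = train_config(), seed = 1,
                  verbose = FALSE) {
  imgs_all <- as_image_list(dataset)
  if (length(imgs_all) == 0) abort("dataset is empty", class = "empty_input")
  n <- length(imgs_all)
  bs <- min(config$batch_size, n)
  n_batches <- n %/% bs
  if (n_batches == 0) abort("dataset smaller than one batch")
  params <- encoder$params
  enc_param_names <- names(params)
  if (config$objective == "cltt") {
    params <- c(params, proj_head_init(encoder$embed_dim, seed))
  } else if (config$objective == "gim") {
    params <- c(params,
                proj_head_init(encoder$config$channels[1], seed, "ph1"),
                proj_head_init(encoder$embed_dim, seed, "ph2"))
  }
  opt <- adam_init(params)
  trace <- numeric(config$epochs)
  enc_run <- encoder

  for (epoch in seq_len(config$epochs)) {
    lr <- epoch_lr(config, epoch)
    # in-batch order: identity, or a fresh within-batch permutation
    order_idx <- seq_len(n_batches * bs)
    if (config$shuffled_condition) {
      order_idx <- with_seed(derive_seed(seed, paste0("shuf-", epoch)), {
        unlist(lapply(seq_len(n_batches), function(b) {
          (b - 1L) * bs + sample.int(bs)
        }), use.names = FALSE)
      })
    }
    ep_loss <- 0
    with_seed(derive_seed(seed, paste0("epoch-", epoch)), {
      for (b in seq_len(n_batches)) {
        take <- order_idx[(b - 1L) * bs + seq_len(bs)]
        batch <- imgs_all[take]
        enc_run$params <- params
        if (config$objective == "cltt") {
          va <- lapply(batch, apply_augmentations, config = config$augment)
          vb <- lapply(batch, apply_augmentations, config = config$augment)
          fa <- encoder_forward(enc_run, va, want_cache = TRUE)
          fb <- encoder_forward(enc_run, vb, want_cache = TRUE)
          pa <- proj_head_fwd(params, fa$emb)
          pb <- proj_head_fwd(params, fb$emb)
          g1 <- cltt_batch_loss_grad(pa$out, pb$out, config$temporal_window,
                                     config$temperature)
          g2 <- cltt_batch_loss_grad(pb$out, pa$out, config$temporal_window,
                                     config$temperature)
          loss <- (g1$loss + g2$loss) / 2
          ha <- proj_head_bwd(params, pa$cache, (g1$dZa + g2$dZb) / 2)
          hb <- proj_head_bwd(params, pb$cache, (g1$dZb + g2$dZa) / 2)
          ga <- encoder_backward_any(enc_run, fa$cache, ha$dZ)
          gb <- encoder_backward_any(enc_run, fb$cache, hb$dZ)
          grads <- mapply(function(x, y) x + y, ga, gb[names(ga)],
                          SIMPLIFY = FALSE)
          grads <- c(grads, mapply(`+`, ha$grads, hb$grads, SIMPLIFY = FALSE))
        } else if (config$objective == "reconstruction") {
          fe <- resnet_forward(params, batch, want_cache = TRUE)
          dec <- ae_decode_fwd(params, fe$emb, enc_run$config)
          X <- images_to_batch(batch)
          loss <- mean((dec$out - X)^2)
          dOut <- 2 * (dec$out - X) / length(X)
          db <- ae_decode_bwd(params, dec$cache, dOut)
          genc <- resnet_backward(params, fe$cache, db$dZ)
          grads <- c(db$grads, genc)
        } else { # gim
          va <- lapply(batch, apply_augmentations, config = config$augment)
          vb <- lapply(batch, apply_augmentations, config = config$augment)
          fa <- gim_forward(params, enc_run$config, va, want_cache = TRUE)
          fb <- gim_forward(params, enc_run$config, vb, want_cache = TRUE)
          loss <- 0
          dMa <- list(); dMb <- list()
          head_grads <- list()
          for (m in 1:2) {
            pref <- paste0("ph", m)
            qa <- proj_head_fwd(params, fa$module_embs[[m]], pref)
            qb <- proj_head_fwd(params, fb$module_embs[[m]], pref)
            # window 1: positives are augmented self-views only
            h1 <- cltt_batch_loss_grad(qa$out, qb$out, 1L, config$temperature)
            h2 <- cltt_batch_loss_grad(qb$out, qa$out, 1L, config$temperature)
            loss <- loss + (h1$loss + h2$loss) / 2
            ba <- proj_head_bwd(params, qa$cache, (h1$dZa + h2$dZb) / 2, pref)
            bb <- proj_head_bwd(params, qb$cache, (h1$dZb + h2$dZa) / 2, pref)
            dMa[[m]] <- ba$dZ
            dMb[[m]] <- bb$dZ
            head_grads <- c(head_grads,
                            mapply(`+`, ba$grads, bb$grads, SIMPLIFY = FALSE))
          }
          loss <- loss / 2
          ga <- gim_backward(params, enc_run$config, fa$cache, dMa)
          gb <- gim_backward(params, enc_run$config, fb$cache, dMb)
          grads <- mapply(function(x, y) x + y, ga, gb[names(ga)],
                          SIMPLIFY = FALSE)
          grads <- c(grads, head_grads)
        }
        st <- adam_step(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + loss
      }
    })
    trace[epoch] <- ep_loss / n_batches
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f  lr %.2g", epoch, config$epochs,
                      trace[epoch], lr))
    }
  }
  encoder$params <- params[enc_param_names]
  structure(list(encoder = encoder, config = config, seed = seed,
                 proj_head = params[setdiff(names(params), enc_param_names)],
                 trace = tibble(epoch = seq_len(config$epochs), loss = trace)),
            class = "rv_fit")
}

#' @export
print.rv_fit <- function(x, ...) {
  cat(sprintf("<trained %s encoder: %d epochs, final loss %.4f>\n",
              x$encoder$kind, nrow(x$trace),
              x$trace$loss[nrow(x$trace)]))
  invisible(x)
}
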