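# User-facing encoder API: construction, embedding extraction, and the
# gradient-isolation contract for GreedyInfoMax.

#' Build an encoder from a configuration
#'
#' Instantiates one of the four encoder families — [vit_config()] (ViT-CoT),
#' [cnn_config()] (contrastive ResNet-10), [ae_config()] (convolutional
#' autoencoder) or [gim_config()] (gradient-isolated CNN) — with seeded
#' random initial weights. The parameter count is recorded on the handle.
#'
#' @param config An encoder configuration object.
#' @param seed Integer seed for weight initialisation.
#' @return An `rv_encoder` handle with elements `kind`, `config`, `params`,
#'   `n_params`, `embed_dim`.
#' @export
build_encoder <- function(config, seed = 1) {
  if (!inherits(config, "encoder_config")) {
    abort("config must be an encoder configuration object")
  }
  kind <- class(config)[1]
  params <- switch(kind,
    vit_config = vit_init(config, seed),
    cnn_config = resnet_init(config, seed),
    ae_config = ae_init(config, seed),
    gim_config = resnet_init(
      cnn_config(channels = config$channels, embed_dim = config$embed_dim,
                 image_size = config$image_size), seed)
  )
  structure(list(kind = sub("_config$", "", kind), config = config,
                 params = params, n_params = n_params(params),
                 embed_dim = if (kind == "ae_config") config$encoder$embed_dim
                             else config$embed_dim,
                 seed = seed),
            class = c(paste0("rv_", sub("_config$", "", kind)), "rv_encoder"))
}

#' @export
print.rv_encoder <- function(x, ...) {
  cat(sprintf("<%s encoder: %s parameters, %d-d embeddings>\n",
              x$kind, format(x$n_params, big.mark = ","), x$embed_dim))
  invisible(x)
}

expected_image_size <- function(encoder) {
  if (encoder$kind == "ae") encoder$config$encoder$image_size
  else encoder$config$image_size
}

as_image_list <- function(images) {
  if (is.data.frame(images)) images$image
  else if (is.array(images) && length(dim(images)) == 3) list(images)
  else if (is.list(images)) images
  else abort("images must be a frame tibble, a list of arrays, or one array")
}

encoder_forward <- function(encoder, images, want_cache = FALSE) {
  imgs <- as_image_list(images)
  sz <- expected_image_size(encoder)
  if (!all(dim(imgs[[1]])[1:2] == sz)) {
    abort(sprintf("images must be %d x %d for this encoder", sz, sz))
  }
  switch(encoder$kind,
    vit = vit_forward(encoder$params, encoder$config, imgs, want_cache),
    cnn = resnet_forward(encoder$params, imgs, want_cache),
    ae = resnet_forward(encoder$params, imgs, want_cache),
    gim = gim_forward(encoder$params, encoder$config, imgs, want_cache)
  )
}

#' Extract last-layer embeddings for a batch of images
#'
#' Runs the frozen encoder and returns one embedding row per image, in input
#' order. For ViT encoders this is the mean over last-layer patch tokens
#' (post final normalisation); for the CNN families it is the output of the
#' embedding head; for the autoencoder only the encoder is used.
#'
#' @param encoder An `rv_encoder` from [build_encoder()].
#' @param images Frame/stimulus tibble with an `image` column, list of
#'   H x W x 3 arrays, or a single array.
#' @return Numeric matrix, one row per image, `encoder$embed_dim` columns.
#' @export
embed <- function(encoder, images) {
  encoder_forward(encoder, images, want_cache = FALSE)$emb
}

# ---- GreedyInfoMax ----------------------------------------------------------

gim_forward <- function(params, cfg, images, want_cache = FALSE) {
  X <- images_to_batch(images)
  h1 <- resnet_half1_fwd(params, X)
  p1 <- gap_fwd(h1$out) # module 1's local embedding
  h2 <- resnet_half2_fwd(params, h1$out)
  cache <- if (want_cache) list(h1 = h1$cache, h2 = h2$cache, p1 = p1,
                                blocker = cfg$gradient_blocker)
  list(emb = h2$emb, module_embs = list(p1$out, h2$emb), cache = cache)
}

# Backward from per-module local losses. dM is a list of gradients wrt each
# module's local embedding; with the blocker on, module 2's gradient stops at
# the module boundary.
gim_backward <- function(params, cfg, cache, dM) {
  b2 <- resnet_half2_bwd(params, cache$h2, dM[[2]])
  dF1 <- gap_bwd(dM[[1]], cache$p1)
  if (!cfg$gradient_blocker) dF1 <- dF1 + b2$dF1
  g1 <- resnet_half1_bwd(params, cache$h1, dF1)
  c(b2$grads, g1)
}

#' Check gradient isolation of a GreedyInfoMax encoder
#'
#' Verifies the gradient-blocker contract: a loss applied to a later module
#' must produce exactly zero parameter gradients in all earlier modules.
#' Probes the encoder with a small seeded batch and a quadratic loss on the
#' last module's embedding. Single-module encoders pass vacuously.
#'
#' @param encoder An `rv_gim` encoder.
#' @return `TRUE` iff no gradient crosses a module boundary.
#' @export
gradient_isolation_check <- function(encoder) {
  if (!inherits(encoder, "rv_gim")) abort("encoder must be a GIM encoder")
  cfg <- encoder$config
  if (length(cfg$module_partition) < 2) return(TRUE)
  sz <- cfg$image_size
  imgs <- with_seed(derive_seed(encoder$seed, "isolation-probe"), {
    lapply(1:2, function(i) array(runif(sz * sz * 3), dim = c(sz, sz, 3)))
  })
  fw <- gim_forward(encoder$params, cfg, imgs, want_cache = TRUE)
  # loss on the last module only: L = sum(emb^2) -> dL/demb = 2 emb
  dM <- list(fw$module_embs[[1]] * 0, 2 * fw$module_embs[[2]])
  grads <- gim_backward(encoder$params, cfg, fw$cache, dM)
  early <- c("stem_W", "stem_b", "b1a_W1", "b1a_b1", "b1a_W2", "b1a_b2",
             "b1b_W1", "b1b_b1", "b1b_W2", "b1b_b2")
  all(vapply(early, function(nm) all(abs(grads[[nm]]) < 1e-12), logical(1)))
}
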