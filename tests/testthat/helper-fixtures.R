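# Shared fixtures, built in code. Kept tiny so the whole suite stays fast.

fx_seeded_image <- function(seed = 1, size = 64) {
  rearviews:::with_seed(seed, {
    rearviews:::quantize8(array(runif(size * size * 3),
                                dim = c(size, size, 3)))
  })
}

fx_moving_square <- function() {
  f0 <- array(0, dim = c(64, 64, 3)); f0[20:32, 20:32, ] <- 1
  f1 <- array(0, dim = c(64, 64, 3)); f1[23:35, 20:32, ] <- 1
  list(f0 = f0, f1 = f1, dy = 3, dx = 0,
       inside = {
         m <- matrix(FALSE, 64, 64); m[22:33, 22:30] <- TRUE; m
       })
}

# constructed-geometry embeddings over the 4 x 4 factorial:
# same-colour objects identical, different colours orthogonal
fx_factorial_labels <- function() {
  tidyr::expand_grid(shape_id = default_shapes(),
                     color_id = names(default_colors()))
}

fx_color_based_embeddings <- function() {
  lab <- fx_factorial_labels()
  diag(4)[match(lab$color_id, unique(lab$color_id)), ]
}

fx_shape_based_embeddings <- function() {
  lab <- fx_factorial_labels()
  diag(4)[match(lab$shape_id, unique(lab$shape_id)), ]
}

fx_tiny_vit <- function(seed = 1, image_size = 64) {
  build_encoder(vit_config(n_layers = 1, n_heads = 1, patch_size = 8,
                           image_size = image_size, embed_dim = 16),
                seed = seed)
}

fx_stream <- function(n = 64, kind = "dense_exploration", seed = 5) {
  generate_condition_dataset(condition_policy(kind), object_spec(), n,
                             seed = seed)
}
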