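# Temporal positive pairing, contrastive and reconstruction losses, and the
# within-batch shuffling control.

#' Temporal positive pairs within a stream
#'
#' For each anchor frame `i`, its temporal positives are the frames `j != i`
#' with `|i - j| < window` — the frames inside the same temporal window
#' (window 3 at 10 frames/s spans about 300 ms). The relation is symmetric.
#' All other frames form the anchor's negative pool.
#'
#' @param stream_length Number of frames.
#' @param window Temporal window size in frames (>= 1); window 1 leaves only
#'   augmented self-views as positives.
#' @return A tibble of ordered pairs `anchor`, `positive`.
#' @export
temporal_positive_pairs <- function(stream_length, window = 3) {
  if (window < 1) abort("window must be >= 1")
  n <- as.integer(stream_length)
  pairs <- tidyr::expand_grid(anchor = seq_len(n), positive = seq_len(n))
  pairs[pairs$anchor != pairs$positive &
          abs(pairs$anchor - pairs$positive) < window, ]
}

l2_normalize_rows <- function(Z) {
  nr <- sqrt(rowSums(Z^2))
  if (any(nr == 0)) abort("cannot normalise a zero embedding")
  Z / nr
}

#' Contrastive-learning-through-time (InfoNCE) loss
#'
#' Normalised-embedding InfoNCE with cosine similarity: for each anchor row
#' and its matched positive row, the loss is the negative log-probability of
#' the positive among the candidate set formed by that positive and the
#' whole negative pool, at temperature `tau`; the result is averaged over
#' anchors. With all pairwise similarities equal and `K` candidates the loss
#' equals `log(K)`.
#'
#' @param anchor_embeddings,positive_embeddings Matrices with matching rows
#'   (anchor i pairs with positive i); nonzero rows.
#' @param negative_pool Matrix of negative embeddings shared by all anchors.
#' @param temperature Softmax temperature (> 0, default 0.5).
#' @return Scalar loss (>= 0).
#' @export
cltt_loss <- function(anchor_embeddings, positive_embeddings, negative_pool,
                      temperature = 0.5) {
  if (temperature <= 0) abort("temperature must be > 0")
  U <- l2_normalize_rows(anchor_embeddings)
  P <- l2_normalize_rows(positive_embeddings)
  N <- l2_normalize_rows(negative_pool)
  sp <- rowSums(U * P) / temperature
  Sn <- U %*% t(N) / temperature
  m <- pmax(sp, apply(Sn, 1, max))
  denom <- exp(sp - m) + rowSums(exp(Sn - m))
  mean(-(sp - m) + log(denom))
}

#' Pixel reconstruction loss
#'
#' Mean squared error over pixels on the `[0, 1]` intensity scale, so
#' identical images score 0 and an all-black / all-white pair scores 1.
#'
#' @param image,decoded Arrays of identical shape.
#' @return Scalar in `[0, 1]` for in-range images.
#' @export
reconstruction_loss <- function(image, decoded) {
  if (!all(dim(image) == dim(decoded))) abort("shapes must match")
  mean((image - decoded)^2)
}

#' Shuffle frames within training batches
#'
#' The shuffled-views control: keeps the multiset of frames (and the batch
#' boundaries) intact but permutes the order within every batch, destroying
#' the temporal continuity that contrastive learning through time exploits.
#' A fresh permutation is drawn for every epoch from the given seed.
#'
#' @param dataset Frame-stream tibble (or any data frame).
#' @param batch_size Batch size (>= 1; size 1 leaves the order unchanged).
#' @param epoch Epoch number (varies the permutation).
#' @param seed Integer seed.
#' @return The dataset with rows permuted within each batch.
#' @export
shuffle_within_batches <- function(dataset, batch_size, epoch = 1, seed = 1) {
  if (batch_size < 1) abort("batch_size must be >= 1")
  n <- nrow(dataset)
  ord <- with_seed(derive_seed(seed, paste0("shuffle-epoch-", epoch)), {
    unlist(lapply(split(seq_len(n), (seq_len(n) - 1) %/% batch_size),
                  function(ix) if (length(ix) > 1) sample(ix) else ix),
           use.names = FALSE)
  })
  dataset[ord, , drop = FALSE]
}

# ---- batched symmetric CLTT loss + gradient --------------------------------

# Za, Zb: B x D raw (unnormalised) embeddings of two augmented views of the
# same ordered batch. Anchors are rows of view A; positives are cross-view
# items within the temporal window (including the same frame); negatives are
# all items of either view outside the anchor's window. The training loop
# calls this in both directions for a symmetric objective. Returns the loss
# and gradients wrt Za, Zb.
cltt_batch_loss_grad <- function(Za, Zb, window, temperature,
                                 pair_index = NULL) {
  B <- nrow(Za)
  idx <- pair_index %||% seq_len(B) # in-batch temporal positions
  Ua <- l2_normalize_rows(Za)
  Ub <- l2_normalize_rows(Zb)
  C <- rbind(Ub, Ua) # candidate bank: other view first, then own view
  dist <- abs(outer(idx, idx, `-`))
  inwin <- dist < window
  loss <- 0; npairs <- 0
  dC <- matrix(0, 2 * B, ncol(Za))
  dUa <- matrix(0, B, ncol(Za))
  S <- (Ua %*% t(C)) / temperature
  for (i in seq_len(B)) {
    pos_cols <- which(inwin[i, ])               # cross-view positives
    neg_cols <- c(which(!inwin[i, ]),           # cross-view negatives
                  B + which(!inwin[i, ]))       # own-view negatives
    if (length(neg_cols) == 0) next
    si <- S[i, ]
    en <- exp(si[neg_cols] - max(si))
    sum_en <- sum(en)
    for (p in pos_cols) {
      ep <- exp(si[p] - max(si))
      denom <- ep + sum_en
      loss <- loss - log(ep / denom)
      npairs <- npairs + 1
      # dL/ds over candidates of this (i, p) term
      coef_p <- ep / denom - 1
      coef_n <- en / denom
      dC[p, ] <- dC[p, ] + coef_p * Ua[i, ]
      dC[neg_cols, ] <- dC[neg_cols, ] + outer(coef_n, Ua[i, ])
      dUa[i, ] <- dUa[i, ] + coef_p * C[p, ] + colSums(coef_n * C[neg_cols, , drop = FALSE])
    }
  }
  if (npairs == 0) return(list(loss = 0, dZa = Za * 0, dZb = Zb * 0))
  sc <- 1 / (npairs * temperature)
  dUb <- dC[seq_len(B), , drop = FALSE] * sc
  dUa <- (dUa + dC[B + seq_len(B), , drop = FALSE]) * sc
  # back through row normalisation
  unnorm_bwd <- function(dU, U, Z) {
    nr <- sqrt(rowSums(Z^2))
    (dU - U * rowSums(dU * U)) / nr
  }
  list(loss = loss / npairs,
       dZa = unnorm_bwd(dUa, Ua, Za),
       dZb = unnorm_bwd(dUb, Ub, Zb))
}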