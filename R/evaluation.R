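# Representational analysis: centred cosine RDMs over the factorial stimulus
# set, colour/shape scores with cell-wise standard errors, and seed-level
# statistics.
#
# Although the matrices are conventionally called representational
# dissimilarity matrices, they are stored as cosine similarities (higher =
# more similar), matching how the scores are defined.

#' Centre stimulus embeddings
#'
#' Subtracts the grand mean vector (the mean over all test-image embeddings)
#' from every row, centring the embedding cloud on zero before cosine
#' similarities are computed. Idempotent.
#'
#' @param matrix Numeric matrix, one embedding per row (>= 1 row).
#' @return Matrix of the same shape with zero column means.
#' @export
center_embeddings <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) < 1) {
    abort("need at least one embedding row", class = "empty_input")
  }
  sweep(matrix, 2, colMeans(matrix))
}

#' Cosine-similarity RDM over the single-view stimulus set
#'
#' Entry (i, j) is the cosine similarity of centred embedding rows i and j;
#' the matrix is symmetric with unit diagonal. Row/column order follows the
#' input rows (the canonical stimulus set is shapes-major, colours-minor).
#'
#' @param centered_matrix 16 x D centred embeddings, no all-zero rows.
#' @param labels Optional tibble/data.frame with `shape_id`, `color_id` per
#'   row; attached as an attribute for scoring and plotting.
#' @return An `rdm` object: 16 x 16 numeric matrix with `labels` attribute.
#' @export
cosine_rdm <- function(centered_matrix, labels = NULL) {
  Z <- as.matrix(centered_matrix)
  nr <- sqrt(rowSums(Z^2))
  if (any(nr < 1e-12)) {
    bad <- which(nr < 1e-12)[1]
    nm <- if (!is.null(labels)) {
      paste(labels$shape_id[bad], labels$color_id[bad], sep = "_")
    } else as.character(bad)
    abort(sprintf("degenerate (zero-norm) embedding for object %s", nm),
          class = "degenerate_embedding")
  }
  U <- Z / nr
  S <- tcrossprod(U)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  if (!is.null(labels)) {
    attr(S, "labels") <- tibble(shape_id = labels$shape_id,
                                color_id = labels$color_id)
  }
  class(S) <- c("rdm", class(S))
  S
}

score_pairs <- function(labels) {
  n <- nrow(labels)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_color <- labels$color_id[pr[, 1]] == labels$color_id[pr[, 2]]
  same_shape <- labels$shape_id[pr[, 1]] == labels$shape_id[pr[, 2]]
  list(pairs = pr, same_color = same_color, same_shape = same_shape)
}

#' Colour and shape scores from an RDM
#'
#' The colour score is the mean similarity over unordered off-diagonal cell
#' pairs whose objects share a colour; the shape score is the analogue for
#' shared shape. In a complete 4 x 4 factorial each score averages 24 cells,
#' and same-shape-same-colour pairs occur only on the (excluded) diagonal,
#' so the two scores are disjoint. Standard errors are taken across the
#' contributing cells.
#'
#' @param rdm An [cosine_rdm()] result (or plain matrix).
#' @param labels Tibble with `shape_id`, `color_id` per row; defaults to the
#'   RDM's attached labels. Must form a complete 4 x 4 factorial.
#' @return A one-row tibble: `color_score`, `shape_score`, `se_color`,
#'   `se_shape`, `n_color_cells`, `n_shape_cells`.
#' @export
match_scores <- function(rdm, labels = attr(rdm, "labels")) {
  if (is.null(labels)) abort("labels are required")
  if (nrow(labels) != length(unique(labels$shape_id)) *
        length(unique(labels$color_id)) ||
      anyDuplicated(paste(labels$shape_id, labels$color_id))) {
    abort("labels must form a complete factorial design")
  }
  sp <- score_pairs(labels)
  vals <- rdm[sp$pairs]
  cvals <- vals[sp$same_color]
  svals <- vals[sp$same_shape]
  tibble(color_score = mean(cvals), shape_score = mean(svals),
         se_color = stats::sd(cvals) / sqrt(length(cvals)),
         se_shape = stats::sd(svals) / sqrt(length(svals)),
         n_color_cells = length(cvals), n_shape_cells = length(svals))
}

stat_row <- function(test, mean_a, mean_b, t, p, df, na_flag = FALSE,
                     na_reason = NA_character_) {
  tibble(test = test, mean_a = mean_a, mean_b = mean_b,
         mean_diff = mean_a - mean_b, t = t, p = p, df = df,
         na_flag = na_flag, na_reason = na_reason)
}

#' Paired t-test across seeds
#'
#' Classical paired t on per-seed differences (df = n - 1, two-sided).
#' When the per-seed differences are numerically constant (sd below
#' `1e-9`) the statistic is undefined — performance across seeds is near
#' identical, preventing a t-test — and the result carries an `na_flag`
#' with the reason instead.
#'
#' @param values_a,values_b Equal-length numeric vectors (>= 2), one value
#'   per seed.
#' @return A one-row `StatResult` tibble.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) abort("lengths must match")
  if (length(values_a) < 2) abort("need at least two paired observations")
  d <- values_a - values_b
  if (stats::sd(d) < 1e-9) {
    return(stat_row("paired", mean(values_a), mean(values_b),
                    NA_real_, NA_real_, NA_real_, TRUE,
                    "near-identical values across seeds prevent a t-test"))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  stat_row("paired", mean(values_a), mean(values_b),
           unname(tt$statistic), tt$p.value, unname(tt$parameter))
}

#' Welch two-sample t-test
#'
#' Unpaired Welch t with Welch-Satterthwaite degrees of freedom, two-sided;
#' used to compare trained against untrained score distributions.
#'
#' @param group_a,group_b Numeric vectors of length >= 2.
#' @return A one-row `StatResult` tibble.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least two observations")
  }
  if (stats::sd(group_a) < 1e-12 && stats::sd(group_b) < 1e-12) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(stat_row("welch", mean(group_a), mean(group_b),
                    if (eq) 0 else NA_real_, if (eq) 1 else NA_real_,
                    NA_real_, !eq,
                    if (!eq) "zero variance in both groups" else NA_character_))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  stat_row("welch", mean(group_a), mean(group_b),
           unname(tt$statistic), tt$p.value, unname(tt$parameter))
}

#' Project stimulus embeddings to 2-D for visualisation
#'
#' Maps each embedding row to a 2-D point for figures (never for scores).
#' The backend is pluggable: `"pca"` (default) uses the first two principal
#' components, `"mds"` classical multidimensional scaling. A t-SNE backend
#' is not bundled; requesting `"tsne"` raises a configuration error telling
#' the user to supply their own projection function via `fn`.
#'
#' @param embeddings Matrix with >= 2 rows.
#' @param labels Optional tibble with one row per embedding, bound to the
#'   output.
#' @param seed Seed for stochastic backends (PCA/MDS are deterministic; the
#'   seed is still threaded through for custom `fn`s).
#' @param method `"pca"`, `"mds"`, or `"custom"` with `fn`.
#' @param fn Custom projection `function(embeddings, seed)` returning an
#'   n x 2 matrix.
#' @return Tibble with `dim1`, `dim2` plus any label columns.
#' @export
project_2d <- function(embeddings, labels = NULL, seed = 1,
                       method = c("pca", "mds", "tsne", "custom"), fn = NULL) {
  method <- match.arg(method)
  E <- as.matrix(embeddings)
  if (nrow(E) < 2) abort("need at least two embeddings")
  xy <- switch(method,
    pca = {
      pc <- stats::prcomp(E, center = TRUE, scale. = FALSE, rank. = 2)
      xy <- pc$x
      if (ncol(xy) < 2) xy <- cbind(xy, 0)
      xy[, 1:2, drop = FALSE]
    },
    mds = {
      d2 <- stats::dist(E)
      xy <- stats::cmdscale(d2, k = 2)
      if (ncol(xy) < 2) xy <- cbind(xy, 0)
      xy
    },
    tsne = abort(paste("no t-SNE backend is bundled; pass method = 'custom'",
                       "with fn = <your projection function>"),
                 class = "configuration_error"),
    custom = {
      if (!is.function(fn)) abort("method 'custom' needs fn",
                                  class = "configuration_error")
      fn(E, seed)
    }
  )
  out <- tibble(dim1 = xy[, 1], dim2 = xy[, 2])
  if (!is.null(labels)) out <- dplyr::bind_cols(as_tibble(labels), out)
  out
}
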