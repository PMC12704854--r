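# Dense optical flow (classical pyramidal Lucas-Kanade) and flow-driven
# saliency. The flow estimator is a pluggable contract: any function with the
# same signature (two frames in, a flow_field out) can drive dynamic
# foveation, e.g. a learned estimator; this classical default keeps the
# pipeline self-contained.

sum_window <- function(m, radius) {
  k <- rep(1, 2 * radius + 1)
  blur_matrix(m, k / 1) # un-normalised box sum with replicate padding
}

gray_of <- function(frame) {
  if (length(dim(frame)) == 3) luminance(frame) else frame
}

lk_level <- function(f0, f1, dy, dx, window = 4, iters = 3) {
  h <- nrow(f0); w <- ncol(f0)
  gy <- (rbind(f0[-1, ], f0[h, ]) - rbind(f0[1, ], f0[-h, ])) / 2
  gx <- (cbind(f0[, -1], f0[, w]) - cbind(f0[, 1], f0[, -w])) / 2
  syy <- sum_window(gy * gy, window)
  sxx <- sum_window(gx * gx, window)
  sxy <- sum_window(gx * gy, window)
  # Tikhonov-regularised solve; only update where the window holds usable
  # texture so flat regions keep their coarse-to-fine estimate
  eps <- 0.05
  det <- (sxx + eps) * (syy + eps) - sxy^2
  textured <- sum_window(gy * gy + gx * gx, 1) > 0.1
  rr <- matrix(rep(seq_len(h), times = w), h)
  cc <- matrix(rep(seq_len(w), each = h), h)
  f1i <- array(c(f1, f1, f1), dim = c(h, w, 3)) # reuse the 3-channel sampler
  for (it in seq_len(iters)) {
    warped <- matrix(bilinear_sample(f1i, as.vector(rr + dy), as.vector(cc + dx))[, 1], h)
    e <- warped - f0
    bx <- sum_window(gx * e, window)
    by <- sum_window(gy * e, window)
    ddx <- -((syy + eps) * bx - sxy * by) / det
    ddy <- -((sxx + eps) * by - sxy * bx) / det
    ddx[!textured] <- 0; ddy[!textured] <- 0
    lim <- 0.5
    dx <- dx + pmin(pmax(ddx, -lim), lim)
    dy <- dy + pmin(pmax(ddy, -lim), lim)
  }
  # keep the per-level estimate within the window's capture range
  cap <- window + 1
  list(dy = pmin(pmax(dy, -cap), cap), dx = pmin(pmax(dx, -cap), cap))
}

#' Estimate dense optical flow between two consecutive frames
#'
#' Coarse-to-fine Lucas-Kanade: per-pixel displacement `(dy, dx)` such that
#' content at pixel `p` in `frame_t` appears near `p + (dy, dx)` in
#' `frame_t1`. Identical frames give zero flow everywhere.
#'
#' @param frame_t,frame_t1 Frames of equal shape (H x W x 3 arrays or
#'   grayscale matrices).
#' @param levels Pyramid levels (default 3).
#' @param window Integration half-window in pixels (default 4).
#' @return A `flow_field` list with matrices `dy`, `dx`, `magnitude`.
#' @export
estimate_flow <- function(frame_t, frame_t1, levels = 3, window = 4) {
  f0 <- gray_of(frame_t); f1 <- gray_of(frame_t1)
  if (!all(dim(f0) == dim(f1))) abort("frames must have the same shape")
  if (identical(f0, f1)) {
    z <- matrix(0, nrow(f0), ncol(f0))
    return(structure(list(dy = z, dx = z, magnitude = z), class = "flow_field"))
  }
  # build pyramid (2x box downsample; crop one row/col if odd)
  pyr <- list(list(f0 = f0, f1 = f1))
  for (l in seq_len(levels - 1)) {
    p <- pyr[[l]]
    h <- nrow(p$f0) %/% 2 * 2; w <- ncol(p$f0) %/% 2 * 2
    if (h < 8 || w < 8) break
    dn <- function(m) {
      m <- m[seq_len(h), seq_len(w), drop = FALSE]
      (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
         m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
    }
    pyr[[l + 1]] <- list(f0 = dn(p$f0), f1 = dn(p$f1))
  }
  dy <- matrix(0, nrow(pyr[[length(pyr)]]$f0), ncol(pyr[[length(pyr)]]$f0))
  dx <- dy
  for (l in rev(seq_along(pyr))) {
    p <- pyr[[l]]
    if (!all(dim(dy) == dim(p$f0))) {
      up <- function(m) {
        src <- array(c(m, m, m), dim = c(dim(m), 3))
        h2 <- nrow(p$f0); w2 <- ncol(p$f0)
        ys <- rep((seq_len(h2) + 0.5) / 2, times = w2)
        xs <- rep((seq_len(w2) + 0.5) / 2, each = h2)
        matrix(bilinear_sample(src, ys, xs)[, 1], h2) * 2
      }
      dy <- up(dy); dx <- up(dx)
    }
    fl <- lk_level(p$f0, p$f1, dy, dx, window = window)
    dy <- fl$dy; dx <- fl$dx
  }
  # flow is only observable where the image carries texture; keep estimates
  # there and diffuse them into textureless neighbourhoods (object interiors
  # inherit the motion of their edges, empty regions fall back to zero)
  h <- nrow(f0); w <- ncol(f0)
  gy <- (rbind(f0[-1, ], f0[h, ]) - rbind(f0[1, ], f0[-h, ])) / 2
  gx <- (cbind(f0[, -1], f0[, w]) - cbind(f0[, 1], f0[, -w])) / 2
  energy <- sum_window(gy^2 + gx^2, 1)
  textured <- energy > 0.1
  k <- gaussian_kernel1d(2 * window)
  den <- blur_matrix(textured * 1, k)
  fill_y <- blur_matrix(dy * textured, k)
  fill_x <- blur_matrix(dx * textured, k)
  reach <- den > 0.02
  dy <- ifelse(textured, dy, ifelse(reach, fill_y / pmax(den, 1e-9), 0))
  dx <- ifelse(textured, dx, ifelse(reach, fill_x / pmax(den, 1e-9), 0))
  # light smoothing regularises isolated over-shoots at corners
  ks <- gaussian_kernel1d(1.5)
  dy <- blur_matrix(dy, ks); dx <- blur_matrix(dx, ks)
  structure(list(dy = dy, dx = dx, magnitude = sqrt(dy^2 + dx^2)),
            class = "flow_field")
}

#' Locate the most salient (highest-flow) region
#'
#' Builds a saliency map by locally aggregating the flow magnitude
#' (`smooth_sigma` Gaussian), then returns the centroid of all pixels within
#' 99% of the map's maximum — the region of most prominent movement. An
#' all-zero (or numerically negligible) field falls back to the image centre.
#'
#' @param flow A `flow_field` from [estimate_flow()].
#' @param smooth_sigma Gaussian sigma (pixels) of the magnitude aggregation;
#'   0 uses the raw magnitude.
#' @return `(row, col)` of the saliency centre.
#' @export
saliency_center <- function(flow, smooth_sigma = 5) {
  mag <- flow$magnitude
  h <- nrow(mag); w <- ncol(mag)
  if (smooth_sigma > 0) mag <- blur_matrix(mag, gaussian_kernel1d(smooth_sigma))
  mx <- max(mag)
  if (!is.finite(mx) || mx < 1e-8) return(c((h + 1) / 2, (w + 1) / 2))
  top <- mag >= 0.99 * mx
  rr <- matrix(rep(seq_len(h), times = w), h)
  cc <- matrix(rep(seq_len(w), each = h), h)
  c(mean(rr[top]), mean(cc[top]))
}
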