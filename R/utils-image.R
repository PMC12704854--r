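# Image primitives. The canonical in-memory image is a numeric H x W x 3
# array with intensities in [0, 1], quantized to 8-bit levels (multiples of
# 1/255) wherever a frame crosses a module boundary.

assert_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort(sprintf("%s must be an H x W x 3 array", what))
  }
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Snap to the 256 representable 8-bit levels.
quantize8 <- function(img) {
  img[] <- round(clamp01(img) * 255) / 255
  img
}

# ITU-R BT.601 luma weights.
LUMA <- c(0.299, 0.587, 0.114)

#' Luminance of an RGB image
#'
#' Standard perceptual luma (0.299, 0.587, 0.114) used everywhere the package
#' converts colour to grayscale (peripheral rod processing, the grayscale
#' augmentation).
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @return H x W matrix of luminances.
#' @export
luminance <- function(img) {
  assert_image(img)
  LUMA[1] * img[, , 1] + LUMA[2] * img[, , 2] + LUMA[3] * img[, , 3]
}

gray_rgb <- function(img) {
  l <- luminance(img)
  array(c(l, l, l), dim = dim(img))
}

# Bilinear sampling at continuous (row, col) coordinates, 1-based, border
# clamped. `ys`/`xs` are equal-length vectors (typically flattened grids).
# Flat single-index corner lookups are shared across channels for speed.
bilinear_sample <- function(img, ys, xs) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- ys - y0; fx <- xs - x0
  i00 <- (x0 - 1) * h + y0; i10 <- (x0 - 1) * h + y1
  i01 <- (x1 - 1) * h + y0; i11 <- (x1 - 1) * h + y1
  w00 <- (1 - fy) * (1 - fx); w10 <- fy * (1 - fx)
  w01 <- (1 - fy) * fx; w11 <- fy * fx
  out <- array(0, dim = c(length(ys), nc))
  plane <- h * w
  for (c in seq_len(nc)) {
    off <- (c - 1) * plane
    out[, c] <- img[i00 + off] * w00 + img[i10 + off] * w10 +
      img[i01 + off] * w01 + img[i11 + off] * w11
  }
  out
}

# Resize via bilinear sampling with half-pixel center alignment.
resize_bilinear <- function(img, out_h, out_w) {
  assert_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  sy <- h / out_h; sx <- w / out_w
  ys <- (seq_len(out_h) - 0.5) * sy + 0.5
  xs <- (seq_len(out_w) - 0.5) * sx + 0.5
  grid_y <- rep(ys, times = out_w)
  grid_x <- rep(xs, each = out_h)
  sam <- bilinear_sample(img, grid_y, grid_x)
  array(sam, dim = c(out_h, out_w, 3))
}

# Exact block-average downsample by an integer factor (e.g. 320 -> 64).
box_downsample <- function(img, factor) {
  assert_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(h %% factor == 0, w %% factor == 0)
  oh <- h %/% factor; ow <- w %/% factor
  out <- array(0, dim = c(oh, ow, 3))
  for (c in 1:3) {
    m <- img[, , c]
    # average rows within blocks, then columns
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = oh)
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = ow))
    out[, , c] <- m
  }
  out
}

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding, per channel.
blur_matrix <- function(m, k) {
  if (length(k) == 1) return(m)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # vertical pass
  mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(h, r), , drop = FALSE])
  acc <- matrix(0, h, w)
  for (i in seq_along(k)) acc <- acc + k[i] * mp[i:(i + h - 1), , drop = FALSE]
  # horizontal pass
  mp <- cbind(acc[, rep(1, r), drop = FALSE], acc, acc[, rep(w, r), drop = FALSE])
  acc <- matrix(0, h, w)
  for (i in seq_along(k)) acc <- acc + k[i] * mp[, i:(i + w - 1), drop = FALSE]
  acc
}

blur_gaussian <- function(img, sigma) {
  assert_image(img)
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  for (c in 1:3) img[, , c] <- blur_matrix(img[, , c], k)
  img
}

flip_horizontal <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

#' Read / write a frame as PNG
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path File path.
#' @return `read_frame_png()` returns an H x W x 3 array; `write_frame_png()`
#'   returns `path` invisibly.
#' @export
write_frame_png <- function(img, path) {
  assert_image(img)
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(c(x, x, x), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x
}
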