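# Artificial image augmentations used during contrastive training.
#
# The canonical augmentation diet applies five operations independently per
# image: random resized crop (always), horizontal flip (50%), Gaussian blur
# (50%), colour jitter (80%) and grayscale (20%).

#' Augmentation configuration
#'
#' @param p_blur,p_grayscale,p_crop,p_flip,p_jitter Application
#'   probabilities (defaults 0.5, 0.2, 1.0, 0.5, 0.8).
#' @param blur_sigma_range Sigma range of the Gaussian blur, pixels.
#' @param crop_scale Area-fraction range of the random resized crop.
#' @param crop_aspect Aspect-ratio range of the crop.
#' @param jitter_strength Named numeric: `brightness`, `contrast`,
#'   `saturation` factor half-ranges and `hue` shift half-range (fraction of
#'   the colour wheel).
#' @param enabled_ops Subset of
#'   `c("crop", "flip", "jitter", "grayscale", "blur")`; disabled operations
#'   are never applied regardless of probability.
#' @return An `augment_config` list.
#' @export
augment_config <- function(p_blur = 0.5, p_grayscale = 0.2, p_crop = 1.0,
                           p_flip = 0.5, p_jitter = 0.8,
                           blur_sigma_range = c(0.1, 2),
                           crop_scale = c(0.6, 1),
                           crop_aspect = c(3 / 4, 4 / 3),
                           jitter_strength = c(brightness = 0.4,
                                               contrast = 0.4,
                                               saturation = 0.4, hue = 0.1),
                           enabled_ops = c("crop", "flip", "jitter",
                                           "grayscale", "blur")) {
  ps <- c(p_blur, p_grayscale, p_crop, p_flip, p_jitter)
  if (any(ps < 0 | ps > 1)) abort("probabilities must be in [0, 1]")
  structure(list(p_blur = p_blur, p_grayscale = p_grayscale, p_crop = p_crop,
                 p_flip = p_flip, p_jitter = p_jitter,
                 blur_sigma_range = blur_sigma_range, crop_scale = crop_scale,
                 crop_aspect = crop_aspect, jitter_strength = jitter_strength,
                 enabled_ops = enabled_ops),
            class = "augment_config")
}

#' No-augmentation configuration
#' @return An `augment_config` with every operation disabled.
#' @export
augment_none <- function() augment_config(enabled_ops = character(0))

random_resized_crop <- function(img, scale, aspect) {
  h <- dim(img)[1]; w <- dim(img)[2]
  area <- runif(1, scale[1], scale[2]) * h * w
  ar <- exp(runif(1, log(aspect[1]), log(aspect[2])))
  ch <- min(h, max(1, round(sqrt(area / ar))))
  cw <- min(w, max(1, round(sqrt(area * ar))))
  top <- sample.int(h - ch + 1L, 1L)
  left <- sample.int(w - cw + 1L, 1L)
  crop <- img[top + seq_len(ch) - 1L, left + seq_len(cw) - 1L, , drop = FALSE]
  resize_bilinear(crop, h, w)
}

color_jitter <- function(img, strength) {
  b <- strength[["brightness"]]; cst <- strength[["contrast"]]
  s <- strength[["saturation"]]; hmax <- strength[["hue"]]
  img <- img * runif(1, 1 - b, 1 + b)
  mu <- mean(luminance(clamp01(img)))
  img <- (img - mu) * runif(1, 1 - cst, 1 + cst) + mu
  g <- gray_rgb(clamp01(img))
  img <- g + runif(1, 1 - s, 1 + s) * (img - g)
  theta <- runif(1, -hmax, hmax) * 2 * pi
  # hue rotation about the luminance axis (YIQ approximation)
  u <- cos(theta); wv <- sin(theta)
  M <- matrix(c(
    0.299 + 0.701 * u + 0.168 * wv, 0.587 - 0.587 * u + 0.330 * wv,
    0.114 - 0.114 * u - 0.497 * wv,
    0.299 - 0.299 * u - 0.328 * wv, 0.587 + 0.413 * u + 0.035 * wv,
    0.114 - 0.114 * u + 0.292 * wv,
    0.299 - 0.300 * u + 1.250 * wv, 0.587 - 0.588 * u - 1.050 * wv,
    0.114 + 0.886 * u - 0.203 * wv), 3, 3, byrow = TRUE)
  d <- dim(img)
  flat <- matrix(img, ncol = 3)
  clamp01(array(flat %*% t(M), dim = d))
}

#' Apply the augmentation pipeline to one image
#'
#' Each enabled operation fires independently with its configured
#' probability, drawing from the current RNG stream (wrap the call in a
#' seeded context for reproducibility). Output shape always equals input
#' shape. The operations actually applied are recorded in the
#' `"ops_applied"` attribute.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param config An [augment_config()].
#' @return Augmented image, same shape, with attribute `ops_applied`.
#' @export
apply_augmentations <- function(image, config) {
  assert_image(image)
  applied <- character(0)
  on_ops <- config$enabled_ops
  if ("crop" %in% on_ops && runif(1) < config$p_crop) {
    image <- random_resized_crop(image, config$crop_scale, config$crop_aspect)
    applied <- c(applied, "crop")
  }
  if ("flip" %in% on_ops && runif(1) < config$p_flip) {
    image <- flip_horizontal(image)
    applied <- c(applied, "flip")
  }
  if ("jitter" %in% on_ops && runif(1) < config$p_jitter) {
    image <- color_jitter(image, config$jitter_strength)
    applied <- c(applied, "jitter")
  }
  if ("grayscale" %in% on_ops && runif(1) < config$p_grayscale) {
    image <- gray_rgb(image)
    applied <- c(applied, "grayscale")
  }
  if ("blur" %in% on_ops && runif(1) < config$p_blur) {
    image <- blur_gaussian(image,
                           runif(1, config$blur_sigma_range[1],
                                 config$blur_sigma_range[2]))
    applied <- c(applied, "blur")
  }
  image <- clamp01(image)
  attr(image, "ops_applied") <- applied
  image
}
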