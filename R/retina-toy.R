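# Toy artificial retinas: full-colour fovea, grayscale (rod-like) periphery.

#' Toy retina configuration
#'
#' A toy retina keeps full colour inside a circular fovea and converts the
#' periphery to luminance, mimicking rod processing; the filtered image is
#' then downsampled for model training. Filters are parameterized by the
#' foveal radius; the canonical bank varies it over
#' 0, 7.5, 15, 30, 60 and 120 pixels at 320 x 320 input resolution.
#'
#' @param fovea_radius Foveal radius in input pixels (>= 0).
#' @param input_resolution Input image side (default 320).
#' @param output_resolution Output side after downsampling (default 64).
#' @param fovea_center `(row, col)` centre; default image centre.
#' @return A `toy_retina_config` list.
#' @export
toy_retina_config <- function(fovea_radius = 30, input_resolution = 320,
                              output_resolution = 64, fovea_center = NULL) {
  if (fovea_radius < 0) abort("fovea_radius must be >= 0")
  center <- fovea_center %||% c((input_resolution + 1) / 2,
                                (input_resolution + 1) / 2)
  if (any(center < 1) || any(center > input_resolution)) {
    abort("fovea_center must lie inside the image")
  }
  structure(list(fovea_radius = fovea_radius,
                 input_resolution = input_resolution,
                 output_resolution = output_resolution,
                 fovea_center = center),
            class = "toy_retina_config")
}

#' The canonical bank of six toy retinas
#'
#' @param radii Foveal radii in pixels; defaults to the canonical six.
#' @param ... Passed to [toy_retina_config()].
#' @return List of `toy_retina_config`s, named by radius.
#' @export
toy_retina_bank <- function(radii = c(0, 7.5, 15, 30, 60, 120), ...) {
  setNames(lapply(radii, function(r) toy_retina_config(fovea_radius = r, ...)),
           paste0("r", radii))
}

#' Binary fovea mask
#'
#' `TRUE` iff the squared distance of a pixel from `center` is at most
#' `radius^2`; the complement is the peripheral mask.
#'
#' @param height,width Mask dimensions.
#' @param center `(row, col)` centre.
#' @param radius Foveal radius in pixels (>= 0).
#' @return A logical `height` x `width` matrix.
#' @export
fovea_mask <- function(height, width, center = c((height + 1) / 2, (width + 1) / 2),
                       radius) {
  if (radius < 0) abort("radius must be >= 0")
  dr <- matrix(rep(seq_len(height) - center[1], times = width), height)
  dc <- matrix(rep(seq_len(width) - center[2], each = height), height)
  dr^2 + dc^2 <= radius^2
}

#' Apply a toy retina to an image
#'
#' Peripheral pixels are replaced by their luminance (all three channels set
#' to the luma value); foveal pixels pass through unchanged; the result is
#' downsampled to the configured output resolution.
#'
#' @param image H x W x 3 array at the configured input resolution.
#' @param config A [toy_retina_config()].
#' @return Filtered image at `output_resolution`.
#' @export
apply_toy_retina <- function(image, config) {
  assert_image(image)
  if (!all(dim(image)[1:2] == config$input_resolution)) {
    abort("image resolution does not match config$input_resolution")
  }
  mask <- fovea_mask(config$input_resolution, config$input_resolution,
                     config$fovea_center, config$fovea_radius)
  out <- gray_rgb(image)
  for (ch in 1:3) {
    m <- out[, , ch]; m[mask] <- image[, , ch][mask]
    out[, , ch] <- m
  }
  if (config$output_resolution != config$input_resolution) {
    if (config$input_resolution %% config$output_resolution == 0) {
      out <- box_downsample(out, config$input_resolution %/% config$output_resolution)
    } else {
      out <- resize_bilinear(out, config$output_resolution, config$output_resolution)
    }
  }
  quantize8(out)
}
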