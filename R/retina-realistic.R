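# Biologically inspired artificial retina: rod/cone receptor mosaic,
# peripheral blur and clutter, cortical magnification, smooth fovea-periphery
# blending and optic-flow-driven dynamic foveation.

#' Realistic retina configuration
#'
#' Emulates hallmark features of the vertebrate eye: a cone-dominated fovea
#' (99% cones by default) and rod-dominated periphery (1% cones), receptive
#' fields that grow with eccentricity (peripheral Gaussian blur), peripheral
#' visual clutter (seeded radial distortion), cortical magnification of the
#' foveal region, a smooth transition between the two zones, and a fovea that
#' can relocate to the most salient (highest optical-flow) region across
#' successive frames.
#'
#' @param fovea_radius Foveal radius in pixels; the canonical settings use
#'   15 and 30 at 320 x 320 input.
#' @param cone_fraction_fovea,cone_fraction_periphery Per-pixel cone
#'   probabilities (defaults 0.99 and 0.01; rod fractions are their
#'   complements).
#' @param peripheral_blur_sigma Gaussian blur sigma applied to the periphery
#'   (pixels).
#' @param clutter_intensity Scale of the peripheral radial distortion
#'   (pixels; 0 disables).
#' @param magnification_strength Exponent of the foveal magnification remap
#'   (0 = identity).
#' @param transition_width Width in pixels of the fovea-periphery blending
#'   ramp (> 0).
#' @param dynamic_fovea If `TRUE`, the fovea follows the flow-saliency centre
#'   of the preceding frame pair.
#' @param mosaic_seed Seed for the receptor mosaic and clutter noise.
#' @param input_resolution,output_resolution Image sides before/after
#'   downsampling.
#' @return A `realistic_retina_config` list.
#' @export
realistic_retina_config <- function(fovea_radius = 30,
                                    cone_fraction_fovea = 0.99,
                                    cone_fraction_periphery = 0.01,
                                    peripheral_blur_sigma = 1.5,
                                    clutter_intensity = 1,
                                    magnification_strength = 0.25,
                                    transition_width = 6,
                                    dynamic_fovea = TRUE,
                                    mosaic_seed = 1,
                                    input_resolution = 320,
                                    output_resolution = 64) {
  if (cone_fraction_fovea < 0 || cone_fraction_fovea > 1 ||
      cone_fraction_periphery < 0 || cone_fraction_periphery > 1) {
    abort("cone fractions must be in [0, 1]")
  }
  if (peripheral_blur_sigma < 0 || clutter_intensity < 0 ||
      magnification_strength < 0) {
    abort("blur, clutter and magnification parameters must be >= 0")
  }
  if (transition_width <= 0) abort("transition_width must be > 0")
  structure(list(fovea_radius = fovea_radius,
                 cone_fraction_fovea = cone_fraction_fovea,
                 cone_fraction_periphery = cone_fraction_periphery,
                 peripheral_blur_sigma = peripheral_blur_sigma,
                 clutter_intensity = clutter_intensity,
                 magnification_strength = magnification_strength,
                 transition_width = transition_width,
                 dynamic_fovea = dynamic_fovea,
                 mosaic_seed = mosaic_seed,
                 input_resolution = input_resolution,
                 output_resolution = output_resolution),
            class = "realistic_retina_config")
}

#' Sample a rod/cone receptor mosaic
#'
#' Each foveal pixel is a cone with probability `cone_fraction_fovea`,
#' each peripheral pixel with probability `cone_fraction_periphery`,
#' independently; remaining pixels are rods. Seeded and reproducible.
#'
#' @param config A [realistic_retina_config()].
#' @param height,width Grid dimensions.
#' @param center Fovea centre `(row, col)`; default grid centre.
#' @return A `receptor_mosaic`: logical `is_cone` matrix plus the fovea mask
#'   and provenance seed.
#' @export
sample_mosaic <- function(config, height, width,
                          center = c((height + 1) / 2, (width + 1) / 2)) {
  mask <- fovea_mask(height, width, center, config$fovea_radius)
  p <- ifelse(mask, config$cone_fraction_fovea, config$cone_fraction_periphery)
  is_cone <- with_seed(derive_seed(config$mosaic_seed, "mosaic"), {
    matrix(runif(height * width) < p, height, width)
  })
  structure(list(is_cone = is_cone, fovea = mask, seed = config$mosaic_seed),
            class = "receptor_mosaic")
}

#' Cortical magnification warp
#'
#' Radially symmetric remap applied inside the fovea only: an output pixel at
#' radius `r < fovea_radius` from the centre samples the input at
#' `r * (r / fovea_radius)^strength`, so content near the centre is
#' progressively expanded (zoomed in) while the fovea boundary and everything
#' outside it are fixed points. `strength = 0` is the identity.
#'
#' @param image H x W x 3 array.
#' @param fovea_center `(row, col)` centre of the warp.
#' @param fovea_radius Radius of the magnified region (pixels).
#' @param strength Nonnegative magnification exponent.
#' @return Warped image of the same shape.
#' @export
cortical_magnify <- function(image, fovea_center, fovea_radius, strength) {
  assert_image(image)
  if (strength < 0) abort("strength must be >= 0")
  if (strength == 0 || fovea_radius <= 0) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  dr <- matrix(rep(seq_len(h) - fovea_center[1], times = w), h)
  dc <- matrix(rep(seq_len(w) - fovea_center[2], each = h), h)
  r <- sqrt(dr^2 + dc^2)
  inside <- r < fovea_radius & r > 0
  scale <- matrix(1, h, w)
  scale[inside] <- (r[inside] / fovea_radius)^strength
  ys <- fovea_center[1] + dr * scale
  xs <- fovea_center[2] + dc * scale
  out <- image
  idx <- which(inside)
  if (length(idx) > 0) {
    sam <- bilinear_sample(image, ys[idx], xs[idx])
    for (ch in 1:3) {
      m <- out[, , ch]; m[idx] <- sam[, ch]
      out[, , ch] <- m
    }
  }
  out
}

#' Peripheral degradation: Gaussian blur plus visual clutter
#'
#' The periphery (complement of `mask`) is blurred with a Gaussian of
#' `blur_sigma` and displaced by a seeded smooth radial distortion whose
#' magnitude scales with `clutter_intensity`, emulating larger receptive
#' fields and crowding away from fixation. Foveal pixels are untouched.
#'
#' @param image H x W x 3 array.
#' @param mask Logical fovea mask (TRUE = fovea).
#' @param blur_sigma Gaussian sigma in pixels (>= 0).
#' @param clutter_intensity Radial displacement scale in pixels (>= 0).
#' @param seed Seed for the clutter noise field.
#' @return Degraded image of the same shape.
#' @export
peripheral_degrade <- function(image, mask, blur_sigma, clutter_intensity,
                               seed = 1) {
  assert_image(image)
  if (blur_sigma < 0 || clutter_intensity < 0) {
    abort("blur_sigma and clutter_intensity must be >= 0")
  }
  if (blur_sigma == 0 && clutter_intensity == 0) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- blur_gaussian(image, blur_sigma)
  if (clutter_intensity > 0) {
    # smooth seeded noise field modulating a radial displacement
    noise <- with_seed(derive_seed(seed, "clutter"), {
      matrix(runif(h * w, -1, 1), h, w)
    })
    noise <- blur_matrix(noise, gaussian_kernel1d(3))
    ctr <- if (any(mask)) {
      rr0 <- matrix(rep(seq_len(h), times = w), h)
      cc0 <- matrix(rep(seq_len(w), each = h), h)
      c(mean(rr0[mask]), mean(cc0[mask]))
    } else c((h + 1) / 2, (w + 1) / 2)
    dr <- matrix(rep(seq_len(h) - ctr[1], times = w), h)
    dc <- matrix(rep(seq_len(w) - ctr[2], each = h), h)
    r <- pmax(sqrt(dr^2 + dc^2), 1e-9)
    disp <- clutter_intensity * noise
    ys <- matrix(rep(seq_len(h), times = w), h) + disp * dr / r
    xs <- matrix(rep(seq_len(w), each = h), h) + disp * dc / r
    sam <- bilinear_sample(out, as.vector(ys), as.vector(xs))
    for (ch in 1:3) out[, , ch] <- matrix(sam[, ch], h, w)
  }
  # fovea untouched
  for (ch in 1:3) {
    m <- out[, , ch]; m[mask] <- image[, , ch][mask]
    out[, , ch] <- m
  }
  out
}

apply_realistic_one <- function(image, config, center, frame_tag) {
  h <- dim(image)[1]; w <- dim(image)[2]
  mask <- fovea_mask(h, w, center, config$fovea_radius)
  mos_cfg <- config
  mos_cfg$mosaic_seed <- derive_seed(config$mosaic_seed, frame_tag)
  mosaic <- sample_mosaic(mos_cfg, h, w, center)
  # rod pixels carry luminance only, cone pixels full colour
  lum <- luminance(image)
  m1 <- image
  for (ch in 1:3) {
    chm <- m1[, , ch]; chm[!mosaic$is_cone] <- lum[!mosaic$is_cone]
    m1[, , ch] <- chm
  }
  p <- peripheral_degrade(m1, mask, config$peripheral_blur_sigma,
                          config$clutter_intensity,
                          seed = mos_cfg$mosaic_seed)
  g <- cortical_magnify(p, center, config$fovea_radius,
                        config$magnification_strength)
  # smooth fovea-periphery blend over transition_width
  dr <- matrix(rep(seq_len(h) - center[1], times = w), h)
  dc <- matrix(rep(seq_len(w) - center[2], each = h), h)
  r <- sqrt(dr^2 + dc^2)
  wgt <- clamp01((config$fovea_radius + config$transition_width / 2 - r) /
                   config$transition_width)
  out <- g
  for (ch in 1:3) out[, , ch] <- wgt * g[, , ch] + (1 - wgt) * p[, , ch]
  out
}

#' Apply the realistic retina to a temporally ordered frame stream
#'
#' Per frame: (1) the fovea centre is the flow-saliency centre of the
#' preceding frame pair when `dynamic_fovea` is on (fixed image centre
#' otherwise, and for the first frame); (2) the receptor mosaic is applied —
#' rod pixels carry luminance only; (3) peripheral blur and clutter;
#' (4) cortical magnification; (5) smooth fovea-periphery blending; finally
#' the frame is downsampled to the configured output resolution.
#'
#' @param frames A frame-stream tibble (with an `image` list-column) or a
#'   plain list of H x W x 3 arrays.
#' @param config A [realistic_retina_config()].
#' @param flow_fn Flow estimator honouring the [estimate_flow()] contract.
#' @return Same container as `frames` with filtered images; tibble input
#'   gains `fovea_row`/`fovea_col` columns recording the per-frame centre.
#' @export
apply_realistic_retina <- function(frames, config, flow_fn = estimate_flow) {
  is_tbl <- is.data.frame(frames)
  imgs <- if (is_tbl) frames$image else frames
  n <- length(imgs)
  if (n == 0) abort("no frames supplied", class = "empty_input")
  if (config$dynamic_fovea && n < 2) {
    warn("dynamic_fovea needs at least 2 frames; falling back to fixed centre")
  }
  centers <- matrix(0, n, 2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    img <- imgs[[i]]
    assert_image(img)
    h <- dim(img)[1]; w <- dim(img)[2]
    center <- c((h + 1) / 2, (w + 1) / 2)
    if (config$dynamic_fovea && i >= 2) {
      center <- saliency_center(flow_fn(imgs[[i - 1]], imgs[[i]]))
    }
    centers[i, ] <- center
    res <- apply_realistic_one(img, config, center, paste0("frame", i))
    if (config$output_resolution != h) {
      res <- if (h %% config$output_resolution == 0) {
        box_downsample(res, h %/% config$output_resolution)
      } else {
        resize_bilinear(res, config$output_resolution, config$output_resolution)
      }
    }
    out[[i]] <- quantize8(res)
  }
  if (is_tbl) {
    frames$image <- out
    frames$fovea_row <- centers[, 1]
    frames$fovea_col <- centers[, 2]
    frames
  } else {
    out
  }
}
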