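# Flat-shaded projective rasterizer for the virtual chamber.
#
# A deliberate replacement for a full game-engine renderer: the analyses
# downstream depend on the shape/colour/view statistics of the streams, not
# on photorealism, so frames are white walls plus the silhouette of the
# currently visible object face, projected through a pinhole camera.

#' Default colour vocabulary
#'
#' RGB values for the built-in colour identifiers.
#' @return Named list of length-3 RGB vectors in `[0, 1]`.
#' @export
default_colors <- function() {
  list(red = c(0.9, 0.1, 0.1), green = c(0.1, 0.75, 0.2),
       blue = c(0.15, 0.25, 0.9), yellow = c(0.95, 0.85, 0.1))
}

#' Default shape vocabulary
#' @return Character vector of shape identifiers with built-in silhouettes.
#' @export
default_shapes <- function() c("circle", "triangle", "square", "cross")

color_rgb <- function(color_id, palette = default_colors()) {
  rgb <- palette[[color_id]]
  if (is.null(rgb)) abort(sprintf("unknown color_id '%s'", color_id))
  rgb
}

# Inside-test for a unit silhouette: (u, v) in [-1, 1]^2, v up.
shape_inside <- function(shape_id, u, v) {
  switch(shape_id,
    circle   = u^2 + v^2 <= 1,
    square   = abs(u) <= 0.886 & abs(v) <= 0.886, # area-matched to circle
    triangle = v >= -0.8 & v <= 1.2 & abs(u) <= 1.05 * (1.2 - v) / 2,
    cross    = (abs(u) <= 1/3 & abs(v) <= 1) | (abs(u) <= 1 & abs(v) <= 1/3),
    abort(sprintf("unknown shape_id '%s'", shape_id))
  )
}

# Camera basis from yaw/pitch/roll (degrees). Yaw 0 faces +y; yaw positive
# turns towards +x; pitch positive looks up; roll about the forward axis.
camera_basis <- function(yaw, pitch, roll) {
  d <- pi / 180
  cy <- cos(yaw * d); sy <- sin(yaw * d)
  cp <- cos(pitch * d); sp <- sin(pitch * d)
  cr <- cos(roll * d); sr <- sin(roll * d)
  # world axes: x lateral, y depth, z up
  fwd <- c(sy * cp, cy * cp, sp)
  right0 <- c(cy, -sy, 0)
  up0 <- c(-sy * sp, -cy * sp, cp)
  right <- cr * right0 + sr * up0
  up <- -sr * right0 + cr * up0
  list(fwd = fwd, right = right, up = up)
}

#' Render one first-person frame
#'
#' Deterministic rasterization of the agent's view: white walls, a shaded
#' floor band (wire-mesh lines under the default texture), and the silhouette
#' of the currently visible object face, foreshortened by the rotation angle
#' and scaled inversely with viewing distance. Near edge-on (within 5 deg)
#' the object is drawn as a thin band showing both face colours split at the
#' rotation axis, since the physical object's edge looks identical during
#' either transition.
#'
#' @param chamber A [chamber_spec()].
#' @param object An [object_spec()].
#' @param pose One-row pose (list or tibble row) with `x`, `y`, `yaw`,
#'   `pitch`, `roll`.
#' @param t Time in seconds (drives the rotation angle).
#' @param resolution Output image side in pixels (default 64).
#' @param palette Colour lookup, as from [default_colors()].
#' @return `resolution` x `resolution` x 3 array in `[0, 1]`, 8-bit quantized.
#' @export
render_frame <- function(chamber, object, pose, t, resolution = 64,
                         palette = default_colors()) {
  x <- pose$x; y <- pose$y
  if (abs(x) > chamber$half_x || abs(y) > chamber$half_y) {
    abort("pose is outside the chamber footprint")
  }
  res <- as.integer(resolution)
  img <- array(1, dim = c(res, res, 3))
  f <- (res / 2) / tan(chamber$fov_deg / 2 * pi / 180)
  cx <- (res + 1) / 2; cy <- (res + 1) / 2
  basis <- camera_basis(pose$yaw, pose$pitch, pose$roll)

  # floor band: horizon where the eye-level ray meets the floor plane drops
  # out of frame; approximate with the pitch-shifted horizon line
  horizon <- cy + f * tan(pose$pitch * pi / 180)
  rows_idx <- seq_len(res)
  floor_rows <- rows_idx[rows_idx > horizon + res * 0.25]
  if (length(floor_rows) > 0) {
    shade <- 0.82
    img[floor_rows, , 1] <- shade; img[floor_rows, , 2] <- shade
    img[floor_rows, , 3] <- shade
    if (chamber$floor_texture == "mesh") {
      mesh <- floor_rows[floor_rows %% max(4L, res %/% 16L) == 0L]
      img[mesh, , 1] <- 0.55; img[mesh, , 2] <- 0.55; img[mesh, , 3] <- 0.55
    }
  }

  # object centre: mounted at eye height on the active display wall (north)
  pw <- c(0 - x, chamber$half_y - y, 0)
  depth <- sum(pw * basis$fwd)
  if (depth > 0.15) {
    u0 <- f * sum(pw * basis$right) / depth
    v0 <- f * sum(pw * basis$up) / depth
    # apparent half extents (chamber units -> pixels)
    hw <- object$width_cm / 2 / CM_PER_UNIT
    hh <- object$height_cm / 2 / CM_PER_UNIT
    ang <- object_angle(t, object$rotation_period_s)
    fshort <- abs(cos(ang * pi / 180))
    face <- visible_face(ang)
    a <- f * hw * max(fshort, 0.045) / depth
    b <- f * hh / depth
    # pixel offsets relative to the projected centre, roll-aligned
    col_off <- matrix(rep(seq_len(res) - cx, each = res), res) - u0
    row_off <- -(matrix(rep(seq_len(res) - cy, times = res), res)) - v0
    if (face == "edge") {
      inside <- abs(col_off) <= a & abs(row_off) <= b
      left <- inside & col_off < 0
      right <- inside & col_off >= 0
      ca <- color_rgb(object$face_a$color_id, palette)
      cb <- color_rgb(object$face_b$color_id, palette)
      for (ch in 1:3) {
        m <- img[, , ch]; m[left] <- ca[ch]; m[right] <- cb[ch]
        img[, , ch] <- m
      }
    } else {
      fc <- if (face == "a") object$face_a else object$face_b
      inside <- shape_inside(fc$shape_id, col_off / a, row_off / b)
      rgbv <- color_rgb(fc$color_id, palette)
      for (ch in 1:3) {
        m <- img[, , ch]; m[inside] <- rgbv[ch]
        img[, , ch] <- m
      }
    }
  }
  quantize8(img)
}

#' Render one test-stimulus image
#'
#' A single object (one shape/colour on both faces) centred on a uniform
#' white background, at the rotation angle `angle_deg` (0 = frontal), with
#' the silhouette foreshortened accordingly.
#'
#' @param shape_id,color_id Object attributes.
#' @param angle_deg Rotation angle in degrees.
#' @param resolution Image side in pixels.
#' @param palette Colour lookup.
#' @return `resolution` x `resolution` x 3 array.
#' @export
render_stimulus <- function(shape_id, color_id, angle_deg = 0, resolution = 64,
                            palette = default_colors()) {
  res <- as.integer(resolution)
  img <- array(1, dim = c(res, res, 3))
  cx <- (res + 1) / 2
  b <- 0.33 * res
  a <- b * (9 / 7) * max(abs(cos(angle_deg * pi / 180)), 0.045)
  col_off <- matrix(rep(seq_len(res) - cx, each = res), res)
  row_off <- -matrix(rep(seq_len(res) - cx, times = res), res)
  inside <- shape_inside(shape_id, col_off / a, row_off / b)
  rgbv <- color_rgb(color_id, palette)
  for (ch in 1:3) {
    m <- img[, , ch]; m[inside] <- rgbv[ch]
    img[, , ch] <- m
  }
  quantize8(img)
}
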