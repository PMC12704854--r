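# Artificial retinas: masks, toy filtering, mosaics, flow, magnification,
# peripheral degradation, and the composed realistic retina.

test_that("fovea mask matches a brute-force distance check and partitions the image", {
  m <- fovea_mask(320, 320, radius = 7.5)
  ctr <- c(160.5, 160.5)
  brute <- 0L
  for (r in 150:171) for (c in 150:171) {
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 7.5^2) brute <- brute + 1L
  }
  expect_equal(sum(m), brute)

  expect_false(any(fovea_mask(320, 320, radius = 0)))       # pure periphery
  expect_true(all(fovea_mask(320, 320, radius = 500)))      # radius > diagonal
  # mask and its complement partition every configuration
  expect_equal(sum(m) + sum(!m), 320L * 320L)
})

test_that("toy retina keeps colour in the fovea and luminance outside", {
  img <- fx_seeded_image(1, 320)

  # radius 0: every output pixel is achromatic
  out0 <- apply_toy_retina(img, toy_retina_config(0))
  expect_equal(out0[, , 1], out0[, , 2])
  expect_equal(out0[, , 2], out0[, , 3])

  # achromatic input is unchanged up to plain downsampling, any radius
  g <- rearviews:::gray_rgb(img)
  outg <- apply_toy_retina(g, toy_retina_config(30))
  expect_equal(outg, rearviews:::quantize8(rearviews:::box_downsample(g, 5)))

  # full-frame fovea: plain downsampled colour input
  outf <- apply_toy_retina(img, toy_retina_config(500))
  expect_equal(outf, rearviews:::quantize8(rearviews:::box_downsample(img, 5)))

  # periphery commutes with the luminance oracle pixel-exactly (no
  # downsampling)
  cfg <- toy_retina_config(20, input_resolution = 64, output_resolution = 64)
  img64 <- fx_seeded_image(2, 64)
  out <- apply_toy_retina(img64, cfg)
  mask <- fovea_mask(64, 64, radius = 20)
  lum <- rearviews:::quantize8(rearviews:::gray_rgb(img64))
  for (ch in 1:3) {
    expect_equal(out[, , ch][!mask], lum[, , ch][!mask])
    expect_equal(out[, , ch][mask], img64[, , ch][mask])
  }

  expect_error(apply_toy_retina(img64, toy_retina_config(10)), "resolution")
  expect_length(toy_retina_bank(), 6)
  expect_equal(vapply(toy_retina_bank(), `[[`, numeric(1), "fovea_radius"),
               c(r0 = 0, r7.5 = 7.5, r15 = 15, r30 = 30, r60 = 60, r120 = 120))
})

test_that("receptor mosaics realise the configured cone fractions", {
  cfg <- realistic_retina_config(fovea_radius = 60, mosaic_seed = 4)
  mos <- sample_mosaic(cfg, 320, 320)
  n_fov <- sum(mos$fovea)
  expect_gt(n_fov, 1e4)
  # realised foveal cone fraction within 3 sigma of 99%
  p <- cfg$cone_fraction_fovea
  expect_lt(abs(mean(mos$is_cone[mos$fovea]) - p),
            3 * sqrt(p * (1 - p) / n_fov) + 1e-12)
  # periphery within 3 sigma of 1%
  q <- cfg$cone_fraction_periphery
  n_per <- sum(!mos$fovea)
  expect_lt(abs(mean(mos$is_cone[!mos$fovea]) - q),
            3 * sqrt(q * (1 - q) / n_per))

  # degenerate probability 1: every foveal pixel a cone
  cfg1 <- realistic_retina_config(fovea_radius = 40, cone_fraction_fovea = 1)
  mos1 <- sample_mosaic(cfg1, 128, 128)
  expect_true(all(mos1$is_cone[mos1$fovea]))

  expect_identical(sample_mosaic(cfg, 320, 320)$is_cone, mos$is_cone)
  cfg_b <- realistic_retina_config(fovea_radius = 60, mosaic_seed = 5)
  expect_false(identical(sample_mosaic(cfg_b, 320, 320)$is_cone, mos$is_cone))
})

test_that("optical flow recovers a known displacement and is antisymmetric", {
  sq <- fx_moving_square()
  fl <- estimate_flow(sq$f0, sq$f1)
  expect_lt(abs(stats::median(fl$dy[sq$inside]) - sq$dy), 1)
  expect_lt(abs(stats::median(fl$dx[sq$inside]) - sq$dx), 1)

  # identical frames: zero magnitude everywhere
  fl0 <- estimate_flow(sq$f0, sq$f0)
  expect_equal(max(fl0$magnitude), 0)

  # swapped argument order approximately negates the flow in the square
  flr <- estimate_flow(sq$f1, sq$f0)
  expect_lt(abs(stats::median(flr$dy[sq$inside]) + sq$dy), 1)

  expect_error(estimate_flow(sq$f0, sq$f0[1:32, 1:32, ]), "shape")
})

test_that("saliency centre finds the dominant mover and falls back to the image centre", {
  sq <- fx_moving_square()
  ctr <- saliency_center(estimate_flow(sq$f0, sq$f1))
  # inside the moving square's bounding box (union over both frames)
  expect_true(ctr[1] >= 20 && ctr[1] <= 35)
  expect_true(ctr[2] >= 20 && ctr[2] <= 32)

  z <- matrix(0, 64, 64)
  zero_field <- structure(list(dy = z, dx = z, magnitude = z),
                          class = "flow_field")
  expect_equal(saliency_center(zero_field), c(32.5, 32.5))

  two <- z; two[10:14, 10:14] <- 1; two[40:44, 40:44] <- 2
  two_field <- structure(list(dy = z, dx = z, magnitude = two),
                         class = "flow_field")
  expect_equal(saliency_center(two_field), c(42, 42))
})

test_that("cortical magnification expands central content and fixes the centre", {
  img <- fx_seeded_image(3, 64)
  expect_identical(cortical_magnify(img, c(32.5, 32.5), 25, 0), img)

  # a central dark disc strictly grows under magnification (area oracle)
  disc <- array(1, dim = c(64, 64, 3))
  dm <- fovea_mask(64, 64, radius = 6)
  for (ch in 1:3) { m <- disc[, , ch]; m[dm] <- 0; disc[, , ch] <- m }
  mag <- cortical_magnify(disc, c(32.5, 32.5), 25, 0.5)
  expect_gt(sum(mag[, , 1] < 0.5), sum(disc[, , 1] < 0.5))

  # the fovea centre is a fixed point
  ctr_px <- img[33, 33, ]
  magc <- cortical_magnify(img, c(33, 33), 20, 0.8)
  expect_equal(magc[33, 33, ], ctr_px, tolerance = 1e-12)
  expect_error(cortical_magnify(img, c(32, 32), 20, -1), ">= 0")
})

test_that("peripheral degradation blurs and distorts outside the fovea only", {
  img <- fx_seeded_image(4, 64)
  mask <- fovea_mask(64, 64, radius = 12)

  expect_identical(peripheral_degrade(img, mask, 0, 0), img)

  # constant field invariance (blur and displacement are no-ops)
  const <- array(0.5, dim = c(64, 64, 3))
  dg <- peripheral_degrade(const, mask, 2, 1.5, seed = 3)
  expect_equal(dg, const, tolerance = 1e-12)

  # fovea pixels untouched
  out <- peripheral_degrade(img, mask, 2, 1, seed = 1)
  for (ch in 1:3) expect_equal(out[, , ch][mask], img[, , ch][mask])

  # step edge: peripheral gradient magnitude drops below the foveal one
  step <- array(0, dim = c(64, 64, 3)); step[, 33:64, ] <- 1
  mask_l <- fovea_mask(64, 64, center = c(32.5, 32.5), radius = 10)
  bl <- peripheral_degrade(step, mask_l, 2, 0)
  gradmag <- function(m) abs(m[, 2:64] - m[, 1:63])
  g <- gradmag(bl[, , 1])
  fov_cols <- 31:34; per_rows <- c(1:10, 55:64)
  expect_gt(max(g[28:36, fov_cols]), max(g[per_rows, fov_cols]))

  # monotonicity: more blur never increases mean peripheral gradient
  grads <- vapply(c(0, 1, 2, 4), function(s) {
    b <- peripheral_degrade(step, mask_l, s, 0)
    mean(gradmag(b[, , 1])[per_rows, ])
  }, numeric(1))
  expect_true(all(diff(grads) <= 1e-12))
})

test_that("the composed realistic retina reduces to identity and tracks motion", {
  # all degradations zeroed + full-cone mosaic = identity
  cfg_id <- realistic_retina_config(
    fovea_radius = 10, cone_fraction_fovea = 1, cone_fraction_periphery = 1,
    peripheral_blur_sigma = 0, clutter_intensity = 0,
    magnification_strength = 0, dynamic_fovea = FALSE,
    input_resolution = 64, output_resolution = 64)
  img <- fx_seeded_image(5, 64)
  expect_identical(apply_realistic_retina(list(img), cfg_id)[[1]], img)

  # static pair with dynamic fovea: fallback centre, deterministic output
  cfg <- realistic_retina_config(fovea_radius = 12, input_resolution = 64,
                                 output_resolution = 64, mosaic_seed = 2)
  st <- tibble::tibble(index = 1:2, image = list(img, img))
  o1 <- apply_realistic_retina(st, cfg)
  expect_equal(o1$fovea_row, c(32.5, 32.5))
  o2 <- apply_realistic_retina(st, cfg)
  expect_identical(o1$image, o2$image)

  # single frame with dynamic fovea warns and falls back
  expect_warning(apply_realistic_retina(list(img), cfg), "at least 2")

  # moving bright bar: the fovea tracks it in at least 90% of frames
  mk <- function(top) {
    a <- array(0.2, dim = c(64, 64, 3))
    a[top:(top + 8), 28:36, 1] <- 1
    rearviews:::quantize8(a)
  }
  tops <- seq(6, 46, by = 4)
  stream <- tibble::tibble(index = seq_along(tops), image = lapply(tops, mk))
  out <- apply_realistic_retina(stream, cfg)
  hit <- out$fovea_row[-1] >= tops[-1] - 1 & out$fovea_row[-1] <= tops[-1] + 9 &
    abs(out$fovea_col[-1] - 32) <= 5
  expect_gte(mean(hit), 0.9)

  # 8-bit validity after the full cascade
  cfg_full <- realistic_retina_config(fovea_radius = 12, input_resolution = 64,
                                      output_resolution = 64)
  res <- apply_realistic_retina(list(img, mk(10)), cfg_full)
  for (r in res) expect_true(all(r >= 0 & r <= 1))
})
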