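# The virtual chamber world: grid geometry, rotation, trajectories,
# rendering and dataset generation.

test_that("teleport grid is equally spaced, inside the footprint, and has the canonical 49 cells", {
  ch <- chamber_spec()
  g <- make_grid_positions(7, 7, ch)
  expect_equal(nrow(g), 49)
  expect_equal(nrow(dplyr::distinct(g[, c("x", "y")])), 49)
  expect_true(all(abs(g$x) < ch$half_x & abs(g$y) < ch$half_y))

  # degenerate 1 x 1 grid sits at the footprint centre
  g1 <- make_grid_positions(1, 1, ch)
  expect_equal(c(g1$x, g1$y), c(0, 0))

  # 2 x 3: spacing constant along each axis, checked by exhaustive pairwise
  # differences
  g23 <- make_grid_positions(2, 3, ch)
  expect_equal(nrow(g23), 6)
  xs <- sort(unique(g23$x)); ys <- sort(unique(g23$y))
  expect_equal(diff(xs), rep(diff(xs)[1], length(xs) - 1))
  expect_equal(diff(ys), rep(diff(ys)[1], length(ys) - 1))
  expect_error(make_grid_positions(0, 3), "dimensions")
})

test_that("object rotation angle follows 360 t / period mod 360", {
  expect_equal(object_angle(0, 6), 0)
  expect_equal(object_angle(3, 6), 180)
  expect_equal(object_angle(6.6, 6), 36)
  expect_error(object_angle(1, 0), "positive")
})

test_that("dense exploration alternates transits at fixed speed with 95-frame dwells", {
  tr <- plan_trajectory(condition_policy("dense_exploration"), 400, seed = 2)
  expect_equal(nrow(tr), 400)
  expect_equal(diff(tr$t), rep(0.1, 399))

  # dwell runs are ceiling(9.5 s x 10 fps) = 95 consecutive constant-position
  # poses
  runs <- rle(tr$phase)
  full_dwells <- which(runs$values == "dwell" & runs$lengths == 95)
  expect_true(length(full_dwells) >= 1)
  ends <- cumsum(runs$lengths)
  i0 <- ends[full_dwells[1]] - 95 + 1
  expect_equal(length(unique(tr$x[i0:(i0 + 94)])), 1)
  # and head angles move during the dwell
  expect_gt(stats::sd(tr$yaw[i0:(i0 + 94)]), 0.1)

  # consecutive transit poses advance exactly move_speed / fps = 0.15 units
  it <- which(tr$phase == "transit")
  consec <- it[which(diff(it) == 1)]
  d <- sqrt(diff(tr$x[consec[1]:(consec[1] + 1)])^2 +
              diff(tr$y[consec[1]:(consec[1] + 1)])^2)
  expect_equal(d, 0.15, tolerance = 1e-10)

  expect_identical(tr, plan_trajectory(condition_policy("dense_exploration"),
                                       400, seed = 2))
})

test_that("teleport policies emit no transit poses and stay on their grids", {
  ch <- chamber_spec()
  grid <- make_grid_positions(7, 7, ch)
  tp <- plan_trajectory(condition_policy("no_transitional_views"), 500, seed = 3)
  expect_true(all(tp$phase == "dwell"))
  visited <- dplyr::distinct(tp[, c("x", "y")])
  # every visited position is one of the 49 grid cells
  hits <- vapply(seq_len(nrow(visited)), function(i) {
    any(abs(grid$x - visited$x[i]) < 1e-9 & abs(grid$y - visited$y[i]) < 1e-9)
  }, logical(1))
  expect_true(all(hits))
  # consecutive distinct positions jump at least one grid spacing
  jumps <- sqrt(diff(tp$x)^2 + diff(tp$y)^2)
  spacing <- min(diff(sort(unique(grid$x))))
  expect_true(all(jumps < 1e-9 | jumps >= spacing - 1e-9))

  ns <- plan_trajectory(condition_policy("no_side_to_side"), 400, seed = 3)
  expect_equal(length(unique(ns$x)), 1) # lateral coordinate constant
  expect_gt(length(unique(ns$y)), 1)    # depth varies

  nd <- plan_trajectory(condition_policy("no_depth"), 400, seed = 3)
  expect_equal(length(unique(nd$y)), 1) # depth coordinate constant
  expect_gt(length(unique(nd$x)), 1)

  nh <- plan_trajectory(condition_policy("no_head_movements"), 200, seed = 4)
  dw <- nh[nh$phase == "dwell", ]
  # gaze locked on the object: yaw determined by position alone
  expected_yaw <- atan2(-dw$x, chamber_spec()$half_y - dw$y) * 180 / pi
  expect_equal(dw$yaw, expected_yaw, tolerance = 1e-9)
})

test_that("renderer is deterministic, empties when facing a blank wall, and follows the rotation", {
  ch <- chamber_spec(); ob <- object_spec()
  pose <- list(x = 0, y = 0, yaw = 0, pitch = 0, roll = 0)
  f1 <- render_frame(ch, ob, pose, 0)
  expect_identical(f1, render_frame(ch, ob, pose, 0))
  expect_equal(dim(f1), c(64, 64, 3))

  # facing the opposite (blank) wall: no object pixels, pure background
  away <- list(x = 0, y = 0, yaw = 180, pitch = 0, roll = 0)
  fb <- render_frame(ch, ob, away, 0, resolution = 64)
  top <- fb[1:32, , ] # above the floor band
  expect_true(all(top == 1))

  # colour-histogram oracle: face A colours at t = 0, face B at t = 3
  count_color <- function(img, rgb) {
    sum(abs(img[, , 1] - rgb[1]) < 0.02 & abs(img[, , 2] - rgb[2]) < 0.02 &
          abs(img[, , 3] - rgb[3]) < 0.02)
  }
  pal <- default_colors()
  f0 <- render_frame(ch, ob, pose, 0)
  f3 <- render_frame(ch, ob, pose, 3)
  expect_gt(count_color(f0, pal$red), 0)
  expect_equal(count_color(f0, pal$blue), 0)
  expect_gt(count_color(f3, pal$blue), 0)
  expect_equal(count_color(f3, pal$red), 0)

  # apparent size shrinks monotonically with distance to the wall
  sizes <- vapply(c(2.5, 0, -2.5), function(y) {
    img <- render_frame(ch, ob, list(x = 0, y = y, yaw = 0, pitch = 0,
                                     roll = 0), 0)
    sum(img[, , 1] != 1)
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))

  expect_error(render_frame(ch, ob, list(x = 99, y = 0, yaw = 0, pitch = 0,
                                         roll = 0), 0), "outside")
})

test_that("condition datasets conserve frame counts, order and seeding", {
  p <- condition_policy("dense_exploration")
  ds <- generate_condition_dataset(p, object_spec(), 100, seed = 7)
  expect_equal(nrow(ds), 100)
  expect_true(all(diff(ds$index) == 1))
  expect_equal(diff(ds$t), rep(0.1, 99))
  expect_equal(ds$condition[1], "dense_exploration")
  ds2 <- generate_condition_dataset(p, object_spec(), 100, seed = 7)
  expect_identical(ds$image, ds2$image)
  # a different seed gives a different stream
  ds3 <- generate_condition_dataset(p, object_spec(), 100, seed = 8)
  expect_false(identical(ds$image, ds3$image))
  # frame-count conservation for every policy
  for (k in c("no_head_movements", "no_transitional_views", "no_side_to_side",
              "no_depth")) {
    expect_equal(nrow(generate_condition_dataset(condition_policy(k),
                                                 object_spec(), 57, seed = 1)),
                 57)
  }
})

test_that("the factorial stimulus set is complete, colour-faithful and deterministic", {
  s1 <- generate_stimulus_set()
  expect_equal(nrow(s1), 16)
  expect_equal(nrow(dplyr::distinct(s1[, c("shape_id", "color_id")])), 16)

  s29 <- generate_stimulus_set(views_per_object = 29)
  expect_equal(nrow(s29), 16 * 29)
  expect_equal(length(unique(s29$angle)), 29)

  # colour fidelity: modal non-background pixel colour equals the label
  pal <- default_colors()
  for (i in seq_len(nrow(s1))) {
    img <- s1$image[[i]]
    obj <- img[, , 1] != 1 | img[, , 2] != 1 | img[, , 3] != 1
    rgb <- c(stats::median(img[, , 1][obj]), stats::median(img[, , 2][obj]),
             stats::median(img[, , 3][obj]))
    expect_equal(rgb, unname(pal[[s1$color_id[i]]]), tolerance = 0.01)
  }

  # determinism: equal labels and view index give identical renders
  s1b <- generate_stimulus_set()
  expect_identical(s1$image, s1b$image)

  expect_error(generate_stimulus_set(shape_ids = rep("circle", 4)),
               "distinct")
  expect_error(generate_stimulus_set(color_ids = c("red", "red", "blue",
                                                   "green")), "distinct")
})

test_that("ingestion subsamples, resizes, truncates and preserves order", {
  # synthetic over-long stream: 120 frames, keep first 100
  imgs <- lapply(1:120, function(i) {
    a <- array(i / 120, dim = c(32, 32, 3)); rearviews:::quantize8(a)
  })
  st <- ingest_frames(imgs, fps = 10, resolution = 16, max_frames = 100)
  expect_equal(nrow(st), 100)
  expect_equal(dim(st$image[[1]]), c(16, 16, 3))
  # order preserved: mean intensity increases with index
  mu <- vapply(st$image, mean, numeric(1))
  expect_true(all(diff(mu) > 0))

  # truncation no-op for a short clip
  st10 <- ingest_frames(imgs[1:10], fps = 10, resolution = 16)
  expect_equal(nrow(st10), 10)

  # fps subsampling halves the count
  st2 <- ingest_frames(imgs, fps = 5, source_fps = 10, resolution = 16)
  expect_equal(nrow(st2), 60)

  expect_identical(st, ingest_frames(imgs, fps = 10, resolution = 16,
                                     max_frames = 100))
  expect_error(ingest_frames(list()), class = "empty_input")
  expect_error(ingest_frames("no/such/dir"), class = "io_error")
})

test_that("frame streams round-trip through PNG + manifest", {
  ds <- fx_stream(5)
  d <- withr::local_tempdir()
  write_frame_stream(ds, d, seed = 5)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_frame_stream(d)
  expect_equal(nrow(back), 5)
  expect_equal(back$image[[3]], ds$image[[3]], tolerance = 1 / 254)
  expect_equal(back$x, ds$x)
})
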