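# Frame-stream and stimulus-set generation.

#' Generate a first-person training stream for one rearing condition
#'
#' Plans a seeded trajectory under `policy` and renders every pose, producing
#' a temporally ordered stream of frame records. Full-scale streams use
#' 80,000 frames per condition; any smaller `n_frames` yields a prefix-like
#' desk-scale stream under the same movement statistics.
#'
#' @param policy A [condition_policy()].
#' @param object An [object_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; identical seeds give identical streams.
#' @param chamber A [chamber_spec()].
#' @param resolution Frame side in pixels (default 64).
#' @return A tibble with one row per frame: `index`, `t`, pose columns,
#'   `phase`, `condition`, and an `image` list-column of H x W x 3 arrays.
#' @export
generate_condition_dataset <- function(policy, object = object_spec(),
                                       n_frames, seed = 1,
                                       chamber = chamber_spec(),
                                       resolution = 64) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  traj <- plan_trajectory(policy, n_frames, seed = seed, chamber = chamber)
  traj$image <- lapply(seq_len(nrow(traj)), function(i) {
    render_frame(chamber, object, traj[i, ], traj$t[i], resolution = resolution)
  })
  traj$condition <- policy$kind
  traj
}

#' Generate the factorial test-stimulus set
#'
#' Renders the 16 test objects of the 4 shapes x 4 colours factorial design.
#' With `views_per_object = 1` (the RDM set) each object is rendered at the
#' frontal view; with more views (29 for the projection set) the views sample
#' distinct rotation angles of the object, evenly spaced across
#' `[-max_view_angle, max_view_angle]` so the silhouette stays identifiable.
#'
#' @param shape_ids Exactly 4 distinct shape identifiers.
#' @param color_ids Exactly 4 distinct colour identifiers.
#' @param views_per_object Views per object (>= 1; 1 for RDMs, 29 for 2-D
#'   projections).
#' @param resolution Image side in pixels.
#' @param max_view_angle Largest absolute rotation angle sampled (degrees).
#' @param palette Colour lookup.
#' @return A tibble with columns `object_id`, `shape_id`, `color_id`,
#'   `view_index`, `angle`, and an `image` list-column; 16 x
#'   `views_per_object` rows, shapes-major, colours-minor order.
#' @export
generate_stimulus_set <- function(shape_ids = default_shapes(),
                                  color_ids = names(default_colors()),
                                  views_per_object = 1,
                                  resolution = 64, max_view_angle = 75,
                                  palette = default_colors()) {
  if (length(shape_ids) != 4 || anyDuplicated(shape_ids)) {
    abort("shape_ids must be exactly 4 distinct identifiers")
  }
  if (length(color_ids) != 4 || anyDuplicated(color_ids)) {
    abort("color_ids must be exactly 4 distinct identifiers")
  }
  if (views_per_object < 1) abort("views_per_object must be >= 1")
  v <- as.integer(views_per_object)
  angles <- if (v == 1) 0 else seq(-max_view_angle, max_view_angle, length.out = v)
  grid <- tidyr::expand_grid(shape_id = shape_ids, color_id = color_ids,
                             view_index = seq_len(v))
  grid$angle <- angles[grid$view_index]
  grid$object_id <- paste(grid$shape_id, grid$color_id, sep = "_")
  grid$image <- pmap(list(grid$shape_id, grid$color_id, grid$angle),
                     function(s, c, a) {
                       render_stimulus(s, c, a, resolution = resolution,
                                       palette = palette)
                     })
  grid[, c("object_id", "shape_id", "color_id", "view_index", "angle", "image")]
}

#' Ingest an egocentric image sequence as a training stream
#'
#' Standardises externally recorded first-person footage to the training
#' contract: frames subsampled to `fps`, resized to
#' `resolution` x `resolution`, truncated to the first `max_frames`, temporal
#' order preserved. Accepts a directory of numbered PNG frames, a list of
#' image arrays, or an N x H x W x 3 array.
#'
#' @param source Directory path, list of H x W x 3 arrays, or 4-D array.
#' @param fps Target frames/s of the output stream (default 10).
#' @param source_fps Frame rate of the source; defaults to `fps` (no
#'   subsampling).
#' @param resolution Output frame side in pixels (default 64).
#' @param max_frames Keep at most the first `max_frames` frames
#'   (default 80000).
#' @return A frame-stream tibble (`index`, `t`, `condition = "ingested"`,
#'   `image` list-column).
#' @export
ingest_frames <- function(source, fps = 10, source_fps = fps, resolution = 64,
                          max_frames = 80000) {
  if (fps <= 0 || source_fps < fps) abort("need source_fps >= fps > 0")
  imgs <- if (is.character(source)) {
    if (!dir.exists(source)) abort(sprintf("cannot read '%s'", source), class = "io_error")
    paths <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
    lapply(paths, read_frame_png)
  } else if (is.array(source) && length(dim(source)) == 4) {
    lapply(seq_len(dim(source)[1]), function(i) source[i, , , , drop = TRUE])
  } else if (is.list(source)) {
    source
  } else {
    abort("source must be a directory, a list of arrays, or a 4-D array")
  }
  if (length(imgs) == 0) abort("no frames decoded from source", class = "empty_input")
  # temporal subsampling to the target rate
  stride <- source_fps / fps
  keep <- unique(floor(seq(1, length(imgs), by = stride)))
  imgs <- imgs[keep]
  if (length(imgs) > max_frames) imgs <- imgs[seq_len(max_frames)]
  imgs <- lapply(imgs, function(im) {
    assert_image(im, "ingested frame")
    if (!all(dim(im)[1:2] == resolution)) {
      im <- resize_bilinear(im, resolution, resolution)
    }
    quantize8(im)
  })
  tibble(index = seq_along(imgs), t = (seq_along(imgs) - 1) / fps,
         condition = "ingested", image = imgs)
}

#' Write / read a frame stream as PNG files plus a JSON manifest
#'
#' Frames are written as zero-padded, index-named PNGs; poses, timestamps,
#' condition tag and seed go into `manifest.json`.
#'
#' @param frames A frame-stream tibble.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return `write_frame_stream()` returns `dir` invisibly;
#'   `read_frame_stream()` returns the frame-stream tibble.
#' @export
write_frame_stream <- function(frames, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%06d.png", frames$index)
  for (i in seq_len(nrow(frames))) {
    write_frame_png(frames$image[[i]], file.path(dir, files[i]))
  }
  meta <- frames[, setdiff(names(frames), "image")]
  meta$file <- files
  jsonlite::write_json(list(seed = seed, frames = meta),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_frame_stream
#' @export
read_frame_stream <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("no manifest in '%s'", dir), class = "io_error")
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  meta <- as_tibble(man$frames)
  meta$image <- lapply(meta$file, function(f) read_frame_png(file.path(dir, f)))
  meta$file <- NULL
  meta
}
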