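# Chamber, object and condition specifications.
#
# Floor coordinates are continuous "chamber units" (1 unit = 10 cm) with the
# origin at the chamber centre: x runs laterally (parallel to the display
# walls), y runs in depth towards the active display wall. The display walls
# are the two opposing walls at the ends of the chamber's length axis.

CM_PER_UNIT <- 10

#' Specify the virtual controlled-rearing chamber
#'
#' The default dimensions replicate the physical rearing chambers:
#' 66 cm (length) x 42 cm (width) x 69 cm (height), with two opposing
#' display walls that act as virtual monitors and a wire-mesh floor.
#'
#' @param length_cm,width_cm,height_cm Chamber dimensions in cm.
#' @param display_walls Two opposing wall identifiers out of
#'   `"north"`/`"south"` (depth axis) or `"east"`/`"west"` (lateral axis).
#' @param floor_texture `"mesh"` or `"plain"`.
#' @param eye_height_cm Agent eye height above the floor (the camera height;
#'   default 5 cm, a newborn-chick scale; exposed because no canonical value
#'   exists).
#' @param fov_deg Horizontal camera field of view in degrees (default 90).
#' @return A `chamber_spec` list.
#' @export
chamber_spec <- function(length_cm = 66, width_cm = 42, height_cm = 69,
                         display_walls = c("north", "south"),
                         floor_texture = c("mesh", "plain"),
                         eye_height_cm = 5, fov_deg = 90) {
  floor_texture <- match.arg(floor_texture)
  if (length_cm <= 0 || width_cm <= 0 || height_cm <= 0) {
    abort("chamber dimensions must be strictly positive")
  }
  opposing <- list(c("north", "south"), c("east", "west"))
  ok <- any(vapply(opposing, function(p) setequal(display_walls, p), logical(1)))
  if (length(display_walls) != 2 || !ok) {
    abort("display_walls must be exactly two opposing walls")
  }
  structure(list(
    length_cm = length_cm, width_cm = width_cm, height_cm = height_cm,
    display_walls = display_walls, floor_texture = floor_texture,
    eye_height_cm = eye_height_cm, fov_deg = fov_deg,
    # footprint half-extents in chamber units
    half_x = width_cm / 2 / CM_PER_UNIT,
    half_y = length_cm / 2 / CM_PER_UNIT
  ), class = "chamber_spec")
}

#' Specify the rotating two-faced imprinting object
#'
#' A single virtual object with two faces, each bearing its own 2-D shape and
#' colour. It rotates about a frontoparallel vertical axis, completing a full
#' rotation every `rotation_period_s` seconds (default 6 s), and measures
#' 9 cm x 7 cm on average.
#'
#' @param face_a,face_b Length-2 character vectors `c(shape_id, color_id)`.
#' @param width_cm,height_cm Object extent in cm.
#' @param rotation_period_s Seconds per full rotation; must be positive.
#' @return An `object_spec` list.
#' @export
object_spec <- function(face_a = c("circle", "red"),
                        face_b = c("triangle", "blue"),
                        width_cm = 9, height_cm = 7,
                        rotation_period_s = 6) {
  if (rotation_period_s <= 0) abort("rotation_period_s must be positive")
  if (identical(unname(face_a), unname(face_b))) {
    abort("face_a and face_b must differ in shape or colour")
  }
  structure(list(
    face_a = list(shape_id = face_a[[1]], color_id = face_a[[2]]),
    face_b = list(shape_id = face_b[[1]], color_id = face_b[[2]]),
    width_cm = width_cm, height_cm = height_cm,
    rotation_period_s = rotation_period_s
  ), class = "object_spec")
}

#' Rearing-condition movement policy
#'
#' Five embodied movement policies. `dense_exploration` alternates straight
#' transits at `move_speed` with stationary dwells of `dwell_duration` during
#' which the head sweeps along yaw, pitch and roll. `no_head_movements`
#' replaces the dwell sweeps with a fixed gaze on the object. The teleport
#' policies (`no_transitional_views`, `no_side_to_side`, `no_depth`) jump
#' between positions of a `grid_rows` x `grid_cols` grid without transit
#' views; the side-to-side ablation pins the lateral coordinate (depth-only
#' moves) and the depth ablation pins the depth coordinate (lateral-only
#' moves). The shuffled control is not a policy: it reuses dense-exploration
#' frames with within-batch reshuffling at training time (see
#' [shuffle_within_batches()]).
#'
#' @param kind Policy name.
#' @param move_speed Transit speed, chamber units/s (default 1.5).
#' @param dwell_duration Dwell time at each location in seconds (default 9.5).
#' @param fps Frames sampled per second (default 10).
#' @param grid_rows,grid_cols Teleport grid dimensions (default 7 x 7).
#' @return A `condition_policy` list.
#' @export
condition_policy <- function(kind = c("dense_exploration", "no_head_movements",
                                      "no_transitional_views", "no_side_to_side",
                                      "no_depth"),
                             move_speed = 1.5, dwell_duration = 9.5,
                             fps = 10, grid_rows = 7, grid_cols = 7) {
  kind <- match.arg(kind)
  if (fps <= 0) abort("fps must be positive")
  if (dwell_duration < 0) abort("dwell_duration must be nonnegative")
  if (grid_rows < 1 || grid_cols < 1) abort("grid dimensions must be >= 1")
  if (move_speed <= 0) abort("move_speed must be positive")
  structure(list(kind = kind, move_speed = move_speed,
                 dwell_duration = dwell_duration, fps = fps,
                 grid_rows = grid_rows, grid_cols = grid_cols),
            class = "condition_policy")
}

#' Equally spaced teleport grid positions
#'
#' Divides the chamber footprint into `rows` x `cols` equally spaced
#' positions, all strictly inside the walls (cell centres of a uniform
#' partition). Grid rows run parallel to the display wall: within a row the
#' lateral coordinate `x` varies and the depth coordinate `y` is constant.
#' The default 7 x 7 grid gives the 49 teleport positions.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param chamber A [chamber_spec()].
#' @return A tibble with columns `row`, `col`, `x`, `y` (chamber units).
#' @export
#' @examples
#' make_grid_positions(7, 7)
make_grid_positions <- function(rows, cols, chamber = chamber_spec()) {
  if (rows < 1 || cols < 1) abort("grid dimensions must be >= 1")
  rows <- as.integer(rows); cols <- as.integer(cols)
  ys <- -chamber$half_y + (seq_len(rows) - 0.5) * (2 * chamber$half_y / rows)
  xs <- -chamber$half_x + (seq_len(cols) - 0.5) * (2 * chamber$half_x / cols)
  tibble(
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    x = rep(xs, times = rows),
    y = rep(ys[seq_len(rows)], each = cols)
  )
}

#' Rotation angle of the imprinting object
#'
#' @param t Time in seconds (vectorised).
#' @param period Rotation period in seconds (default 6); must be positive.
#' @return Angle in degrees, in `[0, 360)`.
#' @export
#' @examples
#' object_angle(3, 6) # 180
object_angle <- function(t, period = 6) {
  if (period <= 0) abort("period must be positive")
  (360 * t / period) %% 360
}

# Which face is visible at a rotation angle: "a" for angle in [-90, 90),
# "b" otherwise; "edge" within +/- edge_deg of edge-on.
visible_face <- function(angle, edge_deg = 5) {
  a <- angle %% 360
  if (min(abs(a - 90), abs(a - 270)) <= edge_deg) return("edge")
  if (a < 90 || a >= 270) "a" else "b"
}
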