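# Agent trajectories under the rearing-condition policies.

# Analytic gaze: yaw/pitch that centre the object (mounted at eye height on
# the active display wall at (0, +half_y)) in the view; roll 0.
gaze_at_object <- function(x, y, chamber) {
  dx <- 0 - x
  dy <- chamber$half_y - y
  yaw <- atan2(dx, dy) * 180 / pi
  c(yaw = yaw, pitch = 0, roll = 0)
}

# Seeded sinusoidal head sweep over all three axes during a dwell; amplitudes
# are capped so the object stays at least partially in frame at the default
# field of view.
dwell_sweep <- function(n, fps, base) {
  amp <- c(runif(1, 8, 22), runif(1, 3, 12), runif(1, 3, 12))
  freq <- runif(3, 0.15, 0.45)
  phase <- runif(3, 0, 2 * pi)
  tt <- (seq_len(n) - 1) / fps
  tibble(
    yaw = base[["yaw"]] + amp[1] * sin(2 * pi * freq[1] * tt + phase[1]),
    pitch = base[["pitch"]] + amp[2] * sin(2 * pi * freq[2] * tt + phase[2]),
    roll = base[["roll"]] + amp[3] * sin(2 * pi * freq[3] * tt + phase[3])
  )
}

random_point <- function(chamber, margin = 0.2) {
  c(runif(1, -chamber$half_x + margin, chamber$half_x - margin),
    runif(1, -chamber$half_y + margin, chamber$half_y - margin))
}

#' Plan an agent trajectory under a rearing condition
#'
#' Produces a pose sequence sampled at `1/fps` spacing. Dense exploration
#' alternates straight transits (at `move_speed`, gaze fixed on the object)
#' with 9.5 s dwells of seeded sinusoidal head sweeps. The no-head-movements
#' policy dwells with the gaze locked on the object. Teleport policies emit
#' no transit poses: positions jump between grid targets (the full grid, the
#' central lateral line for `no_side_to_side`, or the central depth line for
#' `no_depth`), with head sweeps at each location.
#'
#' @param policy A [condition_policy()].
#' @param n_frames Number of poses to emit (>= 1).
#' @param seed Integer seed; identical seeds yield identical trajectories.
#' @param chamber A [chamber_spec()].
#' @return A tibble with columns `index`, `t`, `x`, `y`, `yaw`, `pitch`,
#'   `roll`, `phase` (`"transit"` or `"dwell"`).
#' @export
plan_trajectory <- function(policy, n_frames, seed = 1,
                            chamber = chamber_spec()) {
  if (!inherits(policy, "condition_policy")) abort("policy must be a condition_policy")
  if (n_frames < 1) abort("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  fps <- policy$fps
  n_dwell <- as.integer(ceiling(policy$dwell_duration * fps))

  with_seed(derive_seed(seed, paste0("traj-", policy$kind)), {
    rows <- list()
    emitted <- 0L

    emit <- function(df) {
      keep <- min(nrow(df), n_frames - emitted)
      if (keep > 0) {
        rows[[length(rows) + 1L]] <<- df[seq_len(keep), , drop = FALSE]
        emitted <<- emitted + keep
      }
    }

    make_dwell <- function(pos, with_sweeps) {
      base <- gaze_at_object(pos[1], pos[2], chamber)
      if (with_sweeps && n_dwell > 0) {
        head <- dwell_sweep(n_dwell, fps, base)
      } else {
        head <- tibble(yaw = rep(base[["yaw"]], max(n_dwell, 1L)),
                       pitch = base[["pitch"]], roll = base[["roll"]])
      }
      tibble(x = pos[1], y = pos[2], yaw = head$yaw, pitch = head$pitch,
             roll = head$roll, phase = "dwell")
    }

    if (policy$kind %in% c("dense_exploration", "no_head_movements")) {
      pos <- random_point(chamber)
      sweeps <- policy$kind == "dense_exploration"
      emit(make_dwell(pos, sweeps))
      while (emitted < n_frames) {
        target <- random_point(chamber)
        step <- policy$move_speed / fps
        delta <- target - pos
        dist <- sqrt(sum(delta^2))
        n_step <- floor(dist / step)
        if (n_step >= 1) {
          dirv <- delta / dist
          txy <- outer(seq_len(n_step) * step, dirv)
          txy[, 1] <- txy[, 1] + pos[1]; txy[, 2] <- txy[, 2] + pos[2]
          head <- t(apply(txy, 1, function(p) gaze_at_object(p[1], p[2], chamber)))
          emit(tibble(x = txy[, 1], y = txy[, 2], yaw = head[, 1],
                      pitch = head[, 2], roll = head[, 3], phase = "transit"))
          pos <- txy[n_step, ]
        }
        # dwell at the last transit sample (within one step of the target)
        emit(make_dwell(pos, sweeps))
      }
    } else {
      grid <- make_grid_positions(policy$grid_rows, policy$grid_cols, chamber)
      mid_col <- (policy$grid_cols + 1L) %/% 2L
      mid_row <- (policy$grid_rows + 1L) %/% 2L
      targets <- switch(policy$kind,
        no_transitional_views = grid,
        # side-to-side ablation: lateral coordinate pinned to the central
        # lateral line; the agent only moves closer to / farther from the wall
        no_side_to_side = grid[grid$col == mid_col, , drop = FALSE],
        # depth ablation: depth coordinate pinned; lateral-only moves
        no_depth = grid[grid$row == mid_row, , drop = FALSE]
      )
      cur <- 0L
      while (emitted < n_frames) {
        pick <- if (nrow(targets) == 1L) 1L else {
          p <- sample.int(nrow(targets), 1L)
          while (p == cur) p <- sample.int(nrow(targets), 1L)
          p
        }
        cur <- pick
        emit(make_dwell(c(targets$x[pick], targets$y[pick]), TRUE))
      }
    }

    out <- bind_rows(rows)
    out$index <- seq_len(nrow(out))
    out$t <- (out$index - 1) / fps
    out[, c("index", "t", "x", "y", "yaw", "pitch", "roll", "phase")]
  })
}
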