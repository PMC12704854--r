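# End-to-end experiment orchestration: generate -> (retina) -> train ->
# evaluate -> report, with seeding and manifest provenance.

#' Score an encoder on the factorial stimulus set
#'
#' Convenience composition of the evaluation chain: embed the stimuli with
#' the frozen encoder, centre, build the cosine RDM, and compute the colour
#' and shape scores.
#'
#' @param encoder An `rv_encoder` or `rv_fit`.
#' @param stimuli A stimulus tibble from [generate_stimulus_set()].
#' @return One-row score tibble (see [match_scores()]).
#' @export
score_encoder <- function(encoder, stimuli) {
  if (inherits(encoder, "rv_fit")) encoder <- encoder$encoder
  Z <- embed(encoder, stimuli)
  match_scores(cosine_rdm(center_embeddings(Z), stimuli), stimuli)
}

#' Desk-scale and full-scale experiment presets
#'
#' `desk_preset()` is the configuration used by the package's own end-to-end
#' runs on a single CPU: a 5,000-frame stream, a 64-dimensional 3-layer
#' ViT-CoT, 10 epochs at batch 64 and learning rate 1e-3 (the step count is
#' roughly 100x smaller than the canonical recipe, so the constant rate is
#' raised accordingly). `full_preset()` mirrors the canonical recipe
#' (80,000 frames, 100 epochs, batch 128, learning rate 1e-4); running it is
#' a matter of compute, not code. `micro_preset()` is a further-shrunk
#' variant for test suites.
#'
#' @return A list with `n_frames`, `encoder` (config), `training`
#'   (train_config).
#' @export
desk_preset <- function() {
  list(n_frames = 5000,
       encoder = vit_config(n_layers = 3, n_heads = 3, embed_dim = 64),
       training = train_config("cltt", epochs = 10, batch_size = 64,
                               lr = 1e-3))
}

#' @rdname desk_preset
#' @export
full_preset <- function() {
  list(n_frames = 80000,
       encoder = vit_config(n_layers = 3, n_heads = 3, embed_dim = 128),
       training = train_config("cltt", epochs = 100, batch_size = 128,
                               lr = 1e-4))
}

#' @rdname desk_preset
#' @export
micro_preset <- function() {
  list(n_frames = 512,
       encoder = vit_config(n_layers = 3, n_heads = 3, embed_dim = 48,
                            mlp_ratio = 2),
       training = train_config("cltt", epochs = 6, batch_size = 32,
                               lr = 3e-3))
}

#' Run a full in-silico rearing experiment
#'
#' For every seed: generates the condition's frame stream, optionally
#' filters it through an artificial retina, trains the encoder, and scores
#' both the untrained baseline and the trained model on the factorial
#' stimulus set. Produces seed-level paired tests (shape vs colour within
#' model) and Welch tests (trained vs untrained per score), plus a manifest
#' of content hashes when an output directory is given.
#'
#' @param condition A [condition_policy()] kind name or object; or
#'   `"shuffled"` for the shuffled-views control (dense-exploration frames,
#'   within-batch shuffling each epoch).
#' @param preset A preset list (see [desk_preset()]); individual parts can
#'   be overridden with `encoder_config` / `training_config` / `n_frames`.
#' @param seeds Integer vector of training seeds (canonically 3).
#' @param retina Optional [toy_retina_config()] or
#'   [realistic_retina_config()] applied to the stream before training.
#' @param object The imprinting [object_spec()].
#' @param out_dir Optional directory for score/stat CSVs and the manifest.
#' @param encoder_config,training_config,n_frames Overrides.
#' @param verbose Print stage progress.
#' @return An `rv_experiment`: tibbles `scores` (one row per seed x
#'   trained/untrained), `paired` and `welch` stats, loss `traces`, and the
#'   `manifest`.
#' @export
run_experiment <- function(condition = "dense_exploration",
                           preset = desk_preset(), seeds = 1:3,
                           retina = NULL, object = object_spec(),
                           out_dir = NULL,
                           encoder_config = preset$encoder,
                           training_config = preset$training,
                           n_frames = preset$n_frames, verbose = FALSE) {
  if (length(seeds) == 0) abort("need at least one seed")
  shuffled <- identical(condition, "shuffled")
  policy <- if (inherits(condition, "condition_policy")) {
    condition
  } else if (shuffled) {
    condition_policy("dense_exploration")
  } else {
    condition_policy(condition)
  }
  cond_tag <- if (shuffled) "shuffled" else policy$kind
  if (shuffled) training_config$shuffled_condition <- TRUE

  stimuli <- generate_stimulus_set(resolution = encoder_config$image_size %||%
                                     encoder_config$encoder$image_size)
  scores <- list(); traces <- list(); fits <- list()
  for (s in seeds) {
    if (verbose) message(sprintf("[%s] seed %d: generating %d frames",
                                 cond_tag, s, n_frames))
    stream <- generate_condition_dataset(policy, object, n_frames,
                                         seed = derive_seed(s, "stream"),
                                         resolution = encoder_config$image_size)
    if (!is.null(retina)) {
      stream <- if (inherits(retina, "toy_retina_config")) {
        stream$image <- lapply(stream$image, apply_toy_retina, config = retina)
        stream
      } else {
        apply_realistic_retina(stream, retina)
      }
    }
    enc <- build_encoder(encoder_config, seed = s)
    u <- score_encoder(enc, stimuli)
    if (verbose) message(sprintf("[%s] seed %d: training", cond_tag, s))
    fit <- train(enc, stream, training_config, seed = s, verbose = verbose)
    t <- score_encoder(fit$encoder, stimuli)
    scores[[length(scores) + 1]] <- dplyr::bind_rows(
      mutate(u, phase = "untrained"), mutate(t, phase = "trained")) |>
      mutate(seed = s, condition = cond_tag)
    traces[[length(traces) + 1]] <- mutate(fit$trace, seed = s,
                                           condition = cond_tag)
    fits[[length(fits) + 1]] <- fit
  }
  scores <- bind_rows(scores)
  traces <- bind_rows(traces)

  paired <- welch <- NULL
  tr <- filter(scores, .data$phase == "trained")
  un <- filter(scores, .data$phase == "untrained")
  if (length(seeds) >= 2) {
    paired <- bind_rows(
      mutate(paired_ttest(tr$shape_score, tr$color_score), model = "trained"),
      mutate(paired_ttest(un$shape_score, un$color_score), model = "untrained"))
    welch <- bind_rows(
      mutate(welch_ttest(tr$shape_score, un$shape_score), score = "shape"),
      mutate(welch_ttest(tr$color_score, un$color_score), score = "color"))
  }

  manifest <- list(condition = cond_tag, seeds = seeds,
                   n_frames = n_frames,
                   encoder = unclass(encoder_config),
                   training = unclass(training_config)[
                     setdiff(names(training_config), "augment")],
                   retina = if (!is.null(retina)) unclass(retina),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   version = as.character(utils::packageVersion("rearviews")))
  res <- structure(list(scores = scores, paired = paired, welch = welch,
                        traces = traces, fits = fits, manifest = manifest),
                   class = "rv_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    if (!is.null(paired)) {
      utils::write.csv(report(res), file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(traces, file.path(out_dir, "loss_traces.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(manifest,
        list(artifacts = as.list(tools::md5sum(list.files(out_dir,
               pattern = "\\.csv$", full.names = TRUE))))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.rv_experiment <- function(x, ...) {
  cat(sprintf("<experiment: %s, %d seed(s)>\n", x$manifest$condition,
              length(x$manifest$seeds)))
  print(report(x))
  invisible(x)
}

#' Summarise experiments in the canonical table layout
#'
#' Aggregates seed-level scores into one row per (model, condition) with the
#' columns Mean Shape Score / Mean Colour Score / Mean Difference
#' (Shape - Colour) / t / p / df of the within-model paired test; undefined
#' tests are rendered NA with the recorded reason.
#'
#' @param ... One or more `rv_experiment` objects (or a list of them).
#' @return A tibble ordered by condition then model.
#' @export
report <- function(...) {
  exps <- list(...)
  if (length(exps) == 1 && !inherits(exps[[1]], "rv_experiment")) {
    exps <- exps[[1]]
  }
  if (length(exps) == 0) abort("need at least one experiment")
  rows <- lapply(exps, function(e) {
    by_phase <- e$scores |>
      group_by(.data$phase) |>
      summarise(mean_shape = mean(.data$shape_score),
                mean_color = mean(.data$color_score), n_seeds = n())
    by_phase$condition <- e$manifest$condition
    tst <- e$paired
    if (!is.null(tst)) {
      tst <- tst |> select(model = "model", t = "t", p = "p", df = "df",
                           na_reason = "na_reason")
      by_phase <- left_join(by_phase, tst,
                            by = c(phase = "model"))
    } else {
      by_phase$t <- NA_real_; by_phase$p <- NA_real_; by_phase$df <- NA_real_
      by_phase$na_reason <- "single seed: paired test undefined"
    }
    by_phase
  })
  out <- bind_rows(rows) |>
    mutate(mean_diff = .data$mean_shape - .data$mean_color,
           model = .data$phase) |>
    select("condition", "model", "mean_shape", "mean_color", "mean_diff",
           "t", "p", "df", "n_seeds", "na_reason") |>
    arrange(.data$condition, .data$model)
  out
}

#' Generate the fixture bundle used by the test suite
#'
#' Deterministically builds the small objects the package's tests (and any
#' user smoke test) need: a short frame stream per rearing condition, the
#' factorial stimulus sets (single-view and multi-view), a moving-square
#' frame pair with known displacement, and constructed-geometry embedding
#' sets whose colour/shape scores are known exactly.
#'
#' @param seed Integer seed.
#' @param n_frames Frames per condition stream (default 200).
#' @return A named list (`streams`, `stimuli`, `stimuli_views`,
#'   `moving_square`, `embeddings`).
#' @export
make_fixtures <- function(seed = 1, n_frames = 200) {
  conds <- c("dense_exploration", "no_head_movements", "no_transitional_views",
             "no_side_to_side", "no_depth")
  streams <- setNames(lapply(conds, function(k) {
    generate_condition_dataset(condition_policy(k), object_spec(), n_frames,
                               seed = derive_seed(seed, k))
  }), conds)
  sq0 <- array(0, dim = c(64, 64, 3)); sq0[20:32, 20:32, ] <- 1
  sq1 <- array(0, dim = c(64, 64, 3)); sq1[23:35, 20:32, ] <- 1
  # constructed geometry: same-colour objects identical, colours orthogonal
  shapes <- default_shapes(); colors <- names(default_colors())
  lab <- tidyr::expand_grid(shape_id = shapes, color_id = colors)
  E_color <- diag(4)[match(lab$color_id, colors), ]
  E_shape <- diag(4)[match(lab$shape_id, shapes), ]
  list(streams = streams,
       stimuli = generate_stimulus_set(),
       stimuli_views = generate_stimulus_set(views_per_object = 29),
       moving_square = list(frame_t = quantize8(sq0), frame_t1 = quantize8(sq1),
                            displacement = c(3, 0)),
       embeddings = list(labels = lab, color_based = E_color,
                         shape_based = E_shape))
}
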