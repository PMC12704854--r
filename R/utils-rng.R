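#' @keywords internal
"_PACKAGE"

#' @useDynLib rearviews, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange group_by summarise ungroup select
#'   bind_rows left_join n row_number
#' @importFrom purrr map map2 map_dbl map_int pmap imap
#' @importFrom stats rnorm runif setNames
NULL

# Deterministic seed derivation: one user-facing seed fans out into
# independent per-stage seeds so stages can be rerun in isolation.
# Splitmix-style integer mixing, kept below 2^31 for R's set.seed().
mix32 <- function(x) {
  x <- as.double(x) %% 4294967296
  x <- (x * 747796405 + 2891336453) %% 4294967296
  w <- (floor(x / 2^((x %% 4294967296) %/% 134217728 + 4)) + x) %% 4294967296
  w <- (w * 277803737) %% 4294967296
  w <- (floor(w / 2^22) + w) %% 4294967296
  w %% 2147483647
}

#' Derive a stage seed from a master seed
#'
#' Expands one master seed into reproducible, well-separated sub-seeds keyed
#' by an arbitrary tag, so that independent pipeline stages (world generation,
#' mosaic sampling, training, evaluation) each get their own RNG stream.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the stage or sub-stream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "train")
derive_seed <- function(seed, tag = "") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) h <- mix32(h * 31 + ch)
  as.integer(mix32(h + 1))
}

# Run code under a local RNG state; global .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
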