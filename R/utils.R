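#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom stats rbinom runif setNames
NULL

# Internally all coordinates are 0-based half-open; SAM positions (1-based)
# are converted at the I/O boundary by these two helpers.
sam_to_internal_pos <- function(pos1) as.integer(pos1) - 1L

internal_to_sam_pos <- function(pos0) as.integer(pos0) + 1L

#' Derive a stage seed from a top-level seed
#'
#' All randomness in a pipeline run flows from one top-level seed; each stage
#' draws from a distinct stream obtained by a fixed offset so that stages can
#' be re-run in isolation.
#'
#' @param seed Integer top-level seed.
#' @param stage Integer stage index (>= 1).
#' @return An integer seed, kept within the 32-bit range.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% .Machine$integer.max)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
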