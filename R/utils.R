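## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Lightweight stderr logger with a stage prefix; every analysis stage
## routes its progress and warnings-that-are-not-conditions through here.
#' @noRd
tv_log <- function(..., stage = "tadevolve") {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Deterministic sub-seeds: one independent stream per named stage so that
## adding permutations to one analysis never perturbs another.
#' @noRd
stage_seed <- function(seed, stage) {
  offsets <- c(traits = 11L, blocks = 23L, ard = 37L, genes = 53L,
               edits = 71L, pipeline = 97L, tree = 113L, lengths = 131L)
  off <- offsets[[stage]] %||% 127L
  (as.integer(seed) * 1009L + off) %% .Machine$integer.max
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
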