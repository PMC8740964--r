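#' Discrete belief scale
#'
#' The belief in a single proposition is represented as an integer level on a
#' discrete scale with `resolution` equally spaced values: `0` is strong
#' disbelief, `resolution - 1` is strong belief, and the midpoint
#' `floor((resolution - 1) / 2)` encodes uncertainty. The default
#' seven-point scale mirrors the 7-point Likert scales commonly used in
#' public-opinion surveys.
#'
#' @param resolution Number of discrete belief levels (integer, at least 2).
#'
#' @return An object of class `belief_space` with elements `resolution`,
#'   `levels` (integer vector `0:(resolution - 1)`) and `midpoint`.
#' @examples
#' belief_space()
#' belief_space(13)
#' @export
belief_space <- function(resolution = 7L) {
  if (length(resolution) != 1 || is.na(resolution) ||
      resolution != as.integer(resolution) || resolution < 2) {
    abort("`resolution` must be a single integer >= 2.")
  }
  resolution <- as.integer(resolution)
  structure(
    list(
      resolution = resolution,
      levels = 0:(resolution - 1L),
      midpoint = (resolution - 1L) %/% 2L
    ),
    class = "belief_space"
  )
}

#' @export
print.belief_space <- function(x, ...) {
  cat("<belief_space> ", x$resolution, " levels: 0 (strong disbelief) .. ",
      x$resolution - 1L, " (strong belief), midpoint ", x$midpoint, "\n",
      sep = "")
  invisible(x)
}

# Validate a vector of belief levels against a space; returns integer vector.
check_levels <- function(level, space, arg = "level") {
  if (any(is.na(level)) || any(level != as.integer(level)) ||
      any(level < 0) || any(level > space$resolution - 1L)) {
    abort(sprintf("`%s` must be integer belief levels in 0..%d.",
                  arg, space$resolution - 1L))
  }
  as.integer(level)
}
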