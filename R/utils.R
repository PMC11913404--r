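`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map event times to frame indices
#'
#' Events are logged on a 10 ms grid while photometry frames arrive at the
#' camera rate (default 30 frames/s), so an event rarely falls exactly on a
#' frame. Each time is mapped to the nearest frame; exact half-frame ties
#' round down (toward the earlier frame).
#'
#' @param times numeric vector of times in seconds.
#' @param fps frames per second of the recording.
#' @param t0 time of the first frame (seconds).
#' @return integer vector of 1-based frame indices (unclamped; callers must
#'   range-check against the recording length).
#' @keywords internal
frame_index <- function(times, fps, t0 = 0) {
  # frame i has time t0 + (i - 1)/fps; nearest index with half-ties down
  as.integer(ceiling((times - t0) * fps - 0.5 + 1e-9)) + 1L
}

# column SDs without an extra dependency
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

# number of whole frame steps spanned by a duration (guards fp jitter)
frames_spanned <- function(duration, fps) {
  as.integer(floor(duration * fps + 1e-9))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
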