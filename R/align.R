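new_aligned_matrix <- function(Y, time_axis, block_refs, mode, window_length,
                               dropped = integer()) {
  structure(list(Y = Y, time_axis = time_axis, block_refs = block_refs,
                 mode = mode, window_length = window_length,
                 dropped = dropped),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d x %d (%s), window %.3f s, time [%.3f, %.3f] s",
              nrow(x$Y), ncol(x$Y), x$mode, x$window_length,
              x$time_axis[1], x$time_axis[length(x$time_axis)]))
  if (length(x$dropped)) cat(sprintf(", %d row(s) dropped", length(x$dropped)))
  cat("\n")
  invisible(x)
}

slice_rows <- function(sig, fps, t0, anchors, lo_off, hi_off, n_frames) {
  idx0 <- frame_index(anchors, fps, t0)
  lo <- idx0 + lo_off
  hi <- idx0 + hi_off
  ok <- lo >= 1L & hi <= n_frames
  list(ok = ok, lo = lo[ok])
}

#' Align activity within blocks of one type
#'
#' Builds the K x T matrix `Y` whose rows are the z-scored activity excerpts
#' of the K blocks of a single type, aligned either to the block's initial
#' action event (head-fixed: window runs forward from the anchor) or to its
#' terminal event (tail-fixed: window runs backward to the anchor). Unless
#' overridden, the window length is half the mean duration of the supplied
#' blocks, which keeps adjacent alignments from overlapping.
#'
#' Event timestamps are mapped to the nearest frame (half-frame ties round
#' down); window endpoints are inclusive on the frame grid, so a window of
#' `w` seconds spans `floor(w * fps) + 1` columns. Rows whose window falls
#' outside the recording are dropped and listed in `dropped`. Blocks shorter
#' than the window are retained by default (their windows extend into
#' adjacent behavior, as with any fixed-window design); `strict = TRUE`
#' excludes them.
#'
#' @param trace a processed [photometry_trace()] (channel `signal` present).
#' @param blocks data.frame of blocks of a single `block_type`.
#' @param mode `"head_fixed"` or `"tail_fixed"`.
#' @param window optional window override in seconds.
#' @param signal which channel to sample (default `"z"`).
#' @param strict drop blocks shorter than the window (default `FALSE`).
#' @return an `aligned_matrix`: `Y`, `time_axis` (head-fixed starts at 0,
#'   tail-fixed ends at 0), `block_refs` (the surviving block rows, in
#'   chronological order), `mode`, `window_length`, `dropped`.
#' @export
align_blocks <- function(trace, blocks, mode = c("head_fixed", "tail_fixed"),
                         window = NULL, signal = "z", strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "photometry_trace"), is.data.frame(blocks))
  if (!nrow(blocks)) stop("no blocks to align", call. = FALSE)
  if (length(unique(blocks$block_type)) != 1L) {
    stop("all blocks must share one block_type", call. = FALSE)
  }
  sig <- trace[[signal]]
  if (is.null(sig)) stop("trace lacks channel '", signal, "'", call. = FALSE)
  window <- window %||% (mean(blocks$duration) / 2)
  assert_scalar_pos(window, "window")
  if (strict) {
    short <- blocks$duration < window
    blocks <- blocks[!short, , drop = FALSE]
    if (!nrow(blocks)) {
      warning("no blocks at least as long as the window; empty matrix")
      return(new_aligned_matrix(matrix(numeric(), 0, 0), numeric(), blocks,
                                mode, window))
    }
  }
  nfr <- frames_spanned(window, trace$fps)
  anchors <- if (mode == "head_fixed") blocks$t_start else blocks$t_end
  lo_off <- if (mode == "head_fixed") 0L else -nfr
  hi_off <- if (mode == "head_fixed") nfr else 0L
  sl <- slice_rows(sig, trace$fps, trace$frame_times[1], anchors,
                   lo_off, hi_off, length(sig))
  dropped <- which(!sl$ok)
  if (length(dropped)) {
    warning(sprintf("dropping %d block(s) whose window leaves the recording",
                    length(dropped)))
  }
  if (!any(sl$ok)) {
    warning("no blocks survive alignment; empty matrix")
    return(new_aligned_matrix(matrix(numeric(), 0, nfr + 1L),
                              (0:nfr) / trace$fps * (if (mode == "head_fixed") 1 else -1),
                              blocks[0, ], mode, window, dropped))
  }
  Y <- t(vapply(sl$lo, function(l) sig[l:(l + nfr)], numeric(nfr + 1L)))
  time_axis <- if (mode == "head_fixed") (0:nfr) / trace$fps else
    ((-nfr):0) / trace$fps
  new_aligned_matrix(Y, time_axis, blocks[sl$ok, , drop = FALSE], mode,
                     window, dropped)
}

#' Peri-event activity matrix around single events
#'
#' Fixed windows `[event - pre, event + post]` around a list of event times
#' (e.g. rewarded magazine entries), with time 0 at the event. Endpoints are
#' inclusive on the frame grid: `pre = post = 0.5` s at 30 fps gives 31
#' columns.
#'
#' @param trace a processed [photometry_trace()].
#' @param events numeric vector of event times (s).
#' @param pre,post window extents in seconds (nonnegative, not both 0).
#' @param signal channel to sample (default `"z"`).
#' @return an `aligned_matrix` with `mode = "peri_event"`; `block_refs` is a
#'   data.frame of the surviving event times.
#' @export
peri_event_matrix <- function(trace, events, pre, post, signal = "z") {
  stopifnot(inherits(trace, "photometry_trace"))
  if (pre < 0 || post < 0 || (pre == 0 && post == 0)) {
    stop("need pre, post >= 0 and not both 0", call. = FALSE)
  }
  if (!length(events)) stop("no events to align", call. = FALSE)
  sig <- trace[[signal]]
  if (is.null(sig)) stop("trace lacks channel '", signal, "'", call. = FALSE)
  npre <- frames_spanned(pre, trace$fps)
  npost <- frames_spanned(post, trace$fps)
  sl <- slice_rows(sig, trace$fps, trace$frame_times[1], events,
                   -npre, npost, length(sig))
  dropped <- which(!sl$ok)
  if (length(dropped)) {
    warning(sprintf("dropping %d event(s) whose window leaves the recording",
                    length(dropped)))
  }
  time_axis <- ((-npre):npost) / trace$fps
  if (!any(sl$ok)) {
    warning("no events survive alignment; empty matrix")
    return(new_aligned_matrix(matrix(numeric(), 0, npre + npost + 1L),
                              time_axis, data.frame(event_time = numeric()),
                              "peri_event", pre + post, dropped))
  }
  n_col <- npre + npost + 1L
  Y <- t(vapply(sl$lo, function(l) sig[l:(l + n_col - 1L)], numeric(n_col)))
  new_aligned_matrix(Y, time_axis,
                     data.frame(event_time = events[sl$ok]),
                     "peri_event", pre + post, dropped)
}

#' Interval area under the curve per aligned row
#'
#' Sums each row of an aligned matrix over the columns whose times fall in
#' the closed interval `[a, b]`, with the endpoints matched to the nearest
#' frame. Summing (not integrating) keeps the value in frame units so AUCs
#' are reproducible bit-exactly; a 0.5 s interval at 30 fps spans 16 columns.
#'
#' @param M an `aligned_matrix`.
#' @param interval numeric length-2, `c(a, b)` in seconds within the time
#'   axis span.
#' @return numeric vector, one AUC per row of `M$Y`.
#' @export
interval_auc <- function(M, interval) {
  stopifnot(inherits(M, "aligned_matrix"), length(interval) == 2L)
  a <- min(interval); b <- max(interval)
  ta <- M$time_axis
  step <- if (length(ta) > 1L) ta[2] - ta[1] else 1
  sel <- ta >= a - step / 2 - 1e-9 & ta <= b + step / 2 - 1e-9
  # nearest-frame matching of both endpoints, half-ties toward earlier frames
  if (!any(sel)) stop("interval selects no columns", call. = FALSE)
  rowSums(M$Y[, sel, drop = FALSE])
}
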