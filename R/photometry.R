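#' Create a photometry trace
#'
#' Container for one subject-session's fluorescence recording, sampled at a
#' uniform frame rate (default 30 frames/s). Derived channels (`f_avg`,
#' `f_baseline`, `dff`, `dff_smoothed`, `z`) are filled by [compute_dff()],
#' [smooth_exponential()] and [zscore_session()], or all at once by
#' [process_trace()].
#'
#' @param f_raw numeric vector of raw fluorescence (arbitrary units).
#' @param fps frames per second; ignored if `frame_times` is given.
#' @param t0 time of the first frame in seconds.
#' @param frame_times optional explicit frame times; must be uniformly
#'   spaced within 1e-6 s.
#' @param subject_id opaque label.
#' @return object of class `photometry_trace`.
#' @export
photometry_trace <- function(f_raw, fps = 30, t0 = 0, frame_times = NULL,
                             subject_id = "subject1") {
  f_raw <- as.numeric(f_raw)
  if (length(f_raw) < 2L) stop("trace too short", call. = FALSE)
  if (is.null(frame_times)) {
    assert_scalar_pos(fps, "fps")
    frame_times <- t0 + (seq_along(f_raw) - 1) / fps
  } else {
    if (length(frame_times) != length(f_raw)) {
      stop("frame_times and f_raw lengths differ", call. = FALSE)
    }
    dt <- diff(frame_times)
    if (diff(range(dt)) > 1e-6 || any(dt <= 0)) {
      stop("nonuniform frame spacing (tolerance 1e-6 s)", call. = FALSE)
    }
    fps <- 1 / mean(dt)
  }
  structure(list(subject_id = subject_id, frame_times = frame_times,
                 fps = fps, f_raw = f_raw),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> subject %s: %d frames @ %.3g fps (%.1f s)\n",
              x$subject_id, length(x$f_raw), x$fps,
              x$frame_times[length(x$frame_times)] - x$frame_times[1]))
  cat("channels:", paste(intersect(
    c("f_raw", "f_avg", "f_baseline", "dff", "dff_smoothed", "z"),
    names(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a fluorescence trace
#'
#' Expects a headered CSV `time_s,f_raw`; any derived channels present as
#' extra columns are attached to the returned trace.
#'
#' @param path CSV path.
#' @param subject_id subject label; defaults to the file name sans extension.
#' @return a [photometry_trace()].
#' @export
read_trace <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "f_raw") %in% names(d))) {
    stop("trace file must have columns time_s,f_raw: ", path, call. = FALSE)
  }
  tr <- photometry_trace(d$f_raw, frame_times = d$time_s,
                         subject_id = subject_id %||%
                           sub("\\.[^.]*$", "", basename(path)))
  for (ch in intersect(c("f_avg", "f_baseline", "dff", "dff_smoothed", "z"),
                       names(d))) {
    tr[[ch]] <- d[[ch]]
  }
  tr
}

#' Write a fluorescence trace
#'
#' @param trace a [photometry_trace()]; derived channels, if present, are
#'   written as additional columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photometry_trace"))
  d <- data.frame(time_s = trace$frame_times, f_raw = trace$f_raw)
  for (ch in intersect(c("f_avg", "f_baseline", "dff", "dff_smoothed", "z"),
                       names(trace))) {
    d[[ch]] <- trace[[ch]]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# trailing moving mean over [t - window, t], partial at the start
trailing_mean <- function(x, m) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - m)
  (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
}

# trailing moving min over [t - window, t], partial at the start
trailing_min <- function(x, m) {
  n <- length(x)
  out <- x
  if (m >= 1L && n > 1L) {
    for (k in seq_len(min(m, n - 1L))) {
      out[(k + 1L):n] <- pmin(out[(k + 1L):n], x[1L:(n - k)])
    }
  }
  out
}

#' Compute dF/F against a sliding minimum-of-mean baseline
#'
#' Three-stage baseline correction for slowly drifting fluorescence: the raw
#' signal is first averaged over a trailing window (`avg_window`, default
#' 0.75 s) to give `F_AVG`; the control signal `F_BASELINE` at each frame is
#' the minimum of `F_AVG` over the lookback window (default 3 s) ending at
#' that frame; then `dF/F = (F_RAW - F_BASELINE) / F_BASELINE`. Frames whose
#' window extends before the recording use the available partial window.
#'
#' Windows are causal (trailing), consistent with the baseline being taken
#' over the window preceding each frame; a centered averaging window is
#' available via `align = "center"`.
#'
#' @param trace a [photometry_trace()] with strictly positive `f_raw`.
#' @param avg_window averaging window in seconds (default 0.75).
#' @param baseline_lookback baseline lookback in seconds (default 3).
#' @param align `"trailing"` (default) or `"center"` for the averaging
#'   window.
#' @return the trace with `f_avg`, `f_baseline`, `dff` filled.
#' @export
compute_dff <- function(trace, avg_window = 0.75, baseline_lookback = 3,
                        align = c("trailing", "center")) {
  stopifnot(inherits(trace, "photometry_trace"))
  align <- match.arg(align)
  assert_scalar_pos(avg_window, "avg_window")
  assert_scalar_pos(baseline_lookback, "baseline_lookback")
  x <- trace$f_raw
  if (any(x <= 0)) stop("f_raw must be strictly positive", call. = FALSE)
  m_avg <- frames_spanned(avg_window, trace$fps)
  if (length(x) <= m_avg) stop("trace shorter than the averaging window",
                               call. = FALSE)
  if (align == "trailing") {
    f_avg <- trailing_mean(x, m_avg)
  } else {
    h <- m_avg %/% 2L
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(1L, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    f_avg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m_base <- frames_spanned(baseline_lookback, trace$fps)
  f_base <- trailing_min(f_avg, m_base)
  trace$f_avg <- f_avg
  trace$f_baseline <- f_base
  trace$dff <- (x - f_base) / f_base
  trace
}

#' Exponentially weighted moving-window smoothing
#'
#' Smooths a signal with a truncated one-sided exponential kernel: at frame
#' `t`, a weighted mean of the trailing `width` seconds with weights
#' `exp(-(t - s) / tau)`, renormalized over the frames actually available
#' (so a constant input is a fixed point, including at the edges). A
#' symmetric (two-sided) kernel of total support `width` is available.
#'
#' @param x numeric vector, or a [photometry_trace()] whose `dff` channel
#'   is smoothed into `dff_smoothed`.
#' @param tau decay time constant in seconds (default 0.2).
#' @param width kernel support in seconds (default 1).
#' @param fps frames per second (taken from the trace when `x` is one).
#' @param kernel `"causal"` (default) or `"symmetric"`.
#' @return smoothed vector, or the trace with `dff_smoothed` filled.
#' @export
smooth_exponential <- function(x, tau = 0.2, width = 1, fps = NULL,
                               kernel = c("causal", "symmetric")) {
  kernel <- match.arg(kernel)
  assert_scalar_pos(tau, "tau")
  assert_scalar_pos(width, "width")
  if (inherits(x, "photometry_trace")) {
    if (is.null(x$dff)) stop("run compute_dff() first", call. = FALSE)
    x$dff_smoothed <- smooth_exponential(x$dff, tau = tau, width = width,
                                         fps = x$fps, kernel = kernel)
    return(x)
  }
  if (is.null(fps)) stop("fps required for plain vectors", call. = FALSE)
  n <- length(x)
  if (kernel == "causal") {
    offs <- 0:frames_spanned(width, fps)
  } else {
    h <- frames_spanned(width / 2, fps)
    offs <- (-h):h
  }
  w <- exp(-abs(offs) / (tau * fps))
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_along(offs)) {
    k <- offs[j]
    src <- seq_len(n) - k
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w[j] * x[src[ok]]
    den[ok] <- den[ok] + w[j]
  }
  num / den
}

#' Session-wide z-scoring
#'
#' Standardizes a signal by the mean and SD computed over the entire
#' session, so peri-event excerpts remain comparable across subjects. The
#' session SD is the population SD (denominator n): the whole session is
#' the reference population, not a sample from a longer recording.
#'
#' @param x numeric vector, or a [photometry_trace()] whose `dff_smoothed`
#'   (falling back to `dff`) is standardized into `z`.
#' @return z-scored vector, or the trace with `z` filled.
#' @export
zscore_session <- function(x) {
  if (inherits(x, "photometry_trace")) {
    src <- x$dff_smoothed %||% x$dff
    if (is.null(src)) stop("run compute_dff() first", call. = FALSE)
    x$z <- zscore_session(src)
    return(x)
  }
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) stop("zero-variance signal cannot be z-scored",
                                    call. = FALSE)
  (x - mu) / s
}

#' Full dF/F preprocessing in one call
#'
#' Convenience wrapper: [compute_dff()], [smooth_exponential()],
#' [zscore_session()] with the standard parameters.
#'
#' @param trace a [photometry_trace()].
#' @param avg_window,baseline_lookback,tau,width see the stage functions.
#' @return the trace with all derived channels filled.
#' @export
process_trace <- function(trace, avg_window = 0.75, baseline_lookback = 3,
                          tau = 0.2, width = 1) {
  trace <- compute_dff(trace, avg_window = avg_window,
                       baseline_lookback = baseline_lookback)
  trace <- smooth_exponential(trace, tau = tau, width = width)
  zscore_session(trace)
}

evoked_snr <- function(Y) {
  mu <- colMeans(Y)
  num <- stats::var(mu)
  resid <- sweep(Y, 2, mu)
  den <- mean(apply(resid, 1, stats::var))
  if (den == 0) return(Inf)
  num / den
}

#' Shuffle-null signal-to-noise test for evoked activity
#'
#' Quantifies whether trial-aligned activity carries a reproducible evoked
#' component. The SNR is the variance over time of the across-trial mean
#' trace divided by the mean (over trials) of the within-trial residual
#' variance - a variance-explained ratio for evoked responses. Its
#' significance comes from a time-shuffle null: each shuffle independently
#' permutes timepoints within every trial (destroying temporal structure
#' while keeping each trial's marginal distribution) and the SNR is
#' recomputed; `p = (1 + #(shuffled >= original)) / (1 + n_shuffles)`.
#'
#' @param Y trials x timepoints matrix (at least 5 trials, 10 timepoints),
#'   or an `aligned_matrix`.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed optional RNG seed.
#' @param method `"permute"` (default, independent permutation per trial) or
#'   `"circular"` (random circular shift per trial, preserving
#'   autocorrelation).
#' @return an `snr_report`: list with `snr_original`, `snr_shuffled`
#'   (numeric vector), `p`, `n_shuffles`, `method`, `seed`. Identical trials
#'   give `snr_original = Inf` (noiseless limit) and the smallest attainable
#'   p.
#' @export
snr_shuffle_test <- function(Y, n_shuffles = 1000L, seed = NULL,
                             method = c("permute", "circular")) {
  method <- match.arg(method)
  if (inherits(Y, "aligned_matrix")) Y <- Y$Y
  Y <- as.matrix(Y)
  if (nrow(Y) < 5L) stop("need at least 5 trials", call. = FALSE)
  if (ncol(Y) < 10L) stop("need at least 10 timepoints", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  snr0 <- evoked_snr(Y)
  Tn <- ncol(Y)
  shuf <- vapply(seq_len(n_shuffles), function(b) {
    Yb <- Y
    for (i in seq_len(nrow(Y))) {
      Yb[i, ] <- if (method == "permute") Y[i, sample.int(Tn)] else
        Y[i, (seq_len(Tn) + sample.int(Tn, 1L) - 1L) %% Tn + 1L]
    }
    evoked_snr(Yb)
  }, numeric(1))
  structure(list(snr_original = snr0, snr_shuffled = shuf,
                 p = (1 + sum(shuf >= snr0)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, method = method, seed = seed),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> SNR = %.4g, shuffled median = %.4g, p = %.4g (%d shuffles, %s)\n",
              x$snr_original, stats::median(x$snr_shuffled), x$p,
              x$n_shuffles, x$method))
  invisible(x)
}
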