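#' @title Behavioral event streams
#' @description Constructors and I/O for timestamped operant action events.
#' @name event_stream
NULL

EVENT_KINDS <- c("rNP", "nrNP", "ME", "MX")
BLOCK_TYPES <- c("rNP-ME", "ME-MX", "MX-rNP", "rNP-rNP", "MX-ME")
CYCLE_BLOCK_TYPES <- c("rNP-ME", "ME-MX", "MX-rNP")

#' Create a validated event stream
#'
#' An event stream is one session's ordered action events: rewarded
#' nose-pokes (`rNP`), non-rewarded nose-pokes (`nrNP`), magazine entries
#' (`ME`) and magazine exits (`MX`), timestamped in seconds from session
#' start on a fixed resolution grid (10 ms by default, matching operant
#' chamber logging).
#'
#' @param times numeric vector, seconds from session start (nondecreasing
#'   after a stable sort).
#' @param kinds character vector, one of `rNP`, `nrNP`, `ME`, `MX` per event.
#' @param subject_id opaque subject label.
#' @param session_duration session length in seconds; defaults to the last
#'   event time, and is raised to it if the declared value is smaller.
#' @param resolution event-clock resolution in seconds (default 0.01).
#' @return an object of class `event_stream` with elements `subject_id`,
#'   `events` (data.frame of `time`, `kind`), `session_duration`,
#'   `resolution`.
#' @examples
#' es <- event_stream(c(0.5, 2, 5), c("rNP", "ME", "MX"))
#' es$session_duration
#' @export
event_stream <- function(times, kinds, subject_id = "subject1",
                         session_duration = NULL, resolution = 0.01) {
  if (length(times) != length(kinds)) {
    stop("`times` and `kinds` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty event stream", call. = FALSE)
  kinds <- as.character(kinds)
  bad <- setdiff(unique(kinds), EVENT_KINDS)
  if (length(bad)) {
    stop("unknown event code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  assert_scalar_pos(resolution, "resolution")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("event times must be finite and nonnegative", call. = FALSE)
  }
  off <- abs(times - round(times / resolution) * resolution)
  if (any(off > 1e-9 + 1e-12 * abs(times))) {
    stop("event times are not integer multiples of the resolution grid",
         call. = FALSE)
  }
  ord <- order(times)  # stable: ties keep input order
  times <- times[ord]
  kinds <- kinds[ord]
  dur <- max(session_duration %||% 0, times[length(times)])
  structure(
    list(subject_id = subject_id,
         events = data.frame(time = times, kind = kinds,
                             stringsAsFactors = FALSE),
         session_duration = dur,
         resolution = resolution),
    class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> subject %s: %d events over %.2f s\n",
              x$subject_id, nrow(x$events), x$session_duration))
  print(table(factor(x$events$kind, levels = EVENT_KINDS)))
  invisible(x)
}

#' Read a behavioral event log
#'
#' Expects a headered CSV `time_s,event` with event codes in
#' `rNP`, `nrNP`, `ME`, `MX`, optionally preceded by a comment line
#' `# session_duration_s=<float>`. The session duration is the larger of the
#' declared value and the last event time.
#'
#' @param path path to the CSV log.
#' @param subject_id subject label; defaults to the file name sans extension.
#' @param resolution event-clock resolution in seconds.
#' @return an [event_stream()].
#' @seealso [write_events()]
#' @export
read_events <- function(path, subject_id = NULL, resolution = 0.01) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty event log: ", path, call. = FALSE)
  declared <- NULL
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("session_duration_s\\s*=\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2L) declared <- as.numeric(m[2])
  }
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) && grepl("^\\s*time_s\\s*,", lines[1])) lines <- lines[-1]
  if (!length(lines)) stop("event log has no data rows: ", path, call. = FALSE)
  parts <- strsplit(lines, ",")
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop(sprintf("malformed row %d in %s (expected `time,event`)",
                 which(nf != 2L)[1], path), call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  kd <- trimws(vapply(parts, `[[`, "", 2L))
  if (anyNA(tm)) {
    stop(sprintf("non-numeric time in row %d of %s", which(is.na(tm))[1], path),
         call. = FALSE)
  }
  bad <- which(!kd %in% EVENT_KINDS)
  if (length(bad)) {
    stop(sprintf("unknown event code '%s' in row %d of %s",
                 kd[bad[1]], bad[1], path), call. = FALSE)
  }
  event_stream(tm, kd,
               subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
               session_duration = declared, resolution = resolution)
}

#' Write a behavioral event log
#'
#' Emits the same dialect [read_events()] consumes, so logs round-trip.
#'
#' @param stream an [event_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_duration_s=%.10g", stream$session_duration), con)
  writeLines("time_s,event", con)
  writeLines(sprintf("%.2f,%s", stream$events$time, stream$events$kind), con)
  invisible(path)
}

#' Segment an event stream into behavioral blocks
#'
#' A block is the transition between two adjacent retained action events.
#' Non-rewarded nose-pokes are dropped before pairing (they do not occur in
#' recording sessions and are excluded from analysis). Adjacent pairs whose
#' ordered kinds match one of the five named types become blocks; other pairs
#' (e.g. `ME-ME`) are skipped and counted in the diagnostics attribute.
#' Cycle blocks are `rNP-ME`, `ME-MX`, `MX-rNP`; non-cycle blocks are
#' `rNP-rNP` and `MX-ME`.
#'
#' Each block carries two nuisance covariates: session elapsed
#' `SE = t_start / T_S` (fraction of the session at block onset) and block
#' velocity `BV = 1 / (t_end - t_start)` (1/s, speed of block completion).
#' Zero-duration blocks (tied timestamps) are dropped with a warning since
#' `BV` is undefined.
#'
#' @param stream an [event_stream()].
#' @return data.frame with columns `block_type`, `t_start`, `t_end`,
#'   `duration`, `se`, `bv`, `is_cycle_block`, plus a `diagnostics` attribute
#'   (counts of dropped nrNPs, skipped pairs, dropped zero-duration blocks).
#'   Fewer than two retained events yields a zero-row frame.
#' @examples
#' es <- event_stream(c(0, 2, 5, 8), c("rNP", "ME", "MX", "rNP"))
#' segment_blocks(es)
#' @export
segment_blocks <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$events
  n_nrnp <- sum(ev$kind == "nrNP")
  ev <- ev[ev$kind != "nrNP", , drop = FALSE]
  empty <- data.frame(block_type = character(), t_start = numeric(),
                      t_end = numeric(), duration = numeric(), se = numeric(),
                      bv = numeric(), is_cycle_block = logical(),
                      stringsAsFactors = FALSE)
  diag <- list(dropped_nrnp = n_nrnp, skipped_pairs = 0L,
               dropped_zero_duration = 0L)
  if (nrow(ev) < 2L) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  from <- ev$kind[-nrow(ev)]
  to <- ev$kind[-1L]
  type <- paste(from, to, sep = "-")
  keep <- type %in% BLOCK_TYPES
  diag$skipped_pairs <- sum(!keep)
  t_start <- ev$time[-nrow(ev)][keep]
  t_end <- ev$time[-1L][keep]
  type <- type[keep]
  zero <- t_end <= t_start
  if (any(zero)) {
    warning(sprintf("dropping %d zero-duration block(s) (tied timestamps)",
                    sum(zero)))
    diag$dropped_zero_duration <- sum(zero)
    t_start <- t_start[!zero]; t_end <- t_end[!zero]; type <- type[!zero]
  }
  out <- data.frame(
    block_type = type,
    t_start = t_start,
    t_end = t_end,
    duration = t_end - t_start,
    se = t_start / stream$session_duration,
    bv = 1 / (t_end - t_start),
    is_cycle_block = type %in% CYCLE_BLOCK_TYPES,
    stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- diag
  out
}

#' Segment blocks into reward-to-reward cycles
#'
#' A cycle is the stretch of behavior between two successive rewarded
#' magazine approaches: the sequence of blocks encapsulated by adjacent
#' `rNP-ME` blocks. By default a cycle runs from one `rNP-ME` completion
#' (reward receipt, the block's `ME`) to the next, and its member blocks are
#' every block strictly between the two delimiting `rNP-ME` blocks plus the
#' terminal `rNP-ME` block, so the minimal routine cycle
#' (`ME-MX`, `MX-rNP`, `rNP-ME`) has 3 blocks.
#'
#' @param blocks data.frame from [segment_blocks()], ordered by `t_start`.
#' @param anchor cycle boundary convention: `"ME"` (default; duration is
#'   measured ME-completion to ME-completion) or `"rNP"` (nose-poke to
#'   nose-poke, i.e. `rNP-ME` block starts).
#' @param include_terminal logical; count the terminal `rNP-ME` block as a
#'   member (default `TRUE`).
#' @return data.frame with columns `cycle`, `t_start`, `t_end`, `duration`,
#'   `n_blocks`, `se` (session elapsed of the first member block), and an
#'   attribute `members`: a list of block row indices per cycle. Fewer than
#'   two `rNP-ME` blocks yields zero rows.
#' @examples
#' es <- event_stream(c(0, 2, 5, 8, 9), c("rNP", "ME", "MX", "rNP", "ME"))
#' segment_cycles(segment_blocks(es))
#' @export
segment_cycles <- function(blocks, anchor = c("ME", "rNP"),
                           include_terminal = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(blocks))
  empty <- data.frame(cycle = integer(), t_start = numeric(),
                      t_end = numeric(), duration = numeric(),
                      n_blocks = integer(), se = numeric())
  if (nrow(blocks) && is.unsorted(blocks$t_start)) {
    stop("blocks must be ordered by t_start", call. = FALSE)
  }
  idx <- which(blocks$block_type == "rNP-ME")
  if (length(idx) < 2L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  nc <- length(idx) - 1L
  members <- vector("list", nc)
  out <- data.frame(cycle = seq_len(nc), t_start = NA_real_, t_end = NA_real_,
                    duration = NA_real_, n_blocks = NA_integer_,
                    se = NA_real_)
  bound <- if (anchor == "ME") blocks$t_end else blocks$t_start
  for (k in seq_len(nc)) {
    i <- idx[k]; j <- idx[k + 1L]
    mem <- if (include_terminal) seq.int(i + 1L, j) else
      (if (j - i > 1L) seq.int(i + 1L, j - 1L) else integer())
    members[[k]] <- mem
    out$t_start[k] <- bound[i]
    out$t_end[k] <- bound[j]
    out$duration[k] <- bound[j] - bound[i]
    out$n_blocks[k] <- length(mem)
    out$se[k] <- if (length(mem)) blocks$se[mem[1]] else blocks$se[j]
  }
  attr(out, "members") <- members
  out
}

#' Assign each block to its enclosing cycle
#'
#' @param blocks data.frame from [segment_blocks()].
#' @param cycles data.frame from [segment_cycles()].
#' @return integer vector (length `nrow(blocks)`) of cycle ids, `NA` for
#'   blocks outside every cycle (before the first or after the last reward).
#' @export
assign_block_cycles <- function(blocks, cycles) {
  members <- attr(cycles, "members")
  out <- rep(NA_integer_, nrow(blocks))
  for (k in seq_along(members)) out[members[[k]]] <- k
  out
}

se_bins <- function(n_bins) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  list(breaks = breaks, centers = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

#' Cycle- vs non-cycle-block choice proportions across the session
#'
#' After a nose-poke the animal either goes to the magazine (`rNP-ME`, the
#' cycle choice) or pokes again (`rNP-rNP`); after a magazine exit it either
#' returns to the nose-poke hole (`MX-rNP`) or re-enters the magazine
#' (`MX-ME`). Binning blocks by session elapsed tracks how these choice
#' proportions shift toward the routine as the session progresses.
#'
#' @param blocks data.frame from [segment_blocks()].
#' @param n_bins number of equal-width session-elapsed bins (default 10).
#' @return data.frame with `se_center`, `p_rnp_me` (fraction of rNP-initiated
#'   blocks that are `rNP-ME`), `p_mx_rnp` (fraction of MX-initiated blocks
#'   that are `MX-rNP`), and the bin counts `n_rnp`, `n_mx`. Empty bins are
#'   `NA`.
#' @export
choice_proportions <- function(blocks, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  b <- se_bins(n_bins)
  bin <- findInterval(blocks$se, b$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  start <- sub("-.*$", "", blocks$block_type)
  out <- data.frame(se_center = b$centers,
                    p_rnp_me = NA_real_, p_mx_rnp = NA_real_,
                    n_rnp = 0L, n_mx = 0L)
  for (k in seq_len(n_bins)) {
    in_bin <- bin == k
    r <- in_bin & start == "rNP"
    m <- in_bin & start == "MX"
    out$n_rnp[k] <- sum(r); out$n_mx[k] <- sum(m)
    if (any(r)) out$p_rnp_me[k] <- mean(blocks$block_type[r] == "rNP-ME")
    if (any(m)) out$p_mx_rnp[k] <- mean(blocks$block_type[m] == "MX-rNP")
  }
  out
}

#' Mean blocks-per-cycle across the session
#'
#' A shrinking block count per cycle over session elapsed is the signature of
#' routine formation: fewer detours between successive rewards.
#'
#' @param cycles data.frame from [segment_cycles()]; a cycle's session
#'   elapsed is that of its first member block.
#' @param n_bins number of equal-width session-elapsed bins (default 10).
#' @return data.frame with `se_center`, `mean_n_blocks`, `n_cycles`; empty
#'   bins are `NA`.
#' @export
blocks_per_cycle_curve <- function(cycles, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  b <- se_bins(n_bins)
  out <- data.frame(se_center = b$centers, mean_n_blocks = NA_real_,
                    n_cycles = 0L)
  if (!nrow(cycles)) return(out)
  bin <- findInterval(cycles$se, b$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (k in seq_len(n_bins)) {
    in_bin <- bin == k
    out$n_cycles[k] <- sum(in_bin)
    if (any(in_bin)) out$mean_n_blocks[k] <- mean(cycles$n_blocks[in_bin])
  }
  out
}
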