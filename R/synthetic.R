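#' Configuration for synthetic cohort generation
#'
#' Defines the generative model for multi-subject operant sessions with
#' paired photometry. Behavior: the k-th cycle duration is
#' `T_k = (T_min + (T_0 - T_min) exp(-k / kappa)) * LogNormal(0, sigma_t)` -
#' a decaying mean (routine formation: cycles shorten over the session) with
#' multiplicative jitter on the whole duration, so cycle-to-cycle behavioral
#' variability persists after the routine is established,
#' and non-routine blocks (`rNP-rNP` re-pokes, `MX-ME` magazine re-entries)
#' are inserted with probabilities that decay logistically in session
#' elapsed. Fluorescence: a slow exponential bleach drift multiplying
#' `1 + transients + effects + noise`, where transients are GCaMP6s-like
#' double-exponential bumps locked to every action event, and each effect
#' entry adds activity proportional to a behavioral covariate inside a fixed
#' window around rewarded magazine entries - the ground-truth signal the
#' regression pipeline should recover.
#'
#' @param n_subjects cohort size (default 11).
#' @param session_duration session cap in seconds (default 3600).
#' @param max_rewards session also ends after this many rewards (default 60).
#' @param t0_cycle,t_min,kappa,sigma_t cycle-duration schedule: initial and
#'   asymptotic durations (s), decay constant (cycles), log-normal jitter SD.
#' @param nonroutine insertion rates: list with `p_early`, `p_late`, `mid`,
#'   `slope` of the logistic decay in session elapsed, applied to both
#'   non-routine block types.
#' @param fps photometry frame rate (default 30).
#' @param bleach list `f0` (baseline fluorescence), `frac` (bleachable
#'   fraction), `tau` (s).
#' @param transient list `rise`, `decay` (s), `amp` (named peak dF/F per
#'   event kind), `amp_jitter` (log-normal SD of per-event amplitude).
#' @param effects list of effect entries, each
#'   `list(covariate, window, amp)`: `covariate` in `"RI"`, `"SE"`, `"BV"`;
#'   `window` in seconds relative to rewarded magazine entry; `amp` is dF/F
#'   per unit covariate. Empty list for a null (no-effect) cohort.
#' @param noise_sd frame noise SD as a fraction of the bleach curve.
#' @param subject_sd list of between-subject log-normal SDs: `amp`
#'   (transient/effect gain), `t0` (initial cycle duration).
#' @param resolution event-clock resolution (s).
#' @param seed base RNG seed; per-subject seeds are derived from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 11L, session_duration = 3600,
                              max_rewards = 60L,
                              t0_cycle = 90, t_min = 20, kappa = 10,
                              sigma_t = 0.5,
                              nonroutine = list(p_early = 0.45, p_late = 0.15,
                                                mid = 0.3, slope = 0.12),
                              fps = 30,
                              bleach = list(f0 = 100, frac = 0.3, tau = 1200),
                              transient = list(rise = 0.2, decay = 1.5,
                                               amp = c(rNP = 0.03, ME = 0.05,
                                                       MX = 0.02),
                                               amp_jitter = 0.3),
                              effects = list(
                                list(covariate = "RI", window = c(0, 1.1),
                                     amp = 0.06),
                                list(covariate = "RI", window = c(-0.5, 0),
                                     amp = 0.04)),
                              noise_sd = 0.01,
                              subject_sd = list(amp = 0.2, t0 = 0.15),
                              resolution = 0.01, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              session_duration = session_duration,
              max_rewards = as.integer(max_rewards),
              t0_cycle = t0_cycle, t_min = t_min, kappa = kappa,
              sigma_t = sigma_t, nonroutine = nonroutine, fps = fps,
              bleach = bleach, transient = transient, effects = effects,
              noise_sd = noise_sd, subject_sd = subject_sd,
              resolution = resolution, seed = as.integer(seed))
  assert_scalar_pos(cfg$t_min, "t_min")
  assert_scalar_pos(cfg$fps, "fps")
  if (cfg$t_min < 200 * cfg$resolution) {
    stop("infeasible schedule: t_min too small for event spacing at the ",
         "clock resolution", call. = FALSE)
  }
  if (cfg$t0_cycle < cfg$t_min) stop("t0_cycle must be >= t_min",
                                     call. = FALSE)
  pr <- unlist(cfg$nonroutine[c("p_early", "p_late")])
  if (any(pr < 0 | pr > 1)) stop("insertion probabilities must be in [0, 1]",
                                 call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Null-effect variant of a simulation config
#'
#' Convenience for cohorts whose activity carries no behavioral effect
#' (event-locked transients and noise only), the negative control the
#' cluster test should leave empty.
#'
#' @param cfg a [simulation_config()].
#' @return the config with an empty effect map.
#' @export
null_effect_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  cfg$effects <- list()
  cfg
}

insertion_prob <- function(se, nr) {
  nr$p_late + (nr$p_early - nr$p_late) *
    stats::plogis(-(se - nr$mid) / nr$slope)
}

snap <- function(t, res) round(t / res) * res

# strictly increasing on the resolution grid
enforce_grid <- function(times, res) {
  times <- snap(times, res)
  for (i in seq_along(times)[-1]) {
    if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + res
  }
  times
}

derive_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 1000003 + subject_index * 7919) %%
               2147483647)
}

transient_kernel <- function(tt, rise, decay) {
  k <- (1 - exp(-tt / rise)) * exp(-tt / decay)
  k[tt < 0] <- 0
  k
}

simulate_events <- function(cfg) {
  nr <- cfg$nonroutine
  res <- cfg$resolution
  t0_s <- cfg$t0_cycle * exp(stats::rnorm(1, 0, cfg$subject_sd$t0))
  times <- c()
  kinds <- c()
  push <- function(t, k) {
    times <<- c(times, t)
    kinds <<- c(kinds, k)
  }
  # session opens with the first rewarded approach
  t <- 3 + stats::runif(1, 0, 4)
  push(t, "rNP")
  d_rme <- exp(stats::rnorm(1, log(1.2), 0.25))
  t <- t + d_rme
  push(t, "ME")
  rewards <- 1L
  k <- 0L
  while (rewards < cfg$max_rewards) {
    k <- k + 1L
    Tk <- (cfg$t_min + (t0_s - cfg$t_min) * exp(-k / cfg$kappa)) *
      exp(stats::rnorm(1, 0, cfg$sigma_t))
    Tk <- max(Tk, cfg$t_min * 0.5)
    if (t + Tk > cfg$session_duration) break
    se <- t / cfg$session_duration
    # partition the cycle: magazine dwell and poke-to-magazine latency have
    # realistic, roughly duration-invariant scales (trained mice approach the
    # magazine within ~2 s); travel/exploration absorbs the remainder
    d_me_mx <- max(min(exp(stats::rnorm(1, log(4), 0.4)), 0.4 * Tk), 2 * res)
    d_rme <- max(min(exp(stats::rnorm(1, log(1.2), 0.3)), 0.2 * Tk), 2 * res)
    d_trav <- Tk - d_me_mx - d_rme  # >= 0.4 Tk given the caps above
    t_mx <- t + d_me_mx
    push(t_mx, "MX")
    t_rnp <- t_mx + d_trav
    if (stats::runif(1) < insertion_prob(se, nr)) {
      # magazine re-entry: MX -> ME -> MX before returning to the hole
      a <- t_mx + stats::runif(1, 0.2, 0.45) * d_trav
      b <- a + stats::runif(1, 0.2, 0.4) * (t_rnp - a)
      push(a, "ME")
      push(b, "MX")
    }
    push(t_rnp, "rNP")
    if (stats::runif(1) < insertion_prob(se, nr)) {
      # repeated poke before heading to the magazine
      push(t_rnp + stats::runif(1, 0.2, 0.6) * d_rme, "rNP")
    }
    t <- t + Tk  # rewarded magazine entry closing the cycle
    push(t, "ME")
    rewards <- rewards + 1L
  }
  times <- enforce_grid(times, res)
  dur <- if (rewards >= cfg$max_rewards) times[length(times)] else
    cfg$session_duration
  event_stream(times, kinds, session_duration = dur, resolution = res)
}

effect_covariate_value <- function(covariate, after, ev_time, blocks, cycles,
                                   ri_by_cycle, cyc_of_block) {
  i <- if (after) {
    which(blocks$block_type == "ME-MX" & abs(blocks$t_start - ev_time) < 1e-9)
  } else {
    which(blocks$block_type == "rNP-ME" & abs(blocks$t_end - ev_time) < 1e-9)
  }
  if (length(i) != 1L) return(NA_real_)
  switch(covariate,
         SE = blocks$se[i],
         BV = blocks$bv[i],
         RI = if (is.na(cyc_of_block[i])) NA_real_ else
           ri_by_cycle[cyc_of_block[i]])
}

#' Simulate one subject's session
#'
#' Generates the behavioral event stream and the paired raw fluorescence
#' trace for one subject under a [simulation_config()], plus a ground-truth
#' record of everything injected. Reproducible: the subject's RNG seed is
#' derived from `cfg$seed` and `subject_index`.
#'
#' @param cfg a [simulation_config()].
#' @param subject_index 1-based subject number within the cohort.
#' @return list with `stream` (an [event_stream()]), `trace` (a raw
#'   [photometry_trace()]), and `truth` (cycle durations, routine indices,
#'   per-event injected effect amplitudes, subject gain, seed).
#' @export
simulate_session <- function(cfg, subject_index = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  sid <- sprintf("subject%02d", subject_index)
  seed_s <- derive_seed(cfg$seed, subject_index)
  set.seed(seed_s)
  stream <- simulate_events(cfg)
  stream$subject_id <- sid

  blocks <- segment_blocks(stream)
  cycles <- segment_cycles(blocks)
  ri_by_cycle <- if (nrow(cycles)) routine_index(cycles$duration) else numeric()
  cyc_of_block <- assign_block_cycles(blocks, cycles)

  dur <- stream$session_duration
  n <- frames_spanned(dur, cfg$fps) + 1L
  tt <- (seq_len(n) - 1) / cfg$fps
  amp_mult <- exp(stats::rnorm(1, 0, cfg$subject_sd$amp))

  # event-locked transients
  tr <- cfg$transient
  supp <- frames_spanned(min(8 * tr$decay, 12), cfg$fps)
  kern <- transient_kernel((0:supp) / cfg$fps, tr$rise, tr$decay)
  kern <- kern / max(kern)
  s <- numeric(n)
  ev <- stream$events
  for (i in seq_len(nrow(ev))) {
    base <- unname(tr$amp[ev$kind[i]])
    if (is.na(base) || base == 0) next
    a <- base * amp_mult * exp(stats::rnorm(1, 0, tr$amp_jitter))
    j0 <- frame_index(ev$time[i], cfg$fps)
    j <- j0:min(n, j0 + supp)
    if (j0 > n) next
    s[j] <- s[j] + a * kern[seq_along(j)]
  }

  # covariate-locked effect windows around rewarded magazine entries
  rme <- blocks$t_end[blocks$block_type == "rNP-ME"]
  injected <- list()
  for (e in cfg$effects) {
    after <- mean(e$window) > 0
    vals <- vapply(rme, function(te) {
      effect_covariate_value(e$covariate, after, te, blocks, cycles,
                             ri_by_cycle, cyc_of_block)
    }, numeric(1))
    amps <- e$amp * vals * amp_mult
    for (q in seq_along(rme)) {
      if (!is.finite(amps[q])) next
      j1 <- frame_index(rme[q] + e$window[1], cfg$fps)
      j2 <- frame_index(rme[q] + e$window[2], cfg$fps)
      j <- max(1L, j1):min(n, j2)
      if (!length(j)) next
      s[j] <- s[j] + amps[q]
    }
    injected[[length(injected) + 1L]] <-
      list(covariate = e$covariate, window = e$window, amp = e$amp,
           event_times = rme, covariate_values = vals,
           injected_amps = amps)
  }

  bl <- cfg$bleach
  drift <- bl$f0 * ((1 - bl$frac) + bl$frac * exp(-tt / bl$tau))
  f_raw <- drift * (1 + s + stats::rnorm(n, 0, cfg$noise_sd))
  f_raw <- pmax(f_raw, bl$f0 * 1e-3)
  trace <- photometry_trace(f_raw, fps = cfg$fps, subject_id = sid)

  list(stream = stream, trace = trace,
       truth = list(subject_id = sid, seed = seed_s, amp_mult = amp_mult,
                    cycle_durations = cycles$duration,
                    routine_index = ri_by_cycle,
                    effects = injected))
}

#' Simulate a multi-subject cohort
#'
#' Applies [simulate_session()] per subject and optionally writes the
#' standard file dialects (events CSV, trace CSV, `ground_truth.json`) so
#' the pipeline consumes synthetic data exactly as it would real data.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `sessions` (per-subject lists from
#'   [simulate_session()]), `manifest` (data.frame of subject ids, seeds,
#'   cycle counts, and file paths when written), and `cfg`.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  sessions <- lapply(seq_len(cfg$n_subjects), function(i) {
    simulate_session(cfg, i)
  })
  manifest <- data.frame(
    subject_id = vapply(sessions, function(s) s$truth$subject_id, ""),
    seed = vapply(sessions, function(s) s$truth$seed, integer(1)),
    n_cycles = vapply(sessions, function(s) length(s$truth$cycle_durations),
                      integer(1)),
    events_file = NA_character_, trace_file = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(sessions)) {
      sid <- manifest$subject_id[i]
      manifest$events_file[i] <- file.path(dir, paste0(sid, "_events.csv"))
      manifest$trace_file[i] <- file.path(dir, paste0(sid, "_trace.csv"))
      write_events(sessions[[i]]$stream, manifest$events_file[i])
      write_trace(sessions[[i]]$trace, manifest$trace_file[i])
    }
    jsonlite::write_json(lapply(sessions, `[[`, "truth"),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sessions = sessions, manifest = manifest, cfg = cfg)
}
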