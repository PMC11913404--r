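# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (literal loops, direct enumeration) and
# share no code with the package internals they check.

oracle_block_types <- c("rNP-ME", "ME-MX", "MX-rNP", "rNP-rNP", "MX-ME")

# literal adjacent-pair enumeration over retained events
oracle_blocks <- function(times, kinds, t_session) {
  keep <- kinds != "nrNP"
  tm <- times[keep]
  kd <- kinds[keep]
  out <- data.frame(block_type = character(), t_start = numeric(),
                    t_end = numeric(), stringsAsFactors = FALSE)
  if (length(tm) < 2) return(out)
  for (i in seq_len(length(tm) - 1)) {
    ty <- paste0(kd[i], "-", kd[i + 1])
    if (ty %in% oracle_block_types && tm[i + 1] > tm[i]) {
      out <- rbind(out, data.frame(block_type = ty, t_start = tm[i],
                                   t_end = tm[i + 1],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# literal cycle construction: between consecutive rNP-ME blocks, members are
# the blocks strictly between plus the terminal rNP-ME block; duration is
# measured ME completion to ME completion
oracle_cycles <- function(oblocks) {
  idx <- which(oblocks$block_type == "rNP-ME")
  out <- data.frame(duration = numeric(), n_blocks = integer())
  if (length(idx) < 2) return(out)
  for (k in seq_len(length(idx) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    out <- rbind(out, data.frame(duration = oblocks$t_end[j] - oblocks$t_end[i],
                                 n_blocks = j - i))
  }
  out
}

random_stream_events <- function(n, t_max = 300) {
  times <- sort(sample(seq(0, t_max, by = 0.01), n, replace = FALSE))
  kinds <- sample(c("rNP", "nrNP", "ME", "MX"), n, replace = TRUE)
  list(times = times, kinds = kinds)
}

# literal O(n * w) sliding-window dF/F: trailing mean then trailing min
oracle_dff <- function(f_raw, fps, avg_window = 0.75, lookback = 3) {
  n <- length(f_raw)
  m_avg <- floor(avg_window * fps + 1e-9)
  m_base <- floor(lookback * fps + 1e-9)
  f_avg <- numeric(n)
  for (i in seq_len(n)) f_avg[i] <- mean(f_raw[max(1, i - m_avg):i])
  f_base <- numeric(n)
  for (i in seq_len(n)) f_base[i] <- min(f_avg[max(1, i - m_base):i])
  list(f_avg = f_avg, f_baseline = f_base,
       dff = (f_raw - f_base) / f_base)
}

# direct weighted-mean convolution with a truncated causal exponential
oracle_smooth <- function(x, tau, width, fps) {
  n <- length(x)
  m <- floor(width * fps + 1e-9)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1, i - m):i
    w <- exp(-((i - js) / fps) / tau)
    out[i] <- sum(w * x[js]) / sum(w)
  }
  out
}

# sup |ECDF - Phi| by direct enumeration at the jump points
oracle_ks <- function(x) {
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  mx <- 0
  for (i in seq_len(n)) {
    mx <- max(mx, abs(i / n - pnorm(z[i])), abs((i - 1) / n - pnorm(z[i])))
  }
  mx
}

# simple uniform photometry trace with a known identity-ramp channel
ramp_trace <- function(duration = 60, fps = 30) {
  n <- floor(duration * fps) + 1
  tr <- photometry_trace(rep(100, n), fps = fps)
  tr$z <- tr$frame_times  # identity ramp: each frame carries its own time
  tr$dff_smoothed <- tr$frame_times
  tr
}

# cohort where the square-root-transformed index is exactly normal
sqrt_normal_durations <- function(n_subjects = 21, n_cycles = 30,
                                  mean_ri = 1.5, sd_ri = 0.3) {
  lapply(seq_len(n_subjects), function(i) {
    r <- rnorm(n_cycles, mean_ri, sd_ri)
    r <- pmax(r, 0.2)
    60 / r^2
  })
}

# cohort where the untransformed index L/T is exactly normal
linear_normal_durations <- function(n_subjects = 21, n_cycles = 30) {
  lapply(seq_len(n_subjects), function(i) {
    u <- rnorm(n_cycles, 2, 0.2)
    u <- pmax(u, 0.3)
    60 / u
  })
}

# null weight matrix with an additive group-level bump over given columns
bump_matrix <- function(n_subjects, n_time, bump_cols, bump = 0,
                        noise_sd = 1) {
  B <- matrix(rnorm(n_subjects * n_time, 0, noise_sd), n_subjects, n_time)
  B[, bump_cols] <- B[, bump_cols] + bump
  B
}

# long-format mixed-model data with known covariate-by-time effects
lmm_sim_data <- function(n_subjects = 8, n_blocks = 30, n_time = 8,
                         b_ri = 0.8, b_se = 0, b_bv = 0,
                         sd_subject = 0.5, sd_noise = 1) {
  rows <- vector("list", n_subjects)
  tt <- seq(0, 1, length.out = n_time)
  for (s in seq_len(n_subjects)) {
    u <- rnorm(1, 0, sd_subject)
    ri <- runif(n_blocks, 0.8, 1.8)
    se <- runif(n_blocks)
    bv <- runif(n_blocks, 0.1, 2)
    g <- expand.grid(block = seq_len(n_blocks), time = tt)
    g$ri <- ri[g$block]; g$se <- se[g$block]; g$bv <- bv[g$block]
    g$activity <- u + b_ri * g$ri * g$time + b_se * g$se * g$time +
      b_bv * g$bv * g$time + rnorm(nrow(g), 0, sd_noise)
    g$subject <- sprintf("s%02d", s)
    rows[[s]] <- g
  }
  do.call(rbind, rows)
}
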