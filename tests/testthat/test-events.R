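test_that("event logs parse, validate codes, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.50,rNP", "2.00,ME", "5.00,MX"), f)
  es <- read_events(f)
  expect_s3_class(es, "event_stream")
  expect_equal(nrow(es$events), 3)
  expect_equal(es$session_duration, 5)

  writeLines(c("0.50,rNP", "2.00,XYZ"), f)
  expect_error(read_events(f), "unknown event code 'XYZ' in row 2")

  writeLines(character(), f)
  expect_error(read_events(f), "empty")

  set.seed(11)
  ev <- random_stream_events(1000)
  es <- event_stream(ev$times, ev$kinds, session_duration = 310)
  write_events(es, f)
  back <- read_events(f)
  expect_equal(back$events$time, es$events$time)
  expect_equal(back$events$kind, es$events$kind)
  expect_equal(back$session_duration, es$session_duration)
})

test_that("declared session duration is honored but never below the last event", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# session_duration_s=100", "time_s,event", "1.00,rNP",
               "2.00,ME"), f)
  expect_equal(read_events(f)$session_duration, 100)
  writeLines(c("# session_duration_s=1.5", "time_s,event", "1.00,rNP",
               "2.00,ME"), f)
  expect_equal(read_events(f)$session_duration, 2)
})

test_that("event streams reject off-grid times and bad codes", {
  expect_error(event_stream(c(0, 0.005), c("rNP", "ME")), "resolution grid")
  expect_error(event_stream(0.5, "poke"), "unknown event code")
  expect_silent(event_stream(c(0, 0.005), c("rNP", "ME"),
                             resolution = 0.005))
})

test_that("block segmentation matches hand-traced examples", {
  es <- event_stream(c(0, 2, 5, 8), c("rNP", "ME", "MX", "rNP"))
  b <- segment_blocks(es)
  expect_equal(b$block_type, c("rNP-ME", "ME-MX", "MX-rNP"))
  expect_equal(b$t_start, c(0, 2, 5))
  expect_equal(b$t_end, c(2, 5, 8))
  expect_true(all(b$is_cycle_block))

  b2 <- segment_blocks(event_stream(c(0, 1, 3), c("rNP", "rNP", "ME")))
  expect_equal(b2$block_type, c("rNP-rNP", "rNP-ME"))
  expect_equal(b2$is_cycle_block, c(FALSE, TRUE))

  # non-rewarded pokes are dropped before pairing
  b3 <- segment_blocks(event_stream(c(0, 1, 2), c("rNP", "nrNP", "ME")))
  expect_equal(b3$block_type, "rNP-ME")
  expect_equal(b3$t_end - b3$t_start, 2)
  expect_equal(attr(b3, "diagnostics")$dropped_nrnp, 1L)

  # fewer than two retained events
  b4 <- segment_blocks(event_stream(c(0, 1), c("rNP", "nrNP")))
  expect_equal(nrow(b4), 0)
})

test_that("segmentation agrees with the brute-force pairing oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:200, 1)
    ev <- random_stream_events(n)
    es <- event_stream(ev$times, ev$kinds, session_duration = 310)
    b <- segment_blocks(es)
    o <- oracle_blocks(ev$times, ev$kinds, 310)
    expect_equal(b$block_type, o$block_type)
    expect_equal(b$t_start, o$t_start)
    expect_equal(b$t_end, o$t_end)
    # conservation: rNP-ME count equals MEs directly preceded by rNP
    kd <- ev$kinds[ev$kinds != "nrNP"]
    expect_equal(sum(b$block_type == "rNP-ME"),
                 sum(kd[-1] == "ME" & kd[-length(kd)] == "rNP"))
    # BV is the exact reciprocal of duration
    expect_true(all(abs(b$bv * (b$t_end - b$t_start) - 1) < 1e-12))
    # cycles against the oracle
    cy <- segment_cycles(b)
    oc <- oracle_cycles(o)
    expect_equal(cy$duration, oc$duration)
    expect_equal(cy$n_blocks, oc$n_blocks)
  }
})

test_that("cycles follow the reward-to-reward definition", {
  es <- event_stream(c(0, 2, 5, 8, 9), c("rNP", "ME", "MX", "rNP", "ME"))
  cy <- segment_cycles(segment_blocks(es))
  expect_equal(nrow(cy), 1)
  expect_equal(cy$duration, 7)   # ME completion (2 s) to ME completion (9 s)
  expect_equal(cy$n_blocks, 3)

  # a magazine re-entry inflates the block count via non-cycle blocks
  es2 <- event_stream(c(0, 1, 2, 3, 4, 5, 6),
                      c("rNP", "ME", "MX", "ME", "MX", "rNP", "ME"))
  cy2 <- segment_cycles(segment_blocks(es2))
  expect_equal(cy2$n_blocks, 5)
  expect_equal(cy2$duration, 5)

  # a single rNP-ME block encloses nothing
  es3 <- event_stream(c(0, 2), c("rNP", "ME"))
  expect_equal(nrow(segment_cycles(segment_blocks(es3))), 0)

  # nose-poke anchoring is one switch away
  cy_rnp <- segment_cycles(segment_blocks(es), anchor = "rNP")
  expect_equal(cy_rnp$duration, 8)  # rNP (0 s) to rNP (8 s)
})

test_that("every block belongs to at most one cycle and cycles tile the session", {
  set.seed(31)
  for (rep in 1:20) {
    ev <- random_stream_events(150)
    es <- event_stream(ev$times, ev$kinds, session_duration = 310)
    b <- segment_blocks(es)
    cy <- segment_cycles(b)
    if (!nrow(cy)) next
    cid <- assign_block_cycles(b, cy)
    members <- attr(cy, "members")
    expect_equal(sort(unlist(members)), unique(sort(unlist(members))))
    # cycles abut with no gap or overlap
    if (nrow(cy) > 1) {
      expect_equal(cy$t_start[-1], cy$t_end[-nrow(cy)])
    }
    # membership round-trips through the per-block assignment
    for (k in seq_along(members)) {
      expect_true(all(cid[members[[k]]] == k))
    }
  }
})

test_that("choice proportions and blocks-per-cycle match direct counting", {
  # degenerate composition
  es <- event_stream(c(0, 1, 4, 5, 8, 9), rep(c("rNP", "ME"), 3))
  cp <- choice_proportions(segment_blocks(es), n_bins = 5)
  expect_true(all(cp$p_rnp_me[cp$n_rnp > 0] == 1))

  # 2 rNP-ME + 2 rNP-rNP in one bin -> 0.5
  blocks <- data.frame(
    block_type = c("rNP-ME", "rNP-ME", "rNP-rNP", "rNP-rNP"),
    t_start = c(1, 2, 3, 4), t_end = c(1.5, 2.5, 3.5, 4.5),
    duration = 0.5, se = c(0.01, 0.02, 0.03, 0.04), bv = 2,
    is_cycle_block = c(TRUE, TRUE, FALSE, FALSE))
  cp2 <- choice_proportions(blocks, n_bins = 10)
  expect_equal(cp2$p_rnp_me[1], 0.5)
  expect_true(all(is.na(cp2$p_mx_rnp)))

  # random blocks against direct per-bin counting
  set.seed(41)
  ev <- random_stream_events(500)
  es <- event_stream(ev$times, ev$kinds, session_duration = 310)
  b <- segment_blocks(es)
  cp3 <- choice_proportions(b, n_bins = 10)
  breaks <- seq(0, 1, length.out = 11)
  bin <- findInterval(b$se, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  for (k in 1:10) {
    r <- b$block_type %in% c("rNP-ME", "rNP-rNP") & bin == k
    if (any(r)) {
      expect_equal(cp3$p_rnp_me[k],
                   sum(b$block_type[r] == "rNP-ME") / sum(r))
    } else {
      expect_true(is.na(cp3$p_rnp_me[k]))
    }
  }

  cy <- segment_cycles(b)
  bc <- blocks_per_cycle_curve(cy, n_bins = 10)
  binc <- findInterval(cy$se, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  for (k in 1:10) {
    if (any(binc == k)) {
      expect_equal(bc$mean_n_blocks[k], mean(cy$n_blocks[binc == k]))
    } else {
      expect_true(is.na(bc$mean_n_blocks[k]))
    }
  }
})

test_that("tied timestamps drop the zero-duration block with a warning", {
  es <- event_stream(c(0, 1, 1, 2), c("rNP", "ME", "MX", "rNP"),
                     resolution = 0.01)
  expect_warning(b <- segment_blocks(es), "zero-duration")
  expect_false(any(b$t_end <= b$t_start))
  expect_equal(attr(b, "diagnostics")$dropped_zero_duration, 1L)
})
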