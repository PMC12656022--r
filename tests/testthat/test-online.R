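# Streaming detector, cue control, latency, packet codec.

test_that("decisions are emitted at the 256 + 32 i cadence", {
  m <- fixture_model()
  st <- stream_init(m)
  set.seed(2)
  samp <- matrix(rnorm(255 * 3, 0, 20), ncol = 3)
  st <- stream_step(st, samp)
  expect_equal(nrow(st$decisions), 0L)        # buffer not yet full
  st <- stream_step(st, matrix(rnorm(33 * 3, 0, 20), ncol = 3))
  expect_equal(st$decisions$sample_index, c(256L, 288L))
  st <- stream_step(st, matrix(rnorm(64 * 3, 0, 20), ncol = 3))
  expect_equal(st$decisions$sample_index, c(256L, 288L, 320L, 352L))
})

test_that("streaming decisions equal the batch pipeline under the causal filter", {
  rec <- memo("stream_rec", function() {
    r <- simulate_subject(sim_spec(duration_s = 60, fog_episodes = 1,
                                   fog_dur_range = c(6, 12), margin_s = 0,
                                   stand_fraction = 0, seed = 7))
    r$annotation[] <- 1L     # keep every window in the batch path
    r
  })
  m <- fixture_model()
  batch <- make_batch(rec, zero_phase = FALSE)
  pb <- predict(m, batch_features(batch))
  d <- replay_stream(rec, m, chunk = 50L)     # chunking must not matter
  expect_equal(nrow(d), nrow(batch$windows))
  expect_equal(d$sample_index, batch$start_index + 256L)
  expect_identical(d$label, pb$label)
  expect_identical(d$score, pb$score)         # exact equivalence
})

test_that("cue pattern is a duty-cycled square wave of the stated rate", {
  p <- cue_pattern(1, 0.5)
  expect_true(cue_state(p, 0.25))
  expect_false(cue_state(p, 0.75))
  # numeric-integration oracle for the on-fraction
  p2 <- cue_pattern(2, 0.25)
  tt <- seq(0, 10, by = 0.001); tt <- tt[tt < 10]
  expect_lt(abs(mean(cue_state(p2, tt)) - 0.25), 0.01)
  # long-horizon convergence to duty for other settings
  p3 <- cue_pattern(1.5, 0.7)
  expect_lt(abs(mean(cue_state(p3, tt)) - 0.7), 0.01)
  expect_error(cue_pattern(0, 0.5), "positive")
  expect_error(cue_pattern(1, 1.2), "duty")
})

test_that("cue hysteresis holds through short negative runs", {
  m <- fixture_model()
  st <- stream_init(m, cue_off_after = 2L)
  st$cue_active <- FALSE
  # drive the decision bookkeeping directly through its update rule
  push <- function(st, lab) {
    if (lab == 1L) { st$cue_active <- TRUE; st$neg_streak <- 0L }
    else {
      st$neg_streak <- st$neg_streak + 1L
      if (st$neg_streak >= st$cue_off_after) st$cue_active <- FALSE
    }
    st
  }
  st <- push(st, 1L); expect_true(st$cue_active)
  st <- push(st, 0L); expect_true(st$cue_active)   # one negative: hold
  st <- push(st, 0L); expect_false(st$cue_active)  # second: release
})

test_that("detection latency follows window geometry for a perfect classifier", {
  # onset at a step boundary; decisions follow the majority-label rule:
  # the earliest FoG-majority window starts at onset - 128 and its decision
  # fires 256 samples later, so latency <= 2 s + one 0.5 s step
  onset <- 64 * 20                       # sample 1280
  idx <- seq(256L, 64 * 40, by = 32L)
  starts <- idx - 256L
  labels <- as.integer(starts + 128L >= onset & starts < onset + 64 * 10)
  dec <- data.frame(sample_index = idx, label = labels)
  lat <- detection_latency(onset, dec)
  expect_false(lat$missed)
  expect_lte(lat$latency_s, 0.5 * 4 + 0.5)
  # an onset with no subsequent positive decision is flagged missed
  lat2 <- detection_latency(c(onset, 64 * 39),
                            data.frame(sample_index = idx,
                                       label = labels * (idx < 64 * 35)))
  expect_false(lat2$missed[1])
  expect_true(lat2$missed[2])
  # decisions only after the second of two onsets
  lat3 <- detection_latency(c(100L, 2000L),
                            data.frame(sample_index = idx,
                                       label = as.integer(idx >= 2100)))
  expect_equal(lat3$missed, c(FALSE, FALSE))
  expect_gt(lat3$latency_s[1], lat3$latency_s[2])
})

test_that("packet codec round-trips and rejects corrupt frames", {
  p <- fog_packet(12345L, matrix(c(10, -20, 980, 11, -21, 981), 2, 3,
                                 byrow = TRUE), TRUE, "to_host")
  expect_identical(decode_packet(encode_packet(p)), p)
  pd <- fog_packet(999L, direction = "to_device", decision = 1L)
  expect_identical(decode_packet(encode_packet(pd)), pd)
  line <- encode_packet(p)
  expect_error(decode_packet(substr(line, 1, nchar(line) - 4)), "checksum")
  expect_error(decode_packet("FOG,H,1,0"), "truncated")
  expect_error(decode_packet(sub("^FOG", "XXX", line)), "magic")
  # seeded fuzz: 1000 random packets round-trip exactly
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(0:32, 1)
    pk <- fog_packet(sample.int(1e6, 1),
                     matrix(sample(-32768:32767, n * 3, replace = TRUE),
                            n, 3),
                     sample(c(TRUE, FALSE), 1),
                     sample(c("to_host", "to_device"), 1),
                     decision = if (stats::runif(1) < 0.5) NULL
                                else sample(0:1, 1))
    expect_identical(decode_packet(encode_packet(pk)), pk)
  }
})
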