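test_that("event count, spacing and alternation follow the presentation rate", {
  spec <- sequence_spec(duration = 3.96, delta_t = 0)
  tl <- build_sequence(spec)
  expect_equal(nrow(tl), 23)             # floor(3.96 * 5.89)
  expect_equal(diff(tl$onset), rep(1 / 5.89, 22), tolerance = 1e-12)
  expect_true(all(tl$label == rep(c("A", "B"), length.out = 23)))
  expect_true(all(tl$onset + tl$duration <= attr(tl, "total_duration") + 1e-12))

  # property: count = floor(duration * rate), alternation, for varied specs
  set.seed(11)
  for (i in 1:20) {
    rate <- runif(1, 2, 15)
    dur <- runif(1, 0.5, 6)
    tl2 <- build_sequence(sequence_spec(presentation_rate = rate,
                                        duration = dur, delta_t = 0))
    expect_equal(nrow(tl2), floor(dur * rate + 1e-9))
    labs <- tl2$label
    expect_true(all(labs[-1] != labs[-length(labs)]))
    expect_true(all(diff(tl2$onset) > 0))
  }
})

test_that("a two-IOI sequence holds exactly the minimal A,B pair", {
  tl <- build_sequence(sequence_spec(duration = 2 / 5.89, delta_t = 0))
  expect_equal(nrow(tl), 2)
  expect_equal(tl$label, c("A", "B"))
})

test_that("canonical durations are 1.24 and 3.96 s and the short holds 7 events", {
  d <- canonical_durations()
  expect_equal(unname(d), c(1.24, 3.96))
  expect_lt(d[["short"]], d[["long"]])
  tl <- build_sequence(sequence_spec(duration = d[["short"]], delta_t = 0))
  expect_equal(nrow(tl), 7)              # floor(1.24 * 5.89)
})

test_that("the delay policy shifts only the selected B events by delta_t", {
  base <- build_sequence(sequence_spec(duration = 3.96, delta_t = 0))
  lastb <- build_sequence(sequence_spec(duration = 3.96, delta_t = 0.0485,
                                        delayed_event_policy = "last_b"))
  b_idx <- which(base$label == "B")
  last_b <- b_idx[length(b_idx)]
  expect_equal(lastb$onset[last_b], base$onset[last_b] + 0.0485)
  expect_equal(lastb$onset[-last_b], base$onset[-last_b])

  allb <- build_sequence(sequence_spec(duration = 3.96, delta_t = 0.02,
                                       delayed_event_policy = "all_b"))
  expect_equal(allb$onset[b_idx], base$onset[b_idx] + 0.02)
  expect_equal(allb$onset[-b_idx], base$onset[-b_idx])

  second_b <- build_sequence(sequence_spec(duration = 3.96, delta_t = 0.02,
                                           delayed_event_policy = 2L))
  expect_equal(second_b$onset[b_idx[2]], base$onset[b_idx[2]] + 0.02)
  expect_equal(second_b$onset[-b_idx[2]], base$onset[-b_idx[2]])
})

test_that("delays that collide with the next sound are rejected", {
  expect_error(
    build_sequence(sequence_spec(duration = 3.96, delta_t = 0.1,
                                 delayed_event_policy = "all_b")),
    "collide")
  # the same delay on the final B only is fine (no following A sound)
  expect_silent(build_sequence(sequence_spec(duration = 3.9, delta_t = 0.05,
                                             delayed_event_policy = "last_b")))
})

test_that("invalid sequence specifications are rejected", {
  expect_error(sequence_spec(presentation_rate = -1), "presentation_rate")
  expect_error(sequence_spec(duration = 0), "duration")
  expect_error(sequence_spec(delta_pitch = -5), "delta_pitch")
  expect_error(sequence_spec(delta_t = -0.1), "delta_t")
  expect_error(sequence_spec(tone_duration = 0.2), "tone_duration")
})

test_that("timelines round-trip through CSV", {
  tl <- build_sequence(sequence_spec(duration = 1.24))
  path <- tempfile(fileext = ".csv")
  write_timeline(tl, path)
  tl2 <- read_timeline(path, total_duration = attr(tl, "total_duration"))
  expect_equal(tl2$onset, tl$onset)
  expect_equal(tl2$duration, tl$duration)
  expect_equal(tl2$label, tl$label)
  expect_equal(attr(tl2, "total_duration"), attr(tl, "total_duration"))
})
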