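test_that("adaptation profile matches its closed form", {
  expect_equal(adaptation_profile(0, init = 1, asym = 0.85, tau = 0.5), 1)
  expect_equal(adaptation_profile(100, init = 1, asym = 0.85, tau = 0.5),
               0.85, tolerance = 1e-12)
  expect_equal(adaptation_profile(0.5, init = 1, asym = 0, tau = 0.5),
               exp(-1))
  t <- seq(0, 3, by = 0.05)
  decay <- adaptation_profile(t, 1, 0.85, 0.5)
  expect_true(all(diff(decay) < 0))
  growth <- adaptation_profile(t, 1, 1.5, 0.5)
  expect_true(all(diff(growth) > 0))
  expect_error(adaptation_profile(-0.1, 1, 0, 0.5), "negative")
  expect_error(adaptation_profile(1, 1, 0, 0), "tau")
})

test_that("the weighting function matches Q(t) L exp(-R(t) dpitch / sigma)", {
  p <- input_stage_params(L = 0.6, sigma = 40, q_init = 1)
  expect_equal(weight(0, 0, p), 0.6)
  # Q = R = 1: distance sigma gives L / e
  p1 <- input_stage_params(L = 0.6, sigma = 40, q_init = 1, q_asym = 1,
                           r_init = 1, r_asym = 1)
  expect_equal(weight(40, 1.3, p1), 0.6 * exp(-1))
  # strictly decreasing in delta_pitch at fixed time
  dps <- seq(0, 120, by = 5)
  expect_true(all(diff(weight(dps, 0.7, p)) < 0))
})

test_that("the weighting function is linear in L", {
  set.seed(21)
  for (i in 1:10) {
    dp <- runif(1, 0, 100); tt <- runif(1, 0, 4); L <- runif(1, 0.1, 1)
    w1 <- weight(dp, tt, input_stage_params(L = L))
    w2 <- weight(dp, tt, input_stage_params(L = 2 * L))
    expect_equal(w2, 2 * w1, tolerance = 1e-12)
  }
  # the CI fit (L = 0.35) scales the NH reference (L = 0.6) by 0.35/0.6
  w06 <- weight(50, 1, input_stage_params(L = 0.6))
  w035 <- weight(50, 1, input_stage_params(L = 0.35))
  expect_equal(w035 / w06, 0.35 / 0.6, tolerance = 1e-12)
})

test_that("input adaptation makes the weight non-increasing in time", {
  # r grows from r_init to r_asym > r_init, so at dpitch > 0 the weight decays
  p <- input_stage_params()
  t <- seq(0, 3.96, by = 0.01)
  for (dp in c(10, 50, 100)) {
    w <- weight(dp, t, p)
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("zero pitch difference drives all three units identically", {
  cur <- quick_currents(delta_pitch = 0)
  expect_equal(cur$I[, "A"], cur$I[, "B"])
  expect_equal(cur$I[, "A"], cur$I[, "AB"])
})

test_that("an infinite pitch difference silences the cross pathways only", {
  near <- quick_currents(delta_pitch = 0)
  far <- quick_currents(delta_pitch = 1e9)
  expect_lt(max(far$I[, "AB"]), 1e-12)
  # direct drive during own events is unaffected by the pitch difference:
  # the pointwise max over A and B channels isolates own-event drive
  expect_equal(pmax(far$I[, "A"], far$I[, "B"]),
               pmax(near$I[, "A"], near$I[, "B"]) , tolerance = 1e-12)
})

test_that("peak currents for a single sound follow the weighting function", {
  # freeze Q = R = 1 so peaks are exactly L and L exp(-dp / (2 sigma))
  p <- input_stage_params(L = 0.6, sigma = 40, q_init = 1, q_asym = 1,
                          r_init = 1, r_asym = 1)
  tl <- build_sequence(sequence_spec(duration = 2 / 5.89, delta_t = 0))
  cur <- build_input_currents(tl, 50, p, dt = 0.001)
  expect_equal(max(cur$I[, "A"]), 0.6, tolerance = 1e-9)
  expect_equal(max(cur$I[, "AB"]), 0.6 * exp(-50 / 80), tolerance = 1e-9)
})

test_that("the AB current never exceeds the sum of the direct currents", {
  for (dp in c(0, 12.5, 50, 100)) {
    cur <- quick_currents(delta_pitch = dp)
    expect_true(all(cur$I[, "AB"] <= cur$I[, "A"] + cur$I[, "B"] + 1e-12))
  }
})

test_that("currents vanish between sound envelopes", {
  cur <- quick_currents(delta_pitch = 50)
  tl <- cur$timeline
  gap <- cur$t > tl$onset[1] + tl$duration[1] + 1e-9 &
    cur$t < tl$onset[2] - 1e-9
  expect_true(any(gap))
  expect_true(all(cur$I[gap, ] == 0))
})

test_that("too coarse a sampling step is rejected", {
  tl <- build_sequence(quick_spec())
  expect_error(build_input_currents(tl, 50, dt = 0.05), "dt too coarse")
})
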