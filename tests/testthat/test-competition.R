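test_that("identical seeds reproduce trajectories bit for bit", {
  cur <- quick_currents()
  a <- simulate_trial(cur, seed = 7)
  b <- simulate_trial(cur, seed = 7)
  expect_identical(a$trajectory$u, b$trajectory$u)
  expect_identical(a$trajectory$n, b$trajectory$n)
  expect_identical(a$percept$segregated, b$percept$segregated)
  d <- simulate_trial(cur, seed = 8)
  expect_false(identical(a$trajectory$u, d$trajectory$u))
})

test_that("identical noise-free inputs keep the three units identical", {
  cur <- quick_currents(delta_pitch = 0)
  p <- competition_params(gamma = 0)
  tr <- simulate_trial(cur, p, seed = 1)$trajectory
  expect_equal(tr$u[, "A"], tr$u[, "B"], tolerance = 1e-14)
  expect_equal(tr$u[, "A"], tr$u[, "AB"], tolerance = 1e-14)
})

test_that("a dominant constant AB drive settles into integration", {
  p <- competition_params(gamma = 0)
  cur <- constant_currents(0.1, 0.1, 0.8, duration = 6, dt = p$dt)
  out <- simulate_trial(cur, p, seed = 1)
  n <- length(cur$t)
  uf <- out$trajectory$u[n, ]
  expect_gt(uf["AB"], max(uf["A"], uf["B"]))
  # after the transient the percept stays integrated
  late <- out$percept$segregated[cur$t > 3]
  expect_true(all(late == 0))
  # the noise-free fixed point matches a fine-dt reference integration
  pf <- competition_params(gamma = 0, dt = p$dt / 10)
  curf <- constant_currents(0.1, 0.1, 0.8, duration = 6, dt = pf$dt)
  uff <- simulate_trial(curf, pf, seed = 1)$trajectory$u[length(curf$t), ]
  expect_equal(unname(uf), unname(uff), tolerance = 1e-5)
})

test_that("swapping the A and B inputs and noise streams swaps the units exactly", {
  cur <- quick_currents(delta_pitch = 60)
  swapped <- cur
  swapped$I <- cur$I[, c("B", "A", "AB")]
  colnames(swapped$I) <- c("A", "B", "AB")
  us <- c(101, 202, 303)
  a <- simulate_trial(cur, seed = 1, unit_seeds = us)$trajectory
  b <- simulate_trial(swapped, seed = 1,
                      unit_seeds = us[c(2, 1, 3)])$trajectory
  expect_identical(a$u[, "A"], b$u[, "B"])
  expect_identical(a$u[, "B"], b$u[, "A"])
  expect_identical(a$u[, "AB"], b$u[, "AB"])
})

test_that("noise-free integration converges: halving dt barely moves u", {
  p1 <- competition_params(gamma = 0, dt = 0.001)
  p2 <- competition_params(gamma = 0, dt = 0.0005)
  tl <- build_sequence(sequence_spec(duration = 1.24, delta_pitch = 50))
  c1 <- build_input_currents(tl, 50, dt = p1$dt)
  c2 <- build_input_currents(tl, 50, dt = p2$dt)
  u1 <- simulate_trial(c1, p1, seed = 1)$trajectory$u
  u2 <- simulate_trial(c2, p2, seed = 1)$trajectory$u
  sub <- u2[seq(1, nrow(u2), by = 2), ]
  expect_equal(nrow(sub), nrow(u1))
  expect_lt(max(abs(u1 - sub)), 1e-3)
})

test_that("activities stay inside the sigmoidal range [0, 1]", {
  cur <- quick_currents(delta_pitch = 100)
  for (seed in 1:3) {
    u <- simulate_trial(cur, seed = seed)$trajectory$u
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("the percept readout applies the strict AB-dominance rule", {
  t <- c(0, 0.001, 0.002)
  u <- rbind(c(0.3, 0.2, 0.8),    # AB max -> integrated
             c(0.8, 0.1, 0.3),    # A max -> segregated
             c(0.5, 0.2, 0.5))    # exact tie -> segregated
  traj <- structure(list(t = t,
                         u = `colnames<-`(u, c("A", "B", "AB")),
                         a = u * 0, n = u * 0),
                    class = "network_trajectory")
  expect_equal(readout(traj)$segregated, c(0L, 1L, 1L))
})

test_that("the OU noise reaches its stationary standard deviation", {
  p <- competition_params(gamma = 0.2)
  cur <- constant_currents(0, 0, 0, duration = 60, dt = p$dt)
  nz <- simulate_trial(cur, p, seed = 3)$trajectory$n
  expect_equal(sd(nz[, "A"]), 0.2, tolerance = 0.15)
  # ~ 60 s / (2 tau_n) effective draws -> s.e. of the mean ~ 0.012
  expect_equal(mean(nz[, "A"]), 0, tolerance = 0.05)
  # independent streams across units
  expect_lt(abs(cor(nz[, "A"], nz[, "B"])), 0.1)
})

test_that("mismatched integration steps are rejected", {
  cur <- quick_currents(dt = 0.002)
  expect_error(simulate_percepts(cur, competition_params(dt = 0.001)),
               "share dt")
})

test_that("long ambiguous trials show spontaneous percept switching", {
  cur <- quick_currents(delta_pitch = 50, duration = 3.96)
  P <- simulate_percepts(cur, n_trials = 60, master_seed = 5)
  both <- mean(apply(P, 2, function(x) any(x == 0) && any(x == 1)))
  expect_gt(both, 0.05)
})
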