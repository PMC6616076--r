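fake_truth <- function() {
  # hand-made condition table in the prediction schema (no simulation)
  grid <- expand.grid(delta_pitch = c(0, 25, 50, 100),
                      duration = c(1.24, 3.96), KEEP.OUT.ATTRS = FALSE)
  grid$dprime <- 0.2 + 0.015 * grid$delta_pitch + 0.2 * (grid$duration > 2)
  grid
}

test_that("zero listener noise reproduces the condition truth exactly", {
  spec <- synthetic_study_spec(n_listeners = 5, listener_sd = 0, seed = 3)
  ds <- generate_dataset(spec, truth = fake_truth())
  expect_true(all(abs(ds$per_listener$dprime -
                        rep(fake_truth()$dprime, 5)) < 1e-12))
  expect_equal(ds$behavioral$dprime_mean, fake_truth()$dprime,
               tolerance = 1e-12)
  expect_true(all(ds$behavioral$dprime_sd == 0))
})

test_that("datasets are reproducible under a fixed seed", {
  spec <- synthetic_study_spec(n_listeners = 4, listener_sd = 0.3, seed = 8)
  d1 <- generate_dataset(spec, truth = fake_truth())
  d2 <- generate_dataset(spec, truth = fake_truth())
  expect_identical(d1$per_listener$dprime, d2$per_listener$dprime)
  d3 <- generate_dataset(synthetic_study_spec(n_listeners = 4,
                                              listener_sd = 0.3, seed = 9),
                         truth = fake_truth())
  expect_false(identical(d1$per_listener$dprime, d3$per_listener$dprime))
})

test_that("listener noise has the declared standard-error structure", {
  # mean over 8 listeners deviates from truth with s.e. ~ sd / sqrt(8)
  truth <- fake_truth()
  truth$dprime <- truth$dprime + 2      # keep far from the zero floor
  devs <- sapply(1:400, function(r) {
    spec <- synthetic_study_spec(n_listeners = 8, listener_sd = 0.3,
                                 seed = 1000 + r)
    ds <- generate_dataset(spec, truth = truth)
    ds$behavioral$dprime_mean[1] - truth$dprime[1]
  })
  expect_equal(sd(devs), 0.3 / sqrt(8), tolerance = 0.15)
  expect_equal(mean(devs), 0, tolerance = 0.02)
})

test_that("the zero floor censors negative listener scores", {
  truth <- fake_truth()
  truth$dprime <- 0 * truth$dprime      # truth at the floor
  spec <- synthetic_study_spec(n_listeners = 50, listener_sd = 0.5, seed = 2)
  ds <- generate_dataset(spec, truth = truth)
  expect_true(all(ds$per_listener$dprime >= 0))
  expect_true(any(ds$per_listener$dprime > 0))
  spec2 <- synthetic_study_spec(n_listeners = 50, listener_sd = 0.5,
                                seed = 2, floor_at_zero = FALSE)
  ds2 <- generate_dataset(spec2, truth = truth)
  expect_true(any(ds2$per_listener$dprime < 0))
})

test_that("generated tables are written in the fitting schema", {
  spec <- synthetic_study_spec(n_listeners = 3, listener_sd = 0.2, seed = 4)
  ds <- generate_dataset(spec, truth = fake_truth())
  prefix <- file.path(tempdir(), "synthdata")
  write_dataset(ds, spec, prefix)
  tab <- read_behavioral_table(paste0(prefix, "_means.csv"))
  expect_s3_class(tab, "behavioral_table")
  expect_equal(nrow(tab), nrow(fake_truth()))
  spec_back <- jsonlite::read_json(paste0(prefix, "_spec.json"))
  expect_equal(spec_back$true_sigma, 30)
  expect_equal(spec_back$true_L, 0.35)
})

test_that("model-generated mean scores rise with pitch difference and duration", {
  spec <- synthetic_study_spec(n_listeners = 6, listener_sd = 0.1,
                               delta_pitch_grid = c(0, 50, 100),
                               n_trials = 150, seed = 6)
  ds <- generate_dataset(spec, stream_model_config())
  m <- ds$behavioral
  for (d in unique(m$duration)) {
    sub <- m[m$duration == d, ]
    sub <- sub[order(sub$delta_pitch), ]
    expect_gt(sub$dprime_mean[3], sub$dprime_mean[1])
  }
  long <- m$dprime_mean[m$duration > 2 & m$delta_pitch == 50]
  short <- m$dprime_mean[m$duration < 2 & m$delta_pitch == 50]
  expect_gt(long, short - 0.2)
})
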