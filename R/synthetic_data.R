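#' Specification of a synthetic behavioral study
#'
#' Describes a simulated cohort of cochlear-implant listeners performing the
#' delay-detection task over a grid of pitch differences and the two
#' canonical sequence durations. Condition-level true d-prime scores are
#' model predictions at the generating parameters (`true_sigma`, `true_L`);
#' per-listener scores add independent Gaussian noise on the d-prime scale.
#'
#' @param n_listeners Number of simulated listeners (default 8, spanning the
#'   7- and 9-listener cohorts of the source studies).
#' @param delta_pitch_grid Pitch-difference conditions in percent (default
#'   `c(0, 12.5, 25, 50, 75, 100)`).
#' @param durations Sequence durations in seconds (default the canonical
#'   1.24 and 3.96).
#' @param delta_t Delay of the B sounds in seconds (default 0.0485).
#' @param true_sigma,true_L Generating weighting-function parameters
#'   (defaults 30 and 0.35, the cochlear-implant fit).
#' @param listener_sd Standard deviation of the additive listener noise on
#'   the d-prime scale (default 0.3).
#' @param floor_at_zero Floor per-listener d-prime values at 0 (default
#'   TRUE; negative sensitivity is not meaningful in this task).
#' @param n_trials Simulated trials per condition for the true d-prime
#'   (default 1000).
#' @param seed Integer seed for both the simulations and the listener noise.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_listeners = 8,
                                 delta_pitch_grid = c(0, 12.5, 25, 50, 75, 100),
                                 durations = canonical_durations(),
                                 delta_t = 0.0485,
                                 true_sigma = 30, true_L = 0.35,
                                 listener_sd = 0.3,
                                 floor_at_zero = TRUE,
                                 n_trials = 1000,
                                 seed = 1) {
  if (n_listeners < 1) stop("n_listeners must be >= 1")
  if (listener_sd < 0) stop("listener_sd must be >= 0")
  if (!length(delta_pitch_grid) || !length(durations))
    stop("condition grids must be non-empty")
  structure(list(n_listeners = as.integer(n_listeners),
                 delta_pitch_grid = delta_pitch_grid,
                 durations = unname(durations),
                 delta_t = delta_t,
                 true_sigma = true_sigma, true_L = true_L,
                 listener_sd = listener_sd,
                 floor_at_zero = floor_at_zero,
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a synthetic behavioral d-prime dataset
#'
#' Computes the condition-level true d-prime scores by running the full
#' model at the generating parameters, then draws per-listener scores as
#' truth plus Gaussian noise (floored at zero if requested). Returns both
#' the per-listener table and the condition-mean `behavioral_table` in the
#' fitting module's schema.
#'
#' @param spec A [synthetic_study_spec()].
#' @param config A [stream_model_config()]; its weighting parameters are
#'   overridden by `spec$true_sigma` / `spec$true_L`.
#' @param truth Optional precomputed `dprime_prediction` table for the
#'   spec's condition grid (skips the simulations; useful when generating
#'   many noise replicates from one set of model runs).
#' @return A list with elements `per_listener` (data frame: `listener`,
#'   `delta_pitch`, `duration`, `dprime`), `behavioral` (a
#'   `behavioral_table` of condition means), and `truth` (the noise-free
#'   condition table).
#' @export
generate_dataset <- function(spec = synthetic_study_spec(),
                             config = stream_model_config(),
                             truth = NULL) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  config <- set_weighting(config, sigma = spec$true_sigma, L = spec$true_L)
  config$delta_t <- spec$delta_t
  if (is.null(truth)) {
    truth <- predict_conditions(spec$delta_pitch_grid, spec$durations,
                                config = config, n_trials = spec$n_trials,
                                master_seed = spec$seed)
  }
  n_cond <- nrow(truth)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed + 777)
  per <- do.call(rbind, lapply(seq_len(spec$n_listeners), function(l) {
    d <- truth$dprime + rnorm(n_cond, 0, spec$listener_sd)
    if (spec$floor_at_zero) d <- pmax(d, 0)
    data.frame(listener = l, delta_pitch = truth$delta_pitch,
               duration = truth$duration, dprime = d)
  }))
  means <- aggregate(dprime ~ delta_pitch + duration, per, mean)
  sds <- aggregate(dprime ~ delta_pitch + duration, per, sd)
  behav <- data.frame(delta_pitch = means$delta_pitch,
                      duration = means$duration,
                      dprime_mean = means$dprime,
                      dprime_sd = sds$dprime,
                      n_listeners = spec$n_listeners)
  list(per_listener = per,
       behavioral = as_behavioral_table(behav),
       truth = truth)
}

#' Write a synthetic dataset (per-listener + condition means + spec)
#'
#' Writes `<prefix>_listeners.csv`, `<prefix>_means.csv` (fitting schema)
#' and `<prefix>_spec.json`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param spec The generating [synthetic_study_spec()].
#' @param prefix Output path prefix.
#' @export
write_dataset <- function(dataset, spec, prefix) {
  pl <- dataset$per_listener
  write.csv(data.frame(listener = pl$listener, delta_pitch = pl$delta_pitch,
                       duration_s = pl$duration, dprime = pl$dprime),
            paste0(prefix, "_listeners.csv"), row.names = FALSE, quote = FALSE)
  bh <- dataset$behavioral
  write.csv(data.frame(delta_pitch = bh$delta_pitch, duration_s = bh$duration,
                       dprime_mean = bh$dprime_mean, dprime_sd = bh$dprime_sd,
                       n_listeners = bh$n_listeners),
            paste0(prefix, "_means.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(spec), paste0(prefix, "_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic dataset at known weighting parameters, fits the
#' model to the condition means, and reports true vs. recovered values per
#' free parameter.
#'
#' @param spec A [synthetic_study_spec()].
#' @param fit_cfg A [fit_config()].
#' @param config A [stream_model_config()].
#' @return A list with `report` (data frame: `parameter`, `true`,
#'   `recovered`, `abs_error`, `rel_error`), `fit` (the `fit_result`) and
#'   `dataset`.
#' @export
recovery_experiment <- function(spec = synthetic_study_spec(listener_sd = 0),
                                fit_cfg = fit_config(free = c("sigma", "L")),
                                config = stream_model_config()) {
  dataset <- generate_dataset(spec, config)
  fit <- fit_weighting(dataset$behavioral, fit_cfg, config)
  truth <- c(sigma = spec$true_sigma, L = spec$true_L)
  rec <- c(sigma = fit$sigma_hat, L = fit$L_hat)
  pars <- fit_cfg$free
  report <- data.frame(parameter = pars,
                       true = unname(truth[pars]),
                       recovered = unname(rec[pars]))
  report$abs_error <- abs(report$recovered - report$true)
  report$rel_error <- report$abs_error / report$true
  list(report = report, fit = fit, dataset = dataset)
}
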