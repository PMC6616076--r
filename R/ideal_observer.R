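#' Ideal-observer configuration
#'
#' The ideal observer assumes a 100% hit rate on segregated trials and
#' chance-level performance on integrated trials: with proportion `p` of
#' segregated trials, the hit rate is `H = p + (1 - p) * chance_rate` and
#' the false-alarm rate is `chance_rate`. Both rates are clipped away from
#' 0 and 1 before the normal-quantile transform (the usual extreme-rate
#' correction), giving `d' = qnorm(H) - qnorm(F)`.
#'
#' @param chance_rate Chance performance level (default 0.5, yes/no task).
#' @param rate_clip Clipping bound for the rates; `NULL` (default) uses
#'   `1 / (2 * n_trials)` at evaluation time.
#' @return An object of class `io_config`.
#' @export
io_config <- function(chance_rate = 0.5, rate_clip = NULL) {
  if (chance_rate <= 0 || chance_rate >= 1)
    stop("chance_rate must lie in (0, 1)")
  if (!is.null(rate_clip) && (rate_clip <= 0 || rate_clip >= 0.5))
    stop("rate_clip must lie in (0, 0.5)")
  structure(list(chance_rate = chance_rate, rate_clip = rate_clip),
            class = "io_config")
}

#' Convert a proportion of segregated trials into a d-prime score
#'
#' @param p Proportion of segregated trials in `[0, 1]` (vectorized).
#' @param n_trials Number of trials behind `p` (sets the default rate clip
#'   `1 / (2 * n_trials)`).
#' @param cfg An [io_config()].
#' @return d-prime value(s); 0 at `p = 0`, monotone non-decreasing in `p`,
#'   bounded by the clipped ceiling.
#' @examples
#' dprime_from_proportion(0.5, 1000)  # qnorm(0.75) ~ 0.674
#' @export
dprime_from_proportion <- function(p, n_trials, cfg = io_config()) {
  stopifnot(inherits(cfg, "io_config"), n_trials >= 1)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  clip <- if (is.null(cfg$rate_clip)) 1 / (2 * n_trials) else cfg$rate_clip
  H <- p + (1 - p) * cfg$chance_rate
  FA <- rep(cfg$chance_rate, length(H))
  H <- pmin(pmax(H, clip), 1 - clip)
  FA <- pmin(pmax(FA, clip), 1 - clip)
  qnorm(H) - qnorm(FA)
}

#' Predict the d-prime score for one stimulus condition
#'
#' Runs the full pipeline for a condition: builds the event timeline,
#' converts it into input currents, simulates `n_trials` competition-network
#' trials, classifies each trial as segregated/integrated by majority vote
#' within the decision window around the delayed sound(s), and converts the
#' segregated fraction into a d-prime score through the ideal observer.
#'
#' @param delta_pitch Pitch difference between A and B sounds (percent).
#' @param duration Sequence duration, seconds.
#' @param delta_t Delay of the selected B sounds, seconds; `NULL` uses the
#'   config value.
#' @param config A [stream_model_config()].
#' @param n_trials Number of simulated trials (default 1000).
#' @param master_seed Integer master seed; the same seed reproduces the
#'   prediction exactly.
#' @param window Optional decision window (seconds); default
#'   [decision_window()] of the condition's timeline.
#' @return A one-row data frame of class `dprime_prediction` with columns
#'   `delta_pitch`, `duration`, `delta_t`, `p_segregated`, `dprime`,
#'   `n_trials`, `seed`.
#' @export
predict_condition <- function(delta_pitch, duration, delta_t = NULL,
                              config = stream_model_config(),
                              n_trials = 1000, master_seed = 1,
                              window = NULL) {
  stopifnot(inherits(config, "stream_model_config"))
  if (is.null(delta_t)) delta_t <- config$delta_t
  spec <- sequence_spec(presentation_rate = config$presentation_rate,
                        duration = duration,
                        delta_pitch = delta_pitch,
                        delta_t = delta_t,
                        tone_duration = config$tone_duration,
                        delayed_event_policy = config$delayed_event_policy)
  tl <- build_sequence(spec)
  cur <- build_input_currents(tl, delta_pitch, config$input,
                              dt = config$competition$dt,
                              ramp_duration = config$ramp_duration)
  if (is.null(window)) window <- decision_window(tl)
  cls <- classify_trials(cur, config$competition, n_trials = n_trials,
                         master_seed = master_seed, window = window)
  p <- mean(cls)
  d <- dprime_from_proportion(p, n_trials, config$io)
  structure(data.frame(delta_pitch = delta_pitch, duration = duration,
                       delta_t = delta_t, p_segregated = p, dprime = d,
                       n_trials = n_trials, seed = master_seed),
            class = c("dprime_prediction", "data.frame"))
}

#' Predict d-prime scores over a grid of conditions
#'
#' @param delta_pitch_grid Numeric vector of pitch differences (percent).
#' @param durations Numeric vector of sequence durations, seconds.
#' @inheritParams predict_condition
#' @param seed_stride Per-condition seeds are `master_seed + (i - 1) *
#'   seed_stride` over the condition grid, so each condition uses an
#'   independent but reproducible noise stream.
#' @return A `dprime_prediction` data frame, one row per condition.
#' @export
predict_conditions <- function(delta_pitch_grid,
                               durations = canonical_durations(),
                               config = stream_model_config(),
                               n_trials = 1000, master_seed = 1,
                               seed_stride = 10000) {
  grid <- expand.grid(delta_pitch = delta_pitch_grid, duration = durations,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    predict_condition(grid$delta_pitch[i], grid$duration[i],
                      config = config, n_trials = n_trials,
                      master_seed = master_seed + (i - 1) * seed_stride)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dprime_prediction", "data.frame")
  rownames(out) <- NULL
  out
}

#' Export d-prime predictions as CSV
#' @param pred A `dprime_prediction` data frame.
#' @param path File path.
#' @export
write_predictions <- function(pred, path) {
  out <- data.frame(delta_pitch = pred$delta_pitch,
                    duration_s = pred$duration,
                    delta_t_s = pred$delta_t,
                    p_segregated = pred$p_segregated,
                    dprime = pred$dprime,
                    n_trials = pred$n_trials,
                    seed = pred$seed)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
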