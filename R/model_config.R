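#' Full model configuration
#'
#' Bundles the stimulus conventions, input-stage parameters, competition
#' parameters and ideal-observer settings used by the prediction, fitting
#' and data-generation stages.
#'
#' @param presentation_rate Sound onsets per second (default 5.89).
#' @param delta_t Delay of the selected B sounds, seconds (default 0.0485).
#' @param delayed_event_policy Delay policy passed to [sequence_spec()].
#' @param tone_duration Tone duration in seconds (`NULL` = half the IOI).
#' @param ramp_duration Tone on/off ramp in seconds (default 0.005).
#' @param input An [input_stage_params()].
#' @param competition A [competition_params()].
#' @param io An [io_config()].
#' @return An object of class `stream_model_config`.
#' @export
stream_model_config <- function(presentation_rate = 5.89,
                                delta_t = 0.0485,
                                delayed_event_policy = "last_b",
                                tone_duration = NULL,
                                ramp_duration = 0.005,
                                input = input_stage_params(),
                                competition = competition_params(),
                                io = io_config()) {
  stopifnot(inherits(input, "input_stage_params"),
            inherits(competition, "competition_params"),
            inherits(io, "io_config"))
  if (presentation_rate <= 0) stop("presentation_rate must be > 0")
  if (delta_t < 0) stop("delta_t must be >= 0")
  if (ramp_duration < 0) stop("ramp_duration must be >= 0")
  structure(list(presentation_rate = presentation_rate,
                 delta_t = delta_t,
                 delayed_event_policy = delayed_event_policy,
                 tone_duration = tone_duration,
                 ramp_duration = ramp_duration,
                 input = input,
                 competition = competition,
                 io = io),
            class = "stream_model_config")
}

# replace weighting-function parameters inside a config (used by the fitter)
set_weighting <- function(config, sigma = NULL, L = NULL) {
  stopifnot(inherits(config, "stream_model_config"))
  inp <- config$input
  if (!is.null(sigma)) inp$sigma <- sigma
  if (!is.null(L)) inp$L <- L
  config$input <- do.call(input_stage_params, unclass(inp))
  config
}

#' @export
print.stream_model_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<stream_model_config> rate %.3g Hz, dt %.4g s\n",
    "  input: L = %.3g, sigma = %.3g, tau_ad = %.3g s\n",
    "  competition: beta_i = %.3g, alpha = %.3g, g = %.3g, gamma = %.3g\n"),
    x$presentation_rate, x$delta_t, x$input$L, x$input$sigma, x$input$tau_ad,
    x$competition$beta_i, x$competition$alpha, x$competition$g,
    x$competition$gamma))
  invisible(x)
}
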