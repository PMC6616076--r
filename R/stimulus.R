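#' Specify an alternating A/B sound sequence
#'
#' Describes the symbolic structure of a stimulus: a sequence of alternating
#' A and B sounds at a fixed presentation rate, with an optional temporal
#' delay `delta_t` imposed on selected B sounds (the manipulation detected by
#' listeners in the delay-detection task).
#'
#' @param presentation_rate Sound onsets per second, pooled over A and B
#'   (default 5.89 Hz). The inter-onset interval (IOI) is
#'   `1/presentation_rate`.
#' @param duration Sequence duration in seconds. The canonical short and long
#'   durations are returned by [canonical_durations()].
#' @param delta_pitch Perceptual pitch difference between the A and B sounds,
#'   in percent of the reference difference (an arbitrary linear scale where
#'   100 corresponds to the pitch difference between two widely separated
#'   electrodes).
#' @param delta_t Temporal delay applied to the selected B sounds, in seconds
#'   (default 0.0485, the median delay across listeners).
#' @param tone_duration Duration of each sound in seconds. Defaults to half
#'   the inter-onset interval.
#' @param delayed_event_policy Which B events receive the `delta_t` shift:
#'   `"last_b"` (default), `"all_b"`, `"none"`, or an integer vector of
#'   B-event ordinals (1 = first B sound).
#' @return An object of class `sequence_spec`.
#' @seealso [build_sequence()]
#' @export
sequence_spec <- function(presentation_rate = 5.89,
                          duration = 3.96,
                          delta_pitch = 50,
                          delta_t = 0.0485,
                          tone_duration = NULL,
                          delayed_event_policy = "last_b") {
  stopifnot(is.numeric(presentation_rate), length(presentation_rate) == 1,
            is.numeric(duration), length(duration) == 1,
            is.numeric(delta_pitch), length(delta_pitch) == 1,
            is.numeric(delta_t), length(delta_t) == 1)
  if (presentation_rate <= 0) stop("presentation_rate must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (delta_pitch < 0) stop("delta_pitch must be >= 0")
  if (delta_t < 0) stop("delta_t must be >= 0")
  ioi <- 1 / presentation_rate
  if (is.null(tone_duration)) tone_duration <- ioi / 2
  if (tone_duration <= 0 || tone_duration >= ioi)
    stop("tone_duration must lie in (0, inter-onset interval)")
  if (is.character(delayed_event_policy)) {
    delayed_event_policy <- match.arg(delayed_event_policy,
                                      c("last_b", "all_b", "none"))
  } else if (is.numeric(delayed_event_policy)) {
    delayed_event_policy <- as.integer(delayed_event_policy)
    if (any(delayed_event_policy < 1))
      stop("numeric delayed_event_policy must contain positive B ordinals")
  } else {
    stop("delayed_event_policy must be a keyword or integer vector")
  }
  structure(list(presentation_rate = presentation_rate,
                 duration = duration,
                 delta_pitch = delta_pitch,
                 delta_t = delta_t,
                 tone_duration = tone_duration,
                 delayed_event_policy = delayed_event_policy),
            class = "sequence_spec")
}

#' Canonical short and long sequence durations
#'
#' The two sequence durations used throughout the behavioral comparison:
#' 1.24 s (short) and 3.96 s (long).
#'
#' @return Named numeric vector `c(short = 1.24, long = 3.96)`.
#' @export
canonical_durations <- function() {
  c(short = 1.24, long = 3.96)
}

#' Build the event timeline for a sequence specification
#'
#' Lays out `floor(duration * presentation_rate)` sound onsets at the
#' inter-onset interval, alternating labels A, B, A, B, ... and applies the
#' `delta_t` shift to the B events selected by the spec's delay policy.
#'
#' @param spec A [sequence_spec()].
#' @return An `event_timeline`: a data frame with columns `onset`, `duration`
#'   and `label`, plus attributes `total_duration`, `ioi` and `spec`.
#' @examples
#' tl <- build_sequence(sequence_spec(duration = 1.24, delta_t = 0))
#' nrow(tl)  # floor(1.24 * 5.89) = 7 events
#' @export
build_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  ioi <- 1 / spec$presentation_rate
  n_events <- floor(spec$duration * spec$presentation_rate + 1e-9)
  if (n_events < 1)
    stop("duration too short: no complete event fits the sequence")
  onsets <- (seq_len(n_events) - 1) * ioi
  labels <- rep(c("A", "B"), length.out = n_events)
  b_idx <- which(labels == "B")
  delayed <- integer(0)
  pol <- spec$delayed_event_policy
  if (is.character(pol)) {
    delayed <- switch(pol,
                      none = integer(0),
                      all_b = b_idx,
                      last_b = if (length(b_idx)) b_idx[length(b_idx)] else integer(0))
  } else {
    if (any(pol > length(b_idx)))
      stop("delayed_event_policy refers to B events beyond the sequence")
    delayed <- b_idx[pol]
  }
  onsets[delayed] <- onsets[delayed] + spec$delta_t
  # a shifted B sound must not collide with or pass the following A sound
  for (i in delayed) {
    if (i < n_events && onsets[i] + spec$tone_duration > onsets[i + 1] + 1e-12)
      stop("delta_t shift makes a delayed B sound collide with the next A sound")
  }
  if (any(onsets + spec$tone_duration > spec$duration + 1e-12))
    stop("delta_t shift pushes an event past the sequence duration")
  tl <- data.frame(onset = onsets,
                   duration = rep(spec$tone_duration, n_events),
                   label = labels,
                   stringsAsFactors = FALSE)
  structure(tl,
            total_duration = spec$duration,
            ioi = ioi,
            delayed_events = delayed,
            spec = spec,
            class = c("event_timeline", "data.frame"))
}

#' Write / read an event timeline as CSV
#'
#' Columns `onset_s`, `duration_s`, `label`. `read_timeline()` restores the
#' `event_timeline` class; `total_duration` is taken from the data unless
#' given.
#'
#' @param timeline An `event_timeline`.
#' @param path File path.
#' @param total_duration Optional total duration for `read_timeline()`.
#' @return `read_timeline()` returns an `event_timeline`.
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "event_timeline"))
  out <- data.frame(onset_s = timeline$onset,
                    duration_s = timeline$duration,
                    label = timeline$label)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path, total_duration = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(d)))
    stop("timeline file must have columns onset_s, duration_s, label: ", path)
  if (is.null(total_duration))
    total_duration <- max(d$onset_s + d$duration_s)
  tl <- data.frame(onset = d$onset_s, duration = d$duration_s,
                   label = d$label, stringsAsFactors = FALSE)
  structure(tl,
            total_duration = total_duration,
            ioi = if (nrow(tl) > 1) diff(tl$onset[1:2]) else NA_real_,
            class = c("event_timeline", "data.frame"))
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf(
    "<sequence_spec> rate %.3g Hz, duration %.3g s, dpitch %.3g%%, dt %.4g s\n",
    x$presentation_rate, x$duration, x$delta_pitch, x$delta_t))
  invisible(x)
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline> %d events over %.3g s (IOI %.4g s)\n",
              nrow(x), attr(x, "total_duration"), attr(x, "ioi")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
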