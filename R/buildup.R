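#' Build-up function: time-binned proportion of segregation across trials
#'
#' Averages the binary segregated indicator over trials and over the time
#' samples falling in each bin, yielding the time course of the proportion
#' of segregation over `n_trials` simulated trials.
#'
#' @param traces Either a list of `percept_trace` objects sharing one time
#'   grid, or an integer matrix (time samples x trials) with attribute `t`
#'   as returned by [simulate_percepts()].
#' @param bin_width Bin width in seconds (default 0.1); must be at least the
#'   sampling step.
#' @param t_start Samples before this time are excluded (default 0); used to
#'   drop pre-stimulus samples when the first sound starts later than 0.
#' @return A `buildup_function`: data frame with columns `bin_center` and
#'   `proportion_segregated`, plus attributes `n_trials` and `bin_width`.
#' @export
buildup_function <- function(traces, bin_width = 0.1, t_start = 0) {
  if (is.list(traces) && !is.matrix(traces)) {
    if (!length(traces)) stop("empty trace list")
    if (!all(vapply(traces, inherits, logical(1), "percept_trace")))
      stop("traces must be percept_trace objects")
    t <- traces[[1]]$t
    for (tr in traces) {
      if (length(tr$t) != length(t) || any(abs(tr$t - t) > 1e-9))
        stop("all traces must share the same time grid")
    }
    M <- vapply(traces, function(tr) tr$segregated, integer(length(t)))
    M <- matrix(M, nrow = length(t))
  } else if (is.matrix(traces)) {
    t <- attr(traces, "t")
    if (is.null(t)) stop("percept matrix must carry a 't' attribute")
    M <- traces
  } else stop("traces must be a list of percept_trace or a percept matrix")
  dt <- if (length(t) > 1) t[2] - t[1] else bin_width
  if (bin_width < dt - 1e-12) stop("bin_width must be >= the sampling step")
  keep <- t >= t_start - 1e-12
  t <- t[keep]
  M <- M[keep, , drop = FALSE]
  bin <- floor((t - t_start) / bin_width + 1e-9)
  prop <- tapply(rowMeans(M), bin, mean)
  centers <- t_start + (as.numeric(names(prop)) + 0.5) * bin_width
  structure(data.frame(bin_center = centers,
                       proportion_segregated = as.numeric(prop)),
            n_trials = ncol(M),
            bin_width = bin_width,
            class = c("buildup_function", "data.frame"))
}

#' Classify one trial by majority vote within a decision window
#'
#' A trial counts as segregated iff at least half of the percept samples in
#' `[window_start, window_end)` are segregated.
#'
#' @param trace A `percept_trace`.
#' @param window_start,window_end Window bounds in seconds; the window must
#'   contain at least one sample and lie within the trace span.
#' @return 1 (segregated) or 0 (integrated).
#' @export
classify_trial <- function(trace, window_start, window_end) {
  stopifnot(inherits(trace, "percept_trace"))
  sel <- trace$t >= window_start - 1e-12 & trace$t < window_end - 1e-12
  if (!any(sel)) stop("empty decision window")
  as.integer(mean(trace$segregated[sel]) >= 0.5)
}

#' Default decision window for a timeline
#'
#' The window spans the delayed event(s) plus/minus one inter-onset interval
#' (clipped to the sequence), since the delay-detection task hinges on the
#' percept around the delayed sounds. If the timeline has no delayed events
#' the window brackets the final event instead.
#'
#' @param timeline An `event_timeline`.
#' @return Numeric length-2 vector (start, end) in seconds.
#' @export
decision_window <- function(timeline) {
  stopifnot(inherits(timeline, "event_timeline"))
  ioi <- attr(timeline, "ioi")
  total <- attr(timeline, "total_duration")
  idx <- attr(timeline, "delayed_events")
  if (is.null(idx) || !length(idx)) idx <- nrow(timeline)
  lo <- max(0, min(timeline$onset[idx]) - ioi)
  hi <- min(total, max(timeline$onset[idx] + timeline$duration[idx]) + ioi)
  c(lo, hi)
}

#' Export a build-up function as CSV
#' @param bf A `buildup_function`.
#' @param path File path.
#' @export
write_buildup <- function(bf, path) {
  stopifnot(inherits(bf, "buildup_function"))
  out <- data.frame(bin_center_s = bf$bin_center,
                    proportion_segregated = bf$proportion_segregated,
                    n_trials = attr(bf, "n_trials"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.buildup_function <- function(x, ...) {
  cat(sprintf(
    "<buildup_function> %d bins (%.3g s), %d trials, final proportion %.3f\n",
    nrow(x), attr(x, "bin_width"), attr(x, "n_trials"),
    x$proportion_segregated[nrow(x)]))
  invisible(x)
}
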