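#' Parameters of the cortical input stage
#'
#' The input stage distributes each sound's pulsatile drive across the three
#' competition units through the weighting function
#' \deqn{\omega(\Delta pitch, t) = Q(t) \, L \, e^{-R(t)\,\Delta pitch/\sigma}}
#' where `L` is the amplitude factor, `sigma` the lateral decay constant (in
#' Delta-pitch percent units), and `Q(t)`, `R(t)` exponential decays with time
#' constant `tau_ad` representing amplitude and Delta-pitch adaptation of the
#' input. `Q` decays from `q_init` to `q_asym`; `R` grows from `r_init` to
#' `r_asym`, so the effective input to the cross (AB) pathway shrinks over
#' the first seconds of the sequence — the input-stage contribution to the
#' build-up of segregation.
#'
#' @param L Amplitude factor (dimensionless, > 0). 0.6 is the normal-hearing
#'   reference value; 0.35 the fitted cochlear-implant value.
#' @param sigma Lateral decay constant in Delta-pitch percent (> 0); fitted
#'   values of 40 (L fixed) and 30 (L free) are the canonical settings.
#' @param tau_ad Time constant of Q(t) and R(t) in seconds (default 0.5).
#' @param q_init,q_asym Initial and asymptotic value of Q(t).
#' @param r_init,r_asym Initial and asymptotic value of R(t).
#' @return An object of class `input_stage_params`.
#' @export
input_stage_params <- function(L = 0.6, sigma = 40, tau_ad = 0.5,
                               q_init = 1, q_asym = 0.85,
                               r_init = 1, r_asym = 1.5) {
  vals <- c(L = L, sigma = sigma, tau_ad = tau_ad, q_init = q_init,
            q_asym = q_asym, r_init = r_init, r_asym = r_asym)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all input-stage parameters must be finite and > 0")
  structure(as.list(vals), class = "input_stage_params")
}

#' Exponential adaptation profile
#'
#' `asym + (init - asym) * exp(-t / tau)`: the common form of the amplitude
#' and Delta-pitch adaptation functions Q(t) and R(t).
#'
#' @param t Time since sequence onset, seconds (vectorized, must be >= 0).
#' @param init Value at `t = 0`.
#' @param asym Asymptotic value as `t -> Inf`.
#' @param tau Time constant in seconds (> 0).
#' @return Numeric vector of the same length as `t`.
#' @examples
#' adaptation_profile(0.5, init = 1, asym = 0, tau = 0.5)  # exp(-1)
#' @export
adaptation_profile <- function(t, init, asym, tau) {
  if (tau <= 0) stop("tau must be > 0")
  if (any(t < 0)) stop("negative t not allowed")
  asym + (init - asym) * exp(-t / tau)
}

#' Input weighting function
#'
#' Evaluates `omega(delta_pitch, t) = Q(t) * L * exp(-R(t) * delta_pitch /
#' sigma)`, the amount of input a unit at perceptual distance `delta_pitch`
#' from a sound receives at time `t`.
#'
#' @param delta_pitch Perceptual distance in percent (>= 0; vectorized with
#'   `t` under usual recycling).
#' @param t Time since sequence onset in seconds (>= 0).
#' @param params An [input_stage_params()].
#' @return Numeric vector of weights.
#' @export
weight <- function(delta_pitch, t, params = input_stage_params()) {
  stopifnot(inherits(params, "input_stage_params"))
  if (any(delta_pitch < 0)) stop("delta_pitch must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  Q <- adaptation_profile(t, params$q_init, params$q_asym, params$tau_ad)
  R <- adaptation_profile(t, params$r_init, params$r_asym, params$tau_ad)
  Q * params$L * exp(-R * delta_pitch / params$sigma)
}

# raised-cosine on/off ramps inside a tone of duration d; s is time since
# tone onset; ramp = 0 gives a rectangular envelope
tone_envelope <- function(s, d, ramp) {
  ramp <- min(ramp, d / 2)
  e <- as.numeric(s >= 0 & s <= d)
  if (ramp > 0) {
    on <- s >= 0 & s < ramp
    off <- s > d - ramp & s <= d
    e[on] <- 0.5 * (1 - cos(pi * s[on] / ramp))
    e[off] <- 0.5 * (1 - cos(pi * (d - s[off]) / ramp))
  }
  e
}

#' Convert an event timeline into competition-network input currents
#'
#' Each sound drives all three units through the weighting function evaluated
#' at the unit's perceptual distance from that sound: during an A sound the A
#' unit sits at distance 0, the B unit at `delta_pitch`, and the AB unit at
#' the midpoint `delta_pitch / 2` (symmetrically for B sounds). Q(t) and R(t)
#' run on time since sequence onset, so input weights adapt across the whole
#' sequence rather than within each tone. Tones carry raised-cosine on/off
#' ramps (default 5 ms) so the currents are continuous in time.
#'
#' @param timeline An `event_timeline` from [build_sequence()].
#' @param delta_pitch Pitch difference between the A and B sounds (percent).
#' @param params An [input_stage_params()].
#' @param dt Sampling step in seconds; must satisfy `dt <= tone_duration/4`.
#' @param ramp_duration On/off ramp duration in seconds (0 = rectangular).
#' @return An `input_currents` object: list with `t`, `dt`, and the matrix
#'   `I` (columns `A`, `B`, `AB`), plus the timeline attributes needed by
#'   downstream stages.
#' @export
build_input_currents <- function(timeline, delta_pitch,
                                 params = input_stage_params(),
                                 dt = 0.001, ramp_duration = 0.005) {
  stopifnot(inherits(timeline, "event_timeline"))
  if (delta_pitch < 0) stop("delta_pitch must be >= 0")
  tone_dur <- timeline$duration[1]
  if (dt > tone_dur / 4 + 1e-12)
    stop("dt too coarse: must be <= tone_duration / 4")
  total <- attr(timeline, "total_duration")
  t <- seq(0, total, by = dt)
  env_A <- numeric(length(t))
  env_B <- numeric(length(t))
  for (i in seq_len(nrow(timeline))) {
    on <- timeline$onset[i]
    d <- timeline$duration[i]
    sel <- which(t >= on & t <= on + d)
    if (!length(sel)) next
    e <- tone_envelope(t[sel] - on, d, ramp_duration)
    if (timeline$label[i] == "A") env_A[sel] <- pmax(env_A[sel], e)
    else env_B[sel] <- pmax(env_B[sel], e)
  }
  w0 <- weight(0, t, params)
  w_full <- weight(delta_pitch, t, params)
  w_half <- weight(delta_pitch / 2, t, params)
  I <- cbind(A  = env_A * w0 + env_B * w_full,
             B  = env_A * w_full + env_B * w0,
             AB = (env_A + env_B) * w_half)
  structure(list(t = t, dt = dt, I = I,
                 delta_pitch = delta_pitch,
                 timeline = timeline),
            class = "input_currents")
}

#' Write input currents as CSV (columns t, I_A, I_B, I_AB)
#' @param currents An `input_currents` object.
#' @param path File path.
#' @export
write_input_currents <- function(currents, path) {
  stopifnot(inherits(currents, "input_currents"))
  out <- data.frame(t = currents$t,
                    I_A = currents$I[, "A"],
                    I_B = currents$I[, "B"],
                    I_AB = currents$I[, "AB"])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.input_currents <- function(x, ...) {
  cat(sprintf(
    "<input_currents> %d samples, dt %.4g s, dpitch %.3g%%, peak I_A %.3g\n",
    length(x$t), x$dt, x$delta_pitch, max(x$I[, "A"])))
  invisible(x)
}
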