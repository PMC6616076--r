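# small, fast fixtures shared across tests

quick_spec <- function(duration = 0.68, delta_pitch = 50, delta_t = 0,
                       ...) {
  sequence_spec(duration = duration, delta_pitch = delta_pitch,
                delta_t = delta_t, ...)
}

quick_currents <- function(delta_pitch = 50, duration = 0.68,
                           input = input_stage_params(), dt = 0.001, ...) {
  tl <- build_sequence(quick_spec(duration = duration,
                                  delta_pitch = delta_pitch, ...))
  build_input_currents(tl, delta_pitch, input, dt = dt)
}

# constant-current stimulus for fixed-point and noise checks
constant_currents <- function(I_A, I_B, I_AB, duration = 2, dt = 0.001) {
  t <- seq(0, duration, by = dt)
  structure(list(t = t, dt = dt,
                 I = cbind(A = rep(I_A, length(t)),
                           B = rep(I_B, length(t)),
                           AB = rep(I_AB, length(t))),
                 delta_pitch = NA_real_, timeline = NULL),
            class = "input_currents")
}

toy_trace <- function(t, segregated) {
  structure(list(t = t, segregated = as.integer(segregated)),
            class = "percept_trace")
}
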