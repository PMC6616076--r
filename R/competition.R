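#' Parameters of the three-unit competition network
#'
#' Wilson-Cowan-style rate units for the A, B and AB percepts compete through
#' all-to-all mutual inhibition, recurrent self-excitation, slow subtractive
#' adaptation and additive Ornstein-Uhlenbeck noise injected alongside the
#' input inside the gain:
#' \deqn{\tau_u \dot u_j = -u_j + F(I_j + \alpha u_j - \beta_i \sum_{k \ne j}
#'   u_k - g a_j + n_j)}
#' \deqn{\tau_a \dot a_j = -a_j + u_j}
#' with `F(x) = 1 / (1 + exp(-gain_slope * (x - gain_threshold)))` and `n_j`
#' an OU process with correlation time `tau_n` and stationary s.d. `gamma`.
#'
#' Defaults were calibrated once against the qualitative behavioral regime
#' (rising build-up that plateaus below 1, monotone effect of the pitch
#' difference, build-up effect across durations, spontaneous switching) and
#' then frozen; see the package vignette for the calibration rationale.
#'
#' @param beta_i Mutual inhibition strength (>= 0).
#' @param alpha Recurrent self-excitation strength. Strong enough that the
#'   current percept persists across the silent gaps between tones.
#' @param g Adaptation strength (>= 0).
#' @param tau_u Unit time constant, seconds.
#' @param tau_a Adaptation time constant, seconds; must exceed `tau_u`.
#' @param gamma Stationary standard deviation of the OU noise (>= 0).
#' @param tau_n Noise correlation time, seconds.
#' @param gain_slope,gain_threshold Parameters of the sigmoidal gain.
#' @param dt Integration step, seconds; must satisfy `dt < tau_u / 5`.
#' @return An object of class `competition_params`.
#' @export
competition_params <- function(beta_i = 0.5, alpha = 0.6, g = 0.2,
                               tau_u = 0.3, tau_a = 2.5,
                               gamma = 0.15, tau_n = 0.1,
                               gain_slope = 8, gain_threshold = 0.25,
                               dt = 0.001) {
  if (beta_i < 0 || g < 0 || gamma < 0)
    stop("beta_i, g and gamma must be >= 0")
  if (!(tau_a > tau_u && tau_u > 0))
    stop("require tau_a > tau_u > 0")
  if (tau_n <= 0) stop("tau_n must be > 0")
  if (dt >= tau_u / 5) stop("dt must be < tau_u / 5")
  structure(list(beta_i = beta_i, alpha = alpha, g = g,
                 tau_u = tau_u, tau_a = tau_a,
                 gamma = gamma, tau_n = tau_n,
                 gain_slope = gain_slope, gain_threshold = gain_threshold,
                 dt = dt),
            class = "competition_params")
}

#' Sigmoidal population gain
#' @param x Input argument (vectorized).
#' @param params A [competition_params()].
#' @return Gain output in (0, 1).
#' @export
gain_function <- function(x, params = competition_params()) {
  1 / (1 + exp(-params$gain_slope * (x - params$gain_threshold)))
}

check_dt_match <- function(currents, params) {
  if (abs(currents$dt - params$dt) > 1e-12)
    stop("currents and competition_params must share dt (",
         currents$dt, " vs ", params$dt, ")")
}

#' Simulate a single competition-network trial
#'
#' Integrates the network over the input currents with the Heun
#' predictor-corrector scheme (exact OU noise updates) from all-zero initial
#' conditions, and returns the full trajectory plus the binary percept trace.
#'
#' @param currents An `input_currents` object from [build_input_currents()].
#' @param params A [competition_params()] with matching `dt`.
#' @param seed Integer master seed for this trial's noise.
#' @param unit_seeds Optional length-3 vector of explicit per-unit noise
#'   stream seeds (overrides derivation from `seed`); mainly for symmetry
#'   and reproducibility experiments.
#' @return A list with elements `trajectory` (class `network_trajectory`:
#'   `t`, matrices `u`, `a`, `n` with columns A, B, AB) and `percept` (class
#'   `percept_trace`).
#' @export
simulate_trial <- function(currents, params = competition_params(),
                           seed = 1, unit_seeds = NULL) {
  stopifnot(inherits(currents, "input_currents"))
  check_dt_match(currents, params)
  res <- sim_trials_cpp(currents$I, unclass(params), 1L,
                        as.double(seed), 0, "trace", 1L, 2L,
                        if (is.null(unit_seeds)) NULL else as.double(unit_seeds))
  dimnames(res$u) <- dimnames(res$a) <- dimnames(res$n) <-
    list(NULL, c("A", "B", "AB"))
  traj <- structure(list(t = currents$t, u = res$u, a = res$a, n = res$n),
                    class = "network_trajectory")
  trace <- percept_trace(currents$t, res$segregated)
  list(trajectory = traj, percept = trace)
}

percept_trace <- function(t, segregated) {
  structure(list(t = t, segregated = as.integer(segregated)),
            class = "percept_trace")
}

#' Read out the binary percept from a trajectory
#'
#' The network encodes integration when the AB unit's activity strictly
#' exceeds both the A and the B unit activities, and a segregated percept
#' otherwise (ties count as segregated).
#'
#' @param traj A `network_trajectory`.
#' @return A `percept_trace`: list with `t` and binary `segregated`.
#' @export
readout <- function(traj) {
  stopifnot(inherits(traj, "network_trajectory"))
  seg <- as.integer(!(traj$u[, "AB"] > pmax(traj$u[, "A"], traj$u[, "B"])))
  percept_trace(traj$t, seg)
}

#' Simulate many trials and collect percept traces
#'
#' Runs `n_trials` independent trials of the competition network over the
#' same input currents. Per-trial noise seeds are derived deterministically
#' from `master_seed` and the trial index (see the vignette for the exact
#' derivation), so results do not depend on batching.
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of trials.
#' @param master_seed Integer master seed.
#' @param trial_offset Index offset added to the trial counter when deriving
#'   per-trial seeds (lets disjoint batches extend a run).
#' @return Integer matrix (time samples x trials) of the segregated
#'   indicator, with attribute `t` holding the time grid.
#' @export
simulate_percepts <- function(currents, params = competition_params(),
                              n_trials = 100, master_seed = 1,
                              trial_offset = 0) {
  stopifnot(inherits(currents, "input_currents"), n_trials >= 1)
  check_dt_match(currents, params)
  P <- sim_trials_cpp(currents$I, unclass(params), as.integer(n_trials),
                      as.double(master_seed), as.double(trial_offset),
                      "percept", 1L, 2L, NULL)
  attr(P, "t") <- currents$t
  P
}

#' Classify many trials as segregated/integrated within a decision window
#'
#' Runs `n_trials` trials and applies the majority rule over the samples in
#' `[window[1], window[2])`: a trial counts as segregated iff at least half
#' of the window samples carry the segregated percept.
#'
#' @inheritParams simulate_percepts
#' @param window Numeric length-2 vector: decision window in seconds.
#' @return Integer 0/1 vector of per-trial segregation labels.
#' @export
classify_trials <- function(currents, params = competition_params(),
                            n_trials = 100, master_seed = 1,
                            window, trial_offset = 0) {
  stopifnot(inherits(currents, "input_currents"), length(window) == 2)
  check_dt_match(currents, params)
  i0 <- findInterval(window[1] - 1e-12, currents$t) + 1L
  i1 <- findInterval(window[2] - 1e-12, currents$t) + 1L
  i0 <- max(1L, i0)
  i1 <- min(length(currents$t) + 1L, i1)
  if (i1 <= i0) stop("empty classification window")
  as.integer(sim_trials_cpp(currents$I, unclass(params),
                            as.integer(n_trials), as.double(master_seed),
                            as.double(trial_offset), "classify",
                            i0, i1, NULL))
}

#' Export a trajectory or percept trace as CSV
#' @param x A `network_trajectory` or `percept_trace`.
#' @param path File path.
#' @export
write_trace <- function(x, path) {
  if (inherits(x, "network_trajectory")) {
    out <- data.frame(t = x$t,
                      u_A = x$u[, "A"], u_B = x$u[, "B"], u_AB = x$u[, "AB"],
                      a_A = x$a[, "A"], a_B = x$a[, "B"], a_AB = x$a[, "AB"])
  } else if (inherits(x, "percept_trace")) {
    out <- data.frame(t = x$t, segregated = x$segregated)
  } else stop("x must be a network_trajectory or percept_trace")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.percept_trace <- function(x, ...) {
  cat(sprintf("<percept_trace> %d samples, %.1f%% segregated\n",
              length(x$t), 100 * mean(x$segregated)))
  invisible(x)
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("<network_trajectory> %d samples, final u = (%.3f, %.3f, %.3f)\n",
              length(x$t), x$u[nrow(x$u), 1], x$u[nrow(x$u), 2],
              x$u[nrow(x$u), 3]))
  invisible(x)
}
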