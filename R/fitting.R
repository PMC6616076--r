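#' Read a behavioral d-prime table from CSV
#'
#' Expected header: `delta_pitch,duration_s,dprime_mean` with optional
#' `dprime_sd` and `n_listeners` columns. For externally deposited datasets,
#' map the source columns onto this schema before reading (the pitch
#' difference in percent, the sequence duration in seconds, and the
#' across-listener mean d-prime per condition).
#'
#' @param path CSV file path.
#' @return A `behavioral_table` data frame with columns `delta_pitch`,
#'   `duration`, `dprime_mean` (and `dprime_sd`, `n_listeners` if present).
#' @export
read_behavioral_table <- function(path) {
  if (!file.exists(path)) stop("behavioral data file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("delta_pitch", "duration_s", "dprime_mean")
  if (!all(need %in% names(d)))
    stop("behavioral table must have columns delta_pitch, duration_s, ",
         "dprime_mean: ", path)
  out <- data.frame(delta_pitch = d$delta_pitch, duration = d$duration_s,
                    dprime_mean = d$dprime_mean)
  if ("dprime_sd" %in% names(d)) out$dprime_sd <- d$dprime_sd
  if ("n_listeners" %in% names(d)) out$n_listeners <- d$n_listeners
  as_behavioral_table(out)
}

as_behavioral_table <- function(df) {
  stopifnot(all(c("delta_pitch", "duration", "dprime_mean") %in% names(df)))
  if (anyDuplicated(df[c("delta_pitch", "duration")]))
    stop("duplicate (delta_pitch, duration) conditions in behavioral table")
  if (any(!is.finite(df$dprime_mean))) stop("non-finite dprime_mean")
  structure(df, class = c("behavioral_table", "data.frame"))
}

#' Averaged mean error between predictions and behavioral data
#'
#' The fit objective: the mean over conditions of the absolute difference
#' between predicted and behaviorally measured mean d-prime (optionally the
#' root-mean-square difference).
#'
#' @param predictions A `dprime_prediction` data frame covering every
#'   condition in `data`.
#' @param data A `behavioral_table`.
#' @param metric `"mae"` (default) or `"rmse"`.
#' @return Non-negative scalar; 0 iff predictions match the data exactly.
#' @export
ame <- function(predictions, data, metric = c("mae", "rmse")) {
  metric <- match.arg(metric)
  key_p <- paste(signif(predictions$delta_pitch, 10),
                 signif(predictions$duration, 10))
  key_d <- paste(signif(data$delta_pitch, 10), signif(data$duration, 10))
  idx <- match(key_d, key_p)
  if (anyNA(idx))
    stop("missing predictions for conditions: ",
         paste(key_d[is.na(idx)], collapse = "; "))
  err <- predictions$dprime[idx] - data$dprime_mean
  if (metric == "mae") mean(abs(err)) else sqrt(mean(err^2))
}

#' Configuration of the genetic-algorithm fit
#'
#' @param free Character vector of free weighting-function parameters:
#'   `"sigma"` or `c("sigma", "L")`. Only input-stage parameters are ever
#'   searched; the competition stage is untouched by construction.
#' @param bounds Named list of length-2 numeric bounds per free parameter.
#' @param ga_population Population size (>= 4, default 24).
#' @param ga_generations Number of generations (default 40).
#' @param ga_seed Integer seed for the GA's random draws and for the
#'   per-condition simulation seeds (common random numbers across
#'   candidates).
#' @param n_trials_per_eval Simulated trials per condition during the search
#'   (default 200).
#' @param n_trials_final Trials for the final re-evaluation of the winner
#'   (default 1000).
#' @param metric Error metric passed to [ame()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = "sigma",
                       bounds = list(sigma = c(5, 120), L = c(0.05, 1.2)),
                       ga_population = 24, ga_generations = 40,
                       ga_seed = 1, n_trials_per_eval = 200,
                       n_trials_final = 1000, metric = "mae") {
  free <- match.arg(free, c("sigma", "L"), several.ok = TRUE)
  if (!all(free %in% names(bounds)))
    stop("bounds must be given for every free parameter")
  for (nm in free) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || any(b <= 0) || b[1] > b[2])
      stop("bounds for ", nm, " must be finite, positive and ordered")
  }
  if (ga_population < 4) stop("ga_population must be >= 4")
  structure(list(free = free, bounds = bounds[free],
                 ga_population = as.integer(ga_population),
                 ga_generations = as.integer(ga_generations),
                 ga_seed = as.integer(ga_seed),
                 n_trials_per_eval = as.integer(n_trials_per_eval),
                 n_trials_final = as.integer(n_trials_final),
                 metric = metric),
            class = "fit_config")
}

# objective: AME of the model at weighting parameters theta against data.
# Candidates compared within one generation share per-condition seeds
# (common random numbers, via seed_offset); the seeds are refreshed every
# generation so the search cannot chase one fixed noise realization along
# the sigma-L trade-off ridge.
eval_candidate <- function(theta, data, cfg, config, n_trials,
                           seed_offset = 0) {
  config <- set_weighting(config,
                          sigma = if ("sigma" %in% names(theta)) theta[["sigma"]],
                          L = if ("L" %in% names(theta)) theta[["L"]])
  rows <- lapply(seq_len(nrow(data)), function(i) {
    predict_condition(data$delta_pitch[i], data$duration[i],
                      config = config, n_trials = n_trials,
                      master_seed = cfg$ga_seed + i * 100003 + seed_offset)
  })
  pred <- do.call(rbind, rows)
  ame(pred, data, cfg$metric)
}

#' Fit the weighting function to a behavioral d-prime table
#'
#' Real-coded genetic algorithm (tournament selection of size 2, blend
#' crossover, Gaussian mutation, elitism of one) minimizing the averaged
#' mean error between model-predicted and measured mean d-prime scores.
#' Only the weighting-function parameters named in `cfg$free` are searched.
#' Within a generation all candidates are evaluated with identical
#' per-condition simulation seeds (common random numbers), so the
#' comparisons selection makes are smooth in the parameters; the seeds are
#' refreshed every generation (with the elite re-evaluated alongside its
#' rivals) so the search optimizes the expected error rather than one noise
#' realization. The winning candidate is re-evaluated at `n_trials_final`
#' trials per condition.
#'
#' @param data A `behavioral_table` (see [read_behavioral_table()]).
#' @param cfg A [fit_config()].
#' @param config A [stream_model_config()]; its input-stage values serve as
#'   the fixed values of any non-free parameter.
#' @return A `fit_result` list: `sigma_hat`, `L_hat` (NA when L is fixed),
#'   `ame` (winner re-evaluated at `n_trials_final`), `ame_search`,
#'   `generations_log` (best search AME per generation, non-increasing),
#'   `seed`, `config` echo.
#' @export
fit_weighting <- function(data, cfg = fit_config(),
                          config = stream_model_config()) {
  stopifnot(inherits(data, "behavioral_table") || is.data.frame(data),
            inherits(cfg, "fit_config"))
  data <- as_behavioral_table(as.data.frame(data))
  if (!nrow(data)) stop("behavioral table is empty")

  k <- length(cfg$free)
  lo <- vapply(cfg$bounds, `[`, numeric(1), 1)
  hi <- vapply(cfg$bounds, `[`, numeric(1), 2)

  # private RNG stream; restore the caller's state on exit
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(cfg$ga_seed)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta, gen) {
    key <- paste(gen, paste(signif(theta, 12), collapse = "_"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- eval_candidate(stats::setNames(as.list(theta), cfg$free),
                          data, cfg, config, cfg$n_trials_per_eval,
                          seed_offset = gen * 7919L)
    cache[[key]] <- val
    val
  }

  np <- cfg$ga_population
  pop <- matrix(runif(np * k, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, ncol = k, dimnames = list(NULL, cfg$free))
  fitness <- apply(pop, 1, evaluate, gen = 0L)
  log_best <- numeric(cfg$ga_generations)

  tournament <- function() {
    a <- sample.int(np, 1); b <- sample.int(np, 1)
    if (fitness[a] <= fitness[b]) a else b
  }

  for (gen in seq_len(cfg$ga_generations)) {
    elite <- which.min(fitness)
    newpop <- matrix(NA_real_, np, k, dimnames = list(NULL, cfg$free))
    newpop[1, ] <- pop[elite, ]
    for (i in 2:np) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      child <- p1
      cross <- runif(k) < 0.9
      if (any(cross)) {       # BLX-alpha blend crossover
        w <- runif(sum(cross), -0.5, 1.5)
        child[cross] <- p1[cross] + w * (p2[cross] - p1[cross])
      }
      mut <- runif(k) < 0.25
      if (any(mut))
        child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1 * (hi[mut] - lo[mut]))
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    # fresh seeds each generation: the elite is re-evaluated alongside its
    # rivals, so selection favors candidates that fit across noise draws
    fitness <- apply(pop, 1, evaluate, gen = gen)
    log_best[gen] <- min(fitness)
  }

  best <- which.min(fitness)
  theta <- pop[best, ]
  final_ame <- eval_candidate(stats::setNames(as.list(theta), cfg$free),
                              data, cfg, config, cfg$n_trials_final,
                              seed_offset = (cfg$ga_generations + 1L) * 7919L)
  structure(list(
    sigma_hat = if ("sigma" %in% cfg$free) theta[["sigma"]] else config$input$sigma,
    L_hat = if ("L" %in% cfg$free) theta[["L"]] else NA_real_,
    ame = final_ame,
    ame_search = fitness[best],
    generations_log = cummin(log_best),
    seed = cfg$ga_seed,
    free = cfg$free,
    config = cfg),
    class = "fit_result")
}

#' Write a fit result as JSON
#' @param result A `fit_result`.
#' @param path File path.
#' @export
write_fit_result <- function(result, path) {
  stopifnot(inherits(result, "fit_result"))
  out <- list(sigma_hat = result$sigma_hat, L_hat = result$L_hat,
              ame = result$ame, ame_search = result$ame_search,
              generations_log = result$generations_log,
              seed = result$seed, free = result$free,
              ga_population = result$config$ga_population,
              ga_generations = result$config$ga_generations,
              n_trials_per_eval = result$config$n_trials_per_eval,
              n_trials_final = result$config$n_trials_final)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.fit_result <- function(x, ...) {
  # presentation rounding convention: sigma and AME to the first significant
  # figure, L to the second; raw values are retained in the object
  cat("<fit_result>\n")
  cat(sprintf("  sigma = %g (raw %.6g)\n", signif(x$sigma_hat, 1), x$sigma_hat))
  if (!is.na(x$L_hat))
    cat(sprintf("  L     = %g (raw %.6g)\n", signif(x$L_hat, 2), x$L_hat))
  cat(sprintf("  AME   = %g (raw %.6g, final re-evaluation)\n",
              signif(x$ame, 1), x$ame))
  invisible(x)
}
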