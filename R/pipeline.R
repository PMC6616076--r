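#' Read a pipeline configuration from YAML or JSON
#'
#' The configuration mirrors the nested structure of
#' [stream_model_config()] with optional top-level sections `stimulus`,
#' `input`, `competition`, `io`, `buildup`, `fitting`, `synthetic`, plus
#' `master_seed` and `output_dir`. Every numeric field is validated by the
#' corresponding constructor before any simulation starts; unknown fields
#' raise an error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  structure(cfg, class = "run_config")
}

build_config_from_run <- function(run) {
  known <- c("stimulus", "input", "competition", "io", "buildup", "fitting",
             "synthetic", "master_seed", "output_dir", "command",
             "delta_pitch", "delta_pitch_grid", "duration", "durations",
             "n_trials", "data")
  bad <- setdiff(names(run), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  args <- list()
  st <- run$stimulus
  for (nm in names(st)) {
    ok <- c("presentation_rate", "delta_t", "delayed_event_policy",
            "tone_duration", "ramp_duration")
    if (!nm %in% ok) stop("unknown stimulus config field: stimulus.", nm)
    args[[nm]] <- st[[nm]]
  }
  if (!is.null(run$input))
    args$input <- do.call(input_stage_params, run$input)
  if (!is.null(run$competition))
    args$competition <- do.call(competition_params, run$competition)
  if (!is.null(run$io))
    args$io <- do.call(io_config, run$io)
  do.call(stream_model_config, args)
}

#' Run a pipeline command from a configuration
#'
#' Ties the modeling stages into reproducible commands. Each run writes its
#' artifacts (CSV/JSON) into `output_dir` together with a `manifest.json`
#' recording the command, configuration echo, master seed, package version
#' and wall time, so every artifact is regenerable from its manifest.
#'
#' Commands: `"simulate"` (one trial's trajectory + percept trace),
#' `"buildup"` (build-up function at one condition), `"predict"` (d-prime
#' table over a condition grid), `"fit"` (GA fit to a behavioral CSV),
#' `"generate"` (synthetic dataset), `"recover"` (generate + fit report).
#'
#' @param config A `run_config` list (from [read_run_config()]), a path to
#'   a YAML/JSON file, or `NULL` for all defaults.
#' @param command One of simulate, buildup, predict, fit, generate, recover.
#' @param seed Master seed; overrides `config$master_seed` (default 1).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Invisibly, a list of the artifact paths plus the main result
#'   object.
#' @export
run_pipeline <- function(config = NULL,
                         command = c("simulate", "buildup", "predict", "fit",
                                     "generate", "recover"),
                         seed = NULL, output_dir = NULL) {
  command <- match.arg(command)
  t0 <- Sys.time()
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) config <- structure(list(), class = "run_config")
  seed <- as.integer(if (!is.null(seed)) seed
                     else if (!is.null(config$master_seed)) config$master_seed
                     else 1)
  output_dir <- if (!is.null(output_dir)) output_dir
                else if (!is.null(config$output_dir)) config$output_dir
                else stop("output_dir must be given (argument or config)")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  mc <- build_config_from_run(config)
  n_trials <- if (!is.null(config$n_trials)) config$n_trials else 1000
  dpg <- if (!is.null(config$delta_pitch_grid)) config$delta_pitch_grid
         else c(0, 12.5, 25, 50, 75, 100)
  dp <- if (!is.null(config$delta_pitch)) config$delta_pitch else 50
  durs <- if (!is.null(config$durations)) config$durations
          else unname(canonical_durations())
  dur <- if (!is.null(config$duration)) config$duration else max(durs)

  artifacts <- list()
  result <- NULL
  message(sprintf("[streamseg] %s: seed=%d out=%s", command, seed, output_dir))

  if (command == "simulate") {
    spec <- sequence_spec(presentation_rate = mc$presentation_rate,
                          duration = dur, delta_pitch = dp,
                          delta_t = mc$delta_t,
                          tone_duration = mc$tone_duration,
                          delayed_event_policy = mc$delayed_event_policy)
    tl <- build_sequence(spec)
    cur <- build_input_currents(tl, dp, mc$input, dt = mc$competition$dt,
                                ramp_duration = mc$ramp_duration)
    trial <- simulate_trial(cur, mc$competition, seed = seed)
    artifacts$timeline <- file.path(output_dir, "timeline.csv")
    write_timeline(tl, artifacts$timeline)
    artifacts$currents <- file.path(output_dir, "currents.csv")
    write_input_currents(cur, artifacts$currents)
    artifacts$trajectory <- file.path(output_dir, "trajectory.csv")
    write_trace(trial$trajectory, artifacts$trajectory)
    artifacts$percept <- file.path(output_dir, "percept.csv")
    write_trace(trial$percept, artifacts$percept)
    result <- trial
  } else if (command == "buildup") {
    spec <- sequence_spec(presentation_rate = mc$presentation_rate,
                          duration = dur, delta_pitch = dp,
                          delta_t = mc$delta_t,
                          tone_duration = mc$tone_duration,
                          delayed_event_policy = mc$delayed_event_policy)
    tl <- build_sequence(spec)
    cur <- build_input_currents(tl, dp, mc$input, dt = mc$competition$dt,
                                ramp_duration = mc$ramp_duration)
    P <- simulate_percepts(cur, mc$competition, n_trials = n_trials,
                           master_seed = seed)
    bw <- if (!is.null(config$buildup$bin_width)) config$buildup$bin_width
          else 0.1
    bf <- buildup_function(P, bin_width = bw)
    artifacts$buildup <- file.path(output_dir, "buildup.csv")
    write_buildup(bf, artifacts$buildup)
    result <- bf
  } else if (command == "predict") {
    pred <- predict_conditions(dpg, durs, config = mc, n_trials = n_trials,
                               master_seed = seed)
    artifacts$predictions <- file.path(output_dir, "predictions.csv")
    write_predictions(pred, artifacts$predictions)
    result <- pred
  } else if (command == "fit") {
    if (is.null(config$data)) stop("fit command needs config$data (CSV path)")
    data <- read_behavioral_table(config$data)
    fc <- do.call(fit_config,
                  c(config$fitting, if (is.null(config$fitting$ga_seed))
                    list(ga_seed = seed)))
    fit <- fit_weighting(data, fc, mc)
    artifacts$fit <- file.path(output_dir, "fit.json")
    write_fit_result(fit, artifacts$fit)
    result <- fit
  } else if (command == "generate") {
    sp <- do.call(synthetic_study_spec,
                  c(config$synthetic, if (is.null(config$synthetic$seed))
                    list(seed = seed)))
    ds <- generate_dataset(sp, mc)
    write_dataset(ds, sp, file.path(output_dir, "synthetic"))
    artifacts$means <- file.path(output_dir, "synthetic_means.csv")
    result <- ds
  } else if (command == "recover") {
    sp <- do.call(synthetic_study_spec,
                  c(config$synthetic, if (is.null(config$synthetic$seed))
                    list(seed = seed)))
    fc <- do.call(fit_config,
                  c(config$fitting, if (is.null(config$fitting$ga_seed))
                    list(ga_seed = seed)))
    rec <- recovery_experiment(sp, fc, mc)
    artifacts$report <- file.path(output_dir, "recovery_report.csv")
    write.csv(rec$report, artifacts$report, row.names = FALSE, quote = FALSE)
    artifacts$fit <- file.path(output_dir, "fit.json")
    write_fit_result(rec$fit, artifacts$fit)
    result <- rec
  }

  manifest <- list(command = command,
                   master_seed = seed,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("streamseg")),
                   artifacts = artifacts,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  message(sprintf("[streamseg] %s done in %.1f s", command,
                  manifest$wall_time_s))
  invisible(c(artifacts, list(manifest = manifest_path, result = result)))
}
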