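SCHEMA_VERSION <- "1.0"

#' Write a session bundle to disk
#'
#' Columnar session container: a binary feather table `samples.feather`
#' (time_s plus `f465`/`f405` and/or `detector_v`, and `piezo_v` when
#' present), a feather events table `events.feather` (`time_s`,
#' `event_type` in lick/stim/valve/trial_start/abort, `value`), and a JSON
#' sidecar `metadata.json` carrying the schema version, task configuration,
#' ground-truth parameters, seed and the provenance chain of processing
#' parameters. The binary container round-trips doubles losslessly.
#'
#' @param session A `photolick_session` (or compatible list with `events`,
#'   and optionally `traces`, `raw`, `trials`, `config`, `truth`, `seed`).
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ev <- session$events
  ev_df <- function(times, type)
    data.frame(time_s = as.numeric(times),
               event_type = rep_len(type, length(times)),
               value = rep_len(NA_real_, length(times)))
  events_df <- rbind(
    ev_df(ev$lick_times, "lick"),
    ev_df(ev$stim_times, "stim"),
    ev_df(ev$valve_times, "valve"),
    ev_df(ev$trial_start_times, "trial_start"),
    ev_df(ev$abort_times, "abort"))
  events_df <- events_df[order(events_df$time_s), ]
  arrow::write_feather(events_df, file.path(path, "events.feather"))

  samples <- NULL
  if (!is.null(session$traces)) {
    tr <- session$traces
    samples <- data.frame(
      time_s = tr$t0 + (seq_along(tr$f465) - 1) / tr$fs,
      f465 = tr$f465, f405 = tr$f405)
    if (!is.null(ev$piezo) && length(ev$piezo) == nrow(samples))
      samples$piezo_v <- ev$piezo
  }
  if (!is.null(samples))
    arrow::write_feather(samples, file.path(path, "samples.feather"))
  if (!is.null(session$raw))
    arrow::write_feather(
      data.frame(time_s = session$raw$t0 +
                   (seq_along(session$raw$samples) - 1) / session$raw$fs,
                 detector_v = session$raw$samples),
      file.path(path, "raw.feather"))
  if (!is.null(session$trials))
    arrow::write_feather(as.data.frame(session$trials),
                         file.path(path, "trials.feather"))

  meta <- list(schema_version = SCHEMA_VERSION,
               seed = session$seed,
               session_t_end = ev$session_t_end,
               fs_analysis = if (!is.null(session$traces)) session$traces$fs else 1000,
               config = unclass(session$config),
               truth = unclass(session$truth),
               raw_meta = if (!is.null(session$raw))
                 session$raw[c("fs", "carrier_freqs", "modulation_depth", "t0")]
               else NULL,
               provenance = session$provenance)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. The events table may alternatively be a
#' delimited `events.csv`. A schema-version mismatch is an error naming the
#' expected and found versions; a missing events table is an error.
#'
#' @param path Session directory.
#' @return A `photolick_session`-like list.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("no metadata.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("schema version mismatch: expected ", SCHEMA_VERSION,
         ", found ", meta$schema_version)
  ef <- file.path(path, "events.feather")
  ec <- file.path(path, "events.csv")
  events_df <- if (file.exists(ef)) as.data.frame(arrow::read_feather(ef))
  else if (file.exists(ec)) utils::read.csv(ec)
  else stop("missing events table (events.feather or events.csv) in ", path)

  pick <- function(ty) sort(events_df$time_s[events_df$event_type == ty])
  events <- structure(list(
    lick_times = pick("lick"), stim_times = pick("stim"),
    valve_times = pick("valve"), trial_start_times = pick("trial_start"),
    abort_times = pick("abort"),
    session_t_end = meta$session_t_end, piezo = NULL,
    fs_piezo = meta$fs_analysis), class = "photolick_events")

  traces <- NULL
  sf <- file.path(path, "samples.feather")
  if (file.exists(sf)) {
    s <- as.data.frame(arrow::read_feather(sf))
    if (all(c("f465", "f405") %in% names(s)))
      traces <- structure(list(f465 = s$f465, f405 = s$f405,
                               fs = meta$fs_analysis, t0 = s$time_s[1]),
                          class = "photolick_traces")
    if ("piezo_v" %in% names(s)) events$piezo <- s$piezo_v
  }
  raw <- NULL
  rf <- file.path(path, "raw.feather")
  if (file.exists(rf) && !is.null(meta$raw_meta)) {
    r <- as.data.frame(arrow::read_feather(rf))
    raw <- structure(list(samples = r$detector_v, fs = meta$raw_meta$fs,
                          carrier_freqs = meta$raw_meta$carrier_freqs,
                          modulation_depth = meta$raw_meta$modulation_depth,
                          t0 = meta$raw_meta$t0), class = "photolick_raw")
  }
  trials <- NULL
  tf <- file.path(path, "trials.feather")
  if (file.exists(tf)) {
    trials <- as.data.frame(arrow::read_feather(tf))
    class(trials) <- c("photolick_trials", "data.frame")
  }
  cfg <- meta$config
  config <- if (!is.null(cfg)) do.call(task_config, cfg[
    intersect(names(cfg), names(formals(task_config)))]) else NULL
  truth <- if (!is.null(meta$truth)) do.call(photometry_truth, meta$truth[
    intersect(names(meta$truth), names(formals(photometry_truth)))]) else NULL
  structure(list(events = events, trials = trials, traces = traces, raw = raw,
                 config = config, truth = truth, seed = meta$seed,
                 provenance = meta$provenance),
            class = "photolick_session")
}

#' Run the full analysis pipeline on one synthetic session
#'
#' simulate -> (modulate -> demodulate, optional) -> preprocess -> parse ->
#' quantify every registry window -> learning analysis (whisker sessions
#' with enough trials). Deterministic given `seed`; every stage's
#' parameters are appended to the provenance chain. Output CSVs (per-trial
#' window values, session summary, block series) are written under
#' `out_dir` when given.
#'
#' @param config [task_config()] for the session.
#' @param params [behavior_params()].
#' @param truth [photometry_truth()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory for CSV summaries.
#' @param through_modulation If `TRUE`, analyze traces recovered by
#'   demodulating the modulated detector record rather than the ideal
#'   rendered traces (slower; exercises the acquisition chain).
#' @return A report list: `session`, `prep`, `parsed`, `performance`,
#'   `window_values` (per trial x window), `learning` (or NULL),
#'   `provenance`.
#' @export
run_pipeline <- function(config = task_config("whisker_detection"),
                         params = behavior_params(),
                         truth = photometry_truth(),
                         seed = 1, out_dir = NULL,
                         through_modulation = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  session <- stage("simulate",
    simulate_session(config, params, truth, seed,
                     include_raw = through_modulation))
  traces <- if (through_modulation)
    stage("demodulate", demodulate_session(session$raw))
  else session$traces
  prep <- stage("preprocess", preprocess_session(traces, session$trials))
  parsed <- stage("parse", parse_trials(session$events, config))
  perf <- if (config$task_kind != "free_licking")
    stage("performance", performance_metrics(parsed)) else NULL

  reg <- window_registry()
  wv <- list()
  for (i in seq_len(nrow(reg))) {
    w <- reg$name[i]
    q <- try(quantify_trials(prep, parsed, w), silent = TRUE)
    if (!inherits(q, "try-error")) wv[[w]] <- cbind(window = w, q)
  }
  window_values <- do.call(rbind, wv)
  rownames(window_values) <- NULL

  learning <- NULL
  if (config$task_kind == "whisker_detection" && sum(parsed$stim) >= 51)
    learning <- stage("learning", {
      an <- session_learning_analysis(session)
      an[c("blocks", "dlight_slope", "hit_slope", "learner")]
    })

  provenance <- list(
    package_version = as.character(utils::packageVersion("photolick")),
    seed = seed, config = unclass(config), truth = unclass(truth),
    through_modulation = through_modulation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(window_values,
                     file.path(out_dir, "window_values.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(parsed),
                     file.path(out_dir, "trials.csv"), row.names = FALSE)
    if (!is.null(learning))
      utils::write.csv(learning$blocks,
                       file.path(out_dir, "blocks.csv"), row.names = FALSE)
    summ <- data.frame(
      n_trials = nrow(parsed),
      hit_rate = if (!is.null(perf)) perf$hit_rate else NA,
      fa_rate = if (!is.null(perf)) perf$fa_rate else NA,
      dprime = if (!is.null(perf)) perf$dprime else NA,
      norm_sigma = prep$norm$sigma)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(session = session, prep = prep, parsed = parsed, performance = perf,
       window_values = window_values, learning = learning,
       provenance = provenance)
}
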