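# End-to-end experiment: simulate -> filter -> window -> featurize ->
# train/compare -> metrics + paired t-test, all from one configuration.

#' Experiment configuration
#'
#' Bundles the stage configurations of a full multi-subject experiment. One
#' master `seed` governs every stochastic stage (generation, splits, model
#' fits); re-running with the same configuration reproduces the report.
#'
#' @param synth A [synth_config()].
#' @param bandpass,notch [filter_spec()]s for the two filtering passes.
#' @param window_ms,overlap_fraction Windowing parameters.
#' @param features A [feature_params()].
#' @param a Classes per expert.
#' @param control A [meet_control()].
#' @param split Training fraction for the per-subject evaluation.
#' @param average Metric averaging (`"macro"` or `"weighted"`).
#' @param seed Master seed.
#' @param workdir Optional directory; when given, per-subject recordings and
#'   feature matrices are persisted there as CSV.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              bandpass = filter_spec("bandpass"),
                              notch = filter_spec("notch"),
                              window_ms = 256, overlap_fraction = 0.25,
                              features = feature_params(),
                              a = 2L, control = meet_control(),
                              split = 0.7, average = "macro",
                              seed = 1L, workdir = NULL, verbose = FALSE) {
  structure(list(synth = synth, bandpass = bandpass, notch = notch,
                 window_ms = window_ms, overlap_fraction = overlap_fraction,
                 features = features, a = as.integer(a), control = control,
                 split = split, average = average, seed = as.integer(seed),
                 workdir = workdir, verbose = isTRUE(verbose)),
            class = "experiment_config")
}

#' Build an experiment configuration from a YAML file
#'
#' Reads a YAML document whose top-level keys (`synth`, `bandpass`, `notch`,
#' `windowing`, `features`, `model`, `evaluation`, `io`) override the
#' corresponding [experiment_config()] defaults; omitted keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's (and default) seed.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  take <- function(block, fn) do.call(fn, block %||% list())
  cfg <- experiment_config(
    synth = take(y$synth, synth_config),
    bandpass = take(c(list(kind = "bandpass"), y$bandpass), filter_spec),
    notch = take(c(list(kind = "notch"), y$notch), filter_spec),
    window_ms = y$windowing$window_ms %||% 256,
    overlap_fraction = y$windowing$overlap_fraction %||% 0.25,
    features = take(y$features, feature_params),
    a = y$model$a %||% 2L,
    control = take(y$model$control, meet_control),
    split = y$evaluation$split %||% 0.7,
    average = y$evaluation$average %||% "macro",
    seed = y$seed %||% 1L,
    workdir = y$io$workdir,
    verbose = y$io$verbose %||% FALSE
  )
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$synth$seed <- as.integer(seed)
  }
  cfg
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the full gesture-recognition experiment
#'
#' For every subject: generate (or load) the recording, bandpass and notch
#' filter it, segment it into overlapping windows, extract the 17-feature
#' representation, then fit MEET and the plain extra-trees baseline on a
#' stratified training fraction and score both on the held-out remainder.
#' Finally the per-subject accuracies of the two models are compared with a
#' paired two-tailed t-test.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_report`: `per_subject` (named list of
#'   [compare_models()] results), `accuracy` (subjects x models data.frame,
#'   percent), `t_test` (MEET vs baseline, skipped with a message when fewer
#'   than 2 subjects), `config`, `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  scfg <- config$synth
  scfg$seed <- config$seed
  if (!is.null(config$workdir))
    dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  per_subject <- list()
  acc <- data.frame(subject = character(), meet = numeric(), et = numeric())
  for (s in seq_len(scfg$n_subjects)) {
    sid <- paste0("S", s)
    stage <- "simulate"
    res <- tryCatch({
      log_stage(config$verbose, sid, ": simulate")
      rec <- generate_recording(scfg, s)
      if (!is.null(config$workdir))
        write_recording(rec, file.path(config$workdir, paste0(sid, "_raw.csv")))
      stage <- "preprocess"
      log_stage(config$verbose, sid, ": filter + window")
      rec <- notch_filter(bandpass_filter(rec, config$bandpass), config$notch)
      ws <- segment_windows(rec, config$window_ms, config$overlap_fraction)
      stage <- "featurize"
      log_stage(config$verbose, sid, ": featurize (", length(ws$labels),
                " windows)")
      fm <- featurize(ws, config$features)
      if (!is.null(config$workdir))
        write_features(fm, file.path(config$workdir, paste0(sid, "_features.csv")))
      stage <- "evaluate"
      log_stage(config$verbose, sid, ": train + evaluate")
      compare_models(fm, split = config$split, seed = config$seed + s,
                     a = config$a, control = config$control,
                     average = config$average)
    }, error = function(e)
      stop("stage '", stage, "' failed for subject ", sid, ": ",
           conditionMessage(e), call. = FALSE))
    per_subject[[sid]] <- res
    acc <- rbind(acc, data.frame(
      subject = sid,
      meet = 100 * res$reports$meet$accuracy,
      et = 100 * res$reports$et$accuracy))
  }
  t_test <- NULL
  if (nrow(acc) >= 2L) {
    t_test <- tryCatch(paired_t_test(acc$meet, acc$et), error = function(e) {
      message("t-test skipped: ", conditionMessage(e))
      NULL
    })
  }
  structure(
    list(per_subject = per_subject, accuracy = acc, t_test = t_test,
         config = config,
         provenance = list(seed = config$seed,
                           package_version = as.character(utils::packageVersion("meetsemg")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", nrow(x$accuracy), "subjects (seed",
      x$provenance$seed, ")\n")
  cat("held-out accuracy (%):\n")
  print(x$accuracy, digits = 4, row.names = FALSE)
  if (!is.null(x$t_test)) print(x$t_test)
  invisible(x)
}

#' Serialise an experiment report to JSON
#'
#' Writes the accuracy table, per-subject metric summaries, the t-test and
#' the provenance block (the volatile timestamp is excluded so identical
#' configurations produce identical files).
#'
#' @param report An [run_experiment()] result.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  out <- list(
    schema_version = 1L,
    provenance = report$provenance[c("seed", "package_version")],
    accuracy_percent = report$accuracy,
    t_test = if (!is.null(report$t_test)) unclass(report$t_test),
    per_subject = lapply(report$per_subject, function(r) r$table)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
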