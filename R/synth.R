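# Synthetic sEMG acquisition: block-wise gesture protocol emulation and
# delimited-text recording I/O.

#' Construct a multichannel sEMG recording
#'
#' Container for a labelled multichannel surface EMG recording. The signal is
#' stored as a channels x samples matrix on a millivolt scale, with one
#' gesture-class label per sample (integer codes `1..N`, or `0` for rest).
#'
#' @param signal Numeric matrix, channels x samples.
#' @param sample_rate Sampling rate in samples/second (positive).
#' @param labels Integer vector of per-sample class codes, same length as the
#'   number of samples. Code `0` marks rest.
#' @param subject_id Character scalar identifying the subject.
#' @param class_names Optional character vector naming the class codes
#'   (e.g. `c("TE","ME","FME","FMTE","FMRE","HC")`).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sample_rate, labels, subject_id = "S1",
                          class_names = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != ncol(signal))
    stop("`labels` length (", length(labels), ") must equal the sample count (",
         ncol(signal), ")", call. = FALSE)
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integer class codes", call. = FALSE)
  if (is.null(rownames(signal)))
    rownames(signal) <- paste0("ch", seq_len(nrow(signal)))
  structure(
    list(subject_id = as.character(subject_id), sample_rate = sample_rate,
         signal = signal, labels = labels, class_names = class_names),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> subject", x$subject_id, "\n")
  cat("  channels:", nrow(x$signal), " samples:", ncol(x$signal),
      " (", round(ncol(x$signal) / x$sample_rate, 2), "s @",
      x$sample_rate, "Hz )\n")
  tab <- table(x$labels)
  cat("  labels:", paste0(names(tab), ":", as.integer(tab), collapse = " "), "\n")
  invisible(x)
}

#' Synthetic acquisition configuration
#'
#' Parameters of the synthetic sEMG generator. The defaults emulate a
#' block-wise acquisition protocol: each subject performs `n_classes` gestures
#' for `gesture_duration_s` seconds each, repeating the movement in bursts at
#' an approximate 1-2 s interval, recorded on `n_channels` bipolar channels at
#' `sample_rate` Hz. Each gesture class is given a distinct spectral signature
#' (band-filtered Gaussian noise with a raised-cosine burst envelope) so that
#' classes are separable in both amplitude and spectrum; recordings are
#' contaminated with 50 Hz powerline interference, slow baseline drift and
#' white sensor noise.
#'
#' @param n_subjects Number of subjects the study simulates.
#' @param n_classes Number of gesture classes `N` (>= 2).
#' @param n_channels Number of recording channels `K`.
#' @param sample_rate Sampling rate, samples/second.
#' @param gesture_duration_s Duration of each gesture block, seconds.
#' @param burst_range_s Length-2 numeric: the burst and inter-burst rest
#'   durations are drawn uniformly from this interval (seconds).
#' @param rest_activity Fraction of the burst amplitude still present between
#'   bursts (residual muscle tone); 0 gives fully silent rest intervals.
#' @param class_amplitude Per-class RMS burst amplitude, millivolts. Recycled
#'   to `n_classes`.
#' @param class_center_hz Per-class spectral centre of the burst carrier, Hz.
#'   Must lie strictly below the Nyquist frequency.
#' @param class_bandwidth_hz Per-class carrier bandwidth, Hz.
#' @param powerline_amp Amplitude of the 50 Hz powerline component, mV.
#' @param powerline_hz Powerline frequency, Hz.
#' @param drift_amp Amplitude of the low-frequency (< 5 Hz) baseline drift, mV.
#' @param white_sd Standard deviation of additive white sensor noise, mV.
#' @param rest_label Either `"block"` (inter-burst rest keeps the surrounding
#'   gesture block's label, the default) or `"rest"` (inter-burst samples are
#'   labelled 0 and can be discarded before windowing).
#' @param class_names Optional class-code names.
#' @param seed Integer master seed; a fixed seed yields byte-identical
#'   recordings.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_recording()]
#' @export
synth_config <- function(n_subjects = 4L, n_classes = 6L, n_channels = 2L,
                         sample_rate = 2000L, gesture_duration_s = 40,
                         burst_range_s = c(1, 2), rest_activity = 0.15,
                         class_amplitude = seq(0.8, 1.8, length.out = n_classes),
                         class_center_hz = seq(60, 360, length.out = n_classes),
                         class_bandwidth_hz = 40,
                         powerline_amp = 0.1, powerline_hz = 50,
                         drift_amp = 0.05, white_sd = 0.02,
                         rest_label = c("block", "rest"),
                         class_names = c("TE", "ME", "FME", "FMTE", "FMRE", "HC"),
                         seed = 1L) {
  rest_label <- match.arg(rest_label)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (gesture_duration_s <= 0) stop("`gesture_duration_s` must be > 0", call. = FALSE)
  if (length(burst_range_s) != 2L || any(burst_range_s <= 0) ||
      burst_range_s[1] > burst_range_s[2])
    stop("`burst_range_s` must be an increasing positive pair", call. = FALSE)
  class_amplitude <- rep_len(class_amplitude, n_classes)
  class_center_hz <- rep_len(class_center_hz, n_classes)
  class_bandwidth_hz <- rep_len(class_bandwidth_hz, n_classes)
  nyq <- sample_rate / 2
  if (any(class_center_hz <= 0) || any(class_center_hz >= nyq))
    stop("spectral centres must lie strictly inside (0, sample_rate/2)",
         call. = FALSE)
  if (length(class_names) < n_classes) class_names <- NULL
  structure(
    list(n_subjects = as.integer(n_subjects), n_classes = n_classes,
         n_channels = as.integer(n_channels),
         sample_rate = as.integer(sample_rate),
         gesture_duration_s = gesture_duration_s,
         burst_range_s = burst_range_s,
         rest_activity = rest_activity,
         class_amplitude = class_amplitude,
         class_center_hz = class_center_hz,
         class_bandwidth_hz = class_bandwidth_hz,
         powerline_amp = powerline_amp, powerline_hz = powerline_hz,
         drift_amp = drift_amp, white_sd = white_sd,
         rest_label = rest_label,
         class_names = if (is.null(class_names)) NULL else class_names[seq_len(n_classes)],
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Run `expr` under a private RNG stream; the caller's RNG state is untouched.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Raised-cosine on/off burst envelope over one gesture block.
burst_envelope <- function(n, fs, burst_range, ramp_s = 0.05) {
  env <- numeric(n)
  ramp_n <- max(2L, round(ramp_s * fs))
  ramp_up <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  pos <- round(runif(1, 0.1, 0.4) * fs)  # brief settling before the first burst
  while (pos < n) {
    b <- round(runif(1, burst_range[1], burst_range[2]) * fs)
    g <- round(runif(1, burst_range[1], burst_range[2]) * fs)
    i0 <- pos + 1L
    i1 <- min(pos + b, n)
    if (i1 >= i0) {
      seg <- numeric(i1 - i0 + 1L)
      seg[] <- 1
      k <- min(ramp_n, length(seg))
      seg[seq_len(k)] <- ramp_up[seq_len(k)]
      seg[length(seg) - seq_len(k) + 1L] <- ramp_up[seq_len(k)]
      env[i0:i1] <- pmax(env[i0:i1], seg)
    }
    pos <- pos + b + g
  }
  env
}

# Unit-RMS band-limited Gaussian carrier for one class signature.
class_carrier <- function(n, fs, center, bandwidth) {
  lo <- max(center - bandwidth / 2, 1)
  hi <- min(center + bandwidth / 2, fs / 2 - 1)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic sEMG recording
#'
#' Simulates one subject's session: `n_classes` contiguous gesture blocks of
#' `gesture_duration_s` seconds each. Within a block, the gesture is repeated
#' as bursts of class-signature band-filtered Gaussian noise under a
#' raised-cosine envelope, separated by rest intervals; burst and rest
#' durations are drawn uniformly from `burst_range_s`. Powerline interference,
#' baseline drift and white noise are added on top. Per-sample labels mark
#' block membership (see `rest_label` in [synth_config()]).
#'
#' @param config A [synth_config()].
#' @param subject_index Subject number in `1..n_subjects`.
#' @return A [raw_recording()] with exactly
#'   `n_classes * gesture_duration_s * sample_rate` samples per channel.
#' @examples
#' cfg <- synth_config(n_classes = 2, gesture_duration_s = 2, seed = 7)
#' rec <- generate_recording(cfg, 1)
#' ncol(rec$signal)  # 2 * 2 s * 2000 Hz = 8000 samples
#' @export
generate_recording <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > config$n_subjects)
    stop("`subject_index` must be in 1..n_subjects (= ", config$n_subjects, ")",
         call. = FALSE)
  fs <- config$sample_rate
  n_block <- as.integer(round(config$gesture_duration_s * fs))
  N <- config$n_classes
  K <- config$n_channels
  L <- n_block * N

  with_private_seed(config$seed, {
    subj_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  })
  with_private_seed(subj_seeds[subject_index], {
    sig <- matrix(0, nrow = K, ncol = L,
                  dimnames = list(paste0("ch", seq_len(K)), NULL))
    labels <- integer(L)
    # per-channel gain mimics electrode placement differences
    chan_gain <- runif(K, 0.85, 1.0)
    chan_gain[1] <- 1
    for (cls in seq_len(N)) {
      idx <- ((cls - 1L) * n_block + 1L):(cls * n_block)
      env <- burst_envelope(n_block, fs, config$burst_range_s)
      env_act <- config$rest_activity + (1 - config$rest_activity) * env
      for (k in seq_len(K)) {
        if (config$class_amplitude[cls] != 0) {
          carrier <- class_carrier(n_block, fs, config$class_center_hz[cls],
                                   config$class_bandwidth_hz[cls])
          sig[k, idx] <- chan_gain[k] * config$class_amplitude[cls] *
            env_act * carrier
        }
      }
      labels[idx] <- if (config$rest_label == "block") cls
                     else cls * as.integer(env > 0.5)
    }
    tt <- (seq_len(L) - 1L) / fs
    for (k in seq_len(K)) {
      if (config$powerline_amp != 0)
        sig[k, ] <- sig[k, ] + config$powerline_amp *
          sin(2 * pi * config$powerline_hz * tt + runif(1, 0, 2 * pi))
      if (config$drift_amp != 0)
        sig[k, ] <- sig[k, ] + config$drift_amp *
          sin(2 * pi * runif(1, 0.3, 3) * tt + runif(1, 0, 2 * pi))
      if (config$white_sd != 0)
        sig[k, ] <- sig[k, ] + rnorm(L, sd = config$white_sd)
    }
    raw_recording(sig, fs, labels, subject_id = paste0("S", subject_index),
                  class_names = config$class_names)
  })
}

#' Write / read a recording as delimited text
#'
#' Recordings are exchanged as comma-separated text with a mandatory header
#' `time_s, ch1..chK, label` and one sample per row. The round trip preserves
#' labels and sample count exactly and signal values to at least nine
#' significant digits.
#'
#' @param rec A [raw_recording()].
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [raw_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  L <- ncol(rec$signal)
  dt <- data.table::as.data.table(t(rec$signal))
  data.table::setnames(dt, paste0("ch", seq_len(nrow(rec$signal))))
  dt <- cbind(data.table::data.table(time_s = (seq_len(L) - 1L) / rec$sample_rate),
              dt, data.table::data.table(label = rec$labels))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_recording
#' @param subject_id Subject identifier to attach to the recording read from
#'   `path`.
#' @export
read_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, header = TRUE, fill = FALSE, sep = ","),
      warning = function(w) {
        # fread's own session-cleanup notice is benign; anything else
        # (ragged rows, truncation) is a format defect
        if (grepl("cleaned up", conditionMessage(w), ignore.case = TRUE))
          invokeRestart("muffleWarning")
        stop("malformed recording file '", path, "': ", conditionMessage(w),
             call. = FALSE)
      }),
    error = function(e)
      stop("malformed recording file '", path, "': ", conditionMessage(e),
           call. = FALSE)
  )
  nms <- names(dt)
  if (!"time_s" %in% nms || !"label" %in% nms)
    stop("recording file must have 'time_s' and 'label' columns; got: ",
         paste(nms, collapse = ", "), call. = FALSE)
  ch_cols <- grep("^ch[0-9]+$", nms, value = TRUE)
  if (length(ch_cols) == 0L)
    stop("recording file has no channel columns (ch1..chK)", call. = FALSE)
  ch_cols <- ch_cols[order(as.integer(sub("^ch", "", ch_cols)))]
  for (col in c("time_s", ch_cols, "label")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", col, "' at data line ",
           if (is.na(bad)) "?" else bad + 1L, " of ", path, call. = FALSE)
    }
  }
  t_s <- dt[["time_s"]]
  fs <- if (length(t_s) > 1L) round(1 / median(diff(t_s))) else 1
  sig <- t(as.matrix(dt[, ch_cols, with = FALSE]))
  raw_recording(sig, fs, dt[["label"]],
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
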