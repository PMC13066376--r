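# Preprocessing: bandpass + powerline notch filtering and overlapping-window
# segmentation.

#' Filter specification
#'
#' Describes either the sEMG passband filter (a Butterworth bandpass covering
#' the 10-500 Hz EMG band, 4th order by default) or the powerline notch (a
#' second-order IIR notch, 50 Hz by default). Both are applied
#' forward-backward (zero phase) so that filtering never shifts the signal
#' relative to its per-sample labels.
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low_hz,high_hz Passband edges for the bandpass, Hz.
#' @param notch_hz Notch centre frequency, Hz.
#' @param order Bandpass filter order; must be even (the design uses
#'   `order/2` biquad sections per edge).
#' @param quality_factor Notch sharpness Q; the -3 dB notch width is
#'   `notch_hz / quality_factor`.
#' @param gain Passband amplification `H`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), low_hz = 10,
                        high_hz = 500, notch_hz = 50, order = 4L,
                        quality_factor = 30, gain = 1) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L)
    stop("`order` must be an even integer >= 2", call. = FALSE)
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (quality_factor <= 0) stop("`quality_factor` must be > 0", call. = FALSE)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 notch_hz = notch_hz, order = order,
                 quality_factor = quality_factor, gain = gain),
            class = "filter_spec")
}

#' Digital filter coefficients for a specification
#'
#' Designs the transfer-function coefficients realised by [bandpass_filter()]
#' or [notch_filter()] at a given sampling rate: a Butterworth bandpass of the
#' requested order, or the standard constrained second-order IIR notch. Useful
#' for inspecting the frequency response of the applied filter.
#'
#' @param spec A [filter_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (direct form, descending powers of z^-1).
#' @export
filter_coefficients <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- sample_rate / 2
  if (spec$kind == "bandpass") {
    if (spec$high_hz >= nyq)
      stop("high_hz (", spec$high_hz, ") must be below the Nyquist frequency (",
           nyq, ")", call. = FALSE)
    bf <- signal::butter(spec$order / 2L,
                         c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
    list(b = spec$gain * bf$b, a = bf$a)
  } else {
    if (spec$notch_hz >= nyq)
      stop("notch_hz (", spec$notch_hz, ") must be below the Nyquist frequency (",
           nyq, ")", call. = FALSE)
    # constrained second-order notch: unit gain in the passband, zero at w0,
    # -3 dB bandwidth w0/Q
    w0 <- 2 * pi * spec$notch_hz / sample_rate
    beta <- tan(w0 / (2 * spec$quality_factor))
    g <- 1 / (1 + beta)
    list(b = spec$gain * g * c(1, -2 * cos(w0), 1),
         a = c(1, -2 * g * cos(w0), 2 * g - 1))
  }
}

apply_filter <- function(rec, spec, expected_kind) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!inherits(spec, "filter_spec") || spec$kind != expected_kind)
    stop("`spec` must be a filter_spec of kind '", expected_kind, "'",
         call. = FALSE)
  if (any(!is.finite(rec$signal)))
    stop("signal contains non-finite values; clean or trim before filtering",
         call. = FALSE)
  co <- filter_coefficients(spec, rec$sample_rate)
  out <- rec
  for (k in seq_len(nrow(rec$signal)))
    out$signal[k, ] <- signal::filtfilt(co$b, co$a, rec$signal[k, ])
  out
}

#' Bandpass filter a recording
#'
#' Applies the EMG-band Butterworth bandpass (default 10-500 Hz, order 4)
#' forward and backward (zero phase) to every channel. Length, channel count
#' and labels are unchanged.
#'
#' @param rec A [raw_recording()].
#' @param spec A [filter_spec()] with `kind = "bandpass"`.
#' @return The filtered [raw_recording()].
#' @export
bandpass_filter <- function(rec, spec = filter_spec("bandpass")) {
  apply_filter(rec, spec, "bandpass")
}

#' Notch filter a recording
#'
#' Suppresses powerline interference with a second-order IIR notch (default
#' 50 Hz, Q = 30), applied forward-backward to every channel.
#'
#' @inheritParams bandpass_filter
#' @param spec A [filter_spec()] with `kind = "notch"`.
#' @return The filtered [raw_recording()].
#' @export
notch_filter <- function(rec, spec = filter_spec("notch")) {
  apply_filter(rec, spec, "notch")
}

#' Segment a recording into overlapping windows
#'
#' Cuts each channel into fixed-length windows of `window_ms` milliseconds
#' with fractional overlap `overlap_fraction` between consecutive windows.
#' With the defaults at 2000 Hz this gives W = 512-sample windows advancing by
#' S = 384 samples, so consecutive windows share 128 samples. Window `i`
#' (0-based) spans samples `[i*S, i*S + W)`; trailing samples that do not fill
#' a complete window are dropped. Each window is labelled by the majority of
#' its per-sample labels, ties broken toward the lower class code.
#'
#' @param rec A [raw_recording()].
#' @param window_ms Window length, milliseconds.
#' @param overlap_fraction Fraction of each window shared with its
#'   predecessor, in `[0, 1)`.
#' @return An object of class `window_set`: a list with `windows` (a
#'   W x K x n_windows array), `labels`, `starts` (0-based sample offsets),
#'   `window_len`, `step`, `sample_rate`, `subject_id`.
#' @examples
#' rec <- generate_recording(synth_config(n_classes = 2, gesture_duration_s = 2))
#' ws <- segment_windows(rec)
#' ws$window_len; ws$step; length(ws$labels)
#' @export
segment_windows <- function(rec, window_ms = 256, overlap_fraction = 0.25) {
  stopifnot(inherits(rec, "raw_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must lie in [0, 1)", call. = FALSE)
  W <- as.integer(round(window_ms * rec$sample_rate / 1000))
  S <- as.integer(round(W * (1 - overlap_fraction)))
  if (W < 2L) stop("window too short: W = ", W, " samples", call. = FALSE)
  L <- ncol(rec$signal)
  if (L < W)
    stop("signal too short to window: ", L, " samples < minimum ", W,
         call. = FALSE)
  K <- nrow(rec$signal)
  n_win <- (L - W) %/% S + 1L
  starts <- (seq_len(n_win) - 1L) * S           # 0-based
  win <- array(NA_real_, dim = c(W, K, n_win))
  labels <- integer(n_win)
  for (i in seq_len(n_win)) {
    idx <- (starts[i] + 1L):(starts[i] + W)
    win[, , i] <- t(rec$signal[, idx, drop = FALSE])
    labels[i] <- majority_label(rec$labels[idx])
  }
  structure(
    list(windows = win, labels = labels, starts = starts, window_len = W,
         step = S, sample_rate = rec$sample_rate, subject_id = rec$subject_id),
    class = "window_set"
  )
}

# Majority per-sample label; ties broken toward the lower class code.
majority_label <- function(lab) {
  tab <- table(lab)
  codes <- as.integer(names(tab))
  codes[order(-as.integer(tab), codes)][1]
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> subject", x$subject_id, "\n")
  cat("  windows:", dim(x$windows)[3], "of", x$window_len, "samples x",
      dim(x$windows)[2], "channels, step", x$step, "\n")
  invisible(x)
}
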