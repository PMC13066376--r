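# The 17-feature window representation: 11 time-domain + 6 frequency-domain
# features per window and channel.

#' Feature-extraction parameters
#'
#' Thresholds and spectral options for the window features. Threshold values
#' are absolute amplitudes on the signal's own scale (millivolts here).
#'
#' @param zc_threshold Minimum amplitude change for a sign change to count as
#'   a zero crossing.
#' @param wamp_threshold Minimum successive-sample amplitude change counted by
#'   the Willison amplitude.
#' @param myop_threshold Activation threshold of the myopulse percentage rate.
#' @param log_epsilon Floor added inside logarithms to keep the log detector
#'   finite on zero samples.
#' @param psd_method Power spectral density estimator: `"periodogram"`
#'   (rectangular window, the default) or `"welch"` (Hann-windowed averaged
#'   segments, length `W/4`, half overlapping).
#' @param fr_band_split_hz Boundary between the low and high band of the
#'   frequency ratio, Hz.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(zc_threshold = 0, wamp_threshold = 0.01,
                           myop_threshold = 0.016, log_epsilon = 1e-12,
                           psd_method = c("periodogram", "welch"),
                           fr_band_split_hz = 250) {
  psd_method <- match.arg(psd_method)
  if (zc_threshold < 0 || wamp_threshold < 0 || myop_threshold < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  structure(list(zc_threshold = zc_threshold, wamp_threshold = wamp_threshold,
                 myop_threshold = myop_threshold, log_epsilon = log_epsilon,
                 psd_method = psd_method, fr_band_split_hz = fr_band_split_hz),
            class = "feature_params")
}

#' Canonical feature names
#'
#' The fixed per-channel feature order used throughout the package: eleven
#' time-domain features followed by six frequency-domain features.
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c("MAV", "VAR", "DASDV", "WL", "IEMG", "LOG", "RMS", "AAC",
    "ZC", "WAMP", "MYOP", "TTP", "FR", "MDF", "PKF", "MNF", "MNP")
}

#' Time-domain window features
#'
#' Computes the eleven time-domain features of a single-channel window:
#' mean absolute value (MAV), variance about the mean with denominator W-1
#' (VAR), difference absolute standard deviation value (DASDV), waveform
#' length (WL), integrated EMG (IEMG), log detector (LOG), root mean square
#' (RMS), average amplitude change (AAC), zero crossings above the
#' `zc_threshold` (ZC), Willison amplitude at `wamp_threshold` (WAMP) and
#' myopulse percentage rate at `myop_threshold` (MYOP).
#'
#' @param x Numeric vector, one window of one channel (length >= 2, finite).
#' @param params A [feature_params()].
#' @return Named numeric vector of length 11.
#' @examples
#' time_domain_features(c(1, -1, 1, -1))
#' @export
time_domain_features <- function(x, params = feature_params()) {
  if (length(x) < 2L)
    stop("window must contain at least 2 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop("window contains non-finite values", call. = FALSE)
  W <- length(x)
  dx <- diff(x)
  wl <- sum(abs(dx))
  c(MAV   = mean(abs(x)),
    VAR   = stats::var(x),
    DASDV = sqrt(sum(dx^2) / (W - 1)),
    WL    = wl,
    IEMG  = sum(abs(x)),
    LOG   = exp(mean(log(abs(x) + params$log_epsilon))),
    RMS   = sqrt(mean(x^2)),
    AAC   = wl / (W - 1),
    ZC    = sum(x[-W] * x[-1] < 0 & abs(dx) >= params$zc_threshold),
    WAMP  = sum(abs(dx) >= params$wamp_threshold),
    MYOP  = mean(abs(x) >= params$myop_threshold))
}

# One-sided power spectrum normalised so that sum(P) = mean(x^2) (Parseval).
power_spectrum <- function(x, sample_rate, method = "periodogram") {
  W <- length(x)
  if (method == "periodogram") {
    X <- fft(x)
    nb <- W %/% 2L + 1L
    P <- Mod(X[seq_len(nb)])^2 / W^2
    dbl <- 2:(nb - if (W %% 2L == 0L) 1L else 0L)
    P[dbl] <- 2 * P[dbl]
    list(freq = (seq_len(nb) - 1L) * sample_rate / W, power = P)
  } else {
    seg <- max(8L, 2L^floor(log2(W / 4)))
    step <- seg %/% 2L
    h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1L) / (seg - 1L))
    u <- sum(h^2) / seg
    starts <- seq(1L, W - seg + 1L, by = step)
    nb <- seg %/% 2L + 1L
    P <- numeric(nb)
    for (s in starts) {
      X <- fft(x[s:(s + seg - 1L)] * h)
      P <- P + Mod(X[seq_len(nb)])^2 / (seg^2 * u)
    }
    P <- P / length(starts)
    dbl <- 2:(nb - if (seg %% 2L == 0L) 1L else 0L)
    P[dbl] <- 2 * P[dbl]
    list(freq = (seq_len(nb) - 1L) * sample_rate / seg, power = P)
  }
}

#' Frequency-domain window features
#'
#' Computes the six spectral features of a single-channel window from a
#' one-sided power spectrum `P_j` at frequencies `f_j` (normalised so that
#' `sum(P) = mean(x^2)`): total power (TTP), frequency ratio between the
#' low and high band around `fr_band_split_hz` (FR), median frequency (MDF,
#' the smallest frequency accumulating half the total power), peak frequency
#' (PKF), mean frequency (MNF) and mean power (MNP). For an all-zero window
#' the power ratios are undefined; FR, MDF, PKF and MNF return the documented
#' sentinel 0 with a warning.
#'
#' @param x Numeric vector, one window of one channel (length >= 8).
#' @param sample_rate Sampling rate, Hz.
#' @param params A [feature_params()].
#' @return Named numeric vector of length 6.
#' @export
frequency_domain_features <- function(x, sample_rate,
                                      params = feature_params()) {
  if (length(x) < 8L)
    stop("window must contain at least 8 samples for spectral features",
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("window contains non-finite values", call. = FALSE)
  ps <- power_spectrum(x, sample_rate, params$psd_method)
  P <- ps$power; f <- ps$freq
  ttp <- sum(P)
  if (ttp == 0) {
    warning("all-zero window: spectral ratios undefined, returning 0")
    return(c(TTP = 0, FR = 0, MDF = 0, PKF = 0, MNF = 0, MNP = 0))
  }
  hi <- sum(P[f > params$fr_band_split_hz])
  fr <- if (hi > 0) sum(P[f <= params$fr_band_split_hz]) / hi else {
    warning("no power above the frequency-ratio split: FR set to 0")
    0
  }
  c(TTP = ttp,
    FR  = fr,
    MDF = f[which(cumsum(P) >= ttp / 2)[1]],
    PKF = f[which.max(P)],
    MNF = sum(f * P) / ttp,
    MNP = mean(P))
}

#' Extract the feature matrix of a window set
#'
#' Computes all 17 features for every window and channel. Row `i` is the
#' concatenation over channels of the 17 features of window `i`; columns are
#' named `ch<k>_<FEATURE>` in the canonical order of [feature_names()].
#'
#' @param ws A [segment_windows()] result.
#' @param params A [feature_params()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (n_windows x 17*K numeric matrix), `labels`, `feature_names` (the
#'   column names), `params`, `subject_id`.
#' @export
featurize <- function(ws, params = feature_params()) {
  stopifnot(inherits(ws, "window_set"))
  n <- dim(ws$windows)[3]
  K <- dim(ws$windows)[2]
  if (n == 0L) stop("empty window set", call. = FALSE)
  cols <- as.vector(vapply(seq_len(K), function(k)
    paste0("ch", k, "_", feature_names()), character(17L)))
  vals <- matrix(NA_real_, nrow = n, ncol = 17L * K,
                 dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    row <- tryCatch(
      unlist(lapply(seq_len(K), function(k) {
        x <- ws$windows[, k, i]
        c(time_domain_features(x, params),
          frequency_domain_features(x, ws$sample_rate, params))
      }), use.names = FALSE),
      error = function(e)
        stop("feature extraction failed at window ", i, ": ",
             conditionMessage(e), call. = FALSE)
    )
    vals[i, ] <- row
  }
  structure(list(values = vals, labels = ws$labels, feature_names = cols,
                 params = params, subject_id = ws$subject_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "windows x", ncol(x$values),
      "features (subject", x$subject_id, ")\n")
  invisible(x)
}

#' Convert a feature matrix to a data frame
#'
#' @param x A [featurize()] result.
#' @param ... Unused.
#' @return A data.frame with `subject`, `window_id` (0-based), `label` and one
#'   column per feature.
#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(data.frame(subject = x$subject_id,
                   window_id = seq_len(nrow(x$values)) - 1L,
                   label = x$labels),
        as.data.frame(x$values))
}

#' Write / read a feature matrix as CSV
#'
#' @param fm A [featurize()] result.
#' @param path File path.
#' @export
write_features <- function(fm, path) {
  data.table::fwrite(as.data.frame(fm), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("subject", "window_id", "label")
  if (!all(need %in% names(dt)))
    stop("feature file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  fcols <- setdiff(names(dt), need)
  structure(list(values = as.matrix(dt[, fcols, with = FALSE]),
                 labels = as.integer(dt[["label"]]),
                 feature_names = fcols, params = NULL,
                 subject_id = as.character(dt[["subject"]][1])),
            class = "feature_matrix")
}
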