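# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the feature/filter/fusion
# definitions and deliberately share no code with the package internals.

# Naive per-definition time-domain features.
naive_time_features <- function(x, zc_th = 0, wamp_th = 0.01,
                                myop_th = 0.016, eps = 1e-12) {
  W <- length(x)
  m <- sum(x) / W
  v <- 0
  for (i in 1:W) v <- v + (x[i] - m)^2
  v <- v / (W - 1)
  sumsq_d <- 0; wl <- 0; zc <- 0; wamp <- 0
  for (i in 1:(W - 1)) {
    d <- x[i + 1] - x[i]
    sumsq_d <- sumsq_d + d^2
    wl <- wl + abs(d)
    if (x[i] * x[i + 1] < 0 && abs(d) >= zc_th) zc <- zc + 1
    if (abs(d) >= wamp_th) wamp <- wamp + 1
  }
  logsum <- 0; abssum <- 0; sqsum <- 0; myop <- 0
  for (i in 1:W) {
    logsum <- logsum + log(abs(x[i]) + eps)
    abssum <- abssum + abs(x[i])
    sqsum <- sqsum + x[i]^2
    if (abs(x[i]) >= myop_th) myop <- myop + 1
  }
  c(MAV = abssum / W, VAR = v, DASDV = sqrt(sumsq_d / (W - 1)), WL = wl,
    IEMG = abssum, LOG = exp(logsum / W), RMS = sqrt(sqsum / W),
    AAC = wl / (W - 1), ZC = zc, WAMP = wamp, MYOP = myop / W)
}

# Direct-summation DFT (no fft) -> one-sided spectrum with sum(P) = mean(x^2).
naive_freq_features <- function(x, fs, split_hz = 250) {
  W <- length(x)
  nb <- W %/% 2 + 1
  P <- numeric(nb)
  for (j in 0:(nb - 1)) {
    re <- 0; im <- 0
    for (t in 0:(W - 1)) {
      re <- re + x[t + 1] * cos(2 * pi * j * t / W)
      im <- im - x[t + 1] * sin(2 * pi * j * t / W)
    }
    P[j + 1] <- (re^2 + im^2) / W^2
    if (j > 0 && !(W %% 2 == 0 && j == W %/% 2)) P[j + 1] <- 2 * P[j + 1]
  }
  f <- (0:(nb - 1)) * fs / W
  ttp <- sum(P)
  if (ttp == 0) return(c(TTP = 0, FR = 0, MDF = 0, PKF = 0, MNF = 0, MNP = 0))
  cum <- 0; mdf <- f[nb]
  for (j in 1:nb) {
    cum <- cum + P[j]
    if (cum >= ttp / 2) { mdf <- f[j]; break }
  }
  c(TTP = ttp,
    FR = sum(P[f <= split_hz]) / sum(P[f > split_hz]),
    MDF = mdf, PKF = f[which.max(P)], MNF = sum(f * P) / ttp, MNP = mean(P))
}

# Analytic magnitude response of direct-form coefficients at frequency f.
response_magnitude <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# Brute-force window starts: advance a cursor until a window no longer fits.
brute_force_starts <- function(L, W, S) {
  starts <- integer(0)
  s <- 0
  while (s + W <= L) {
    starts <- c(starts, s)
    s <- s + S
  }
  starts
}

# Brute-force fusion: enumerate every product and pick the winning class,
# ties toward the lowest code.
brute_force_fuse <- function(Z, M, class_order) {
  best <- -Inf; win <- Inf
  for (j in seq_along(Z)) {
    p <- Z[j] * M[j]
    if (p > best || (p == best && class_order[j] < win)) {
      best <- p
      win <- class_order[j]
    }
  }
  win
}

# Small, fast generator configuration for model-level tests.
quick_config <- function(n_classes = 6, duration = 8, seed = 42, ...) {
  synth_config(n_subjects = 1, n_classes = n_classes,
               gesture_duration_s = duration, seed = seed, ...)
}

# Recording wrapper around a plain single/multi-channel signal matrix.
as_recording <- function(x, fs = 2000, labels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  raw_recording(x, fs, labels %||% rep(1L, ncol(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
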