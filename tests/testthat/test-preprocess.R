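# Filtering (frequency-response oracles) and overlapping-window segmentation.

fs <- 2000
tt <- (0:19999) / fs
mid <- 8000:12000  # steady-state region, clear of filter transients

test_that("bandpass response meets the passband and stopband specs", {
  co <- filter_coefficients(filter_spec("bandpass"), fs)
  # flat to within 1 dB across [2*low, high/1.5]
  for (f in seq(20, 500 / 1.5, by = 10)) {
    db <- 20 * log10(response_magnitude(co$b, co$a, f, fs))
    expect_lt(abs(db), 1, label = paste("dB deviation at", f, "Hz"))
  }
  # >= 20 dB down at 2 Hz, monotone decay outside the passband
  expect_lt(20 * log10(response_magnitude(co$b, co$a, 2, fs)), -20)
  lo <- vapply(c(8, 6, 4, 2), function(f)
    response_magnitude(co$b, co$a, f, fs), 0)
  expect_true(all(diff(lo) < 0))
  hi <- vapply(c(520, 600, 700, 900), function(f)
    response_magnitude(co$b, co$a, f, fs), 0)
  expect_true(all(diff(hi) < 0))
})

test_that("bandpass attenuates DC and passes an in-band tone", {
  dc <- bandpass_filter(as_recording(rep(1, 20000), fs))
  expect_lt(mean(abs(dc$signal[1, mid])), 1e-6)
  tone <- bandpass_filter(as_recording(sin(2 * pi * 100 * tt), fs))
  amp <- max(abs(tone$signal[1, mid]))
  expect_lt(abs(20 * log10(amp)), 1)
  slow <- bandpass_filter(as_recording(sin(2 * pi * 2 * tt), fs))
  expect_lt(max(abs(slow$signal[1, mid])), 10^(-20 / 20))
})

test_that("notch suppresses 50 Hz and leaves neighbours untouched", {
  co <- filter_coefficients(filter_spec("notch"), fs)
  expect_lt(response_magnitude(co$b, co$a, 50, fs), 1e-6)
  for (f in c(30, 70, 100, 200)) {
    db <- 20 * log10(response_magnitude(co$b, co$a, f, fs))
    expect_lt(abs(db), 1, label = paste("dB deviation at", f, "Hz"))
  }
  hum <- notch_filter(as_recording(sin(2 * pi * 50 * tt), fs))
  expect_lt(max(abs(hum$signal[1, mid])), 0.1)
  tone <- notch_filter(as_recording(sin(2 * pi * 100 * tt), fs))
  expect_lt(abs(20 * log10(max(abs(tone$signal[1, mid])))), 1)
  zero <- notch_filter(as_recording(rep(0, 1000), fs))
  expect_true(all(zero$signal == 0))
})

test_that("filters are linear and shape-preserving", {
  set.seed(31)
  x <- rnorm(4000); y <- rnorm(4000)
  a <- 2.5; b <- -0.7
  for (flt in list(bandpass_filter, notch_filter)) {
    lhs <- flt(as_recording(a * x + b * y, fs))$signal[1, ]
    rhs <- a * flt(as_recording(x, fs))$signal[1, ] +
      b * flt(as_recording(y, fs))$signal[1, ]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  rec <- generate_recording(quick_config(n_classes = 2, duration = 1), 1)
  out <- notch_filter(bandpass_filter(rec))
  expect_identical(dim(out$signal), dim(rec$signal))
  expect_identical(out$labels, rec$labels)
})

test_that("invalid filter configurations and inputs are rejected", {
  expect_error(filter_coefficients(filter_spec("bandpass", high_hz = 1100), fs),
               "Nyquist")
  expect_error(filter_coefficients(filter_spec("notch", notch_hz = 1000), fs),
               "Nyquist")
  expect_error(filter_spec("bandpass", order = 3), "even")
  expect_error(filter_spec("bandpass", low_hz = 500, high_hz = 10), "low_hz")
  bad <- as_recording(c(rnorm(100), NaN, rnorm(100)), fs)
  expect_error(bandpass_filter(bad), "non-finite")
  expect_error(notch_filter(as_recording(rnorm(10), fs),
                            filter_spec("bandpass")), "kind 'notch'")
})

test_that("default windowing of a full-length recording gives 512/384/1249", {
  L <- 480000
  rec <- as_recording(matrix(0, 1, L), fs)
  ws <- segment_windows(rec)
  expect_equal(ws$window_len, 512)
  expect_equal(ws$step, 384)
  starts <- brute_force_starts(L, 512, 384)
  expect_equal(dim(ws$windows)[3], length(starts))
  expect_equal(length(starts), 1249)
  expect_equal(ws$starts, starts)
})

test_that("window count and coverage laws hold across random geometries", {
  set.seed(7)
  for (rep in 1:25) {
    L <- sample(600:5000, 1)
    window_ms <- sample(50:300, 1)
    overlap <- runif(1, 0, 0.9)
    W <- round(window_ms * fs / 1000)
    S <- round(W * (1 - overlap))
    if (S < 1 || L < W) next
    rec <- as_recording(matrix(rnorm(L), 1), fs)
    ws <- segment_windows(rec, window_ms, overlap)
    starts <- brute_force_starts(L, W, S)
    expect_equal(ws$starts, starts)
    expect_equal(dim(ws$windows)[3], floor((L - W) / S) + 1)
    expect_true(all(diff(ws$starts) == S))
    expect_lte(max(ws$starts) + W, L)       # no window exceeds the signal
    expect_gt(max(ws$starts) + S + W, L)    # no further window would fit
    # window content matches the half-open [i*S, i*S + W) slice
    i <- sample(seq_along(starts), 1)
    expect_identical(ws$windows[, 1, i],
                     rec$signal[1, (starts[i] + 1):(starts[i] + W)])
  }
})

test_that("consecutive default windows share exactly 128 samples", {
  rec <- as_recording(matrix(rnorm(2000), 1), fs)
  ws <- segment_windows(rec)
  expect_equal(ws$window_len - ws$step, 128)
  expect_identical(ws$windows[(ws$step + 1):ws$window_len, 1, 1],
                   ws$windows[1:(ws$window_len - ws$step), 1, 2])
})

test_that("windowing boundaries and errors", {
  expect_equal(dim(segment_windows(as_recording(rnorm(512), fs))$windows)[3], 1)
  expect_error(segment_windows(as_recording(rnorm(511), fs)),
               "too short.*512")
  expect_error(segment_windows(as_recording(rnorm(1000), fs),
                               overlap_fraction = 1), "overlap_fraction")
  expect_error(segment_windows(as_recording(rnorm(1000), fs),
                               overlap_fraction = -0.1), "overlap_fraction")
})

test_that("window labels are the majority vote, ties to the lower code", {
  x <- rnorm(512)
  lab <- c(rep(2L, 200), rep(1L, 312))
  ws <- segment_windows(as_recording(x, fs, lab))
  expect_equal(ws$labels, 1L)
  lab_tie <- c(rep(5L, 256), rep(3L, 256))
  expect_equal(segment_windows(as_recording(x, fs, lab_tie))$labels, 3L)
})
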