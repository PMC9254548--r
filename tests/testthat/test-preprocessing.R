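test_that("Laplacian filter removes common-mode signals and matches a loop oracle", {
  mont <- sensorimotor_montage()
  rate <- 512
  n <- 256
  # identical signal on all channels -> zero wherever a neighbor exists
  common <- matrix(rep(sin(2 * pi * 7 * (1:n) / rate), 14), n)
  rec <- eeg_recording(common, rate, mont$channels)
  out <- laplacian_filter(rec, mont)
  has_nb <- lengths(mont$neighbors) > 0
  expect_true(all(abs(out$data[, has_nb]) < 1e-12))

  # impulse on Cz only: Cz passes through, each neighbor of Cz outputs
  # -impulse / |its neighbor set|
  imp <- matrix(0, n, 14, dimnames = list(NULL, mont$channels))
  imp[10, "Cz"] <- 1
  out <- laplacian_filter(eeg_recording(imp, rate, mont$channels), mont)
  expect_equal(unname(out$data[10, "Cz"]), 1)
  for (nb in mont$neighbors[["Cz"]]) {
    expect_equal(unname(out$data[10, nb]), -1 / length(mont$neighbors[[nb]]))
  }

  # random input equals a direct center-minus-neighbor-mean loop
  set.seed(1)
  x <- matrix(rnorm(n * 14), n, dimnames = list(NULL, mont$channels))
  out <- laplacian_filter(eeg_recording(x, rate, mont$channels), mont)
  for (ch in mont$channels) {
    nb <- mont$neighbors[[ch]]
    expected <- if (length(nb)) {
      x[, ch] - rowMeans(x[, nb, drop = FALSE])
    } else {
      x[, ch]
    }
    expect_equal(unname(out$data[, ch]), unname(expected))
  }
})

test_that("Laplacian filter is linear and preserves extra channels", {
  mont <- sensorimotor_montage()
  chans <- c(mont$channels, eog_channels())
  set.seed(2)
  X <- matrix(rnorm(128 * 16), 128, dimnames = list(NULL, chans))
  Y <- matrix(rnorm(128 * 16), 128, dimnames = list(NULL, chans))
  f <- function(m) laplacian_filter(eeg_recording(m, 512, chans), mont)$data
  expect_equal(f(2 * X + 3 * Y), 2 * f(X) + 3 * f(Y))
  expect_equal(f(X)[, eog_channels()], X[, eog_channels()])
})

test_that("sliding window count follows floor((duration - length)/hop) + 1", {
  mk <- function(sec) eeg_recording(matrix(0, round(sec * 512), 1), 512, "Cz")
  expect_equal(nrow(sliding_windows(mk(1))), 1)
  expect_equal(nrow(sliding_windows(mk(2))), 17)
  for (sec in c(1.5, 3.27, 5)) {
    w <- sliding_windows(mk(sec))
    expect_equal(nrow(w), floor((sec - 1) / 0.0625) + 1)
    expect_true(all(w$end <= round(sec * 512)))
    # windows jointly cover every sample index
    covered <- sort(unique(unlist(Map(seq, w$start, w$end))))
    expect_true(all(seq_len(max(w$end)) %in% covered))
  }
  expect_warning(w0 <- sliding_windows(mk(0.5)), "shorter")
  expect_equal(nrow(w0), 0)
  expect_true(isTRUE(attr(w0, "too_short")))
})

test_that("Welch PSD: zero input, sinusoid bin location, Parseval, offset invariance", {
  rate <- 512
  t <- (0:(rate - 1)) / rate
  zero <- welch_psd(matrix(0, rate, 2), rate)
  expect_true(all(zero == 0))
  expect_equal(diff(attr(zero, "freqs"))[1], 2)

  # unit 20 Hz sinusoid peaks in the 20 Hz bin
  psd <- welch_psd(matrix(sin(2 * pi * 20 * t), rate, 1), rate)
  expect_equal(attr(psd, "freqs")[which.max(psd)], 20)

  # Parseval: integrated PSD approximates the variance (white noise,
  # averaged over 100 windows)
  set.seed(3)
  ratio <- replicate(100, {
    x <- rnorm(rate)
    sum(welch_psd(matrix(x, rate, 1), rate)) * 2 / var(x)
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)

  # adding a constant offset leaves the PSD unchanged (mean removal)
  set.seed(4)
  x <- matrix(rnorm(rate), rate, 1)
  expect_equal(welch_psd(x, rate), welch_psd(x + 42, rate))

  expect_error(welch_psd(matrix(NA_real_, rate, 1), rate), "NaN")
})

test_that("band-pass filter: DC rejection, pass-band gain, stop-band attenuation", {
  rate <- 512
  n <- rate * 8
  t <- (0:(n - 1)) / rate
  mk <- function(x) eeg_recording(matrix(x, n, 1), rate, "Cz")
  mid <- (rate * 2):(n - rate * 2)      # avoid edges

  dc <- bandpass(mk(rep(5, n)), c(8, 12))
  expect_lt(max(abs(dc$data[mid, 1])), 1e-5)

  # 10 Hz sine through the mu band: unit gain, zero phase lag
  s10 <- sin(2 * pi * 10 * t)
  out <- bandpass(mk(s10), c(8, 12))$data[, 1]
  gain <- sqrt(mean(out[mid]^2) / mean(s10[mid]^2))
  expect_lt(abs(gain - 1), 0.02)
  lag <- which.max(ccf(out[mid], s10[mid], lag.max = 10, plot = FALSE)$acf)
  expect_equal(lag, 11)                  # zero-lag bin of ccf

  # 30 Hz sine through the mu band: > 20 dB attenuation
  s30 <- sin(2 * pi * 30 * t)
  out30 <- bandpass(mk(s30), c(8, 12))$data[, 1]
  att <- 20 * log10(sqrt(mean(out30[mid]^2) / mean(s30[mid]^2)))
  expect_lt(att, -20)

  expect_error(bandpass(mk(s10), c(12, 8)), "invalid band")
})

test_that("psd_frames agrees with per-window welch_psd and labels windows correctly", {
  s <- fixture_session()
  rec <- s$recording
  fr <- psd_frames(rec, stride = 7, max_freq = 48)
  lap <- laplacian_filter(rec)
  mont <- sensorimotor_montage()
  wins <- sliding_windows(lap)
  wins <- wins[seq(1, nrow(wins), by = 7), ]
  for (i in c(1, 11)) {
    direct <- welch_psd(lap$data[wins$start[i]:wins$end[i], mont$channels],
                        rec$rate)
    keep <- attr(direct, "freqs") <= 48
    expect_equal(fr$power[i, , ], unname(direct[, keep]), tolerance = 1e-12)
  }
  fr <- label_windows(fr, s$trials)
  lab <- which(!is.na(fr$labels))
  # labeled windows lie fully inside a trial's task interval
  for (i in sample(lab, 5)) {
    tr <- s$trials[fr$times[i] + 1e-9 >= s$trials$onset + 0.5 &
                     fr$times[i] + 1 <= s$trials$onset + s$trials$duration +
                     1e-9, ]
    expect_equal(nrow(tr), 1)
    expect_equal(as.character(fr$labels[i]), tr$label)
  }
})
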