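# Shared fixtures, generated in code and memoized for the test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# random SPD matrix of dimension d with moderate conditioning
random_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) / d + diag(0.5, d)
  S * scale
}

# a short flat recording with all 16 channels
flat_recording <- function(seconds = 4, rate = 512) {
  mont <- sensorimotor_montage()
  chans <- c(mont$channels, eog_channels())
  eeg_recording(matrix(0, seconds * rate, length(chans)), rate, chans)
}

# a single synthetic session at full separability, cached
fixture_session <- function() {
  memo("session_full", simulate_session(
    simulation_config(seed = 401, blink_rate = 0, saccade_rate = 0), 1))
}

# labeled PSD frame of the cached session
fixture_frame <- function() {
  memo("frame_full", {
    s <- fixture_session()
    label_windows(psd_frames(s$recording, stride = 4), s$trials)
  })
}

# a decoder fitted on the cached session (beta-band features)
fixture_model <- function() {
  memo("model_full", {
    fr <- fixture_frame()
    ranked <- cva_rank_features(fr)
    mask <- select_features(ranked, 6)
    grid <- feature_grid(fr)
    keep <- which(!is.na(fr$labels))
    cols <- match(paste(mask$channel, mask$freq),
                  paste(grid$channel, grid$freq))
    X <- psd_features(fr, grid)[keep, cols]
    fit_gaussian_classifier(X, droplevels(factor(fr$labels[keep])),
                            mask = mask[, c("channel", "freq")])
  })
}
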