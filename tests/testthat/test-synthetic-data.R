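test_that("simulation is byte-identical under a fixed seed and differs across seeds", {
  cfg <- simulation_config(seed = 404)
  a <- simulate_session(cfg, 2)
  b <- simulate_session(cfg, 2)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$blinks, b$truth$blinks)
  c <- simulate_session(simulation_config(seed = 405), 2)
  expect_false(identical(a$recording$data, c$recording$data))
  d <- simulate_session(cfg, 3)
  expect_false(identical(a$recording$data, d$recording$data))
})

test_that("trial structure follows the calibration protocol", {
  cfg <- simulation_config(seed = 406)
  s <- simulate_session(cfg, 1)
  tr <- s$trials
  expect_equal(nrow(tr), 30)
  expect_equal(as.vector(table(tr$label)[mi_classes()]), c(15L, 15L))
  expect_true(all(tr$duration >= 4.5 & tr$duration <= 5.5))
  expect_true(all(diff(tr$onset) > 0))
  expect_true(all(tr$onset + tr$duration <= recording_duration(s$recording)))
})

test_that("programmed class contrast controls decodability: chance at g = 0, high at depth 0.8", {
  fr <- fixture_frame()        # full separability session
  m <- fixture_model()
  perf <- decoding_performance(fr, m)
  expect_gt(perf$accuracy, 90)

  cfg0 <- simulation_config(seed = 407, blink_rate = 0, saccade_rate = 0,
                            separability = trajectory_constant(0))
  s0 <- simulate_session(cfg0, 1)
  fr0 <- label_windows(psd_frames(s0$recording, stride = 4), s0$trials)
  p0 <- decoding_performance(fr0, m)
  n_acc <- p0$n_accepted
  # chance level within a binomial 99% CI
  expect_lt(abs(p0$accuracy / 100 - 0.5), 2.58 * sqrt(0.25 / n_acc) + 0.02)
})

test_that("generated band-power contrast at modulated channels matches the programmed depth", {
  depth <- 0.6
  cfg <- simulation_config(
    seed = 408, blink_rate = 0, saccade_rate = 0,
    topography = data.frame(class = "both_hands", channel = "C3",
                            band = "beta", depth = depth))
  # pool two runs (60 trials) for a stable estimate
  num <- den <- c()
  for (r in 1:2) {
    s <- simulate_session(cfg, r)
    fr <- label_windows(psd_frames(s$recording, stride = 2,
                                   laplacian = FALSE), s$trials)
    bp <- band_power(fr, band_definition("beta"))
    keep <- which(!is.na(fr$labels))
    num <- c(num, bp[keep[fr$labels[keep] == "both_hands"], "C3"])
    den <- c(den, bp[keep[fr$labels[keep] == "both_feet"], "C3"])
  }
  # ERD suppresses carrier power by `depth`; the pink background adds a
  # class-independent floor, so compare after subtracting the floor
  # estimated from a zero-carrier channel pair is overkill here: the beta
  # carrier dominates C3 band power, so the ratio reflects the depth with
  # a small upward bias. Require agreement within 5 percentage points
  # after accounting for the measured background share.
  ratio <- mean(num) / mean(den)
  cfg_ref <- simulation_config(seed = 408, blink_rate = 0, saccade_rate = 0,
                               band_rms = c(mu = 7, beta = 0),
                               topography = cfg$topography)
  s_ref <- simulate_session(cfg_ref, 1)
  fr_ref <- label_windows(psd_frames(s_ref$recording, stride = 4,
                                     laplacian = FALSE), s_ref$trials)
  floor_share <- mean(band_power(fr_ref, band_definition("beta"))[, "C3"]) /
    mean(den)
  expected <- (1 - depth) * (1 - floor_share) + floor_share
  expect_lt(abs(ratio - expected), 0.05)
})

test_that("EOG injection: disabled rates leave data unchanged, event counts are Poisson", {
  cfg <- simulation_config(seed = 409, blink_rate = 0, saccade_rate = 0)
  s <- simulate_session(cfg, 1)
  out <- inject_eog(s$recording, s$truth, blink_rate = 0, amplitude = 150,
                    saccade_rate = 0)
  expect_identical(out$recording$data, s$recording$data)
  expect_equal(nrow(out$truth$blinks), 0)

  set.seed(61)
  rate_bpm <- 12
  counts <- vapply(1:20, function(i) {
    inj <- inject_eog(s$recording, s$truth, blink_rate = rate_bpm,
                      amplitude = 150, saccade_rate = 0)
    sum(inj$truth$blinks$type == "blink")
  }, numeric(1))
  lambda <- rate_bpm * recording_duration(s$recording) / 60
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.25)

  bare <- eeg_recording(matrix(0, 512, 2), 512, c("A", "B"))
  expect_error(inject_eog(bare, list(), 5, 150), "EOG channels")
})

test_that("training histories: lazy sessions, period tags, and break validation", {
  cfg <- study_history("break", seed = 410)
  set <- simulate_training_history(cfg, 30)
  expect_equal(nrow(set$runs), 30)
  expect_equal(set$runs$period, rep(c("period1", "period2"), c(20, 10)))
  expect_equal(set$runs$type[1:3], rep("calibration", 3))
  s <- get_session(set, 4)
  expect_equal(s$recording$meta$run_type, "online")
  expect_error(simulate_training_history(cfg, 15), "break index")
  expect_error(get_session(set, 31), "out of range")
})

test_that("trajectory configuration errors surface as configuration errors", {
  cfg <- simulation_config(seed = 411,
                           separability = function(r) rep(NaN, length(r)))
  expect_error(simulate_session(cfg, 1), "non-finite trajectory")
  expect_error(simulation_config(break_spec = list(after_run = 0)),
               "after_run")
})
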