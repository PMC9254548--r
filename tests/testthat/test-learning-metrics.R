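test_that("Fisher score closed forms and direct-oracle agreement", {
  x <- rnorm(50)
  expect_equal(fisher_score(x, x), 0)
  set.seed(40)
  x1 <- rnorm(2000, 2, 1)
  x2 <- rnorm(2000, 0, 1)
  expect_equal(fisher_score(x1, x2), sqrt(2), tolerance = 0.1)
  for (i in 1:20) {
    a <- rnorm(30, rnorm(1), runif(1, 0.5, 2))
    b <- rnorm(30, rnorm(1), runif(1, 0.5, 2))
    expect_equal(fisher_score(a, b),
                 abs(mean(a) - mean(b)) / sqrt(sd(a)^2 + sd(b)^2),
                 tolerance = 1e-12)
  }
  z <- rep(3, 10)
  fs <- fisher_score(z, z)
  expect_equal(as.numeric(fs), 0)
  fs <- fisher_score(rep(1, 10), rep(2, 10))
  expect_true(is.infinite(fs))
  expect_true(isTRUE(attr(fs, "degenerate")))
  expect_error(fisher_score(1, rnorm(5)), ">= 2 samples")
})

test_that("1-D channels'-domain bcDist equals the Fisher score under the SD convention", {
  set.seed(41)
  for (i in 1:100) {
    n1 <- sample(5:60, 1)
    n2 <- sample(5:60, 1)
    a <- rnorm(n1, rnorm(1, 0, 3), runif(1, 0.2, 3))
    b <- rnorm(n2, rnorm(1, 0, 3), runif(1, 0.2, 3))
    bc <- bc_dist(run_distribution(matrix(a), "channels", "both_hands"),
                  run_distribution(matrix(b), "channels", "both_feet"),
                  convention = "sd")
    expect_equal(bc, fisher_score(a, b), tolerance = 1e-12)
  }
})

test_that("bcDist: null closeness, homogeneity, and wcDist zero/shift closed forms", {
  set.seed(42)
  # both classes from one distribution: near zero
  A <- matrix(rnorm(500 * 4), ncol = 4)
  B <- matrix(rnorm(500 * 4), ncol = 4)
  d1 <- run_distribution(A, "channels", "both_hands")
  d2 <- run_distribution(B, "channels", "both_feet")
  expect_lt(bc_dist(d1, d2), 0.1)

  # doubling the mean separation at fixed dispersion doubles bcDist
  shift <- c(1, 0, 0, 0)
  d2a <- run_distribution(sweep(A, 2, shift, `+`), "channels", "both_feet")
  d2b <- run_distribution(sweep(A, 2, 2 * shift, `+`), "channels", "both_feet")
  expect_equal(bc_dist(d1, d2b), 2 * bc_dist(d1, d2a), tolerance = 1e-12)

  # wcDist of a run against itself is exactly zero
  r1 <- run_distribution(A, "channels", "both_hands", run = 1)
  expect_equal(wc_dist(r1, r1), 0)

  # a pure shift of norm Delta with equal dispersions gives Delta / (2 sigma)
  rs <- run_distribution(sweep(A, 2, c(3, 4, 0, 0), `+`), "channels",
                         "both_hands", run = 2)
  m <- colMeans(A)
  sigma <- mean(sqrt(rowSums(sweep(A, 2, m)^2)))
  expect_equal(wc_dist(rs, r1), 5 / (2 * sigma), tolerance = 1e-12)

  expect_error(wc_dist(rs, run_distribution(A, "channels", "both_feet")),
               "classes differ")
})

test_that("Riemann-domain wcDist is invariant to a fixed mixing applied to both runs", {
  set.seed(43)
  mk <- function(W = diag(4)) {
    lapply(1:25, function(i) {
      X <- W %*% matrix(rnorm(4 * 60), 4)
      sample_covariance(X)
    })
  }
  set.seed(43)
  S1 <- mk()
  set.seed(44)
  S2 <- mk()
  W <- matrix(rnorm(16), 4)
  set.seed(43)
  S1w <- mk(W)
  set.seed(44)
  S2w <- mk(W)
  d1 <- run_distribution(S1, "riemann", "both_hands", run = 1)
  d2 <- run_distribution(S2, "riemann", "both_hands", run = 2)
  d1w <- run_distribution(S1w, "riemann", "both_hands", run = 1)
  d2w <- run_distribution(S2w, "riemann", "both_hands", run = 2)
  expect_equal(wc_dist(d2w, d1w), wc_dist(d2, d1), tolerance = 1e-4)
})

test_that("topographic discriminancy peaks at the modulated channel and follows labels", {
  cfg <- simulation_config(
    seed = 402, blink_rate = 0, saccade_rate = 0,
    topography = data.frame(class = "both_hands", channel = "C4",
                            band = "beta", depth = 0.9))
  s <- simulate_session(cfg, 1)
  fr <- label_windows(psd_frames(s$recording, stride = 4), s$trials)
  map <- topographic_discriminancy(fr, band_definition("beta"))
  expect_equal(names(which.max(map)), "C4")
  expect_true(all(map >= 0))

  # identical class distributions: all channels near zero
  cfg0 <- simulation_config(seed = 403, blink_rate = 0, saccade_rate = 0,
                            separability = trajectory_constant(0))
  s0 <- simulate_session(cfg0, 1)
  fr0 <- label_windows(psd_frames(s0$recording, stride = 4), s0$trials)
  map0 <- topographic_discriminancy(fr0, band_definition("beta"))
  expect_lt(max(map0), 0.25)
  expect_gt(max(map), 2 * median(map))   # focal peak vs flat background
})

test_that("decoding performance: label flip symmetry and all-rejected handling", {
  fr <- fixture_frame()
  m <- fixture_model()
  perf <- decoding_performance(fr, m)
  expect_gt(perf$accuracy, 90)
  expect_lt(perf$rejection, 20)

  flipped <- fr
  flipped$labels <- factor(
    ifelse(is.na(fr$labels), NA,
           ifelse(fr$labels == "both_hands", "both_feet", "both_hands")),
    levels = mi_classes())
  pf <- decoding_performance(flipped, m)
  expect_equal(pf$accuracy, 100 - perf$accuracy, tolerance = 1e-9)
  expect_equal(pf$rejection, perf$rejection)

  # impossible threshold: everything rejected, accuracy undefined
  m2 <- m
  m2$th_rej <- 1.1
  p2 <- decoding_performance(fr, m2)
  expect_true(p2$undefined)
  expect_true(is.na(p2$accuracy))
  expect_equal(p2$rejection, 100)
})
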