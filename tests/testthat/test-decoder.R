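test_that("CVA ranking puts a separating feature first and is near zero under the null", {
  set.seed(30)
  n <- 300
  X <- matrix(rnorm(n * 6), n)
  y <- rep(mi_classes(), each = n / 2)
  X[, 4] <- ifelse(y == "both_hands", rnorm(n, 10, 0.5), rnorm(n, -10, 0.5))
  ranked <- cva_rank_features(X, y)
  expect_equal(ranked$feature[1], 4)

  # identical class distributions: all scores small
  set.seed(31)
  X0 <- matrix(rnorm(500 * 10), 500)
  r0 <- cva_rank_features(X0, rep(mi_classes(), each = 250))
  expect_lt(max(r0$score), 0.05)

  expect_error(cva_rank_features(X, rep("both_hands", n)), "two classes")
})

test_that("CVA ranking largely agrees with Fisher-score ranking on diagonal-covariance features", {
  set.seed(32)
  agree <- replicate(10, {
    n <- 400
    p <- 8
    mu1 <- rnorm(p, 0, 1)
    mu2 <- mu1 + rnorm(p, 0, 0.8)
    sds <- runif(p, 0.5, 2)
    X <- rbind(
      sweep(sweep(matrix(rnorm(n / 2 * p), ncol = p), 2, sds, `*`), 2, mu1, `+`),
      sweep(sweep(matrix(rnorm(n / 2 * p), ncol = p), 2, sds, `*`), 2, mu2, `+`))
    y <- rep(mi_classes(), each = n / 2)
    cva <- cva_rank_features(X, y)
    fs <- vapply(seq_len(p), function(j)
      fisher_score(X[y == y[1], j], X[y != y[1], j]), numeric(1))
    top_cva <- cva$feature[1:5]
    top_fs <- order(-fs)[1:5]
    length(intersect(top_cva, top_fs)) / 5
  })
  expect_gte(mean(agree), 0.9)
})

test_that("feature selection honors carryover policy and its limits", {
  ranked <- data.frame(channel = c("C4", "Cz", "C3", "FCz", "Fz"),
                       freq = c(22, 20, 18, 24, 12),
                       score = c(0.5, 0.4, 0.3, 0.2, 0.05))
  carry <- data.frame(channel = "Fz", freq = 12)
  sel <- select_features(ranked, 3, carryover = carry, floor = 0)
  expect_true(any(sel$channel == "Fz" & sel$freq == 12))
  expect_equal(nrow(sel), 3)
  # no carryover: plain top-k
  sel <- select_features(ranked, 3)
  expect_setequal(paste(sel$channel, sel$freq), c("C4 22", "Cz 20", "C3 18"))
  # infinite floor: carryover ignored
  sel <- select_features(ranked, 3, carryover = carry, floor = Inf)
  expect_false(any(sel$channel == "Fz"))
  expect_warning(select_features(ranked, 10), "truncating")
})

test_that("Gaussian classifier separates well-separated classes and is at chance on shuffled labels", {
  set.seed(33)
  n <- 400
  X <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 4), ncol = 2))
  y <- rep(mi_classes(), each = n)
  m <- fit_gaussian_classifier(X, y)
  pred <- m$classes[max.col(classify(m, X))]
  expect_gt(mean(pred == y), 0.95)

  ys <- sample(y)
  ms <- fit_gaussian_classifier(X, ys)
  preds <- ms$classes[max.col(classify(ms, X))]
  expect_lt(abs(mean(preds == ys) - 0.5), 0.05)
})

test_that("posterior is 0.5 on the perpendicular bisector with single isotropic prototypes", {
  set.seed(34)
  # symmetric classes around the origin along x
  X <- rbind(matrix(rnorm(600, -2, 1), ncol = 2),
             matrix(rnorm(600, 2, 1), ncol = 2))
  y <- rep(mi_classes(), each = 300)
  m <- fit_gaussian_classifier(X, y, n_prototypes = 1)
  # force exact symmetry of the fitted model, then query the bisector
  mid <- (m$proto[[1]]$mean + m$proto[[2]]$mean) / 2
  m$proto[[1]]$mean <- m$proto[[1]]$mean - mid
  m$proto[[2]]$mean <- -m$proto[[1]]$mean
  m$proto[[2]]$logvar <- m$proto[[1]]$logvar
  axis_dir <- m$proto[[2]]$mean[1, ] - m$proto[[1]]$mean[1, ]
  w <- axis_dir / exp(m$proto[[1]]$logvar[1, ])
  perp <- c(-w[2], w[1])                # perpendicular in the metric of w
  for (a in c(-1, 0, 2)) {
    z <- a * perp                       # standardized-space bisector point
    x <- z * m$scale + m$center
    expect_equal(unname(classify(m, x)[1, 1]), 0.5, tolerance = 1e-9)
  }
})

test_that("posterior matches a brute-force Bayes oracle and normalizes", {
  m <- fixture_model()
  set.seed(35)
  p <- length(m$center)
  X <- matrix(abs(rnorm(100 * p, 1, 0.5)), ncol = p)
  post <- classify(m, X)
  expect_equal(unname(rowSums(post)), rep(1, 100), tolerance = 1e-12)
  # independent direct-Bayes recomputation with plain dnorm products
  Z <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  oracle <- matrix(NA_real_, 100, 2)
  for (i in 1:100) {
    f <- numeric(2)
    for (c in 1:2) {
      pc <- m$proto[[c]]
      for (k in seq_along(pc$w)) {
        f[c] <- f[c] + pc$w[k] *
          prod(dnorm(Z[i, ], pc$mean[k, ], sqrt(exp(pc$logvar[k, ]))))
      }
    }
    oracle[i, ] <- f / sum(f)
  }
  expect_lt(max(abs(post - oracle)), 1e-10)
})

test_that("a vector at a prototype mean with distant rivals is classified near-certainly", {
  set.seed(36)
  X <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 30, 0.5), ncol = 2))
  y <- rep(mi_classes(), each = 100)
  m <- fit_gaussian_classifier(X, y, n_prototypes = 1)
  at_mean <- m$proto[[1]]$mean[1, ] * m$scale + m$center
  expect_gt(classify(m, at_mean)[1, 1], 0.999)
})

test_that("rejection boundary is inclusive at th_rej = 0.6", {
  expect_false(apply_rejection(c(0.59, 0.41)))
  expect_true(apply_rejection(c(0.60, 0.40)))
  expect_false(apply_rejection(c(0.5, 0.5)))
  expect_true(apply_rejection(c(0.95, 0.05)))
  expect_equal(apply_rejection(rbind(c(0.7, 0.3), c(0.45, 0.55))),
               c(TRUE, FALSE))
})

test_that("integrator: INC under rejection, closed-form time-to-command, refractory", {
  hop <- 0.0625
  # all samples rejected forever: y stays uniform, no command
  st <- integrator_state()
  for (i in 1:100) {
    out <- integrate_step(st, "rejected", i * hop)
    st <- out$state
    expect_null(out$command)
  }
  expect_equal(unname(st$y), c(0.5, 0.5))

  # constant (1, 0) evidence: command at the smallest n with
  # 1 - 0.5 (1 - alpha)^n >= 1 - eps_cmd  (independent closed form)
  alpha <- 0.1
  eps <- 0.025
  n_expect <- ceiling(log(eps / 0.5) / log(1 - alpha))
  st <- integrator_state(alpha = alpha, eps_cmd = eps)
  n_obs <- NA
  for (i in 1:60) {
    out <- integrate_step(st, c(1, 0), i * hop)
    st <- out$state
    if (!is.null(out$command)) {
      n_obs <- i
      break
    }
  }
  expect_equal(n_obs, n_expect)
  expect_equal(out$command, "both_hands")
  expect_equal(unname(st$y), c(0.5, 0.5))   # uniform reset

  # two command-triggering bursts 0.4 s apart: refractory keeps one command
  st <- integrator_state()
  cmds <- character(0)
  tme <- 0
  burst <- function(st, tme, cmds) {
    repeat {
      tme <- tme + hop
      out <- integrate_step(st, c(1, 0), tme)
      st <- out$state
      if (!is.null(out$command)) cmds <- c(cmds, out$command)
      if (length(cmds) > 0 || tme > 10) break
    }
    list(st = st, tme = tme, cmds = cmds)
  }
  b1 <- burst(st, tme, cmds)
  st <- b1$st
  tme <- b1$tme + 0.4
  # second burst within the refractory window
  n2 <- 0
  cmds2 <- character(0)
  repeat {
    tme <- tme + hop
    out <- integrate_step(st, c(1, 0), tme)
    st <- out$state
    n2 <- n2 + 1
    if (!is.null(out$command)) cmds2 <- c(cmds2, out$command)
    if (max(st$y) >= 1 - st$eps_cmd || n2 > 10) break
  }
  expect_equal(length(b1$cmds), 1)
  expect_equal(length(cmds2), 0)         # suppressed by the 1 s refractory

  expect_error(integrate_step(st, c(1, 0), tme - 1), "non-monotone")
})

test_that("integrator safety and monotonicity properties", {
  hop <- 0.0625
  # no commands ever under uniform evidence, for several alphas
  for (alpha in c(0.05, 0.1, 0.5, 1)) {
    st <- integrator_state(alpha = alpha)
    cmds <- 0
    for (i in 1:200) {
      out <- integrate_step(st, c(0.5, 0.5), i * hop)
      st <- out$state
      if (!is.null(out$command)) cmds <- cmds + 1
      expect_true(all(st$y >= 0 & st$y <= 1))
      expect_equal(sum(st$y), 1, tolerance = 1e-12)
    }
    expect_equal(cmds, 0)
  }
  # time-to-command decreases with alpha and with evidence strength
  ttc <- function(alpha, p1) {
    st <- integrator_state(alpha = alpha)
    for (i in 1:2000) {
      out <- integrate_step(st, c(p1, 1 - p1), i * hop)
      st <- out$state
      if (!is.null(out$command)) return(i)
    }
    Inf
  }
  t_alpha <- vapply(c(0.05, 0.1, 0.2, 0.4), ttc, numeric(1), p1 = 0.99)
  expect_true(all(diff(t_alpha) <= 0))
  t_evid <- vapply(c(0.98, 0.99, 1), function(p) ttc(0.1, p), numeric(1))
  expect_true(all(diff(t_evid) <= 0))
})
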