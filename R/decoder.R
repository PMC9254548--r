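#' Spatio-spectral feature grid and extraction
#'
#' The decoder's candidate features are (channel, 2 Hz band center) pairs
#' within 4-48 Hz. `feature_grid` enumerates them for a PSD frame;
#' `psd_features` extracts the corresponding windows x features matrix.
#'
#' @param frame a `psd_frame`.
#' @param lo,hi frequency limits in Hz.
#' @return `feature_grid`: data.frame with columns `channel`, `freq`.
#' @export
feature_grid <- function(frame, lo = 4, hi = 48) {
  f <- frame$freqs[frame$freqs >= lo & frame$freqs <= hi]
  expand.grid(channel = frame$channels, freq = f,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' @rdname feature_grid
#' @param mask data.frame with columns `channel`, `freq` (a feature mask).
#' @return `psd_features`: numeric windows x features matrix.
#' @export
psd_features <- function(frame, mask) {
  ci <- match(mask$channel, frame$channels)
  fi <- match(mask$freq, frame$freqs)
  if (anyNA(ci) || anyNA(fi)) stop("mask refers to unknown channel or bin")
  out <- vapply(seq_len(nrow(mask)),
                function(j) frame$power[, ci[j], fi[j]],
                numeric(dim(frame$power)[1]))
  out <- matrix(out, nrow = dim(frame$power)[1])
  colnames(out) <- paste0(mask$channel, "@", mask$freq, "Hz")
  out
}

#' Rank spatio-spectral features by canonical discriminant power
#'
#' Two-class canonical variate analysis: the single canonical axis is the
#' (ridge-stabilized) discriminant direction; each feature's score is its
#' squared canonical loading (correlation with the canonical variate)
#' times the canonical correlation. Features are returned in descending
#' score order with deterministic ties broken by channel order, then band.
#'
#' @param frame a labeled `psd_frame` (clean labeled windows are used), or
#'   a numeric feature matrix if `labels` is given.
#' @param labels optional factor/character labels when `frame` is a matrix.
#' @param mask candidate features (default: full 4-48 Hz grid).
#' @param ridge relative ridge added to the within-class covariance for
#'   stability (default 1e-6).
#' @return data.frame `channel`, `freq`, `score`, ordered by decreasing
#'   score (columns `channel`/`freq` absent for plain-matrix input).
#' @export
cva_rank_features <- function(frame, labels = NULL, mask = NULL,
                              ridge = 1e-6) {
  if (inherits(frame, "psd_frame")) {
    if (is.null(mask)) mask <- feature_grid(frame)
    keep <- clean_labeled(frame)
    if (!length(keep)) stop("no clean labeled windows")
    X <- psd_features(frame, mask)[keep, , drop = FALSE]
    y <- droplevels(factor(frame$labels[keep]))
  } else {
    X <- as.matrix(frame)
    y <- droplevels(factor(labels))
    if (!is.null(mask) && nrow(mask) != ncol(X)) {
      stop("mask rows must match feature columns")
    }
  }
  if (nlevels(y) != 2) stop("need exactly two classes in the labels")
  if (min(table(y)) < 2) stop("need at least 2 windows per class")
  cls <- levels(y)
  m1 <- colMeans(X[y == cls[1], , drop = FALSE])
  m2 <- colMeans(X[y == cls[2], , drop = FALSE])
  Xc <- X
  Xc[y == cls[1], ] <- sweep(X[y == cls[1], , drop = FALSE], 2, m1)
  Xc[y == cls[2], ] <- sweep(X[y == cls[2], , drop = FALSE], 2, m2)
  Sw <- crossprod(Xc) / (nrow(X) - 2)
  Sw <- Sw + diag(ridge * mean(diag(Sw)) + 1e-300, ncol(X))
  w <- solve(Sw, m1 - m2)                    # canonical (discriminant) axis
  z <- drop(X %*% w)
  rho <- abs(stats::cor(z, as.numeric(y)))
  sz <- stats::sd(z)
  loading <- if (sz == 0) rep(0, ncol(X)) else {
    sx <- apply(X, 2, stats::sd)
    cv <- drop(crossprod(sweep(X, 2, colMeans(X)), z - mean(z))) /
      (nrow(X) - 1)
    ifelse(sx == 0, 0, cv / (sx * sz))
  }
  score <- loading^2 * rho
  if (!is.null(mask)) {
    out <- data.frame(mask, score = score)
    ci <- match(out$channel, unique(mask$channel))
    out[order(-out$score, ci, out$freq), , drop = FALSE]
  } else {
    out <- data.frame(feature = seq_len(ncol(X)), score = score)
    out[order(-out$score, out$feature), , drop = FALSE]
  }
}

#' Select a feature mask from a ranking
#'
#' Top-`k` features by score, with carryover: features used by the previous
#' decoder are force-included whenever their current score exceeds `floor`,
#' mirroring the stability policy of re-using previous features when
#' possible.
#'
#' @param ranked ranking from [cva_rank_features()].
#' @param k number of features to select.
#' @param carryover previous feature mask (data.frame `channel`, `freq`) or
#'   NULL.
#' @param floor minimum current score for a carryover feature to be kept
#'   (default 0: kept whenever it still carries any discriminant power).
#' @return Feature mask data.frame (`channel`, `freq`, `score`).
#' @export
select_features <- function(ranked, k, carryover = NULL, floor = 0) {
  stopifnot(k >= 1)
  if (k > nrow(ranked)) {
    warning("k exceeds available features; truncating")
    k <- nrow(ranked)
  }
  key <- paste(ranked$channel, ranked$freq)
  forced <- logical(nrow(ranked))
  if (!is.null(carryover) && nrow(carryover)) {
    ck <- paste(carryover$channel, carryover$freq)
    forced <- key %in% ck & ranked$score > floor
  }
  picked <- which(forced)
  if (length(picked) > k) picked <- picked[seq_len(k)]
  rest <- setdiff(seq_len(nrow(ranked)), picked)
  picked <- c(picked, rest[seq_len(k - length(picked))])
  ranked[sort(picked), , drop = FALSE]
}

# Internal: 1-D ring SOM over one class's samples.
som_init <- function(X, M, epochs = 200) {
  n <- nrow(X)
  # seed prototypes along the first principal direction of the class
  mu <- colMeans(X)
  pc <- tryCatch(stats::prcomp(X, center = TRUE)$rotation[, 1],
                 error = function(e) rep(0, ncol(X)))
  sdev <- stats::sd(drop(scale(X, center = mu, scale = FALSE) %*% pc))
  if (!is.finite(sdev) || sdev == 0) sdev <- 1e-3
  offs <- seq(-1, 1, length.out = M)
  W <- t(vapply(offs, function(o) mu + o * sdev * pc, numeric(ncol(X))))
  if (M == 1) return(matrix(mu, 1))
  ring_d <- function(i, j) pmin(abs(i - j), M - abs(i - j))
  # batch SOM: per epoch, all samples are assigned to their BMU and each
  # prototype moves toward the neighborhood-weighted sample mean
  H <- outer(seq_len(M), seq_len(M), ring_d)
  for (ep in seq_len(epochs)) {
    frac <- ep / epochs
    radius <- max(M / 2 * (0.5 / (M / 2))^frac, 0.5)
    lr <- 0.5 * (0.02 / 0.5)^frac
    d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
    bmu <- max.col(-d2, ties.method = "first")
    Hw <- exp(-H^2 / (2 * radius^2))             # M x M neighborhood
    for (m in seq_len(M)) {
      wgt <- Hw[m, bmu]
      sw <- sum(wgt)
      if (sw > 0) {
        target <- colSums(X * wgt) / sw
        W[m, ] <- W[m, ] + lr * (target - W[m, ])
      }
    }
  }
  W
}

# Internal: per-class mixture densities for a standardized feature matrix.
# proto: list of classes, each list(mean = M x p, logvar = M x p, w = M).
mixture_density <- function(proto, X) {
  out <- vapply(proto, function(pc) {
    M <- nrow(pc$mean)
    dens <- 0
    for (m in seq_len(M)) {
      v <- exp(pc$logvar[m, ])
      q <- sweep(X, 2, pc$mean[m, ])^2
      ll <- -0.5 * (rowSums(sweep(q, 2, v, `/`)) +
                      sum(pc$logvar[m, ]) + ncol(X) * log(2 * pi))
      dens <- dens + pc$w[m] * exp(ll)
    }
    dens
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = list(NULL, names(proto)))
}

#' Fit the Gaussian prototype classifier
#'
#' Per-class Gaussian prototypes (diagonal covariance, equal weights)
#' initialized by a 1-D ring self-organizing map over each class's feature
#' vectors, then refined jointly by batch gradient descent on the
#' cross-entropy of the class posteriors (means and log-variances; stopped
#' when the loss decrease falls below `tol` or at `max_epochs`). Features
#' are standardized internally; the model stores the transform.
#'
#' @param X windows x features numeric matrix (selected features).
#' @param labels factor/character class labels (two classes).
#' @param mask the feature mask behind the columns of `X` (stored).
#' @param n_prototypes prototypes per class (default 2).
#' @param th_rej rejection threshold on the maximum posterior (default 0.6).
#' @param som_epochs SOM initialization epochs (default 200).
#' @param lr gradient-descent learning rate (default 0.01).
#' @param max_epochs maximum refinement epochs (default 500).
#' @param tol loss-decrease stopping tolerance (default 1e-6).
#' @param transform `"raw"` or `"log"` (log10 of the PSD before
#'   standardization).
#' @param var_floor minimum prototype variance in standardized units.
#' @return An object of class `decoder_model`.
#' @export
fit_gaussian_classifier <- function(X, labels, mask = NULL,
                                    n_prototypes = 2, th_rej = 0.6,
                                    som_epochs = 200, lr = 0.01,
                                    max_epochs = 500, tol = 1e-6,
                                    transform = c("raw", "log"),
                                    var_floor = 1e-4) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) stop("need exactly two classes")
  if (min(table(y)) < max(2, n_prototypes)) {
    stop("need at least max(2, n_prototypes) samples per class")
  }
  if (transform == "log") X <- log10(pmax(X, 1e-300))
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  cls <- levels(y)
  proto <- lapply(cls, function(cl) {
    Zc <- Z[y == cl, , drop = FALSE]
    W <- som_init(Zc, n_prototypes, som_epochs)
    # assign samples to nearest prototype for initial variances
    lv <- matrix(0, n_prototypes, ncol(Z))
    if (n_prototypes == 1) {
      lv[1, ] <- log(pmax(apply(Zc, 2, stats::var), var_floor))
    } else {
      a <- apply(Zc, 1, function(x) which.min(colSums((t(W) - x)^2)))
      for (m in seq_len(n_prototypes)) {
        sel <- Zc[a == m, , drop = FALSE]
        v <- if (nrow(sel) >= 2) apply(sel, 2, stats::var) else
          apply(Zc, 2, stats::var)
        lv[m, ] <- log(pmax(v, var_floor))
      }
    }
    list(mean = W, logvar = lv, w = rep(1 / n_prototypes, n_prototypes))
  })
  names(proto) <- cls
  yi <- as.integer(y)                      # 1 or 2
  n <- nrow(Z)
  loss_of <- function(pr) {
    f <- mixture_density(pr, Z)
    p <- f / pmax(rowSums(f), 1e-300)
    -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-300)))
  }
  loss <- loss_of(proto)
  epochs <- 0L
  for (ep in seq_len(max_epochs)) {
    epochs <- ep
    f <- mixture_density(proto, Z)
    post <- f / pmax(rowSums(f), 1e-300)
    new <- proto
    for (c in 1:2) {
      resid <- (yi == c) - post[, c]       # d log P_y / d log f_c
      pc <- proto[[c]]
      for (m in seq_len(nrow(pc$mean))) {
        v <- exp(pc$logvar[m, ])
        D <- sweep(Z, 2, pc$mean[m, ])
        ll <- -0.5 * (rowSums(sweep(D^2, 2, v, `/`)) +
                        sum(pc$logvar[m, ]) + ncol(Z) * log(2 * pi))
        r_cm <- pc$w[m] * exp(ll) / pmax(f[, c], 1e-300)
        wgt <- resid * r_cm
        gmu <- colSums(wgt * sweep(D, 2, v, "/")) / n
        glv <- colSums(wgt * 0.5 * (sweep(D^2, 2, v, "/") - 1)) / n
        new[[c]]$mean[m, ] <- pc$mean[m, ] + lr * gmu
        new[[c]]$logvar[m, ] <- pmax(pc$logvar[m, ] + lr * glv,
                                     log(var_floor))
      }
    }
    new_loss <- loss_of(new)
    if (!is.finite(new_loss)) break
    proto <- new
    if (loss - new_loss < tol && ep > 1) {
      loss <- new_loss
      break
    }
    loss <- new_loss
  }
  structure(
    list(classes = cls, proto = proto, mask = mask, th_rej = th_rej,
         transform = transform, center = center, scale = scale_,
         loss = loss, epochs = epochs),
    class = "decoder_model"
  )
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %d features, %d prototypes/class, th_rej = %g\n",
    length(x$center), nrow(x$proto[[1]]$mean), x$th_rej))
  if (!is.null(x$mask)) {
    cat("features:", paste0(x$mask$channel, "@", x$mask$freq, "Hz",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior class probabilities
#'
#' Posterior over the two motor-imagery classes, proportional to the
#' prototype-weighted Gaussian mixture density of each class (equal class
#' priors), normalized to sum to one.
#'
#' @param model a `decoder_model`.
#' @param X feature vector or windows x features matrix (same features and
#'   order as at fit time).
#' @return windows x 2 matrix of posteriors (columns named by class).
#' @export
classify <- function(model, X) {
  stopifnot(inherits(model, "decoder_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$center)) stop("feature dimension mismatch")
  if (any(!is.finite(X))) stop("non-finite feature input")
  if (model$transform == "log") X <- log10(pmax(X, 1e-300))
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  f <- mixture_density(model$proto, Z)
  s <- rowSums(f)
  p <- ifelse(s > 0, 1, NA) * f / pmax(s, 1e-300)
  p[s == 0, ] <- 0.5                        # numerically void: uninformative
  colnames(p) <- model$classes
  p
}

#' Rejection rule on the posterior
#'
#' A sample is accepted iff its maximum posterior probability reaches the
#' rejection threshold (boundary inclusive): `max(p) >= th_rej`.
#'
#' @param posterior numeric posterior vector (or matrix, one row per
#'   sample).
#' @param th_rej rejection threshold (default 0.6).
#' @return Logical (vector) `accepted`.
#' @export
apply_rejection <- function(posterior, th_rej = 0.6) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  apply(posterior, 1, max) >= th_rej
}

#' Evidence integrator state
#'
#' Exponential accumulation of accepted posteriors: `y <- y + alpha (p -
#' y)`, clipped to `[0, 1]` and renormalized. A command for a class is
#' delivered when its integrated probability comes within `eps_cmd` of 1,
#' after which the integrator resets to the uniform distribution and a
#' refractory period blocks further commands. Rejected and
#' artifact-frozen samples leave the integrated vector unchanged, so
#' sustained uncertainty keeps the system in the intentional non-control
#' (INC) state.
#'
#' @param alpha integration rate in (0, 1] (default 0.1).
#' @param eps_cmd command band below 1.0 (default 0.025): a command fires
#'   when `max(y) >= 1 - eps_cmd`.
#' @param refractory lockout between consecutive commands, s (default 1).
#' @param classes class names (default [mi_classes()]).
#' @return list of class `integrator_state`.
#' @export
integrator_state <- function(alpha = 0.1, eps_cmd = 0.025, refractory = 1,
                             classes = mi_classes()) {
  stopifnot(alpha > 0, alpha <= 1, eps_cmd > 0, refractory >= 0)
  structure(
    list(y = stats::setNames(rep(0.5, length(classes)), classes),
         alpha = alpha, eps_cmd = eps_cmd, refractory = refractory,
         last_command = -Inf, last_time = -Inf),
    class = "integrator_state"
  )
}

#' One integration step
#'
#' @param state an `integrator_state`.
#' @param evidence numeric posterior vector (accepted sample), or the
#'   string `"rejected"` (below-threshold sample) or `"frozen"` (artifact
#'   guard active); both leave the integrator unchanged.
#' @param timestamp sample time in seconds (strictly increasing).
#' @return list with `state` (updated) and `command` (class name or NULL).
#' @export
integrate_step <- function(state, evidence, timestamp) {
  stopifnot(inherits(state, "integrator_state"))
  if (timestamp <= state$last_time) stop("non-monotone timestamps")
  state$last_time <- timestamp
  command <- NULL
  if (is.numeric(evidence)) {
    p <- evidence / sum(evidence)
    y <- state$y + state$alpha * (p - state$y)
    y <- pmin(pmax(y, 0), 1)
    y <- y / sum(y)
    state$y <- y
    if (max(y) >= 1 - state$eps_cmd &&
        timestamp - state$last_command >= state$refractory) {
      command <- names(y)[which.max(y)]
      state$y[] <- 0.5
      state$last_command <- timestamp
    }
  } else if (!identical(evidence, "rejected") &&
             !identical(evidence, "frozen")) {
    stop("evidence must be a posterior vector, \"rejected\" or \"frozen\"")
  }
  list(state = state, command = command)
}

#' Run the full decoding chain over a PSD frame
#'
#' Classifies every window, applies rejection and artifact freezing, feeds
#' the integrator, and returns the per-window record plus the delivered
#' command log.
#'
#' @param model a `decoder_model`.
#' @param frame a `psd_frame` (mask-selected features are extracted from
#'   it); the frame's `artifact` mask drives freezing.
#' @param state an `integrator_state` (default fresh).
#' @return list with `samples` (data.frame: time, posteriors, accepted,
#'   frozen) and `commands` (data.frame: time, class).
#' @export
decode_stream <- function(model, frame, state = integrator_state()) {
  stopifnot(inherits(frame, "psd_frame"))
  X <- psd_features(frame, model$mask)
  post <- classify(model, X)
  acc <- apply_rejection(post, model$th_rej)
  cmd_t <- numeric(0)
  cmd_c <- character(0)
  for (i in seq_along(frame$times)) {
    ev <- if (frame$artifact[i]) "frozen" else if (!acc[i]) "rejected" else
      post[i, ]
    st <- integrate_step(state, ev, frame$times[i])
    state <- st$state
    if (!is.null(st$command)) {
      cmd_t <- c(cmd_t, frame$times[i])
      cmd_c <- c(cmd_c, st$command)
    }
  }
  list(samples = data.frame(time = frame$times, post, accepted = acc,
                            frozen = frame$artifact),
       commands = data.frame(time = cmd_t, class = cmd_c),
       state = state)
}
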