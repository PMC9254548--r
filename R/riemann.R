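#' Sample covariance matrix of a band-passed window
#'
#' For a 1 s window of zero-mean band-pass filtered channels
#' `X` (channels x samples), the sample covariance matrix (SCM) is
#' `C = X X' / (T - 1)`. Rows are re-centered internally. If the smallest
#' eigenvalue falls below a regularization floor, diagonal shrinkage
#' `lambda I` with `lambda = eps_spd * trace(C)/C` is added and the event is
#' recorded in the attribute `regularized`.
#'
#' @param x channels x samples numeric matrix.
#' @param eps_spd relative regularization floor (default 1e-10).
#' @return The C x C SPD matrix, with attribute `regularized` (logical).
#' @export
sample_covariance <- function(x, eps_spd = 1e-10) {
  x <- as.matrix(x)
  if (ncol(x) <= 1) stop("need T > 1 samples")
  x <- x - rowMeans(x)
  C <- tcrossprod(x) / (ncol(x) - 1)
  C <- (C + t(C)) / 2
  lam <- eps_spd * sum(diag(C)) / nrow(C)
  reg <- FALSE
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < lam || ev_min <= 0) {
    if (lam <= 0) stop("degenerate (all-zero) window; cannot regularize")
    C <- C + diag(lam, nrow(C))
    reg <- TRUE
  }
  attr(C, "regularized") <- reg
  C
}

# Internal: validate an SPD matrix, returning its symmetrized form.
check_spd <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > tol * max(1, max(abs(A)))) {
    stop("matrix is not symmetric")
  }
  A <- (A + t(A)) / 2
  if (min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("matrix is not positive definite")
  }
  A
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `delta(A, B) = sqrt(sum(log^2 lambda_i))` where `lambda_i` are the
#' eigenvalues of `A^{-1} B`, i.e. the length of the geodesic joining the
#' two matrices on the SPD manifold under the affine-invariant metric.
#' Computed via Cholesky whitening (`L^{-1} B L^{-T}`) for numerical
#' stability.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @export
geodesic_distance <- function(A, B) {
  A <- check_spd(A)
  B <- check_spd(B)
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  L <- t(chol(A))                          # lower triangular
  W <- forwardsolve(L, t(forwardsolve(L, B)))
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("whitened matrix not positive definite")
  sqrt(sum(log(ev)^2))
}

# Internal: matrix power of an SPD matrix via eigendecomposition.
spd_power <- function(A, p) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% (e$values^p * t(e$vectors))
}

# Internal: matrix log of an SPD matrix.
spd_log <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix log of non-SPD matrix")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

# Internal: matrix exp of a symmetric matrix.
sym_exp <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Geometric (Karcher) mean of a set of SPD matrices
#'
#' Iterative fixed-point algorithm: map the set to the tangent space at the
#' current estimate M (`log(M^{-1/2} C_i M^{-1/2})`), average, and map back
#' through the exponential, until the tangent-space mean norm drops below
#' `tol`. The result minimizes the sum of squared geodesic distances to the
#' set. Initialized at the arithmetic mean.
#'
#' @param S list of SPD matrices (uniform dimension).
#' @param tol Frobenius-norm stopping tolerance on the tangent mean
#'   (default 1e-8).
#' @param max_iter maximum iterations (default 50).
#' @return The SPD mean, with attribute `converged` (logical) and
#'   `iterations`.
#' @export
geometric_mean <- function(S, tol = 1e-8, max_iter = 50) {
  if (!length(S)) stop("empty SPD set")
  S <- lapply(S, function(A) (as.matrix(A) + t(as.matrix(A))) / 2)
  d <- unique(vapply(S, nrow, 1L))
  if (length(d) != 1L) stop("matrices of mixed dimension")
  if (length(S) == 1L) {
    M <- check_spd(S[[1]])
    attr(M, "converged") <- TRUE
    attr(M, "iterations") <- 0L
    return(M)
  }
  M <- Reduce(`+`, S) / length(S)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mh <- spd_power(M, 0.5)
    Mih <- spd_power(M, -0.5)
    Tm <- matrix(0, d, d)
    for (C in S) Tm <- Tm + spd_log(Mih %*% C %*% Mih)
    Tm <- Tm / length(S)
    M <- Mh %*% sym_exp(Tm) %*% Mh
    M <- (M + t(M)) / 2
    if (sqrt(sum(Tm^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("geometric mean did not converge in ", max_iter, " iterations")
  }
  attr(M, "converged") <- converged
  attr(M, "iterations") <- it
  M
}

#' Geodesic dispersion of an SPD set around a center
#'
#' Mean geodesic distance from each member to the center: the
#' Riemann-domain analogue of "average distance around the mean" used as
#' the denominator of the learning metrics.
#'
#' @param S list of SPD matrices.
#' @param center SPD matrix (typically their geometric mean).
#' @return Nonnegative scalar.
#' @export
spd_dispersion <- function(S, center) {
  if (!length(S)) stop("empty SPD set")
  center <- check_spd(center)
  # whiten once with the center for speed: delta(C, M) = ||log(M^-1/2 C M^-1/2)||
  Mih <- spd_power(center, -0.5)
  d <- vapply(S, function(C) {
    W <- Mih %*% C %*% Mih
    ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("non-SPD member")
    sqrt(sum(log(ev)^2))
  }, numeric(1))
  mean(d)
}

#' Window SCM set for one run and band
#'
#' Band-pass filters the montage channels, slides 1 s windows, and computes
#' one SCM per clean labeled window, giving the Riemann-domain substrate of
#' the learning metrics.
#'
#' @param rec an `eeg_recording`.
#' @param trials trial table (`onset`, `duration`, `label`).
#' @param band a [band_definition()].
#' @param montage a `montage`.
#' @param hop window hop in seconds.
#' @param stride keep every `stride`-th window (speed/resolution trade-off).
#' @param artifact_intervals optional suppressed intervals to exclude.
#' @param latency cue-to-task latency (s) excluded after each cue.
#' @param shrinkage relative diagonal loading added to every SCM:
#'   `lambda = shrinkage * trace(C)/C` (default 0.01). One-second
#'   narrow-band windows yield badly conditioned covariance estimates whose
#'   smallest eigenvalues are numerical noise; a 1\% floor keeps geodesic
#'   computations stable without masking structure.
#' @return list of class `scm_set`: `scms` (list of SPD matrices), `labels`
#'   (factor), `times`, `band`, `meta`.
#' @export
scm_set <- function(rec, trials, band, montage = sensorimotor_montage(),
                    hop = 0.0625, stride = 1L, artifact_intervals = NULL,
                    latency = 0.5, shrinkage = 0.01) {
  rng <- if (is.list(band)) band$range else band
  fb <- bandpass(rec, rng)
  x <- t(channel_data(fb, montage$channels))   # channels x samples
  wins <- sliding_windows(fb, length = 1, hop = hop)
  if (stride > 1L) wins <- wins[seq(1, nrow(wins), by = stride), , drop = FALSE]
  lab <- factor(rep(NA, nrow(wins)), levels = mi_classes())
  wend <- wins$time + 1
  for (i in seq_len(nrow(trials))) {
    lo <- trials$onset[i] + latency
    hi <- trials$onset[i] + trials$duration[i]
    sel <- wins$time >= lo & wend <= hi
    lab[sel] <- as.character(trials$label[i])
  }
  bad <- rep(FALSE, nrow(wins))
  if (!is.null(artifact_intervals) && nrow(artifact_intervals)) {
    for (i in seq_len(nrow(artifact_intervals))) {
      bad <- bad | (wins$time < artifact_intervals$end[i] &
                      wend > artifact_intervals$start[i])
    }
  }
  keep <- which(!is.na(lab) & !bad)
  scms <- lapply(keep, function(i) {
    C <- sample_covariance(x[, wins$start[i]:wins$end[i], drop = FALSE])
    if (shrinkage > 0) {
      C <- C + diag(shrinkage * sum(diag(C)) / nrow(C), nrow(C))
    }
    C
  })
  structure(
    list(scms = scms, labels = lab[keep], times = wins$time[keep],
         band = if (is.list(band)) band$name else paste(rng, collapse = "-"),
         meta = rec$meta),
    class = "scm_set"
  )
}

#' @export
print.scm_set <- function(x, ...) {
  cat(sprintf("<scm_set> %d SCMs (%s band); classes: %s\n",
              length(x$scms), x$band,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}
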