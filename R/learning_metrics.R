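#' Fisher score of two scalar samples
#'
#' `FS = |mean1 - mean2| / sqrt(sd1^2 + sd2^2)`, the per-feature class
#' discriminancy used for topographic maps. With both variances zero the
#' score is 0 for equal means and `Inf` (flagged via attribute
#' `degenerate`) otherwise.
#'
#' @param x1,x2 numeric vectors (>= 2 samples each).
#' @return Nonnegative scalar.
#' @export
fisher_score <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2) stop("need >= 2 samples per set")
  v <- stats::var(x1) + stats::var(x2)
  d <- abs(mean(x1) - mean(x2))
  if (v == 0) {
    out <- if (d == 0) 0 else Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d / sqrt(v)
}

#' Per-run, per-class feature distribution
#'
#' Bundles the artifact-free windows of one run and one class in one of
#' the two neural domains: the channels' domain (windows x 14 matrix of
#' band-averaged PSD values) or the Riemann domain (list of window SCMs).
#'
#' @param data windows x channels matrix (`domain = "channels"`) or list of
#'   SPD matrices (`domain = "riemann"`).
#' @param domain `"channels"` or `"riemann"`.
#' @param class class label.
#' @param run run index.
#' @return object of class `run_distribution`.
#' @export
run_distribution <- function(data, domain = c("channels", "riemann"),
                             class = NA, run = NA) {
  domain <- match.arg(domain)
  if (domain == "channels") {
    data <- as.matrix(data)
    if (nrow(data) < 2) stop("need >= 2 windows")
  } else {
    if (!is.list(data) || length(data) < 2) stop("need >= 2 window SCMs")
  }
  structure(list(data = data, domain = domain, class = class, run = run),
            class = "run_distribution")
}

# Internal: mean pattern of a run distribution. The geometric mean of
# noisy 1 s window SCMs needs no more than metric-level precision, so the
# fixed point is run at 1e-6 with a generous iteration budget.
rd_mean <- function(d) {
  if (d$domain == "channels") colMeans(d$data) else
    geometric_mean(d$data, tol = 1e-6, max_iter = 120)
}

# Internal: dispersion around a center under a convention.
#  "meandist": mean (Euclidean | geodesic) distance to the center;
#  "sd": total standard deviation (quadrature over dimensions /
#        root-mean-square geodesic distance), the convention under which
#        the 1-D channels'-domain bcDist reduces exactly to the Fisher
#        score.
rd_dispersion <- function(d, center, convention = "meandist") {
  if (d$domain == "channels") {
    dist2 <- rowSums(sweep(d$data, 2, center)^2)
    if (convention == "sd") {
      sqrt(sum(dist2) / (nrow(d$data) - 1))
    } else {
      mean(sqrt(dist2))
    }
  } else {
    if (convention == "sd") {
      Mih <- spd_power(center, -0.5)
      d2 <- vapply(d$data, function(C) {
        ev <- eigen(Mih %*% C %*% Mih, symmetric = TRUE,
                    only.values = TRUE)$values
        sum(log(pmax(ev, 1e-300))^2)
      }, numeric(1))
      sqrt(mean(d2))
    } else {
      spd_dispersion(d$data, center)
    }
  }
}

# Internal: combine the two dispersions per the convention.
combine_sigma <- function(s1, s2, convention) {
  if (convention == "sd") sqrt(s1^2 + s2^2) else s1 + s2
}

# Internal: distance between mean patterns in a domain.
mean_distance <- function(m1, m2, domain) {
  if (domain == "channels") sqrt(sum((m1 - m2)^2)) else
    geodesic_distance(m1, m2)
}

#' Between-class distance of one run
#'
#' Normalized distance between the mean neural patterns of the two
#' motor-imagery classes within a run:
#' `bcDist = delta(mu_bh, mu_bf) / (sigma_bh + sigma_bf)`,
#' with `delta` the Euclidean distance between mean band-power vectors
#' (channels' domain) or the geodesic distance between class geometric
#' means (Riemann domain), and `sigma` the corresponding dispersion around
#' each mean. Under `convention = "sd"` the dispersions are standard
#' deviations combined in quadrature, making the one-dimensional channels'
#' domain value coincide exactly with the Fisher score.
#'
#' @param d1,d2 `run_distribution`s of the two classes (same domain/run).
#' @param convention `"meandist"` (default) or `"sd"`.
#' @return Nonnegative scalar.
#' @export
bc_dist <- function(d1, d2, convention = c("meandist", "sd")) {
  convention <- match.arg(convention)
  stopifnot(inherits(d1, "run_distribution"),
            inherits(d2, "run_distribution"))
  if (d1$domain != d2$domain) stop("domains differ")
  m1 <- rd_mean(d1)
  m2 <- rd_mean(d2)
  num <- mean_distance(m1, m2, d1$domain)
  den <- combine_sigma(rd_dispersion(d1, m1, convention),
                       rd_dispersion(d2, m2, convention), convention)
  if (den == 0) {
    out <- if (num == 0) 0 else Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  num / den
}

#' Within-class distance of a run from the first training run
#'
#' `wcDist = delta(mu_1, mu_r) / (sigma_1 + sigma_r)` for one class:
#' the shift of the class's mean neural pattern in run `r` relative to the
#' chronologically first recorded run, normalized by the two dispersions.
#' Use [wc_dist_avg()] for the class-averaged value.
#'
#' @param d_r `run_distribution` of the class in run r.
#' @param d_1 `run_distribution` of the same class in the first run.
#' @param convention `"meandist"` (default) or `"sd"`.
#' @return Nonnegative scalar.
#' @export
wc_dist <- function(d_r, d_1, convention = c("meandist", "sd")) {
  convention <- match.arg(convention)
  stopifnot(inherits(d_r, "run_distribution"),
            inherits(d_1, "run_distribution"))
  if (d_r$domain != d_1$domain) stop("domains differ")
  if (!identical(d_r$class, d_1$class)) stop("classes differ")
  m1 <- rd_mean(d_1)
  mr <- rd_mean(d_r)
  num <- mean_distance(m1, mr, d_r$domain)
  den <- combine_sigma(rd_dispersion(d_1, m1, convention),
                       rd_dispersion(d_r, mr, convention), convention)
  if (den == 0) {
    out <- if (num == 0) 0 else Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  num / den
}

#' @rdname wc_dist
#' @param d_r_bh,d_r_bf run-r distributions of the two classes.
#' @param d_1_bh,d_1_bf first-run distributions of the two classes.
#' @export
wc_dist_avg <- function(d_r_bh, d_1_bh, d_r_bf, d_1_bf,
                        convention = c("meandist", "sd")) {
  convention <- match.arg(convention)
  (wc_dist(d_r_bh, d_1_bh, convention) +
     wc_dist(d_r_bf, d_1_bf, convention)) / 2
}

#' Topographic discriminancy map
#'
#' Per-channel class discriminancy: the Fisher score of each 2 Hz PSD bin
#' between the two classes, averaged over the bins inside the band. High
#' values over lateral electrodes indicate hand-imagery features, over
#' medial electrodes foot-imagery features.
#'
#' @param frame a labeled `psd_frame`.
#' @param band a [band_definition()] (default beta, 16-26 Hz).
#' @return Named numeric vector, one value per channel.
#' @export
topographic_discriminancy <- function(frame, band = band_definition("beta")) {
  stopifnot(inherits(frame, "psd_frame"))
  rng <- if (is.list(band)) band$range else band
  sel <- which(frame$freqs >= rng[1] & frame$freqs <= rng[2])
  if (!length(sel)) stop("band contains no frequency bins")
  keep <- clean_labeled(frame)
  y <- droplevels(factor(frame$labels[keep]))
  if (nlevels(y) != 2) stop("need labeled windows of both classes")
  cls <- levels(y)
  out <- vapply(seq_along(frame$channels), function(ci) {
    fs <- vapply(sel, function(bi) {
      fisher_score(frame$power[keep[y == cls[1]], ci, bi],
                   frame$power[keep[y == cls[2]], ci, bi])
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  stats::setNames(out, frame$channels)
}

#' Sample-by-sample decoding performance
#'
#' Classifies every clean labeled window of a run and reports the
#' sample-by-sample accuracy (% correct among accepted samples) and the
#' rejection rate (% of samples whose maximum posterior fell below the
#' rejection threshold).
#'
#' @param frame a labeled `psd_frame`.
#' @param model a `decoder_model`.
#' @return list with `accuracy` (percent, NA with `undefined = TRUE` when
#'   every sample is rejected), `rejection` (percent), `n` (total clean
#'   labeled samples), `n_accepted`, `undefined`.
#' @export
decoding_performance <- function(frame, model) {
  stopifnot(inherits(frame, "psd_frame"), inherits(model, "decoder_model"))
  keep <- clean_labeled(frame)
  if (!length(keep)) stop("no clean labeled windows")
  X <- psd_features(frame, model$mask)[keep, , drop = FALSE]
  post <- classify(model, X)
  acc <- apply_rejection(post, model$th_rej)
  pred <- model$classes[max.col(post)]
  truth <- as.character(frame$labels[keep])
  n <- length(keep)
  n_acc <- sum(acc)
  accuracy <- if (n_acc == 0) NA_real_ else
    100 * mean(pred[acc] == truth[acc])
  list(accuracy = accuracy, rejection = 100 * (1 - n_acc / n), n = n,
       n_accepted = n_acc, undefined = n_acc == 0)
}
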