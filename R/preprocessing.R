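#' Sliding analysis windows
#'
#' Enumerates 1 s analysis windows slid every 62.5 ms (defaults), fully
#' contained in the recording. The number of windows is
#' `floor((duration - length)/hop) + 1`.
#'
#' @param rec an `eeg_recording` (or anything with a duration via `n/rate`).
#' @param length window length in seconds.
#' @param hop hop between window onsets in seconds.
#' @return A data.frame with columns `start` (1-based sample index), `end`,
#'   and `time` (window onset in seconds). Zero rows, with attribute
#'   `too_short = TRUE`, when the recording is shorter than one window.
#' @export
sliding_windows <- function(rec, length = 1, hop = 0.0625) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- nrow(rec$data)
  wlen <- round(length * rec$rate)
  whop <- hop * rec$rate
  if (n < wlen) {
    out <- data.frame(start = integer(0), end = integer(0), time = numeric(0))
    attr(out, "too_short") <- TRUE
    warning("recording shorter than one window; returning empty window set")
    return(out)
  }
  nwin <- floor((n - wlen) / whop) + 1
  start <- round((seq_len(nwin) - 1) * whop) + 1L
  data.frame(start = as.integer(start),
             end = as.integer(start + wlen - 1L),
             time = (start - 1) / rec$rate)
}

#' Welch power spectral density of one analysis window
#'
#' Computes the one-sided PSD at 2 Hz resolution for each channel of a 1 s
#' window: the window is split into half-second Hamming-tapered segments with
#' 50\% overlap (three segments for a 1 s window), each segment's constant
#' trend is removed, and the segment periodograms are averaged. At 512 Hz
#' this yields 256-sample segments and hence exactly 2 Hz bin spacing.
#'
#' @param window numeric matrix, samples x channels, spanning 1 s.
#' @param rate sampling rate in Hz.
#' @return A channels x bins matrix of power density (uV^2/Hz) with the bin
#'   center frequencies (Hz) as an attribute `freqs` and as column names.
#' @export
welch_psd <- function(window, rate) {
  window <- as.matrix(window)
  if (anyNA(window)) stop("NaN/NA in PSD input window")
  seg_len <- round(rate / 2)        # 2 Hz resolution
  step <- seg_len %/% 2             # 50% overlap
  n <- nrow(window)
  if (n < seg_len) stop("window shorter than one Welch segment")
  starts <- seq(1L, n - seg_len + 1L, by = step)
  pg <- segment_periodograms_detrended(window, starts, seg_len, rate)
  psd <- t(apply(pg$power, c(1, 3), mean))      # channels x bins
  dimnames(psd) <- list(colnames(window), pg$freqs)
  attr(psd, "freqs") <- pg$freqs
  psd
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase). Input edges
#' are mirror-padded before filtering to suppress startup transients.
#'
#' @param rec an `eeg_recording`.
#' @param band numeric length-2 vector `(lo, hi)` in Hz, 0 < lo < hi <
#'   rate/2.
#' @param order filter order (default 4).
#' @return A filtered `eeg_recording`.
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= rec$rate / 2) {
    stop("invalid band: need 0 < lo < hi < rate/2")
  }
  bf <- signal::butter(order, band / (rec$rate / 2), type = "pass")
  out <- apply(rec$data, 2, function(x) filtfilt_mirrored(bf, x))
  eeg_recording(out, rec$rate, rec$channels, rec$meta)
}

# Internal: forward-backward filtering with mirrored edges.
filtfilt_mirrored <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 512L)
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    xp <- x
  }
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' PSD feature frames for a recording
#'
#' Applies the Laplacian filter, slides 1 s windows every `hop` seconds, and
#' computes the Welch PSD of every window on the 14 montage channels,
#' producing the windows x channels x frequency-bins tensor that feeds the
#' decoder and the channels'-domain learning metrics.
#'
#' @param rec an `eeg_recording` containing the montage channels.
#' @param montage a `montage`.
#' @param hop window hop in seconds (default 0.0625).
#' @param stride keep every `stride`-th window (default 1 = all); coarser
#'   strides trade temporal resolution for speed in batch re-analyses.
#' @param max_freq highest bin center retained, Hz (default 48).
#' @param laplacian apply the spatial filter first (default TRUE).
#' @return An object of class `psd_frame`: list with `power` (windows x
#'   channels x bins array), `freqs`, `times` (window onsets, s), `win_len`
#'   (s), `labels` (factor, NA until labeled), `artifact` (logical mask,
#'   FALSE until a guard mask is attached), and `meta` from the recording.
#' @export
psd_frames <- function(rec, montage = sensorimotor_montage(), hop = 0.0625,
                       stride = 1L, max_freq = 48, laplacian = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (laplacian) rec <- laplacian_filter(rec, montage)
  wins <- sliding_windows(rec, length = 1, hop = hop)
  if (stride > 1L) wins <- wins[seq(1, nrow(wins), by = stride), , drop = FALSE]
  x <- channel_data(rec, montage$channels)
  seg_len <- round(rec$rate / 2)
  step <- seg_len %/% 2
  rel <- seq(0L, round(rec$rate) - seg_len, by = step)
  all_starts <- sort(unique(as.integer(outer(wins$start, rel, "+"))))
  # per-segment constant detrend == per-segment mean removal before taper;
  # remove the global channel mean first, then per-segment residual means
  xc <- sweep(x, 2, colMeans(x))
  pg <- segment_periodograms_detrended(xc, all_starts, seg_len, rec$rate)
  keep <- pg$freqs <= max_freq
  nwin <- nrow(wins)
  nch <- ncol(x)
  power <- array(0, c(nwin, nch, sum(keep)))
  for (j in seq_along(rel)) {
    pos <- match(wins$start + rel[j], all_starts)
    power <- power + aperm(pg$power[keep, pos, , drop = FALSE], c(2, 3, 1))
  }
  power <- power / length(rel)
  structure(
    list(power = power, freqs = pg$freqs[keep], times = wins$time,
         win_len = 1, channels = montage$channels,
         labels = factor(rep(NA, nwin), levels = mi_classes()),
         artifact = rep(FALSE, nwin), meta = rec$meta),
    class = "psd_frame"
  )
}

# Internal: like segment_periodograms but removes each segment's mean first
# (constant detrend inside Welch segments).
segment_periodograms_detrended <- function(x, starts, seg_len, rate) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  scale <- 1 / (rate * sum(w^2))
  nbin <- seg_len %/% 2 + 1
  freqs <- (0:(nbin - 1)) * rate / seg_len
  idx <- outer(0:(seg_len - 1), starts, "+")
  out <- array(NA_real_, c(nbin, length(starts), ncol(x)))
  dbl <- rep(2, nbin)
  dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[nbin] <- 1
  for (ch in seq_len(ncol(x))) {
    seg <- matrix(x[idx, ch], nrow = seg_len)
    seg <- sweep(seg, 2, colMeans(seg))
    ft <- stats::mvfft(seg * w)[seq_len(nbin), , drop = FALSE]
    out[, , ch] <- (Mod(ft)^2) * scale * dbl
  }
  list(power = out, freqs = freqs)
}

#' @export
print.psd_frame <- function(x, ...) {
  cat(sprintf("<psd_frame> %d windows x %d channels x %d bins (%g-%g Hz)\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freqs), max(x$freqs)))
  nl <- sum(!is.na(x$labels))
  cat(sprintf("labeled windows: %d; artifact-masked: %d\n",
              nl, sum(x$artifact)))
  invisible(x)
}

#' Two-class labels used throughout
#' @return `c("both_hands", "both_feet")`.
#' @export
mi_classes <- function() c("both_hands", "both_feet")

#' Label PSD windows from a trial table
#'
#' Assigns a class label to every window fully contained in a trial's task
#' interval. The first `latency` seconds after the cue are excluded so that
#' windows reflect task execution rather than cue processing.
#'
#' @param frame a `psd_frame`.
#' @param trials data.frame with columns `onset` (cue time, s), `duration`
#'   (s) and `label`.
#' @param latency cue-to-task latency excluded after the cue (default 0.5 s).
#' @return The frame with its `labels` field filled.
#' @export
label_windows <- function(frame, trials, latency = 0.5) {
  stopifnot(inherits(frame, "psd_frame"))
  lab <- factor(rep(NA, length(frame$times)), levels = mi_classes())
  wend <- frame$times + frame$win_len
  for (i in seq_len(nrow(trials))) {
    lo <- trials$onset[i] + latency
    hi <- trials$onset[i] + trials$duration[i]
    sel <- frame$times >= lo & wend <= hi
    lab[sel] <- as.character(trials$label[i])
  }
  frame$labels <- lab
  frame
}

#' Attach an artifact mask to a PSD frame
#'
#' Marks every window overlapping a suppressed interval so that downstream
#' metrics use artifact-free data only.
#'
#' @param frame a `psd_frame`.
#' @param intervals data.frame with columns `start`, `end` (seconds) of
#'   suppressed time, e.g. from [detect_eog_artifacts()].
#' @return The frame with its `artifact` mask updated (OR-ed).
#' @export
mask_artifacts <- function(frame, intervals) {
  stopifnot(inherits(frame, "psd_frame"))
  if (is.null(intervals) || nrow(intervals) == 0) return(frame)
  wend <- frame$times + frame$win_len
  for (i in seq_len(nrow(intervals))) {
    frame$artifact <- frame$artifact |
      (frame$times < intervals$end[i] & wend > intervals$start[i])
  }
  frame
}

# Internal: windows usable for analysis (labeled + artifact-free).
clean_labeled <- function(frame) {
  which(!is.na(frame$labels) & !frame$artifact)
}

#' Band-averaged channel feature vectors
#'
#' Averages the PSD over the 2 Hz bins inside a frequency band, giving one
#' value per channel per window: the channels'-domain feature space of the
#' learning metrics.
#'
#' @param frame a `psd_frame`.
#' @param band a band definition from [band_definition()] or a length-2
#'   numeric range in Hz.
#' @return windows x channels matrix.
#' @export
band_power <- function(frame, band) {
  rng <- if (is.list(band)) band$range else band
  sel <- frame$freqs >= rng[1] & frame$freqs <= rng[2]
  if (!any(sel)) stop("band contains no frequency bins")
  out <- if (sum(sel) == 1L) {
    frame$power[, , sel]
  } else {
    apply(frame$power[, , sel, drop = FALSE], c(1, 2), mean)
  }
  colnames(out) <- frame$channels
  out
}

#' Standard frequency bands
#'
#' The mu (8-12 Hz) and beta (16-26 Hz) sensorimotor bands.
#'
#' @param name `"mu"` or `"beta"`, or a custom name with `range` given.
#' @param range optional length-2 Hz range overriding the standard one.
#' @return list with `name` and `range`.
#' @export
band_definition <- function(name = c("mu", "beta"), range = NULL) {
  if (is.null(range)) {
    name <- match.arg(name)
    range <- switch(name, mu = c(8, 12), beta = c(16, 26))
  }
  if (range[1] >= range[2]) stop("band lo must be < hi")
  list(name = name, range = range)
}
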