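#' Horizontal and vertical EOG components
#'
#' From two frontal electrodes (approximately Fp1 and Fp2), the horizontal
#' component is their difference and the vertical component their average:
#' `HEOG = Fp1 - Fp2`, `VEOG = (Fp1 + Fp2)/2`, sample-wise. Blinks project
#' with the same sign on both electrodes (large VEOG), horizontal saccades
#' with opposite signs (large HEOG).
#'
#' @param frame numeric matrix, samples x 2 (columns `EOG_Fp1`, `EOG_Fp2`,
#'   uV), or any 2-column matrix in that order.
#' @return list with numeric vectors `heog` and `veog`.
#' @export
eog_components <- function(frame) {
  frame <- as.matrix(frame)
  if (ncol(frame) != 2) stop("need exactly two EOG channels (Fp1, Fp2)")
  list(heog = frame[, 1] - frame[, 2],
       veog = (frame[, 1] + frame[, 2]) / 2)
}

# Internal: the guard's 1-10 Hz order-2 Butterworth.
eog_filter <- function(rate) signal::butter(2, c(1, 10) / (rate / 2), "pass")

#' Low-frequency EOG amplitude envelope
#'
#' Filters a signal with a zero-lag (forward-backward) second-order
#' Butterworth band-pass at 1-10 Hz, mirroring the signal at both edges
#' before filtering to avoid boundary discontinuities, and returns the
#' absolute value of the result.
#'
#' @param x numeric sample vector.
#' @param rate sampling rate in Hz.
#' @return Nonnegative amplitude vector, same length as `x`.
#' @export
lowfreq_envelope <- function(x, rate) {
  abs(filtfilt_mirrored(eog_filter(rate), x))
}

#' Initialize the EOG guard
#'
#' State for frame-wise artifact gating: a detection threshold on the
#' filtered EOG amplitude, a freeze horizon applied after every detection,
#' and a trailing signal buffer so zero-lag filtering can be evaluated at
#' frame granularity without future samples.
#'
#' @param rate sampling rate in Hz (default 512).
#' @param threshold detection threshold, uV (default 30).
#' @param freeze freeze horizon after a detection, s (default 2).
#' @param buffer_len trailing buffer length in seconds (default 1).
#' @return list of class `eog_guard` (mutable-by-return state).
#' @export
eog_guard <- function(rate = 512, threshold = 30, freeze = 2,
                      buffer_len = 1) {
  stopifnot(threshold > 0, freeze >= 0)
  structure(
    list(rate = rate, threshold = threshold, freeze = freeze,
         buffer = matrix(numeric(0), 0, 2),
         buffer_samples = round(buffer_len * rate),
         frozen_until = -Inf, n_seen = 0L, flags = integer(0)),
    class = "eog_guard"
  )
}

#' Scan one 32-sample EOG frame
#'
#' Appends the frame to the trailing buffer, filters the buffered HEOG and
#' VEOG with the zero-lag 1-10 Hz Butterworth (mirrored edges), and reads
#' back the amplitude over the newest frame. The frame is flagged when
#' either amplitude exceeds the threshold; a flag freezes command output
#' until 2 s (the freeze horizon) past the end of the flagged frame.
#' Overlapping flags extend the freeze, never shorten it. If the buffer is
#' still shorter than one filter-settling span the frame is reported
#' undecidable and treated as clean.
#'
#' @param state an `eog_guard` state.
#' @param frame samples x 2 matrix (Fp1, Fp2), typically 32 samples.
#' @return list with `flag` (logical), `suppress` (logical: commands must be
#'   suppressed during this frame), `undecidable` (logical), and `state`
#'   (updated guard state).
#' @export
scan_frame <- function(state, frame) {
  stopifnot(inherits(state, "eog_guard"))
  frame <- as.matrix(frame)
  if (ncol(frame) != 2) stop("need exactly two EOG channels")
  nf <- nrow(frame)
  buf <- rbind(state$buffer, frame)
  if (nrow(buf) > state$buffer_samples) {
    buf <- buf[(nrow(buf) - state$buffer_samples + 1):nrow(buf), ,
               drop = FALSE]
  }
  state$buffer <- buf
  t_start <- state$n_seen / state$rate
  state$n_seen <- state$n_seen + nf
  t_end <- state$n_seen / state$rate
  undecidable <- nrow(buf) < max(24L, 3L * 3L * 2L)  # ~filter settling span
  flag <- FALSE
  if (!undecidable) {
    comp <- eog_components(buf)
    h <- lowfreq_envelope(comp$heog, state$rate)
    v <- lowfreq_envelope(comp$veog, state$rate)
    tail_idx <- (length(h) - nf + 1):length(h)
    flag <- max(h[tail_idx], v[tail_idx]) > state$threshold
  }
  if (flag) {
    state$frozen_until <- max(state$frozen_until, t_end + state$freeze)
  }
  state$flags <- c(state$flags, as.integer(flag))
  list(flag = flag, suppress = flag || t_start < state$frozen_until,
       undecidable = undecidable, state = state)
}

#' Batch EOG artifact detection over a recording
#'
#' Splits the EOG channels into consecutive 32-sample frames (62.5 ms at
#' 512 Hz), filters HEOG/VEOG once over the whole recording with the
#' zero-lag 1-10 Hz Butterworth (mirrored edges), flags every frame whose
#' amplitude exceeds the threshold, and derives the suppressed intervals
#' (each flagged frame's end plus the freeze horizon, overlaps merged).
#'
#' @param rec an `eeg_recording` containing the channels of
#'   [eog_channels()].
#' @param threshold detection threshold, uV (default 30).
#' @param freeze freeze horizon, s (default 2).
#' @param frame_len frame length in samples (default 32).
#' @return list with `frames` (data.frame: `start`, `end` seconds, `flag`),
#'   `intervals` (data.frame of merged suppressed intervals `start`,
#'   `end`), and `flagged_fraction`.
#' @export
detect_eog_artifacts <- function(rec, threshold = 30, freeze = 2,
                                 frame_len = 32L) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- channel_data(rec, eog_channels())
  comp <- eog_components(x)
  h <- lowfreq_envelope(comp$heog, rec$rate)
  v <- lowfreq_envelope(comp$veog, rec$rate)
  n <- nrow(x)
  nfr <- n %/% frame_len
  if (nfr == 0) stop("recording shorter than one EOG frame")
  idx <- matrix(seq_len(nfr * frame_len), nrow = frame_len)
  amp <- pmax(apply(matrix(h[idx], nrow = frame_len), 2, max),
              apply(matrix(v[idx], nrow = frame_len), 2, max))
  flag <- amp > threshold
  fstart <- (seq_len(nfr) - 1) * frame_len / rec$rate
  fend <- fstart + frame_len / rec$rate
  frames <- data.frame(start = fstart, end = fend, flag = flag)
  intervals <- merge_intervals(
    data.frame(start = fstart[flag], end = fend[flag] + freeze)
  )
  list(frames = frames, intervals = intervals,
       flagged_fraction = mean(flag))
}

# Internal: merge overlapping [start, end] intervals.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1]
  out_e <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
      } else {
        out_s <- c(out_s, iv$start[i])
        out_e <- c(out_e, iv$end[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}
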