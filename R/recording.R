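#' EEG recording container
#'
#' A light container for a multichannel EEG recording: a numeric
#' time-by-channel matrix in microvolts, the sampling rate, ordered channel
#' labels (10-20 system), and free-form run metadata (session date, run
#' index, run type).
#'
#' @param data numeric matrix, time samples in rows, channels in columns (uV).
#' @param rate sampling rate in Hz.
#' @param channels character vector of channel labels, one per column.
#' @param meta named list of metadata (e.g. `run_index`, `run_type`, `date`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channels, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (length(channels) != ncol(data)) {
    stop("length(channels) must equal ncol(data)")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a positive scalar (Hz)")
  }
  colnames(data) <- channels
  structure(
    list(data = data, rate = rate, channels = as.character(channels),
         meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$data) / x$rate))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$rate

#' Write / read a recording as a plain-text container
#'
#' Recordings are serialized as a CSV sample matrix plus a JSON sidecar
#' carrying the rate, channel order and metadata, so that sessions survive
#' round trips through text-only storage.
#'
#' @param rec an `eeg_recording`.
#' @param path base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.csv(as.data.frame(rec$data), paste0(path, ".csv"),
                   row.names = FALSE)
  side <- list(rate = rec$rate, channels = rec$channels, meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param path base path used at write time.
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(side)) {
    stop("recording container not found at ", path)
  }
  dat <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  eeg_recording(dat, rate = info$rate, channels = info$channels,
                meta = as.list(info$meta))
}

# Internal: select channel columns by label with a structural error on miss.
channel_data <- function(rec, labels) {
  miss <- setdiff(labels, rec$channels)
  if (length(miss)) {
    stop("channels missing from recording: ", paste(miss, collapse = ", "))
  }
  rec$data[, labels, drop = FALSE]
}
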