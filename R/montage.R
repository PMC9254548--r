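#' Sensorimotor 10-20 montage
#'
#' The 14-channel sensorimotor montage used for decoding (Fz, FC3, FC1, FCz,
#' FC2, FC4, C3, C1, Cz, C2, C4, CP1, CPz, CP2), with approximate planar
#' 10-20 grid coordinates and cross-shaped (orthogonal nearest-neighbor)
#' adjacency restricted to this channel set. Edge channels keep whatever
#' orthogonal neighbors exist.
#'
#' @return A list of class `montage` with elements `channels` (ordered
#'   labels), `coords` (channels x 2 matrix, lateral x / anterior y grid
#'   units) and `neighbors` (named list of neighbor label vectors).
#' @export
sensorimotor_montage <- function() {
  coords <- rbind(
    Fz  = c(0, 2),
    FC3 = c(-2, 1), FC1 = c(-1, 1), FCz = c(0, 1), FC2 = c(1, 1),
    FC4 = c(2, 1),
    C3  = c(-2, 0), C1  = c(-1, 0), Cz  = c(0, 0), C2  = c(1, 0),
    C4  = c(2, 0),
    CP1 = c(-1, -1), CPz = c(0, -1), CP2 = c(1, -1)
  )
  colnames(coords) <- c("x", "y")
  chans <- rownames(coords)
  neighbors <- lapply(chans, function(ch) {
    dx <- coords[, "x"] - coords[ch, "x"]
    dy <- coords[, "y"] - coords[ch, "y"]
    # orthogonal step on the grid: one unit along exactly one axis
    nb <- chans[(abs(dx) == 1 & dy == 0) | (dx == 0 & abs(dy) == 1)]
    setdiff(nb, ch)
  })
  names(neighbors) <- chans
  structure(list(channels = chans, coords = coords, neighbors = neighbors),
            class = "montage")
}

#' EOG channel labels used by the artifact guard
#' @return Character vector of the two frontal EOG channel labels.
#' @export
eog_channels <- function() c("EOG_Fp1", "EOG_Fp2")

#' Laplacian spatial filter
#'
#' Subtracts from each montage channel the mean of its adjacent electrodes,
#' acting as a spatial high-pass that sharpens focal sensorimotor activity
#' and removes common-mode components. Channels with no neighbors, and
#' channels not present in the montage (e.g. EOG), pass through unchanged.
#' Channel order and sampling rate are preserved.
#'
#' @param rec an `eeg_recording` containing all montage channels.
#' @param montage a `montage` (default [sensorimotor_montage()]).
#' @return A filtered `eeg_recording`.
#' @export
laplacian_filter <- function(rec, montage = sensorimotor_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(montage$channels, rec$channels)
  if (length(miss)) {
    stop("montage channels missing from recording: ",
         paste(miss, collapse = ", "))
  }
  out <- rec$data
  for (ch in montage$channels) {
    nb <- montage$neighbors[[ch]]
    if (length(nb)) {
      out[, ch] <- rec$data[, ch] - rowMeans(rec$data[, nb, drop = FALSE])
    }
  }
  eeg_recording(out, rec$rate, rec$channels, rec$meta)
}
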