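#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels, so the referenced
#' data have zero channel mean at each time point. Idempotent.
#'
#' @param rec an [EEGRecording-class] with at least two channels.
#' @return the re-referenced [EEGRecording-class] (same shape).
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2) stop("average reference requires at least 2 channels")
  rec@data <- sweep(rec@data, 2, colMeans(rec@data))
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward per channel
#' (zero phase; the effective magnitude order is twice `order`).
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi band edges in Hz, `0 < lo < hi < sampleRate / 2`.
#' @param order Butterworth order of each pass (default 4).
#' @return the filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(rec, lo = 1, hi = 30, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@sampleRate
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("band (", lo, ", ", hi, ") outside (0, Nyquist = ", fs / 2, ")")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  # channels are demeaned first: DC lies outside the passband, and removing
  # it up front avoids step transients at the record edges
  out <- t(apply(rec@data, 1, function(x) signal::filtfilt(bf, x - mean(x))))
  dimnames(out) <- dimnames(rec@data)
  rec@data <- out
  rec
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the recording into contiguous epochs of `epochLengthS` seconds;
#' any trailing remainder shorter than one epoch is discarded. Pure
#' segmentation: concatenating the epochs reproduces the (truncated)
#' input exactly.
#'
#' @param rec an [EEGRecording-class].
#' @param epochLengthS epoch length in seconds (default 5).
#' @return an [EpochSet-class]; zero epochs (with a warning) if the
#'   recording is shorter than one epoch.
#' @export
epochRecording <- function(rec, epochLengthS = 5) {
  stopifnot(is(rec, "EEGRecording"))
  if (epochLengthS <= 0) stop("epochLengthS must be positive")
  fs <- rec@sampleRate
  nsamp <- round(epochLengthS * fs)
  ne <- floor(ncol(rec@data) / nsamp)
  if (ne == 0) warning("recording shorter than one epoch; returning 0 epochs")
  k <- nrow(rec@data)
  ep <- array(0, dim = c(ne, k, nsamp))
  for (i in seq_len(ne))
    ep[i, , ] <- rec@data[, ((i - 1L) * nsamp + 1L):(i * nsamp)]
  new("EpochSet", epochs = ep, epochLengthS = epochLengthS, sampleRate = fs,
      channelLabels = rec@channelLabels, subjectId = rec@subjectId,
      group = rec@group, moca = rec@moca,
      params = list(epochLengthS = epochLengthS))
}

#' Per-epoch baseline correction
#'
#' Subtracts each epoch's per-channel mean. In continuous resting-state
#' data the epoch itself is the only available baseline.
#'
#' @param epochs an [EpochSet-class].
#' @return the baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  ep <- epochs@epochs
  mu <- apply(ep, c(1, 2), mean)
  epochs@epochs <- ep - as.vector(mu)   # recycles over the sample dimension
  epochs
}

#' Full preprocessing chain
#'
#' Reference to the common average, band-pass filter, segment into
#' non-overlapping epochs, baseline-correct each epoch — in that order.
#' `cleaner` is an optional artifact-removal hook: a function
#' `EEGRecording -> EEGRecording` applied after filtering (e.g. an external
#' ICA-based cleaner); the default passes the data through unchanged.
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi band-pass edges in Hz (defaults 1 and 30).
#' @param epochLengthS epoch length in seconds (default 5).
#' @param order Butterworth order per pass (default 4).
#' @param cleaner optional artifact-removal function, or `NULL`.
#' @return an [EpochSet-class].
#' @export
preprocessRecording <- function(rec, lo = 1, hi = 30, epochLengthS = 5,
                                order = 4, cleaner = NULL) {
  rec <- averageReference(rec)
  rec <- bandpassFilter(rec, lo = lo, hi = hi, order = order)
  if (!is.null(cleaner)) {
    rec <- cleaner(rec)
    if (!is(rec, "EEGRecording")) stop("cleaner must return an EEGRecording")
  }
  ep <- epochRecording(rec, epochLengthS = epochLengthS)
  ep@params <- list(lo = lo, hi = hi, order = order,
                    epochLengthS = epochLengthS,
                    cleaner = !is.null(cleaner))
  baselineCorrect(ep)
}
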