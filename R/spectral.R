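#' Canonical EEG frequency bands
#'
#' The three bands analysed throughout the package: delta (1-4 Hz), theta
#' (4-7 Hz), alpha (8-13 Hz). Band membership is half-open, `lo <= f < hi`,
#' so theta's 4 Hz lower edge is not double-counted with delta.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha"),
             lo = c(1, 4, 8), hi = c(4, 7, 13),
             stringsAsFactors = FALSE)
}

resolve_band <- function(band, bands = eegBands()) {
  if (is.character(band)) {
    row <- bands[bands$name == band, ]
    if (!nrow(row)) stop("unknown band name: ", band)
    c(row$lo, row$hi)
  } else {
    if (length(band) != 2 || band[1] >= band[2]) stop("band must be (lo, hi) with lo < hi")
    as.numeric(band)
  }
}

welch_window <- function(name, n) {
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    rectangular = rep(1, n),
    stop("unknown window: ", name))
}

# Welch one-sided PSD (density, unit^2/Hz) of a channels x samples matrix,
# averaged over 50%-style overlapping windowed segments. Each segment is
# mean-subtracted before windowing.
welch_psd_matrix <- function(x, fs, segmentS, overlapFrac, window) {
  k <- nrow(x); n <- ncol(x)
  nseg <- round(segmentS * fs)
  if (nseg < 2) stop("segment too short")
  if (nseg > n) stop("Welch segment longer than the available data")
  if (overlapFrac < 0 || overlapFrac >= 1) stop("overlapFrac must be in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlapFrac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- welch_window(window, nseg)
  U <- fs * sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- matrix(0, k, nf)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- mvfft(t(seg) * w)               # nseg x k complex
    P <- t(Mod(X[seq_len(nf), , drop = FALSE])^2) / U
    # one-sided: double all bins except DC and (even nseg) Nyquist
    dbl <- 2:(nf - if (nseg %% 2 == 0) 1L else 0L)
    P[, dbl] <- 2 * P[, dbl]
    acc <- acc + P
  }
  list(freqs = (seq_len(nf) - 1L) / segmentS, power = acc / length(starts),
       nSegments = length(starts))
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram per channel. For an [EpochSet-class] the
#' average runs over the Welch segments of every epoch; a plain matrix
#' (channels x samples) or numeric vector is treated as a single epoch.
#' Frequency resolution is `1 / segmentS`; the returned power is a
#' one-sided spectral density (microV^2/Hz) so that summing
#' `power * df` over all bins recovers the signal variance.
#'
#' @param x an [EpochSet-class], a channels x samples matrix, or a numeric
#'   vector.
#' @param sampleRate sampling rate in Hz (taken from `x` for an EpochSet).
#' @param segmentS Welch segment length in seconds (default 2).
#' @param overlapFrac fractional overlap between segments (default 0.5).
#' @param window taper name: `hamming` (default), `hann` or `rectangular`.
#' @return a [PSDResult-class].
#' @export
welchPsd <- function(x, sampleRate = NULL, segmentS = 2, overlapFrac = 0.5,
                     window = "hamming") {
  if (is(x, "EpochSet")) {
    fs <- x@sampleRate
    ne <- nEpochs(x)
    if (round(segmentS * fs) > dim(x@epochs)[3])
      stop("Welch segment longer than the epoch length")
    acc <- NULL; freqs <- NULL; nsegTot <- 0L
    for (i in seq_len(ne)) {
      r <- welch_psd_matrix(epochMatrix(x, i), fs, segmentS, overlapFrac, window)
      freqs <- r$freqs
      acc <- if (is.null(acc)) r$power * r$nSegments else acc + r$power * r$nSegments
      nsegTot <- nsegTot + r$nSegments
    }
    power <- acc / nsegTot
    labels <- x@channelLabels
  } else {
    if (is.null(sampleRate)) stop("sampleRate is required for matrix/vector input")
    fs <- sampleRate
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    r <- welch_psd_matrix(m, fs, segmentS, overlapFrac, window)
    freqs <- r$freqs; power <- r$power
    labels <- rownames(m)
  }
  if (!is.null(labels)) rownames(power) <- labels
  new("PSDResult", freqs = freqs, power = power,
      params = list(segmentS = segmentS, overlapFrac = overlapFrac,
                    window = window, sampleRate = fs))
}

#' Per-channel band power from a PSD
#'
#' Mean spectral density over the frequency bins `f` with
#' `lo <= f < hi` (half-open convention). The mean rather than the integral
#' is used so the value is invariant to the frequency resolution; group
#' contrasts are unaffected by this choice.
#'
#' @param psd a [PSDResult-class].
#' @param band a band name from [eegBands()] or a numeric `(lo, hi)` pair in
#'   Hz.
#' @return named numeric vector, one scalar per channel.
#' @export
bandPower <- function(psd, band) {
  stopifnot(is(psd, "PSDResult"))
  b <- resolve_band(band)
  sel <- psd@freqs >= b[1] & psd@freqs < b[2]
  if (!any(sel)) stop("no frequency bins inside band (", b[1], ", ", b[2], ")")
  rowMeans(psd@power[, sel, drop = FALSE])
}

#' Long-format band-power table for a cohort
#'
#' Runs the full per-subject pipeline — preprocessing (average reference,
#' band-pass, epoching, baseline) then Welch PSD and band power — and
#' returns one row per subject x electrode x band.
#'
#' @param recordings list of [EEGRecording-class], all sharing one montage
#'   and sampling rate.
#' @param bands band definition data.frame (default [eegBands()]).
#' @param lo,hi band-pass edges in Hz.
#' @param epochLengthS epoch length in seconds.
#' @param segmentS,overlapFrac,window Welch parameters.
#' @return data.frame with columns `subject_id`, `group`, `moca`,
#'   `electrode`, `band`, `power`.
#' @export
cohortBandTable <- function(recordings, bands = eegBands(), lo = 1, hi = 30,
                            epochLengthS = 5, segmentS = 2,
                            overlapFrac = 0.5, window = "hamming") {
  stopifnot(length(recordings) > 0)
  ref <- recordings[[1]]
  for (r in recordings) {
    if (!identical(channelLabels(r), channelLabels(ref)) ||
        !identical(sampleRate(r), sampleRate(ref)))
      stop("inconsistent montage or sampling rate across recordings")
  }
  out <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    ep <- preprocessRecording(rec, lo = lo, hi = hi,
                              epochLengthS = epochLengthS)
    psd <- welchPsd(ep, segmentS = segmentS, overlapFrac = overlapFrac,
                    window = window)
    rows <- lapply(seq_len(nrow(bands)), function(b) {
      bp <- bandPower(psd, c(bands$lo[b], bands$hi[b]))
      data.frame(subject_id = subjectId(rec), group = groupLabel(rec),
                 moca = mocaScore(rec), electrode = channelLabels(rec),
                 band = bands$name[b], power = unname(bp),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
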