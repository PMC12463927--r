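#' Phase randomization of multichannel data
#'
#' Independently per channel: FFT, replace the phases of all
#' non-DC/non-Nyquist bins with uniform random phases (respecting conjugate
#' symmetry so the result is real), inverse FFT. The amplitude spectrum of
#' every channel is preserved exactly while all cross-channel phase
#' relations are destroyed — the null transformation of the surrogate
#' significance test.
#'
#' Uses the current RNG stream (seed via `set.seed()`).
#'
#' @param x channels x samples numeric matrix, or a numeric vector.
#' @return same-shape real matrix/vector.
#' @export
phaseRandomize <- function(x) {
  vec <- !is.matrix(x)
  m <- if (vec) matrix(x, nrow = 1) else x
  if (!all(is.finite(m))) stop("input contains non-finite values")
  n <- ncol(m)
  top <- (n - 1L) %/% 2L
  out <- m
  for (ch in seq_len(nrow(m))) {
    F <- fft(m[ch, ])
    if (top >= 1L) {
      ph <- runif(top, 0, 2 * pi)
      idx <- 2L:(top + 1L)
      F[idx] <- Mod(F[idx]) * exp(1i * ph)
      F[n + 2L - idx] <- Conj(F[idx])
    }
    out[ch, ] <- Re(fft(F, inverse = TRUE)) / n
  }
  if (vec) out[1, ] else out
}

band_freq_grid <- function(bands, gridStep = 0.5, fLo = 1, fHi = 30) {
  grid <- seq(fLo, fHi, by = gridStep)
  lapply(seq_len(nrow(bands)), function(b)
    grid[grid >= bands$lo[b] & grid < bands$hi[b]])
}

epochs_as_list <- function(epochs) {
  if (is(epochs, "EpochSet"))
    lapply(seq_len(nEpochs(epochs)), function(i) epochMatrix(epochs, i))
  else if (is.list(epochs)) epochs
  else list(epochs)
}

#' Surrogate null distribution for DTF_Mean
#'
#' Builds the empirical null of the band-averaged DTF under the hypothesis
#' of no cross-channel coupling: for each surrogate, every epoch is
#' phase-randomized channel-wise, the MVAR model refitted, and the
#' epoch-averaged DTF_Mean recomputed. Per edge and band the significance
#' threshold is the sorted surrogate value at rank
#' `ceiling((1 - alpha) * nSurrogates)` — rank 950 of 1000 at alpha = 0.05.
#'
#' Surrogate fits that fail (singular or non-finite) are redrawn; more than
#' `retryBudget` failures abort with an error reporting the count.
#'
#' @param epochs an [EpochSet-class] or list of channels x samples matrices.
#' @param bands band definition data.frame (default [eegBands()]).
#' @param p MVAR order (default 2).
#' @param nSurrogates number of surrogates (>= 20; default 1000).
#' @param alpha significance level (default 0.05).
#' @param gridStep frequency grid step in Hz (default 0.5, over 1-30 Hz).
#' @param retryBudget redraw budget for failed surrogate fits.
#' @param fs sampling rate in Hz; required when `epochs` is a bare matrix
#'   list (taken from the EpochSet otherwise).
#' @return a [SurrogateNull-class].
#' @export
surrogateThreshold <- function(epochs, bands = eegBands(), p = 2,
                               nSurrogates = 1000, alpha = 0.05,
                               gridStep = 0.5, retryBudget = 20L,
                               fs = NULL) {
  nSurrogates <- as.integer(nSurrogates)
  if (nSurrogates < 20L) stop("nSurrogates must be at least 20")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  eplist <- epochs_as_list(epochs)
  if (is(epochs, "EpochSet")) fs <- epochs@sampleRate
  if (is.null(fs)) stop("fs is required when epochs is not an EpochSet")
  bf <- band_freq_grid(bands, gridStep)
  res <- cpp_surrogate_band_dtf(eplist, as.integer(p), fs, bf,
                                nSurrogates, as.integer(retryBudget))
  vals <- res$values                       # k x k x nbands x nSurr
  k <- dim(vals)[1]
  nb <- dim(vals)[3]
  # sort each edge's surrogate values: one radix order over (edge, value)
  m <- matrix(vals, nrow = k * k * nb)     # rows = (target, source, band)
  m <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  sorted <- array(m, dim = c(k, k, nb, nSurrogates))
  rank <- as.integer(ceiling((1 - alpha) * nSurrogates))
  thr <- lapply(seq_len(nrow(bands)), function(b) {
    tm <- sorted[, , b, rank]
    diag(tm) <- 0
    tm
  })
  names(thr) <- bands$name
  new("SurrogateNull", values = sorted, thresholds = thr,
      bands = bands$name, nSurrogates = nSurrogates, alpha = alpha,
      rankIndex = rank)
}

#' Apply surrogate thresholds to a DTF_Mean matrix
#'
#' Entries strictly greater than their edge threshold are kept; all others
#' (including exact ties — conservative) are set to 0, as is the diagonal.
#'
#' @param dtfMeanMat target x source DTF_Mean matrix.
#' @param null a [SurrogateNull-class].
#' @param band band name present in `null`.
#' @return thresholded target x source matrix.
#' @export
thresholdNetwork <- function(dtfMeanMat, null, band) {
  stopifnot(is(null, "SurrogateNull"))
  if (!band %in% null@bands) stop("band not present in the surrogate null: ", band)
  thr <- null@thresholds[[band]]
  if (!all(dim(dtfMeanMat) == dim(thr))) stop("shape mismatch between matrix and thresholds")
  out <- ifelse(dtfMeanMat > thr, dtfMeanMat, 0)
  diag(out) <- 0
  out
}

#' Subject-level DTF connectivity with surrogate thresholding
#'
#' The connectivity stage for one subject: per-epoch MVAR fits, band- and
#' epoch-averaged DTF_Mean matrices, and (when `nSurrogates > 0`) the
#' phase-randomization surrogate null with thresholded networks. The
#' observed statistic and the surrogate null are computed with one shared
#' numerical core, evaluated at the in-band grid frequencies.
#'
#' @param epochs an [EpochSet-class].
#' @param bands band definition data.frame (default [eegBands()]).
#' @param order MVAR order (default 2) or `"auto"` for BIC selection over
#'   `1:6` on the first epoch.
#' @param nSurrogates surrogate count (default 1000; 0 disables
#'   thresholding).
#' @param alpha surrogate significance level (default 0.05).
#' @param gridStep frequency grid step in Hz (default 0.5).
#' @return a [ConnectivityResult-class].
#' @export
subjectConnectivity <- function(epochs, bands = eegBands(), order = 2,
                                nSurrogates = 1000, alpha = 0.05,
                                gridStep = 0.5) {
  stopifnot(is(epochs, "EpochSet"))
  if (nEpochs(epochs) < 1) stop("no epochs to analyse")
  eplist <- epochs_as_list(epochs)
  fs <- epochs@sampleRate
  if (identical(order, "auto")) order <- selectOrderBIC(eplist[[1]], 1:6)
  order <- as.integer(order)
  bf <- band_freq_grid(bands, gridStep)
  obs <- cpp_epoch_band_dtf(eplist, order, fs, bf)   # k x k x nbands
  labels <- epochs@channelLabels
  dm <- lapply(seq_len(nrow(bands)), function(b) {
    m <- obs[, , b]
    dimnames(m) <- list(target = labels, source = labels)
    m
  })
  names(dm) <- bands$name
  null <- NULL; thr <- list()
  if (nSurrogates > 0) {
    null <- surrogateThreshold(epochs, bands = bands, p = order,
                               nSurrogates = nSurrogates, alpha = alpha,
                               gridStep = gridStep)
    thr <- lapply(bands$name, function(b) thresholdNetwork(dm[[b]], null, b))
    names(thr) <- bands$name
  }
  new("ConnectivityResult", dtfMean = dm, thresholded = thr, null = null,
      bands = bands, order = order, nEpochs = nEpochs(epochs),
      channelLabels = labels, subjectId = epochs@subjectId,
      group = epochs@group, moca = epochs@moca)
}

#' Long-format connectivity table for a cohort
#'
#' Runs preprocessing and [subjectConnectivity()] for every recording and
#' returns one row per subject x band x directed edge (diagonal excluded):
#' the DTF_Mean value, its surrogate threshold, the thresholded value and a
#' significance flag.
#'
#' @param recordings list of [EEGRecording-class].
#' @param bands band definition data.frame.
#' @param lo,hi,epochLengthS preprocessing parameters.
#' @param order,nSurrogates,alpha,gridStep connectivity parameters (see
#'   [subjectConnectivity()]).
#' @return data.frame with columns `subject_id`, `group`, `moca`, `band`,
#'   `source`, `target`, `value`, `threshold`, `thresholded`, `significant`.
#' @export
cohortConnectivityTable <- function(recordings, bands = eegBands(), lo = 1,
                                    hi = 30, epochLengthS = 5, order = 2,
                                    nSurrogates = 1000, alpha = 0.05,
                                    gridStep = 0.5) {
  out <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    ep <- preprocessRecording(rec, lo = lo, hi = hi,
                              epochLengthS = epochLengthS)
    cr <- subjectConnectivity(ep, bands = bands, order = order,
                              nSurrogates = nSurrogates, alpha = alpha,
                              gridStep = gridStep)
    labels <- cr@channelLabels
    k <- length(labels)
    offdiag <- which(row(matrix(0, k, k)) != col(matrix(0, k, k)))
    rows <- lapply(bands$name, function(b) {
      m <- cr@dtfMean[[b]]
      thr <- if (!is.null(cr@null)) cr@null@thresholds[[b]] else matrix(NA_real_, k, k)
      tm <- if (length(cr@thresholded)) cr@thresholded[[b]] else m
      data.frame(subject_id = subjectId(rec), group = groupLabel(rec),
                 moca = mocaScore(rec), band = b,
                 source = labels[col(m)[offdiag]],
                 target = labels[row(m)[offdiag]],
                 value = m[offdiag], threshold = thr[offdiag],
                 thresholded = tm[offdiag],
                 significant = if (!is.null(cr@null)) m[offdiag] > thr[offdiag] else NA,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
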