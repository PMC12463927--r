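#' Channel labels of an EEG object
#' @param x an object with electrode labels.
#' @return character vector of electrode names.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Sampling rate of an EEG object
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Raw data matrix of a recording
#' @param x an [EEGRecording-class].
#' @return channels x samples numeric matrix.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' Subject identifier
#' @param x an object carrying subject metadata.
#' @return subject id string.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Group label (NC or MCI)
#' @param x an object carrying subject metadata.
#' @return group label string.
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' MoCA score
#' @param x an object carrying subject metadata.
#' @return MoCA score (0-30) or NA.
#' @export
setGeneric("mocaScore", function(x) standardGeneric("mocaScore"))

#' Number of epochs
#' @param x an [EpochSet-class].
#' @return epoch count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "MontageSpec", function(x) x@channelLabels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "ConnectivityResult", function(x) x@channelLabels)

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)

#' @rdname eegData
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname subjectId
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname subjectId
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @rdname groupLabel
#' @export
setMethod("groupLabel", "EEGRecording", function(x) x@group)
#' @rdname groupLabel
#' @export
setMethod("groupLabel", "EpochSet", function(x) x@group)

#' @rdname mocaScore
#' @export
setMethod("mocaScore", "EEGRecording", function(x) x@moca)
#' @rdname mocaScore
#' @export
setMethod("mocaScore", "EpochSet", function(x) x@moca)

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])

#' Extract one epoch as a channels x samples matrix
#'
#' @param x an [EpochSet-class].
#' @param i epoch index.
#' @return channels x samples numeric matrix.
#' @export
epochMatrix <- function(x, i) {
  stopifnot(is(x, "EpochSet"))
  if (i < 1 || i > nEpochs(x)) stop("epoch index out of range")
  m <- x@epochs[i, , , drop = FALSE]
  dim(m) <- dim(x@epochs)[2:3]
  rownames(m) <- x@channelLabels
  m
}

#' Band-averaged DTF matrix of a subject
#'
#' @param x a [ConnectivityResult-class].
#' @param band band name.
#' @param thresholded if TRUE, return the surrogate-thresholded network.
#' @return target x source numeric matrix.
#' @export
dtfMeanMatrix <- function(x, band, thresholded = FALSE) {
  stopifnot(is(x, "ConnectivityResult"))
  src <- if (thresholded) x@thresholded else x@dtfMean
  if (!band %in% names(src)) stop("unknown band: ", band)
  src[[band]]
}

setMethod("show", "MontageSpec", function(object) {
  tab <- table(factor(object@regionOf[object@channelLabels], levels = EEG_REGIONS))
  cat("MontageSpec with", length(object@channelLabels), "electrodes\n")
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz, MoCA %s\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@sampleRate,
              ifelse(is.na(object@moca), "NA", format(object@moca))))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s' (%s): %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              object@subjectId, object@group, d[1], d[2], d[3],
              object@epochLengthS, object@sampleRate))
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: order %d, %d channels, %d samples, %s\n",
              object@order, nrow(object@resCov), object@nSamplesUsed,
              if (object@stable) "stable" else "UNSTABLE"))
})

setMethod("show", "DTFResult", function(object) {
  cat(sprintf("DTFResult: %d x %d channels over %d frequencies (%g-%g Hz)\n",
              object@k, object@k, length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "SurrogateNull", function(object) {
  cat(sprintf("SurrogateNull: %d surrogates, alpha %g (rank %d), bands: %s\n",
              object@nSurrogates, object@alpha, object@rankIndex,
              paste(object@bands, collapse = ", ")))
})

setMethod("show", "ConnectivityResult", function(object) {
  cat(sprintf("ConnectivityResult '%s' (%s): %d channels, order %d, %d epochs\n",
              object@subjectId, object@group, length(object@channelLabels),
              object@order, object@nEpochs))
  cat("  bands:", paste(object@bands$name, collapse = ", "),
      if (length(object@thresholded)) "(surrogate-thresholded)" else "(unthresholded)", "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects/group, %g s @ %g Hz, seed %d\n",
              object@nSubjectsPerGroup, object@durationS, object@sampleRateHz,
              object@seed))
  cat(sprintf("  %d band effect(s), %d coupling(s), noise sd %g\n",
              nrow(object@bandEffects), nrow(object@couplings), object@noiseSd))
})
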