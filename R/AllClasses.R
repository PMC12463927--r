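EEG_REGIONS <- c("frontal", "central", "temporal", "parietal", "occipital")
EEG_GROUPS <- c("NC", "MCI")

#' Electrode montage with region assignment
#'
#' A ten-twenty montage of 32 electrodes, each assigned to exactly one scalp
#' region (frontal, central, temporal, parietal, occipital). Region
#' membership drives the lobe-level summaries and the bottom-up/top-down
#' orientation of directed edges.
#'
#' @slot channelLabels ordered character vector of 32 unique electrode names.
#' @slot regionOf named character vector mapping every label to a region.
#' @seealso [defaultMontage()], [mapRegion()]
#' @export
setClass("MontageSpec",
  representation(channelLabels = "character", regionOf = "character"),
  validity = function(object) {
    msg <- character()
    lab <- object@channelLabels
    if (length(lab) != 32L) msg <- c(msg, "montage must have exactly 32 channel labels")
    if (anyDuplicated(lab)) msg <- c(msg, "channel labels must be unique")
    reg <- object@regionOf
    if (!setequal(names(reg), lab)) msg <- c(msg, "regionOf must map every channel label exactly once")
    if (!all(reg %in% EEG_REGIONS))
      msg <- c(msg, sprintf("regions must be one of: %s", paste(EEG_REGIONS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' One subject's EEG recording
#'
#' Multichannel EEG as a channels x samples matrix (microvolts) with
#' montage labels, sampling rate and subject metadata (group label and
#' MoCA score).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot channelLabels ordered electrode names, one per row of `data`.
#' @slot sampleRate sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot group `"NC"` or `"MCI"`.
#' @slot moca MoCA score in [0, 30] (`NA` if unknown).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", channelLabels = "character",
                 sampleRate = "numeric", subjectId = "character",
                 group = "character", moca = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@channelLabels))
      msg <- c(msg, "data row count must equal channel label count")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    if (!object@group %in% EEG_GROUPS)
      msg <- c(msg, "group must be 'NC' or 'MCI'")
    if (!is.na(object@moca) && (object@moca < 0 || object@moca > 30))
      msg <- c(msg, "moca must be in [0, 30]")
    if (length(msg)) msg else TRUE
  }
)

#' Epoch-segmented EEG
#'
#' Contiguous, non-overlapping fixed-length epochs of one recording, stored
#' as an epoch x channel x sample array, with the preprocessing provenance
#' needed to interpret them.
#'
#' @slot epochs numeric array, epoch x channel x sample.
#' @slot epochLengthS epoch length in seconds.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelLabels electrode names.
#' @slot subjectId subject identifier.
#' @slot group group label carried from the recording.
#' @slot moca MoCA score carried from the recording.
#' @slot params list of preprocessing parameters applied upstream.
#' @export
setClass("EpochSet",
  representation(epochs = "array", epochLengthS = "numeric",
                 sampleRate = "numeric", channelLabels = "character",
                 subjectId = "character", group = "character",
                 moca = "numeric", params = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@epochs)
    if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
    else {
      if (d[2] != length(object@channelLabels))
        msg <- c(msg, "second dimension must equal channel count")
      if (d[3] != round(object@epochLengthS * object@sampleRate))
        msg <- c(msg, "sample count per epoch must equal epochLengthS * sampleRate")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Welch power spectral density estimate
#'
#' One-sided spectral density per channel on a regular frequency grid, with
#' the Welch parameters that produced it.
#'
#' @slot freqs strictly increasing frequency grid in Hz.
#' @slot power channel x frequency matrix (microV^2/Hz), non-negative.
#' @slot params list of Welch parameters (segment length, overlap, window,
#'   sampling rate).
#' @export
setClass("PSDResult",
  representation(freqs = "numeric", power = "matrix", params = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@power) != length(object@freqs))
      msg <- c(msg, "power columns must match freqs")
    if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "freqs must be strictly increasing")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted multivariate autoregressive model
#'
#' Order-p MVAR fit for one epoch: coefficient matrices `A[[n]]` (k x k,
#' the weight of every channel's lag-n past in each channel's present),
#' residual covariance, and a stability flag (all companion-matrix
#' eigenvalues inside the unit circle).
#'
#' @slot order model order p.
#' @slot A list of p coefficient matrices, each k x k.
#' @slot resCov k x k residual covariance.
#' @slot nSamplesUsed number of regression rows used in the fit.
#' @slot stable logical stability flag.
#' @slot channelLabels optional electrode names.
#' @export
setClass("MVARModel",
  representation(order = "integer", A = "list", resCov = "matrix",
                 nSamplesUsed = "integer", stable = "logical",
                 channelLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (object@order < 1L) msg <- c(msg, "order must be >= 1")
    if (length(object@A) != object@order) msg <- c(msg, "A must hold `order` matrices")
    k <- nrow(object@resCov)
    if (ncol(object@resCov) != k) msg <- c(msg, "resCov must be square")
    if (!all(vapply(object@A, function(a) all(dim(a) == k), logical(1))))
      msg <- c(msg, "all coefficient matrices must be k x k")
    if (max(abs(object@resCov - t(object@resCov))) > 1e-8 * (1 + max(abs(object@resCov))))
      msg <- c(msg, "resCov must be symmetric")
    if (length(msg)) msg else TRUE
  }
)

#' Spectral transfer matrix H(f)
#'
#' Complex transfer tensor of an MVAR model on a frequency grid:
#' `H(f) = (I - sum_n A_n exp(-i 2 pi f n / fs))^-1`.
#'
#' @slot freqs frequency grid in Hz.
#' @slot H complex array, k x k x length(freqs).
#' @export
setClass("SpectralTransfer",
  representation(freqs = "numeric", H = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@H)
    if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "H must be k x k x nfreq")
    else if (d[3] != length(object@freqs)) msg <- c(msg, "third dimension must match freqs")
    if (!all(is.finite(Re(object@H))) || !all(is.finite(Im(object@H))))
      msg <- c(msg, "H must be finite at all grid frequencies")
    if (length(msg)) msg else TRUE
  }
)

#' Normalized DTF of one model
#'
#' The directed transfer function gamma^2_ij(f) = |H_ij(f)|^2 / sum_m
#' |H_im(f)|^2 — the share of inflow into target i attributable to source j
#' at frequency f. Rows (targets) sum to 1 at every frequency.
#'
#' @slot freqs frequency grid in Hz.
#' @slot gamma2 numeric array, target x source x frequency, entries in [0, 1].
#' @slot k channel count.
#' @export
setClass("DTFResult",
  representation(freqs = "numeric", gamma2 = "array", k = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@gamma2)
    if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "gamma2 must be k x k x nfreq")
    else {
      if (d[1] != object@k) msg <- c(msg, "k must match gamma2 dimensions")
      if (d[3] != length(object@freqs)) msg <- c(msg, "third dimension must match freqs")
    }
    if (any(object@gamma2 < -1e-12) || any(object@gamma2 > 1 + 1e-12))
      msg <- c(msg, "gamma2 entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Surrogate null distribution for DTF_Mean edges
#'
#' Per-edge, per-band sorted surrogate DTF_Mean values from independent
#' per-channel phase randomization, and the significance threshold at rank
#' `ceiling((1 - alpha) * nSurrogates)` (rank 950 of 1000 at alpha = 0.05).
#'
#' @slot values numeric array target x source x band x surrogate, sorted
#'   ascending along the surrogate dimension.
#' @slot thresholds named list (per band) of target x source threshold matrices.
#' @slot bands character vector of band names.
#' @slot nSurrogates number of surrogates.
#' @slot alpha significance level.
#' @slot rankIndex rank used for the threshold.
#' @export
setClass("SurrogateNull",
  representation(values = "array", thresholds = "list", bands = "character",
                 nSurrogates = "integer", alpha = "numeric",
                 rankIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(vapply(object@thresholds, function(m) any(m < 0 | m > 1), logical(1))))
      msg <- c(msg, "thresholds must lie in [0, 1]")
    if (!identical(names(object@thresholds), object@bands))
      msg <- c(msg, "thresholds must be named by band")
    if (object@rankIndex < 1L || object@rankIndex > object@nSurrogates)
      msg <- c(msg, "rankIndex must be in 1..nSurrogates")
    if (length(msg)) msg else TRUE
  }
)

#' Subject-level band-averaged DTF connectivity
#'
#' For one subject: per-band target x source DTF_Mean matrices (gamma^2
#' averaged over in-band frequencies, then over epochs), the surrogate
#' thresholds (if computed), and the thresholded networks in which
#' non-significant edges are set to 0.
#'
#' @slot dtfMean named list (per band) of target x source matrices.
#' @slot thresholded named list (per band) of thresholded matrices (empty if
#'   no surrogates were run).
#' @slot null a [SurrogateNull-class] or `NULL`.
#' @slot bands band definition data frame (name, lo, hi).
#' @slot order MVAR order used.
#' @slot nEpochs number of epochs averaged.
#' @slot channelLabels electrode names.
#' @slot subjectId,group,moca subject metadata.
#' @export
setClass("ConnectivityResult",
  representation(dtfMean = "list", thresholded = "list", null = "ANY",
                 bands = "data.frame", order = "integer", nEpochs = "integer",
                 channelLabels = "character", subjectId = "character",
                 group = "character", moca = "numeric"))

#' Specification of a synthetic two-cohort EEG study
#'
#' Parameters of the synthetic generator: cohort sizes, recording duration
#' and rate, per-group multiplicative band-power effects on chosen
#' electrodes, directed lagged couplings between chosen channel pairs,
#' broadband noise level, per-group MoCA distributions, an optional linear
#' MoCA-coupling link, and the master seed.
#'
#' @slot nSubjectsPerGroup subjects per group.
#' @slot durationS recording duration in seconds.
#' @slot sampleRateHz sampling rate in Hz.
#' @slot bandEffects data.frame(group, band, electrode, multiplier).
#' @slot couplings data.frame(group, source, target, band, strength, lag).
#' @slot noiseSd broadband white-noise standard deviation.
#' @slot bandAmplitude named numeric (delta, theta, alpha): baseline
#'   amplitude of each band oscillator, emulating the 1/f shape of resting
#'   EEG (slow rhythms strongest).
#' @slot oscRadius named numeric (delta, theta, alpha): AR(2) pole radius
#'   per band; delta is broad, alpha sharp, mirroring the sharpness of the
#'   physiological rhythms.
#' @slot mocaMean,mocaSd named numeric (NC, MCI) MoCA means and SDs.
#' @slot mocaLink MoCA points added per coupling-strength z-score (0 = no link).
#' @slot couplingCv coefficient of variation of per-subject coupling strength.
#' @slot seed master RNG seed.
#' @export
setClass("CohortSpec",
  representation(nSubjectsPerGroup = "integer", durationS = "numeric",
                 sampleRateHz = "numeric", bandEffects = "data.frame",
                 couplings = "data.frame", noiseSd = "numeric",
                 bandAmplitude = "numeric", oscRadius = "numeric",
                 mocaMean = "numeric", mocaSd = "numeric",
                 mocaLink = "numeric", couplingCv = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjectsPerGroup < 1L) msg <- c(msg, "nSubjectsPerGroup must be >= 1")
    if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
    be <- object@bandEffects
    if (nrow(be) && any(be$multiplier <= 0)) msg <- c(msg, "amplitude multipliers must be > 0")
    cp <- object@couplings
    if (nrow(cp)) {
      if (any(cp$lag < 1)) msg <- c(msg, "coupling lag must be >= 1")
      if (any(cp$strength < 0 | cp$strength >= 1)) msg <- c(msg, "coupling strength must be in [0, 1)")
    }
    bands <- eegBands()
    used <- unique(c(be$band, cp$band))
    if (length(used) && !all(used %in% bands$name))
      msg <- c(msg, "band names must be one of delta, theta, alpha")
    if (object@sampleRateHz <= 2 * max(bands$hi))
      msg <- c(msg, "sample rate must exceed twice the highest band edge")
    if (!setequal(names(object@mocaMean), EEG_GROUPS) || !setequal(names(object@mocaSd), EEG_GROUPS))
      msg <- c(msg, "mocaMean and mocaSd must be named NC and MCI")
    if (!setequal(names(object@bandAmplitude), bands$name) || any(object@bandAmplitude <= 0))
      msg <- c(msg, "bandAmplitude must be positive and named delta, theta, alpha")
    if (!setequal(names(object@oscRadius), bands$name) ||
        any(object@oscRadius <= 0 | object@oscRadius >= 1))
      msg <- c(msg, "oscRadius must be in (0, 1) and named delta, theta, alpha")
    if (length(msg)) msg else TRUE
  }
)
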