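#' Band-limited stochastic oscillator
#'
#' Generates a zero-mean, unit-variance stochastic signal whose power is
#' concentrated in the requested band, as a damped AR(2) resonator: white
#' noise driven through a two-pole filter with pole radius `r` at the band
#' midpoint frequency. This keeps the synthetic signals inside the model
#' family the connectivity stage fits (finite-order autoregression), so the
#' ground-truth spectra and couplings are exactly representable downstream.
#'
#' @param band numeric `(lo, hi)` in Hz, inside `(0, sampleRate / 2)`.
#' @param sampleRate sampling rate in Hz.
#' @param n number of samples; `n = 0` returns a zero-length series.
#' @param r pole radius of the resonator. The default scales with the band
#'   width, `r = 1 - pi * (hi - lo) / (2 * sampleRate)`, so the resonance
#'   half-power width is about half the band width and at least 70% of the
#'   generated 1-30 Hz power falls inside the requested band.
#' @param burn burn-in samples discarded so the series is stationary.
#' @return numeric vector of length `n`, zero mean and unit variance for
#'   `n >= 2`.
#' @examples
#' set.seed(1)
#' x <- makeOscillator(c(8, 13), 250, 2500)
#' @export
makeOscillator <- function(band, sampleRate, n, r = NULL, burn = 500L) {
  b <- resolve_band(band)
  if (b[1] <= 0 || b[2] >= sampleRate / 2)
    stop("band (", b[1], ", ", b[2], ") outside the open Nyquist range (0, ",
         sampleRate / 2, ")")
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  if (n == 0L) return(numeric(0))
  osc_filter(rnorm(n + burn), b, sampleRate, r = r, burn = burn)
}

# AR(2) resonator driven by `drive` (innovations, possibly plus a lagged
# source term); returns the normalized series with the burn-in dropped
osc_filter <- function(drive, band, sampleRate, r = NULL, burn = 500L) {
  if (is.null(r)) r <- 1 - pi * (band[2] - band[1]) / (2 * sampleRate)
  f0 <- mean(band)
  a1 <- 2 * r * cos(2 * pi * f0 / sampleRate)
  a2 <- -r^2
  x <- as.numeric(stats::filter(drive, c(a1, a2), method = "recursive"))
  n <- length(drive) - burn
  x <- x[(burn + 1L):(burn + n)]
  if (n >= 2L) (x - mean(x)) / sd(x) else x - x
}

#' Define a synthetic two-cohort study
#'
#' Constructor for [CohortSpec-class]. Defaults mirror the study design the
#' generator emulates: 250 Hz sampling, 5-minute recordings, MoCA
#' distributions of 26.70 (1.38) for NC and 19.91 (2.98) for MCI.
#'
#' @param nSubjectsPerGroup subjects per group (default 20).
#' @param durationS recording duration in seconds (default 300).
#' @param sampleRateHz sampling rate in Hz (default 250).
#' @param bandEffects data.frame with columns `group`, `band`, `electrode`,
#'   `multiplier`: multiplicative amplitude effects on the named band
#'   oscillator at the named electrode for subjects of `group`.
#' @param couplings data.frame with columns `group`, `source`, `target`,
#'   `band`, `strength`, `lag`: the target channel additionally receives
#'   `strength` times the source's band oscillator delayed by `lag` samples.
#' @param noiseSd broadband white-noise SD added to every channel
#'   (default 0.5; band oscillators have unit variance before the
#'   amplitude weights).
#' @param bandAmplitude named numeric baseline amplitudes of the band
#'   oscillators; the default `c(delta = 1.3, theta = 0.9, alpha = 0.7)`
#'   follows the 1/f shape of resting EEG spectra.
#' @param oscRadius named numeric AR(2) pole radius per band; the default
#'   `c(delta = 0.95, theta = 0.966, alpha = 0.969)` makes the slow delta
#'   rhythm broad and the alpha rhythm sharp, mirroring real resting-state
#'   spectra.
#' @param mocaMean,mocaSd named numeric `c(NC = , MCI = )` MoCA parameters.
#' @param mocaLink MoCA points added per coupling-strength z-score
#'   (negative values make stronger coupling co-occur with lower MoCA;
#'   0 disables the link).
#' @param couplingCv per-subject coefficient of variation of coupling
#'   strength (default 0.25).
#' @param seed master seed for [generateCohorts()].
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjectsPerGroup = 20L, durationS = 300,
                       sampleRateHz = 250, bandEffects = NULL,
                       couplings = NULL, noiseSd = 0.5,
                       bandAmplitude = c(delta = 1.3, theta = 0.9, alpha = 0.7),
                       oscRadius = c(delta = 0.95, theta = 0.966, alpha = 0.969),
                       mocaMean = c(NC = 26.70, MCI = 19.91),
                       mocaSd = c(NC = 1.38, MCI = 2.98),
                       mocaLink = 0, couplingCv = 0.25, seed = 1L) {
  empty_be <- data.frame(group = character(), band = character(),
                         electrode = character(), multiplier = numeric(),
                         stringsAsFactors = FALSE)
  empty_cp <- data.frame(group = character(), source = character(),
                         target = character(), band = character(),
                         strength = numeric(), lag = integer(),
                         stringsAsFactors = FALSE)
  new("CohortSpec",
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      durationS = durationS, sampleRateHz = sampleRateHz,
      bandEffects = if (is.null(bandEffects)) empty_be else bandEffects,
      couplings = if (is.null(couplings)) empty_cp else couplings,
      noiseSd = noiseSd, bandAmplitude = bandAmplitude,
      oscRadius = oscRadius, mocaMean = mocaMean, mocaSd = mocaSd,
      mocaLink = mocaLink, couplingCv = couplingCv, seed = as.integer(seed))
}

#' Generate one synthetic EEG subject
#'
#' Each channel is the sum of one unit-variance oscillator per band
#' (delta, theta, alpha), scaled by any matching band-effect multiplier for
#' the subject's group, plus white noise. Directed couplings are dynamic:
#' the target channel's band oscillator is regenerated with the lagged,
#' unit-variance source oscillator added (weight = `strength`) to its
#' innovations inside the AR(2) recursion, so the source's in-band signal
#' — innovations included — drives the target's band dynamics. This makes
#' the oscillator pair a genuine vector-autoregression in the oscillator
#' space, with a well-defined, recoverable direction of influence (a
#' purely additive lagged narrowband copy would be nearly deterministic
#' given the target's own past, leaving almost no directed information for
#' an autoregressive estimator). The MoCA score is drawn from the group's
#' distribution, truncated to [0, 30] and rounded to the nearest integer;
#' when `mocaLink` is non-zero it is shifted by the subject's
#' coupling-strength z-score.
#'
#' Uses the current RNG stream; seed via `set.seed()` or use
#' [generateCohorts()] for a fully deterministic cohort.
#'
#' @param spec a [CohortSpec-class].
#' @param montage a [MontageSpec-class].
#' @param group `"NC"` or `"MCI"`.
#' @param id subject identifier.
#' @return an [EEGRecording-class].
#' @export
generateSubject <- function(spec, montage = defaultMontage(), group = "NC",
                            id = "S01") {
  stopifnot(is(spec, "CohortSpec"), is(montage, "MontageSpec"))
  validObject(spec)
  if (!group %in% EEG_GROUPS) stop("group must be 'NC' or 'MCI'")
  labels <- montage@channelLabels
  elecs <- unique(c(spec@bandEffects$electrode, spec@couplings$source,
                    spec@couplings$target))
  bad <- setdiff(elecs, labels)
  if (length(bad)) stop("unknown electrode(s) in spec: ", paste(bad, collapse = ", "))

  k <- length(labels)
  fs <- spec@sampleRateHz
  n <- round(spec@durationS * fs)
  burn <- 500L
  ntot <- n + burn
  bands <- eegBands()
  norm01 <- function(x) (x - mean(x)) / sd(x)
  coefs <- lapply(seq_len(nrow(bands)), function(b) {
    bb <- c(bands$lo[b], bands$hi[b])
    r <- spec@oscRadius[bands$name[b]]
    c(2 * r * cos(2 * pi * mean(bb) / fs), -r^2)
  })

  # per-band innovations and raw (burn-in kept) base oscillators
  innov <- lapply(seq_len(nrow(bands)), function(b) matrix(rnorm(k * ntot), k))
  oscFull <- lapply(seq_len(nrow(bands)), function(b)
    t(apply(innov[[b]], 1, function(e)
      as.numeric(stats::filter(e, coefs[[b]], method = "recursive")))))
  names(innov) <- names(oscFull) <- bands$name

  # dynamic couplings: rebuild each coupled target's band oscillator with
  # the lagged normalized source oscillator added to its innovations
  cp <- spec@couplings[spec@couplings$group == group, , drop = FALSE]
  zs <- if (nrow(cp)) rnorm(nrow(cp)) else numeric(0)
  if (nrow(cp)) {
    key <- paste(cp$band, cp$target)
    for (kk in unique(key)) {
      rows <- which(key == kk)
      b <- cp$band[rows[1]]
      tgt <- match(cp$target[rows[1]], labels)
      drive <- innov[[b]][tgt, ]
      for (i in rows) {
        s <- min(0.99, cp$strength[i] * max(0, 1 + spec@couplingCv * zs[i]))
        lag <- as.integer(cp$lag[i])
        src <- norm01(oscFull[[b]][match(cp$source[i], labels), ])
        drive[(lag + 1L):ntot] <- drive[(lag + 1L):ntot] +
          s * src[1L:(ntot - lag)]
      }
      oscFull[[b]][tgt, ] <- as.numeric(
        stats::filter(drive, coefs[[match(b, bands$name)]], method = "recursive"))
    }
  }

  be <- spec@bandEffects
  dat <- matrix(rnorm(k * n, sd = spec@noiseSd), k, n)
  for (b in bands$name) {
    mult <- rep(spec@bandAmplitude[b], k)
    rows <- be[be$group == group & be$band == b, , drop = FALSE]
    if (nrow(rows))
      mult[match(rows$electrode, labels)] <- mult[match(rows$electrode, labels)] *
        rows$multiplier
    oscn <- t(apply(oscFull[[b]][, (burn + 1L):ntot, drop = FALSE], 1, norm01))
    dat <- dat + oscn * mult
  }

  moca <- spec@mocaMean[group] + spec@mocaLink * mean(c(zs, 0)) +
    rnorm(1, sd = spec@mocaSd[group])
  moca <- round(min(30, max(0, moca)))

  rownames(dat) <- labels
  new("EEGRecording", data = dat, channelLabels = labels, sampleRate = fs,
      subjectId = id, group = group, moca = unname(moca))
}

#' Generate a full two-cohort dataset
#'
#' Deterministic under `spec@seed`: NC subjects are generated first, then
#' MCI, each drawing from one seeded RNG stream. A manifest records subject
#' id, group, MoCA and the ground-truth effects active for that group.
#' If `outDir` is given, each recording is written as a TSV matrix with a
#' JSON sidecar (see [writeRecording()]) plus `manifest.csv`.
#'
#' @param spec a [CohortSpec-class].
#' @param montage a [MontageSpec-class].
#' @param outDir optional output directory.
#' @return list with elements `recordings` (list of [EEGRecording-class])
#'   and `manifest` (data.frame).
#' @export
generateCohorts <- function(spec, montage = defaultMontage(), outDir = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  np <- spec@nSubjectsPerGroup
  ids <- c(sprintf("NC%02d", seq_len(np)), sprintf("MCI%02d", seq_len(np)))
  groups <- rep(EEG_GROUPS, each = np)
  recs <- vector("list", length(ids))
  for (i in seq_along(ids))
    recs[[i]] <- generateSubject(spec, montage, groups[i], ids[i])
  manifest <- data.frame(
    subject_id = ids, group = groups,
    moca = vapply(recs, mocaScore, numeric(1)),
    n_channels = length(montage@channelLabels),
    sample_rate_hz = spec@sampleRateHz,
    duration_s = spec@durationS,
    band_effects = vapply(groups, function(g) {
      rows <- spec@bandEffects[spec@bandEffects$group == g, , drop = FALSE]
      if (!nrow(rows)) "" else paste(sprintf("%s:%s:x%g", rows$band,
                                             rows$electrode, rows$multiplier),
                                     collapse = ";")
    }, character(1)),
    couplings = vapply(groups, function(g) {
      rows <- spec@couplings[spec@couplings$group == g, , drop = FALSE]
      if (!nrow(rows)) "" else paste(sprintf("%s:%s->%s:%g@%d", rows$band,
                                             rows$source, rows$target,
                                             rows$strength, rows$lag),
                                     collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (r in recs) writeRecording(r, outDir)
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}

#' Simulate from a known MVAR process
#'
#' Draws `n` samples of `X(t) = sum_l A[[l]] X(t-l) + e(t)` with Gaussian
#' innovations, discarding a burn-in. Used as the ground-truth generator in
#' parameter-recovery and DTF oracle checks.
#'
#' @param A list of k x k coefficient matrices (lag 1..p).
#' @param n samples to return.
#' @param sd innovation standard deviation (scalar or length-k).
#' @param burn burn-in samples discarded.
#' @return k x n numeric matrix.
#' @export
simulateMVAR <- function(A, n, sd = 1, burn = 500L) {
  p <- length(A)
  k <- nrow(A[[1]])
  ntot <- n + burn
  x <- matrix(0, k, ntot)
  e <- matrix(rnorm(k * ntot, sd = sd), k, ntot)
  for (t in (p + 1):ntot) {
    acc <- e[, t]
    for (l in seq_len(p)) acc <- acc + A[[l]] %*% x[, t - l]
    x[, t] <- acc
  }
  x[, (burn + 1):ntot, drop = FALSE]
}
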