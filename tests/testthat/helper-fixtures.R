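# shared fixtures: everything is generated in code at test time

make_recording <- function(data, fs = 250, id = "S01", group = "NC",
                           moca = 26) {
  labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  new("EEGRecording", data = data, channelLabels = labels, sampleRate = fs,
      subjectId = id, group = group, moca = moca)
}

white_recording <- function(k = 4, seconds = 20, fs = 250, seed = 1, ...) {
  set.seed(seed)
  make_recording(matrix(rnorm(k * seconds * fs), k), fs = fs, ...)
}

# epochs straight from a matrix, skipping the filter chain
matrix_epochs <- function(x, fs = 250, epochLengthS = 5, ...) {
  epochRecording(make_recording(x, fs = fs, ...), epochLengthS)
}

# a small, quick two-cohort spec for pipeline-level tests
small_cohort_spec <- function(seed = 1, n = 4, seconds = 10, ...) {
  cohortSpec(nSubjectsPerGroup = n, durationS = seconds, seed = seed, ...)
}

delta_freqs <- seq(1, 3.5, 0.5)
all_band_freqs <- function(gridStep = 0.5)
  lapply(seq_len(3), function(b) {
    bands <- eegBands()
    g <- seq(1, 30, gridStep)
    g[g >= bands$lo[b] & g < bands$hi[b]]
  })

# random stable MVAR coefficient list (rescaled until stable)
random_stable_mvar <- function(k, p, scale = 0.4) {
  repeat {
    A <- lapply(seq_len(p), function(l) matrix(rnorm(k * k, sd = scale / l), k))
    if (eegdtf:::mvar_is_stable(A)) return(A)
    scale <- scale * 0.8
  }
}
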