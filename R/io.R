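#' Write a recording as a plain-text matrix with a JSON sidecar
#'
#' The data matrix goes to `<id>.tsv` (samples x channels, tab-separated,
#' with a header of channel labels); metadata (labels, sampling rate,
#' group, MoCA) to `<id>.json`.
#'
#' @param rec an [EEGRecording-class].
#' @param dir output directory.
#' @return the two file paths, invisibly.
#' @export
writeRecording <- function(rec, dir) {
  stopifnot(is(rec, "EEGRecording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(rec@subjectId, ".tsv"))
  js <- file.path(dir, paste0(rec@subjectId, ".json"))
  m <- t(rec@data)
  colnames(m) <- rec@channelLabels
  utils::write.table(m, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = rec@subjectId,
                            channel_labels = rec@channelLabels,
                            sample_rate_hz = rec@sampleRate,
                            group = rec@group, moca = rec@moca),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a recording written by [writeRecording()]
#'
#' @param path path to the `.tsv` matrix file (the `.json` sidecar is
#'   expected alongside it).
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path) {
  js <- sub("\\.tsv$", ".json", path)
  if (!file.exists(path) || !file.exists(js))
    stop("missing data or sidecar file for ", path)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (!identical(colnames(m), meta$channel_labels))
    stop("channel labels in sidecar do not match the matrix header")
  dat <- t(m)
  rownames(dat) <- meta$channel_labels
  new("EEGRecording", data = dat, channelLabels = meta$channel_labels,
      sampleRate = meta$sample_rate_hz, subjectId = meta$subject_id,
      group = meta$group,
      moca = if (is.null(meta$moca)) NA_real_ else meta$moca)
}

#' Read a directory of recordings via its manifest
#'
#' @param dir directory holding `manifest.csv` plus one `.tsv`/`.json` pair
#'   per subject.
#' @return list with `recordings` and `manifest`.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  recs <- lapply(manifest$subject_id, function(id)
    readRecording(file.path(dir, paste0(id, ".tsv"))))
  list(recordings = recs, manifest = manifest)
}
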