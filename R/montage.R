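#' Construct an electrode montage
#'
#' @param channelLabels ordered character vector of 32 ten-twenty electrode
#'   names.
#' @param regionOf named character vector mapping every label to one of
#'   `frontal`, `central`, `temporal`, `parietal`, `occipital`.
#' @return a [MontageSpec-class].
#' @examples
#' m <- defaultMontage()
#' mapRegion("Oz", m)
#' @export
montageSpec <- function(channelLabels, regionOf) {
  new("MontageSpec", channelLabels = channelLabels,
      regionOf = regionOf[channelLabels])
}

#' Default 32-electrode ten-twenty montage
#'
#' The standard 32-channel layout used throughout the package, with each
#' electrode assigned to one scalp region. Frontal covers the prefrontal and
#' frontal rows (FP/AF/F/FC); central the C row; temporal T7/T8; parietal
#' the CP/P rows; occipital the PO row and Oz. The assignment is
#' configurable via [montageSpec()].
#'
#' @return a [MontageSpec-class] with 32 electrodes.
#' @export
defaultMontage <- function() {
  labels <- c("FP1", "FP2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
              "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
              "PO7", "PO3", "PO4", "PO8", "Oz")
  region <- c(
    setNames(rep("frontal", 13), c("FP1", "FP2", "AF3", "AF4", "F7", "F3",
                                   "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6")),
    setNames(rep("central", 3), c("C3", "Cz", "C4")),
    setNames(rep("temporal", 2), c("T7", "T8")),
    setNames(rep("parietal", 9), c("CP5", "CP1", "CP2", "CP6", "P7", "P3",
                                   "Pz", "P4", "P8")),
    setNames(rep("occipital", 5), c("PO7", "PO3", "PO4", "PO8", "Oz")))
  montageSpec(labels, region)
}

#' Map an electrode to its scalp region
#'
#' @param electrode electrode label.
#' @param montage a [MontageSpec-class].
#' @return region name (`frontal`, `central`, `temporal`, `parietal` or
#'   `occipital`).
#' @export
mapRegion <- function(electrode, montage = defaultMontage()) {
  stopifnot(is(montage, "MontageSpec"))
  bad <- setdiff(electrode, montage@channelLabels)
  if (length(bad)) stop("unknown electrode(s): ", paste(bad, collapse = ", "))
  unname(montage@regionOf[electrode])
}
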