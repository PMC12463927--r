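# anterior-posterior rank used for edge orientation; temporal electrodes sit
# laterally, so edges touching them are additionally flagged "lateral"
REGION_RANK <- c(occipital = 1, parietal = 2, central = 3, temporal = 4,
                 frontal = 5)

#' Classify a directed edge as bottom-up, top-down or within-region
#'
#' Orientation follows the anterior-posterior ordering
#' occipital < parietal < central < temporal < frontal: an edge from a more
#' posterior to a more anterior region is bottom-up, the reverse top-down,
#' and equal regions within-region. Temporal electrodes lie lateral to this
#' axis; they are ranked between central and frontal, and edges involving
#' them carry a lateral flag in [summarizeFindings()].
#'
#' @param sourceRegion,targetRegion region names.
#' @return `"bottom-up"`, `"top-down"` or `"within-region"`.
#' @examples
#' classifyOrientation("occipital", "frontal")  # bottom-up
#' classifyOrientation("frontal", "parietal")   # top-down
#' @export
classifyOrientation <- function(sourceRegion, targetRegion) {
  if (!all(c(sourceRegion, targetRegion) %in% names(REGION_RANK)))
    stop("unknown region")
  s <- REGION_RANK[sourceRegion]; t <- REGION_RANK[targetRegion]
  unname(ifelse(s < t, "bottom-up", ifelse(s > t, "top-down", "within-region")))
}

#' Lobe-level summary of significant units
#'
#' Translates a comparison table into presentation units: for electrode
#' tables, per band and direction the count of significant electrodes in
#' each scalp region (with the electrode lists); for edge tables, the list
#' of significant directed edges labeled by region pair and
#' bottom-up/top-down orientation.
#'
#' @param comparisons a comparison table from [compareGroups()] (electrode
#'   or edge flavour).
#' @param montage a [MontageSpec-class].
#' @return for electrode tables, a data.frame with `band`, `direction`,
#'   `region`, `count`, `electrodes`; for edge tables, a data.frame with
#'   `band`, `source`, `target`, `source_region`, `target_region`,
#'   `orientation`, `lateral`, `direction`, `effect`, `q`. Zero significant
#'   units yield a zero-row frame.
#' @export
summarizeFindings <- function(comparisons, montage = defaultMontage()) {
  sig <- comparisons[isTRUE_vec(comparisons$significant), , drop = FALSE]
  if ("electrode" %in% names(comparisons)) {
    grid <- expand.grid(band = unique(comparisons$band),
                        direction = c("MCI>NC", "MCI<NC"),
                        region = EEG_REGIONS, stringsAsFactors = FALSE)
    grid$count <- 0L
    grid$electrodes <- ""
    for (i in seq_len(nrow(grid))) {
      e <- sig$electrode[sig$band == grid$band[i] &
                         sig$direction == grid$direction[i]]
      e <- e[mapRegion(e, montage) == grid$region[i]]
      grid$count[i] <- length(e)
      grid$electrodes[i] <- paste(e, collapse = ",")
    }
    grid[order(grid$band, grid$direction, grid$region), ]
  } else if (all(c("source", "target") %in% names(comparisons))) {
    if (!nrow(sig))
      return(data.frame(band = character(), source = character(),
                        target = character(), source_region = character(),
                        target_region = character(), orientation = character(),
                        lateral = logical(), direction = character(),
                        effect = numeric(), q = numeric(),
                        stringsAsFactors = FALSE))
    sr <- mapRegion(sig$source, montage)
    tr <- mapRegion(sig$target, montage)
    out <- data.frame(band = sig$band, source = sig$source,
                      target = sig$target, source_region = sr,
                      target_region = tr,
                      orientation = classifyOrientation(sr, tr),
                      lateral = sr == "temporal" | tr == "temporal",
                      direction = sig$direction, effect = sig$effect,
                      q = sig$q, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$band, out$source, out$target), ]
  } else stop("comparison table must carry 'electrode' or 'source'+'target'")
}

isTRUE_vec <- function(x) !is.na(x) & x
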