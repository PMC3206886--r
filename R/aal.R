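# The 45 AAL cortical/subcortical region abbreviations, expanded to 90
# labels by hemisphere.
.aalBase <- c(
  "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
  "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
  "ACG", "MCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING", "SOG",
  "MOG", "IOG", "FFG", "PoCG", "SPL", "IPL", "SMG", "ANG", "PCUN", "PCL",
  "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup", "MTG", "TPOmid",
  "ITG")

#' AAL region labels for the 90-node parcellation
#'
#' The 45 automated-anatomical-labeling (AAL) cortical and subcortical
#' region abbreviations, one label per hemisphere, giving the 90 network
#' nodes. By default labels are interleaved left/right
#' (\code{PreCG.L, PreCG.R, SFGdor.L, ...}); the ordering is configurable
#' because region-level analyses only require a consistent order.
#'
#' @param interleaved if \code{TRUE} (default) alternate .L/.R per region;
#'   otherwise all left labels then all right labels.
#' @return Character vector of 90 labels.
#' @examples
#' head(aalRegionLabels())
#' @export
aalRegionLabels <- function(interleaved = TRUE) {
  if (interleaved) {
    as.vector(rbind(paste0(.aalBase, ".L"), paste0(.aalBase, ".R")))
  } else {
    c(paste0(.aalBase, ".L"), paste0(.aalBase, ".R"))
  }
}
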