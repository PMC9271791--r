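#' Segment CSF spaces on non-contrast CT
#'
#' Classical intensity-based CSF segmentation: brain voxels inside the CSF
#' Hounsfield window (default \[-5, 15\] HU, bracketing water with a noise
#' margin while staying below infarcted tissue) are morphologically opened
#' with a 1-voxel-radius ball to remove noise speckle, and connected
#' components smaller than `min_component_ml` are discarded.
#'
#' This is the classical stand-in for a learned CSF segmenter. On real
#' follow-up CT, severely edematous infarct can overlap any fixed CSF
#' window; a learned model disambiguates by context. Any callable honouring
#' the same contract (volume + brain mask in, [VoxelMask-class] out) can be
#' plugged into the pipelines via their `csf_segmenter` config entry.
#'
#' @param volume A [CTVolume-class].
#' @param brainMask Nonempty [VoxelMask-class] restricting the search.
#' @param csf_hu CSF inclusion window in HU (low, high). Widening the window
#'   never shrinks the output.
#' @param min_component_ml Minimum surviving component volume (ml).
#' @return A [VoxelMask-class], a subset of `brainMask` (possibly empty).
#' @export
segmentCSF <- function(volume, brainMask, csf_hu = c(-5, 15),
                       min_component_ml = 0.3) {
  stopifnot(is(volume, "CTVolume"), is(brainMask, "VoxelMask"))
  if (!sameGrid(brainMask, volume)) stop("brainMask is not on the volume grid")
  if (voxelCount(brainMask) == 0L) stop("brainMask is empty")
  m <- brainMask@voxels & volume@voxels >= csf_hu[1L] &
    volume@voxels <= csf_hu[2L]
  m <- .opening(m, 1L) & brainMask@voxels
  lab <- .labelComponents(m, 26L)
  minVox <- min_component_ml * 1000 / prod(volume@spacing)
  out <- array(FALSE, dim(m))
  for (i in seq_along(lab$sizes)) {
    if (lab$sizes[i] >= minVox) out[lab$indices[[i]]] <- TRUE
  }
  .maskLike(out, volume)
}
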