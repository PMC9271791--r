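#' Segment the visible infarct hypodensity on follow-up NCCT
#'
#' Classical stand-in for a learned infarct segmenter, honouring the same
#' contract. Candidate voxels are brain, non-CSF, within the 0-40 HU
#' infarct window, and darker than the smoothed contralateral intensity at
#' the mirrored location by at least an adaptive margin. Both the image and
#' its reflection are smoothed with a `smoothing_mm` Gaussian before the
#' contralateral difference is taken, which suppresses voxel noise; the
#' inclusion margin is the larger of `delta_hu` and `plateau_fraction`
#' times the estimated plateau of the hypodensity (the median smoothed
#' difference over voxels above half its robust maximum). Thresholding at a
#' fixed fraction of the plateau rather than at a fixed HU margin keeps the
#' segmentation centred on the demarcated lesion across the whole range of
#' water-uptake severities, and slightly erodes the partial-volume
#' transition shell, which keeps the region's mean density representative
#' of the demarcated infarct. Candidates are closed with a 1-voxel ball,
#' re-restricted to the brain/non-CSF/HU-window contract, components below
#' `min_component_ml` are dropped, and the largest 3D connected component
#' is kept ([refineLargestComponent()]).
#'
#' @param volume A [CTVolume-class] (follow-up NCCT).
#' @param brainMask,csfMask [VoxelMask-class] objects on the same grid.
#' @param plane The [MidlinePlane-class] used for contralateral comparison.
#' @param infarct_hu Infarct HU window (default 0-40).
#' @param delta_hu Minimum contralateral difference (HU floor of the
#'   adaptive margin).
#' @param plateau_fraction Fraction of the estimated hypodensity plateau
#'   used as the adaptive margin.
#' @param smoothing_mm Gaussian smoothing applied before the contralateral
#'   difference (mm).
#' @param min_component_ml Minimum component volume before refinement (ml).
#' @param connectivity 3D connectivity rule (6, 18 or 26).
#' @param exclusion_margin_mm Margin around CSF and the brain-mask boundary
#'   excluded from the contralateral-difference map: partial-volume
#'   gradients at tissue/CSF and tissue/skull interfaces produce spurious
#'   mirrored differences that would otherwise dominate the plateau
#'   estimate when the true hypodensity is subtle.
#' @param reference_hu Tissue-plausibility band (HU) for the smoothed
#'   densities entering the contralateral comparison: the mirrored
#'   reference must look like normal tissue and the voxel's own smoothed
#'   neighbourhood must not be skull-contaminated, otherwise steep
#'   partial-volume gradients turn sub-voxel midline error into spurious
#'   "hypodensity".
#' @return A [VoxelMask-class]; empty when no hypodensity is found
#'   ("no visible infarct").
#' @export
segmentInfarct <- function(volume, brainMask, csfMask, plane,
                           infarct_hu = c(0, 40), delta_hu = 1,
                           plateau_fraction = 0.8, smoothing_mm = 2,
                           min_component_ml = 1, connectivity = 26L,
                           exclusion_margin_mm = 3.5,
                           reference_hu = c(20, 45)) {
  stopifnot(is(volume, "CTVolume"), is(brainMask, "VoxelMask"),
            is(csfMask, "VoxelMask"), is(plane, "MidlinePlane"))
  validObject(plane)
  if (!sameGrid(brainMask, volume) || !sameGrid(csfMask, volume)) {
    stop("masks are not on the volume grid")
  }
  dm <- dim(volume@voxels)
  sigma <- smoothing_mm / volume@spacing
  sm <- .gaussSmooth(volume@voxels, sigma)

  parench <- brainMask@voxels & !csfMask@voxels
  rEx <- ceiling(exclusion_margin_mm / min(volume@spacing))
  parench <- .erodeBall(parench, rEx)
  idx <- which(parench)
  W <- .linearToWorld(idx, dm, volume@spacing, volume@origin)
  Wr <- .reflectPoints(W, plane@point, plane@normal)
  contra <- .trilinear(sm, .worldToVoxel(Wr, volume@spacing, volume@origin))
  diffv <- contra - sm[idx]        # positive where this side is darker
  diffv[is.na(diffv)] <- 0

  # a voxel only counts as hypodense relative to a plausible normal-tissue
  # reference, and only when its own smoothed neighbourhood is not
  # skull-contaminated
  refOK <- !is.na(contra) & contra >= reference_hu[1L] &
    contra <= reference_hu[2L] & sm[idx] <= reference_hu[2L]

  pos <- diffv[diffv > 0 & refOK]
  empty <- .maskLike(array(FALSE, dm), volume)
  if (length(pos) < 10L) return(empty)
  m99 <- stats::quantile(pos, 0.999, names = FALSE)
  plateau <- stats::median(pos[pos >= 0.5 * m99])
  # the margin must clear both the configured HU floor and the noise floor
  # of the smoothed difference map (3.5 robust SDs leaves only scattered
  # sub-component false voxels over a whole brain), and tracks the
  # hypodensity plateau for demarcated lesions
  noiseFloor <- 3.5 * stats::mad(diffv, center = 0)
  thr <- max(delta_hu, noiseFloor, plateau_fraction * plateau)

  cand <- array(FALSE, dm)
  cand[idx[diffv >= thr & refOK]] <- TRUE
  cand <- cand & volume@voxels >= infarct_hu[1L] &
    volume@voxels <= infarct_hu[2L]
  cand <- .closing(cand, 1L)
  cand <- cand & parench & volume@voxels >= infarct_hu[1L] &
    volume@voxels <= infarct_hu[2L]

  lab <- .labelComponents(cand, connectivity)
  minVox <- min_component_ml * 1000 / prod(volume@spacing)
  keep <- which(lab$sizes >= minVox)
  if (length(keep) == 0L) return(empty)
  filtered <- array(FALSE, dm)
  for (i in keep) filtered[lab$indices[[i]]] <- TRUE
  refineLargestComponent(.maskLike(filtered, volume),
    volume = volume, connectivity = connectivity
  )
}

#' Keep only the largest 3D connected component of a mask
#'
#' Refinement step identifying the largest connected region in three
#' dimensions as the likely primary infarct territory and discarding
#' smaller disconnected voxels. Size ties are broken deterministically: by
#' lower mean HU when a volume is supplied, then by lowest linear voxel
#' index.
#'
#' @param mask A [VoxelMask-class].
#' @param volume Optional [CTVolume-class] for the mean-HU tie-break.
#' @param connectivity 3D connectivity rule (default 26).
#' @return A [VoxelMask-class] with a single component (or empty input
#'   returned unchanged).
#' @export
refineLargestComponent <- function(mask, volume = NULL, connectivity = 26L) {
  stopifnot(is(mask, "VoxelMask"))
  lab <- .labelComponents(mask@voxels, connectivity)
  if (length(lab$sizes) == 0L) return(mask)
  big <- which(lab$sizes == max(lab$sizes))
  if (length(big) > 1L && !is.null(volume)) {
    meanHU <- vapply(big, function(i) {
      mean(volume@voxels[lab$indices[[i]]])
    }, numeric(1))
    big <- big[meanHU == min(meanHU)]
  }
  if (length(big) > 1L) {
    firstIdx <- vapply(big, function(i) lab$indices[[i]][1L], numeric(1))
    big <- big[which.min(firstIdx)]
  }
  out <- array(FALSE, dim(mask@voxels))
  out[lab$indices[[big[1L]]]] <- TRUE
  .maskLike(out, mask)
}

#' Volume of a mask in ml
#'
#' @param mask A [VoxelMask-class] with known spacing.
#' @return Voxel count times voxel volume, in ml.
#' @export
infarctVolumeMl <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  voxelCount(mask) * prod(mask@spacing) / 1000
}
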