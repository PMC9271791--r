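#' Construct an HU threshold configuration
#'
#' @param infarct_hu Window for visible infarct in follow-up mode
#'   (default 0-40 HU).
#' @param baseline_core_hu Window for the CTP core region at baseline
#'   (default 20-80 HU).
#' @param normal_hu Window for the mirrored normal region (default
#'   20-80 HU).
#' @return A [ThresholdConfig-class].
#' @export
thresholdConfig <- function(infarct_hu = c(0, 40),
                            baseline_core_hu = c(20, 80),
                            normal_hu = c(20, 80)) {
  new("ThresholdConfig",
    infarct_hu = as.numeric(infarct_hu),
    baseline_core_hu = as.numeric(baseline_core_hu),
    normal_hu = as.numeric(normal_hu)
  )
}

# shared densitometry core: two regions, CSF removal first, then closed HU
# windows, exclusion accounting, minimum surviving-voxel floor
.nwuFromRegions <- function(volume, ischemic, normal, csf, winI, winN,
                            thresholds, mode, min_voxels, warnings,
                            apply_csf = TRUE, apply_windows = TRUE) {
  vox <- volume@voxels
  iIdx <- which(ischemic)
  nIdx <- which(normal)
  nCsf <- c(0, 0)
  if (apply_csf && !is.null(csf)) {
    cs <- csf@voxels
    keepI <- !cs[iIdx]; keepN <- !cs[nIdx]
    nCsf <- c(sum(!keepI), sum(!keepN))
    iIdx <- iIdx[keepI]; nIdx <- nIdx[keepN]
  }
  nThr <- c(0, 0)
  if (apply_windows) {
    vi <- vox[iIdx]
    keepI <- vi >= winI[1L] & vi <= winI[2L]
    vn <- vox[nIdx]
    keepN <- vn >= winN[1L] & vn <= winN[2L]
    nThr <- c(sum(!keepI), sum(!keepN))
    iIdx <- iIdx[keepI]; nIdx <- nIdx[keepN]
  }
  if (length(iIdx) < min_voxels || length(nIdx) < min_voxels) {
    stop(sprintf(
      "region vanished after exclusions (%d ischemic / %d normal voxels survive, floor %d)",
      length(iIdx), length(nIdx), min_voxels
    ))
  }
  dI <- mean(vox[iIdx])
  dN <- mean(vox[nIdx])
  volMl <- sum(ischemic) * prod(volume@spacing) / 1000
  nwu <- 100 * (1 - dI / dN)
  new("NWUResult",
    nwu_percent = nwu, d_ischemic = dI, d_normal = dN,
    n_ischemic_used = length(iIdx), n_normal_used = length(nIdx),
    n_removed_csf = stats::setNames(nCsf, c("ischemic", "normal")),
    n_removed_threshold = stats::setNames(nThr, c("ischemic", "normal")),
    thresholds = thresholds, mode = mode,
    infarct_volume_ml = volMl,
    edema_volume_ml = nwu / 100 * volMl,
    warnings = warnings
  )
}

#' Compute net water uptake from an infarct mask
#'
#' The infarct region is mirrored across the midline plane to define the
#' homologous contralateral (normal) region; mirrored voxels that land back
#' inside the infarct (midline-crossing lesions) are excluded from the
#' normal region with a warning. CSF voxels are removed from both regions
#' first, then each region is restricted to its closed HU window: the
#' ischemic side uses `infarct_hu` (0-40) in `"followup-infarct"` mode or
#' `baseline_core_hu` (20-80) in `"baseline-core"` mode, the normal side
#' always uses `normal_hu` (20-80). NWU is
#' `100 * (1 - mean(ischemic HU) / mean(normal HU))` over the surviving
#' voxels.
#'
#' @param volume The NCCT [CTVolume-class].
#' @param infarct Nonempty infarct/core [VoxelMask-class].
#' @param csf CSF [VoxelMask-class] (may be empty).
#' @param plane The [MidlinePlane-class].
#' @param thresholds A [ThresholdConfig-class].
#' @param mode `"followup-infarct"` or `"baseline-core"`.
#' @param brainMask Optional [VoxelMask-class]; when supplied, mirrored
#'   voxels outside it are dropped, with a warning recorded in the result
#'   when more than 20% of the mirror region falls outside.
#' @param min_voxels Minimum surviving voxels per region (default 50);
#'   fewer is an error, since a mean over fewer voxels is noise-dominated.
#' @return An [NWUResult-class].
#' @examples
#' ph <- makePhantom(phantomSpec(
#'   shape = c(64L, 76L, 54L),
#'   spacing = c(2.2, 2.2, 2.2), infarct_volume_ml = 60
#' ))
#' computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth)
#' @export
computeNWU <- function(volume, infarct, csf, plane,
                       thresholds = thresholdConfig(),
                       mode = c("followup-infarct", "baseline-core"),
                       brainMask = NULL, min_voxels = 50L) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "CTVolume"), is(infarct, "VoxelMask"),
            is(csf, "VoxelMask"), is(plane, "MidlinePlane"))
  validObject(thresholds)
  if (!sameGrid(infarct, volume) || !sameGrid(csf, volume)) {
    stop("masks are not on the volume grid")
  }
  if (voxelCount(infarct) == 0L) stop("infarct mask is empty")
  warnings <- character(0)

  mirror <- mirrorMask(infarct, plane)@voxels
  overlap <- mirror & infarct@voxels
  if (any(overlap)) {
    warnings <- c(warnings, sprintf(
      "%d mirrored voxels land inside the infarct mask and were excluded from the normal region",
      sum(overlap)
    ))
    mirror <- mirror & !infarct@voxels
  }
  if (!is.null(brainMask)) {
    outside <- mirror & !brainMask@voxels
    fracOut <- sum(outside) / max(1L, sum(mirror))
    if (fracOut > 0.2) {
      warnings <- c(warnings, sprintf(
        "mirror region falls %.0f%% outside the brain mask", 100 * fracOut
      ))
    }
    mirror <- mirror & brainMask@voxels
  }
  winI <- if (mode == "followup-infarct") thresholds@infarct_hu
  else thresholds@baseline_core_hu
  .nwuFromRegions(volume, infarct@voxels, mirror, csf,
    winI, thresholds@normal_hu, thresholds, mode,
    min_voxels, warnings
  )
}

#' Construct a patch sampling specification
#'
#' @param slice_z_mm Four axial slice positions (world z, mm).
#' @param center_lr_mm Unsigned lateral offset of patch centers from the
#'   midline (mm).
#' @param center_ap_mm Anterior-posterior patch center coordinate (mm).
#' @param patch_edge_mm Square patch edge (mm), default 20.
#' @param side Affected hemisphere.
#' @return A [PatchSpec-class].
#' @export
patchSpec <- function(slice_z_mm, center_lr_mm, center_ap_mm,
                      patch_edge_mm = 20, side = "left") {
  new("PatchSpec",
    patch_edge_mm = patch_edge_mm, slice_z_mm = as.numeric(slice_z_mm),
    center_lr_mm = center_lr_mm, center_ap_mm = center_ap_mm, side = side
  )
}

#' Patch-based NWU estimation
#'
#' Places square standard patches on four axial slices within the
#' middle-cerebral-artery territory of the affected hemisphere; the normal
#' region is their mirror across the midline plane. CSF is removed from
#' both regions and both are restricted to the `normal_hu` (20-80) window
#' before the density ratio is taken. A sampling method: it does not
#' require a core or infarct mask, but dilutes NWU wherever the patches
#' include non-ischemic tissue.
#'
#' @param volume The NCCT [CTVolume-class].
#' @param spec A [PatchSpec-class].
#' @param plane The [MidlinePlane-class].
#' @param csf CSF [VoxelMask-class].
#' @param thresholds A [ThresholdConfig-class].
#' @param brainMask Optional brain [VoxelMask-class] to clip both regions.
#' @param min_voxels Minimum surviving voxels per region.
#' @return An [NWUResult-class] with mode `"patch"`.
#' @export
patchNWU <- function(volume, spec, plane, csf,
                     thresholds = thresholdConfig(), brainMask = NULL,
                     min_voxels = 50L) {
  stopifnot(is(volume, "CTVolume"), is(spec, "PatchSpec"),
            is(plane, "MidlinePlane"), is(csf, "VoxelMask"))
  validObject(spec)
  dm <- dim(volume@voxels)
  sp <- volume@spacing
  org <- volume@origin
  zIdx <- round((spec@slice_z_mm - org[3L]) / sp[3L]) + 1
  if (any(zIdx < 1L | zIdx > dm[3L])) {
    stop("patch slice positions lie outside the volume")
  }
  s <- if (spec@side == "left") -1 else 1
  cx <- plane@point[1L] + s * spec@center_lr_mm
  half <- spec@patch_edge_mm / 2
  xs <- org[1L] + (seq_len(dm[1L]) - 1) * sp[1L]
  ys <- org[2L] + (seq_len(dm[2L]) - 1) * sp[2L]
  inX <- abs(xs - cx) <= half
  inY <- abs(ys - spec@center_ap_mm) <= half
  isch <- array(FALSE, dm)
  isch[inX, inY, unique(zIdx)] <- TRUE
  if (!any(isch)) stop("patches cover no voxels")
  ischMask <- .maskLike(isch, volume)
  normal <- mirrorMask(ischMask, plane)@voxels & !isch
  warnings <- character(0)
  if (!is.null(brainMask)) {
    isch <- isch & brainMask@voxels
    normal <- normal & brainMask@voxels
  }
  .nwuFromRegions(volume, isch, normal, csf,
    thresholds@normal_hu, thresholds@normal_hu, thresholds, "patch",
    min_voxels, warnings
  )
}

#' Construct a circular-ROI sampling specification
#'
#' @param centers n x 3 matrix of world coordinates (mm), 1 <= n <= 13, all
#'   in the affected hemisphere.
#' @param diameter_mm ROI diameter (mm), default 10.
#' @param side Affected hemisphere.
#' @return An [ROISpec-class].
#' @export
roiSpec <- function(centers, diameter_mm = 10, side = "left") {
  new("ROISpec",
    centers = rbind(centers), diameter_mm = diameter_mm, side = side
  )
}

#' ROI-sampling NWU estimation (manual-protocol analogue)
#'
#' Places circular 2D regions (discs confined to each center's axial slice)
#' of ~10 mm diameter at up to 13 sites within the infarct, mirrors the set
#' across the midline, and computes NWU from the two mean densities. No CSF
#' removal and no HU thresholding is applied: the manual protocol this
#' emulates avoids hemorrhage and CSF by placement.
#'
#' @param volume The NCCT [CTVolume-class].
#' @param spec An [ROISpec-class]; every center must lie on the affected
#'   side of the plane.
#' @param plane The [MidlinePlane-class].
#' @param min_voxels Minimum voxels per region.
#' @return An [NWUResult-class] with mode `"roi"`.
#' @export
roiNWU <- function(volume, spec, plane, min_voxels = 50L) {
  stopifnot(is(volume, "CTVolume"), is(spec, "ROISpec"),
            is(plane, "MidlinePlane"))
  validObject(spec)
  d <- .planeDistance(spec@centers, plane@point, plane@normal)
  s <- if (spec@side == "left") -1 else 1
  if (any(s * d <= 0)) {
    stop("ROI center on the wrong side of the midline plane")
  }
  dm <- dim(volume@voxels)
  sp <- volume@spacing
  org <- volume@origin
  xs <- org[1L] + (seq_len(dm[1L]) - 1) * sp[1L]
  ys <- org[2L] + (seq_len(dm[2L]) - 1) * sp[2L]
  r2 <- (spec@diameter_mm / 2)^2
  isch <- array(FALSE, dm)
  for (i in seq_len(nrow(spec@centers))) {
    cc <- spec@centers[i, ]
    k <- round((cc[3L] - org[3L]) / sp[3L]) + 1
    if (k < 1L || k > dm[3L]) stop("ROI center outside the volume")
    disc <- outer((xs - cc[1L])^2, (ys - cc[2L])^2, "+") <= r2
    isch[, , k] <- isch[, , k] | disc
  }
  ischMask <- .maskLike(isch, volume)
  normal <- mirrorMask(ischMask, plane)@voxels & !isch
  .nwuFromRegions(volume, isch, normal, NULL,
    c(-Inf, Inf), c(-Inf, Inf), thresholdConfig(), "roi",
    min_voxels, character(0),
    apply_csf = FALSE, apply_windows = FALSE
  )
}
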