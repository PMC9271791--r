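setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "CTVolume %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm (%s)\n",
    d[1L], d[2L], d[3L], object@spacing[1L], object@spacing[2L],
    object@spacing[3L], object@orientation
  ))
  cat(sprintf(
    "  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
    min(object@voxels), max(object@voxels),
    object@origin[1L], object@origin[2L], object@origin[3L]
  ))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  n <- sum(object@voxels)
  cat(sprintf(
    "VoxelMask %d x %d x %d, %d voxels inside (%.1f ml)\n",
    d[1L], d[2L], d[3L], n, n * prod(object@spacing) / 1000
  ))
})

setMethod("show", "MidlinePlane", function(object) {
  cat(sprintf(
    "MidlinePlane through (%.1f, %.1f, %.1f) mm, normal (%.3f, %.3f, %.3f)%s\n",
    object@point[1L], object@point[2L], object@point[3L],
    object@normal[1L], object@normal[2L], object@normal[3L],
    if (object@converged) "" else " [optimiser did not improve: initial plane]"
  ))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) *
    180 / pi
  cat(sprintf(
    "RigidTransform rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm%s\n",
    ang, object@translation[1L], object@translation[2L],
    object@translation[3L],
    if (object@converged) "" else " [optimiser did not improve: identity]"
  ))
})

setMethod("show", "CTPSeries", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "CTPSeries %d x %d x %d voxels, %d frames over %.1f s\n",
    d[1L], d[2L], d[3L], d[4L], max(object@times) - min(object@times)
  ))
})

setMethod("show", "PerfusionMaps", function(object) {
  bm <- object@brainMask@voxels
  cat(sprintf(
    "PerfusionMaps: CBF median %.2f (a.u.), Tmax median %.1f s over %d brain voxels\n",
    stats::median(object@cbf[bm]), stats::median(object@tmax[bm]), sum(bm)
  ))
})

setMethod("show", "NWUResult", function(object) {
  cat(sprintf(
    "NWUResult [%s]: NWU = %.2f%%\n", object@mode, object@nwu_percent
  ))
  cat(sprintf(
    "  D_ischemic = %.2f HU (n = %d), D_normal = %.2f HU (n = %d)\n",
    object@d_ischemic, object@n_ischemic_used,
    object@d_normal, object@n_normal_used
  ))
  cat(sprintf(
    "  removed: CSF %d/%d, threshold %d/%d (ischemic/normal)\n",
    object@n_removed_csf[1L], object@n_removed_csf[2L],
    object@n_removed_threshold[1L], object@n_removed_threshold[2L]
  ))
  if (length(object@warnings)) {
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  }
})

setMethod("show", "AgreementStats", function(object) {
  if (!is.na(object@icc)) {
    cat(sprintf(
      "AgreementStats: ICC(2,1) = %.3f (95%% CI %.3f-%.3f), n = %d\n",
      object@icc, object@icc_ci[1L], object@icc_ci[2L], object@n
    ))
  }
  if (!is.na(object@bias)) {
    cat(sprintf(
      "  Bland-Altman bias = %.3f, LoA [%.3f, %.3f], n = %d\n",
      object@bias, object@loa_low, object@loa_high, object@n
    ))
  }
})

setMethod("show", "PhantomBundle", function(object) {
  cat(sprintf(
    "PhantomBundle: true NWU %.1f%%, infarct %.1f ml, tilt %.1f deg, seed %d\n",
    object@trueNWUPercent,
    voxelCount(object@infarctMask) * prod(object@infarctMask@spacing) / 1000,
    object@spec@tilt_deg, object@spec@seed
  ))
})
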