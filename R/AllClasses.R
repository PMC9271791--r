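#' @import methods
NULL

HU_FLOOR <- -1024
HU_CEILING <- 3071

#' CTVolume: a 3D CT volume in Hounsfield units
#'
#' The carrier of all densitometry in the package: a 3D scalar grid of CT
#' numbers (HU) with physical voxel spacing in mm. Volumes are held in the
#' canonical RAS orientation (axis 1 left->right, axis 2 posterior->anterior,
#' axis 3 inferior->superior) so that "left hemisphere" always means low
#' first-axis world coordinate. Values are clamped to \[-1024, 3071\] HU on
#' construction, which removes scanner padding values that would otherwise
#' corrupt region density means.
#'
#' @slot voxels 3D numeric array of HU.
#' @slot spacing Per-axis voxel size in mm (length 3, all > 0).
#' @slot origin Physical position (mm) of the first voxel center.
#' @slot orientation Three-letter anatomical axis code, always "RAS"
#'   internally.
#' @slot nativeOrientation Orientation of the source file, restored on write.
#'
#' @seealso [readCTVolume()], [writeVolume()], [makePhantom()]
#' @export
setClass("CTVolume", representation(
  voxels = "array",
  spacing = "numeric",
  origin = "numeric",
  orientation = "character",
  nativeOrientation = "character"
), prototype(
  orientation = "RAS",
  nativeOrientation = "RAS"
))

setValidity("CTVolume", function(object) {
  msg <- character(0)
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L)) {
    msg <- c(msg, "voxels must be a 3D array with every extent >= 1")
  }
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
    any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three finite positive values (mm)")
  }
  if (length(object@origin) != 3L || !all(is.finite(object@origin))) {
    msg <- c(msg, "origin must be three finite values (mm)")
  }
  rng <- suppressWarnings(range(object@voxels))
  if (is.finite(rng[1L]) && (rng[1L] < HU_FLOOR || rng[2L] > HU_CEILING)) {
    msg <- c(msg, sprintf(
      "HU values must lie within [%d, %d] after loading", HU_FLOOR, HU_CEILING
    ))
  }
  if (length(msg)) msg else TRUE
})

#' VoxelMask: a binary region on a CT grid
#'
#' A strictly binary 3D region (infarct, mirror, CSF, core, brain, ...)
#' sharing the geometry of the [CTVolume-class] it indexes. Stored as a
#' logical array together with its own spacing/origin so masks can be
#' validated against a reference grid.
#'
#' @slot voxels Logical 3D array.
#' @slot spacing,origin Grid geometry, identical to the reference volume.
#'
#' @seealso [readMask()], [sameGrid()]
#' @export
setClass("VoxelMask", representation(
  voxels = "array",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("VoxelMask", function(object) {
  msg <- character(0)
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L)) {
    msg <- c(msg, "voxels must be a 3D array with every extent >= 1")
  }
  if (!is.logical(object@voxels)) {
    msg <- c(msg, "mask values must be strictly binary (logical)")
  }
  if (anyNA(object@voxels)) msg <- c(msg, "mask values must not be NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
    any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three finite positive values (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' MidlinePlane: the mid-sagittal symmetry plane
#'
#' A plane in physical (mm) coordinates, parameterised by a point on the
#' plane and a unit normal. The normal points towards the patient's right
#' (+x in canonical RAS), so the signed distance of a voxel center to the
#' plane is negative in the left hemisphere.
#'
#' @slot point Numeric length-3, a point on the plane (mm).
#' @slot normal Unit normal (|n| = 1 within 1e-6).
#' @slot converged FALSE when the symmetry optimiser failed to improve on its
#'   initialisation and the initial plane was returned.
#'
#' @seealso [estimateMidline()], [mirrorMask()], [splitHemispheres()]
#' @export
setClass("MidlinePlane", representation(
  point = "numeric",
  normal = "numeric",
  converged = "logical"
), prototype(converged = TRUE))

setValidity("MidlinePlane", function(object) {
  msg <- character(0)
  if (length(object@point) != 3L || any(!is.finite(object@point))) {
    msg <- c(msg, "point must be three finite mm coordinates")
  }
  if (length(object@normal) != 3L ||
    abs(sqrt(sum(object@normal^2)) - 1) > 1e-6) {
    msg <- c(msg, "normal must be a unit vector (|n| = 1 within 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: a 6-dof rigid-body transform
#'
#' Maps physical points of the fixed image into the moving image's physical
#' space: p_moving = rotation %*% (p_fixed - center) + center + translation.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1 (within 1e-6).
#' @slot translation Length-3 mm vector.
#' @slot center Rotation center in mm (fixed-image frame).
#' @slot converged FALSE when the optimiser could not improve on identity.
#'
#' @seealso [registerRigid()], [applyTransformToMask()]
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric",
  center = "numeric",
  converged = "logical"
), prototype(converged = TRUE))

setValidity("RigidTransform", function(object) {
  msg <- character(0)
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) ||
    max(abs(crossprod(R) - diag(3))) > 1e-6 ||
    abs(det(R) - 1) > 1e-6) {
    msg <- c(msg, "rotation must be orthonormal with determinant +1")
  }
  if (length(object@translation) != 3L) {
    msg <- c(msg, "translation must have length 3")
  }
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (length(msg)) msg else TRUE
})

#' CTPSeries: a dynamic (4D) CT-perfusion acquisition
#'
#' @slot voxels 4D array (3 spatial dimensions + time) of HU.
#' @slot times Acquisition time points in seconds, strictly increasing, at
#'   least 10 frames.
#' @slot spacing,origin Spatial grid geometry (mm).
#'
#' @seealso [makeCTPSeries()], [selectAIF()], [deconvolveCTP()]
#' @export
setClass("CTPSeries", representation(
  voxels = "array",
  times = "numeric",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("CTPSeries", function(object) {
  msg <- character(0)
  d <- dim(object@voxels)
  if (length(d) != 4L) msg <- c(msg, "voxels must be a 4D array")
  if (length(object@times) < 10L || any(diff(object@times) <= 0)) {
    msg <- c(msg, "times must be strictly increasing with >= 10 points")
  }
  if (length(d) == 4L && d[4L] != length(object@times)) {
    msg <- c(msg, "fourth dimension must match length(times)")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three positive values (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' PerfusionMaps: voxelwise CBF and Tmax from deconvolution
#'
#' CBF is in arbitrary units proportional to ml/100g/min (only ratios enter
#' the core rule); Tmax is in seconds within \[0, duration\].
#'
#' @slot cbf,tmax 3D numeric arrays on the CTP spatial grid.
#' @slot brainMask [VoxelMask-class] of voxels the maps are valid on.
#' @slot spacing,origin Grid geometry (mm).
#'
#' @seealso [deconvolveCTP()], [coreMask()]
#' @export
setClass("PerfusionMaps", representation(
  cbf = "array",
  tmax = "array",
  brainMask = "VoxelMask",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("PerfusionMaps", function(object) {
  msg <- character(0)
  if (!identical(dim(object@cbf), dim(object@tmax))) {
    msg <- c(msg, "cbf and tmax must share dimensions")
  }
  bm <- object@brainMask@voxels
  if (!identical(dim(bm), dim(object@cbf))) {
    msg <- c(msg, "brainMask must share the map grid")
  } else {
    if (any(object@cbf[bm] < 0)) msg <- c(msg, "cbf must be >= 0 in brainMask")
    if (any(object@tmax[bm] < 0)) msg <- c(msg, "tmax must be >= 0 in brainMask")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdConfig: HU windows for NWU densitometry
#'
#' The asymmetric thresholding scheme: visible infarct on follow-up CT is
#' windowed to 0-40 HU (the lower bound widened from the classical 20 HU so
#' severely edematous voxels are kept; the upper bound tightened from 80 HU
#' so hemorrhagic transformation and contrast staining are excluded), while
#' the normal mirrored region and the baseline CTP core keep the classical
#' 20-80 HU window. All intervals are closed (inclusive at both ends).
#'
#' @slot infarct_hu Window for visible infarct in follow-up mode.
#' @slot baseline_core_hu Window for the ischemic region in baseline-core
#'   mode.
#' @slot normal_hu Window for the mirrored normal region (all modes).
#'
#' @seealso [thresholdConfig()], [computeNWU()]
#' @export
setClass("ThresholdConfig", representation(
  infarct_hu = "numeric",
  baseline_core_hu = "numeric",
  normal_hu = "numeric"
), prototype(
  infarct_hu = c(0, 40),
  baseline_core_hu = c(20, 80),
  normal_hu = c(20, 80)
))

setValidity("ThresholdConfig", function(object) {
  bad <- function(x) length(x) != 2L || !all(is.finite(x)) || x[1L] >= x[2L]
  msg <- character(0)
  if (bad(object@infarct_hu)) msg <- c(msg, "infarct_hu must be low < high")
  if (bad(object@baseline_core_hu)) {
    msg <- c(msg, "baseline_core_hu must be low < high")
  }
  if (bad(object@normal_hu)) msg <- c(msg, "normal_hu must be low < high")
  if (length(msg)) msg else TRUE
})

#' CoreMaskConfig: the CBF-ratio rule for baseline core
#'
#' Core infarct is tissue with CBF strictly below `cbf_core_fraction` (default
#' 0.30) of the normal reference, where normal tissue is defined by
#' Tmax < `tmax_normal_s` (default 4 s).
#'
#' @slot cbf_core_fraction Fraction of normal CBF below which tissue is core.
#' @slot tmax_normal_s Tmax cutoff (s) defining the normal reference tissue.
#'
#' @seealso [coreMask()]
#' @export
setClass("CoreMaskConfig", representation(
  cbf_core_fraction = "numeric",
  tmax_normal_s = "numeric"
), prototype(cbf_core_fraction = 0.30, tmax_normal_s = 4.0))

setValidity("CoreMaskConfig", function(object) {
  msg <- character(0)
  f <- object@cbf_core_fraction
  if (length(f) != 1L || !is.finite(f) || f <= 0 || f >= 1) {
    msg <- c(msg, "cbf_core_fraction must lie in (0, 1)")
  }
  t <- object@tmax_normal_s
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    msg <- c(msg, "tmax_normal_s must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' NWUResult: a net water uptake measurement
#'
#' Net water uptake is the percent density deficit of ischemic tissue
#' relative to its mirrored contralateral region,
#' `nwu_percent = 100 * (1 - d_ischemic / d_normal)`, computed over voxels
#' surviving CSF removal and HU windowing. Exclusion accounting is kept per
#' region so every removed voxel is attributable.
#'
#' @slot nwu_percent NWU in percent.
#' @slot d_ischemic,d_normal Mean HU of the surviving ischemic / normal
#'   voxels.
#' @slot n_ischemic_used,n_normal_used Surviving voxel counts.
#' @slot n_removed_csf,n_removed_threshold Named length-2 counts
#'   (ischemic, normal) of voxels removed by CSF masking and HU windowing.
#' @slot thresholds The [ThresholdConfig-class] used.
#' @slot mode One of "baseline-core", "followup-infarct", "patch", "roi".
#' @slot infarct_volume_ml Volume of the ischemic region (ml) before
#'   exclusions.
#' @slot edema_volume_ml Derived total edema volume,
#'   `nwu_percent/100 * infarct_volume_ml` (exposed, not validated).
#' @slot warnings Character vector of QC warnings recorded during the
#'   measurement (e.g. mirror region leaving the brain mask).
#'
#' @seealso [computeNWU()], [patchNWU()], [roiNWU()]
#' @export
setClass("NWUResult", representation(
  nwu_percent = "numeric",
  d_ischemic = "numeric",
  d_normal = "numeric",
  n_ischemic_used = "integer",
  n_normal_used = "integer",
  n_removed_csf = "numeric",
  n_removed_threshold = "numeric",
  thresholds = "ThresholdConfig",
  mode = "character",
  infarct_volume_ml = "numeric",
  edema_volume_ml = "numeric",
  warnings = "character"
), prototype(warnings = character(0)))

setValidity("NWUResult", function(object) {
  msg <- character(0)
  expected <- 100 * (1 - object@d_ischemic / object@d_normal)
  if (abs(object@nwu_percent - expected) > 1e-9) {
    msg <- c(msg, "nwu_percent must equal 100 * (1 - d_ischemic / d_normal)")
  }
  if (!object@mode %in% c("baseline-core", "followup-infarct", "patch", "roi")) {
    msg <- c(msg, "unknown mode")
  }
  if (object@mode %in% c("baseline-core", "followup-infarct", "patch")) {
    win <- object@thresholds@normal_hu
    if (object@d_normal < win[1L] || object@d_normal > win[2L]) {
      msg <- c(msg, "d_normal must lie within the normal HU window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AgreementStats: validation statistics for paired measurements
#'
#' Holds the intraclass correlation ICC(2,1) (single-measure, absolute
#' agreement, two-way random effects) with its 95% confidence interval,
#' and/or Bland-Altman bias and limits of agreement
#' (bias +/- 1.96 * sd of the paired differences).
#'
#' @slot icc ICC(2,1) estimate (NA when not computed). The population
#'   parameter lies in \[-1, 1\]; the sample estimator can fall below -1
#'   for pathological small-sample input, which is preserved rather than
#'   clipped.
#' @slot icc_ci Length-2 95% confidence interval for the ICC.
#' @slot bias Mean difference x - y (measurement units).
#' @slot loa_low,loa_high Limits of agreement.
#' @slot n Number of measurement pairs.
#'
#' @seealso [icc21()], [blandAltman()]
#' @export
setClass("AgreementStats", representation(
  icc = "numeric",
  icc_ci = "numeric",
  bias = "numeric",
  loa_low = "numeric",
  loa_high = "numeric",
  n = "integer"
), prototype(
  icc = NA_real_, icc_ci = c(NA_real_, NA_real_),
  bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_
))

setValidity("AgreementStats", function(object) {
  msg <- character(0)
  if (!is.na(object@icc)) {
    if (object@icc > 1 + 1e-9) {
      msg <- c(msg, "icc cannot exceed 1")
    }
    ci <- object@icc_ci
    if (length(ci) != 2L ||
      (all(is.finite(ci)) &&
        (object@icc < ci[1L] - 1e-9 || object@icc > ci[2L] + 1e-9))) {
      msg <- c(msg, "icc_ci must contain icc")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic head phantom
#'
#' The generator emulates the densitometric situation the pipeline is built
#' for: brain parenchyma around 38 HU, CSF around 8 HU, a skull shell on an
#' air background, a unilateral infarct whose tissue density is scaled by
#' (1 - w) for water-uptake fraction w, optional hyperdense hemorrhagic
#' transformation foci, optional head tilt, partial-volume blur and Gaussian
#' noise. The same spec and seed always produce a bit-identical phantom.
#'
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec", representation(
  shape = "integer",
  spacing = "numeric",
  tissue_hu_mean = "numeric",
  tissue_hu_sd = "numeric",
  csf_hu_mean = "numeric",
  csf_hu_sd = "numeric",
  uptake_fraction = "numeric",
  infarct_volume_ml = "numeric",
  ht_fraction = "numeric",
  ht_hu_range = "numeric",
  tilt_deg = "numeric",
  noise_sd = "numeric",
  infarct_side = "character",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 8L)) {
    msg <- c(msg, "shape must be three extents >= 8")
  }
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  w <- object@uptake_fraction
  if (w < 0 || w >= 1) msg <- c(msg, "uptake_fraction must lie in [0, 1)")
  if (object@ht_fraction < 0 || object@ht_fraction >= 1) {
    msg <- c(msg, "ht_fraction must lie in [0, 1)")
  }
  if (object@tissue_hu_sd < 0 || object@csf_hu_sd < 0 || object@noise_sd < 0) {
    msg <- c(msg, "all sd parameters must be >= 0")
  }
  if (length(object@ht_hu_range) != 2L ||
    object@ht_hu_range[1L] >= object@ht_hu_range[2L]) {
    msg <- c(msg, "ht_hu_range must be an increasing HU interval")
  }
  if (!object@infarct_side %in% c("left", "right")) {
    msg <- c(msg, "infarct_side must be 'left' or 'right'")
  }
  if (object@infarct_volume_ml <= 0) {
    msg <- c(msg, "infarct_volume_ml must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomBundle: a phantom with its ground truth
#'
#' @slot ncct The synthetic non-contrast CT ([CTVolume-class]).
#' @slot brainMask,csfMask,infarctMask,htMask Ground-truth
#'   [VoxelMask-class] regions (brainMask covers everything inside the inner
#'   skull including CSF).
#' @slot trueNWUPercent 100 * uptake fraction w.
#' @slot midlineTruth The construction [MidlinePlane-class] after tilt.
#' @slot spec The generating [PhantomSpec-class].
#'
#' @seealso [makePhantom()]
#' @export
setClass("PhantomBundle", representation(
  ncct = "CTVolume",
  brainMask = "VoxelMask",
  csfMask = "VoxelMask",
  infarctMask = "VoxelMask",
  htMask = "VoxelMask",
  trueNWUPercent = "numeric",
  midlineTruth = "MidlinePlane",
  spec = "PhantomSpec"
))

setValidity("PhantomBundle", function(object) {
  msg <- character(0)
  if (any(object@infarctMask@voxels & object@csfMask@voxels)) {
    msg <- c(msg, "infarct mask must be disjoint from the CSF mask")
  }
  if (any(object@infarctMask@voxels & !object@brainMask@voxels)) {
    msg <- c(msg, "infarct mask must lie within the brain mask")
  }
  w <- object@spec@uptake_fraction
  if (abs(object@trueNWUPercent - 100 * w) > 1e-9) {
    msg <- c(msg, "trueNWUPercent must equal 100 * uptake_fraction")
  }
  if (length(msg)) msg else TRUE
})

#' PatchSpec: standard-patch sampling for baseline NWU
#'
#' Square patches of edge `patch_edge_mm` placed on four axial slices within
#' the middle-cerebral-artery territory of the affected hemisphere; their
#' mirror across the midline gives the normal region.
#'
#' @slot patch_edge_mm Patch edge length (mm), default 20.
#' @slot slice_z_mm Four axial slice positions (mm, world z).
#' @slot center_lr_mm Unsigned lateral offset of the patch centers from the
#'   midline (mm).
#' @slot center_ap_mm Anterior-posterior patch center coordinate (mm).
#' @slot side Affected hemisphere, "left" or "right".
#'
#' @seealso [patchNWU()], [patchSpec()]
#' @export
setClass("PatchSpec", representation(
  patch_edge_mm = "numeric",
  slice_z_mm = "numeric",
  center_lr_mm = "numeric",
  center_ap_mm = "numeric",
  side = "character"
), prototype(patch_edge_mm = 20, side = "left"))

setValidity("PatchSpec", function(object) {
  msg <- character(0)
  if (object@patch_edge_mm <= 0) msg <- c(msg, "patch_edge_mm must be > 0")
  if (length(object@slice_z_mm) != 4L) {
    msg <- c(msg, "exactly 4 axial slices are required per hemisphere")
  }
  if (!object@side %in% c("left", "right")) {
    msg <- c(msg, "side must be 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
})

#' ROISpec: circular-ROI sampling for manual-protocol NWU
#'
#' Up to 13 circular regions of ~10 mm diameter placed within the infarct in
#' the ASPECTS territories; discs are 2D, confined to each center's axial
#' slice, matching the slice-based manual protocol.
#'
#' @slot centers n x 3 matrix of world coordinates (mm), 1 <= n <= 13.
#' @slot diameter_mm ROI diameter (mm), default 10.
#' @slot side Affected hemisphere the centers must lie in.
#'
#' @seealso [roiNWU()], [roiSpec()]
#' @export
setClass("ROISpec", representation(
  centers = "matrix",
  diameter_mm = "numeric",
  side = "character"
), prototype(diameter_mm = 10, side = "left"))

setValidity("ROISpec", function(object) {
  msg <- character(0)
  n <- nrow(object@centers)
  if (is.null(n) || n < 1L || n > 13L || ncol(object@centers) != 3L) {
    msg <- c(msg, "centers must be an n x 3 matrix with 1 <= n <= 13")
  }
  if (object@diameter_mm <= 0) msg <- c(msg, "diameter_mm must be > 0")
  if (!object@side %in% c("left", "right")) {
    msg <- c(msg, "side must be 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
})
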