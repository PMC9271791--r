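#' Build the pipeline configuration
#'
#' Collects every numeric parameter of the automated workflow with its
#' default, so that a single object (serialisable to/from YAML) fully
#' determines a run. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `nwu_config`.
#' @section Parameters:
#' \describe{
#'   \item{csf_hu_low, csf_hu_high}{CSF segmentation window (HU), -5..15.}
#'   \item{csf_min_component_ml}{Minimum CSF component volume (ml), 0.3.}
#'   \item{delta_hu}{Floor of the contralateral-difference margin (HU), 1.}
#'   \item{plateau_fraction}{Adaptive margin as a fraction of the estimated
#'     hypodensity plateau, 0.8.}
#'   \item{smoothing_mm}{Smoothing before the contralateral difference, 2.}
#'   \item{min_component_ml}{Minimum infarct component (ml), 1.}
#'   \item{connectivity}{3D connectivity rule, 26.}
#'   \item{infarct_hu_low, infarct_hu_high}{Follow-up infarct window, 0..40.}
#'   \item{baseline_core_hu_low, baseline_core_hu_high}{Baseline core
#'     window, 20..80.}
#'   \item{normal_hu_low, normal_hu_high}{Normal-region window, 20..80.}
#'   \item{cbf_core_fraction}{CBF core rule fraction, 0.30.}
#'   \item{tmax_normal_s}{Tmax cutoff for normal tissue (s), 4.}
#'   \item{svd_threshold_fraction}{Deconvolution SVD truncation, 0.2.}
#'   \item{aif_k}{Voxels averaged into the AIF, 9.}
#'   \item{aif_min_enhancement}{Minimum bolus enhancement (HU), 5.}
#'   \item{min_voxels}{Minimum surviving voxels per NWU region, 50.}
#'   \item{seed}{RNG seed recorded in outputs (may be NA).}
#' }
#' @export
nwuConfig <- function(...) {
  cfg <- list(
    csf_hu_low = -5, csf_hu_high = 15, csf_min_component_ml = 0.3,
    delta_hu = 1, plateau_fraction = 0.8, smoothing_mm = 2,
    exclusion_margin_mm = 3.5,
    min_component_ml = 1, connectivity = 26L,
    infarct_hu_low = 0, infarct_hu_high = 40,
    baseline_core_hu_low = 20, baseline_core_hu_high = 80,
    normal_hu_low = 20, normal_hu_high = 80,
    cbf_core_fraction = 0.30, tmax_normal_s = 4.0,
    svd_threshold_fraction = 0.2, aif_k = 9L, aif_min_enhancement = 5,
    min_voxels = 50L, seed = NA_integer_
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  .validateConfig(cfg)
  class(cfg) <- "nwu_config"
  cfg
}

.validateConfig <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$csf_hu_low < cfg$csf_hu_high, "CSF window must be low < high")
  chk(cfg$infarct_hu_low < cfg$infarct_hu_high,
      "infarct window must be low < high")
  chk(cfg$baseline_core_hu_low < cfg$baseline_core_hu_high,
      "baseline core window must be low < high")
  chk(cfg$normal_hu_low < cfg$normal_hu_high,
      "normal window must be low < high")
  chk(cfg$cbf_core_fraction > 0 && cfg$cbf_core_fraction < 1,
      "cbf_core_fraction must lie in (0, 1)")
  chk(cfg$tmax_normal_s > 0, "tmax_normal_s must be > 0")
  chk(cfg$svd_threshold_fraction > 0 && cfg$svd_threshold_fraction < 1,
      "svd_threshold_fraction must lie in (0, 1)")
  chk(cfg$plateau_fraction > 0 && cfg$plateau_fraction < 1,
      "plateau_fraction must lie in (0, 1)")
  chk(cfg$connectivity %in% c(6L, 18L, 26L), "connectivity must be 6/18/26")
  chk(cfg$min_voxels >= 1, "min_voxels must be >= 1")
  chk(cfg$delta_hu >= 0, "delta_hu must be >= 0")
  invisible(cfg)
}

.thresholdsFromConfig <- function(cfg) {
  thresholdConfig(
    infarct_hu = c(cfg$infarct_hu_low, cfg$infarct_hu_high),
    baseline_core_hu = c(cfg$baseline_core_hu_low, cfg$baseline_core_hu_high),
    normal_hu = c(cfg$normal_hu_low, cfg$normal_hu_high)
  )
}

# shared preprocessing: brain mask, CSF, midline
.preprocessNCCT <- function(ncct, cfg, csf_segmenter = NULL) {
  brain <- extractBrainMask(ncct)
  if (voxelCount(brain) == 0L) stop("no brain found in the volume")
  csf <- if (is.null(csf_segmenter)) {
    segmentCSF(ncct, brain,
      csf_hu = c(cfg$csf_hu_low, cfg$csf_hu_high),
      min_component_ml = cfg$csf_min_component_ml
    )
  } else {
    csf_segmenter(ncct, brain)
  }
  plane <- estimateMidline(ncct, brain)
  list(brain = brain, csf = csf, plane = plane)
}

#' Run the automated follow-up NWU pipeline
#'
#' Orchestrates brain-mask extraction, CSF segmentation, symmetry-based
#' midline estimation, infarct segmentation with largest-component
#' refinement, and NWU computation in follow-up mode (0-40 HU ischemic /
#' 20-80 HU normal). Scans without visible infarct hypodensity stop with
#' "no visible infarct".
#'
#' @param ncct The follow-up [CTVolume-class].
#' @param config An [nwuConfig()] list.
#' @param csf_segmenter,infarct_segmenter Optional plug-in segmenters:
#'   functions `(volume, brainMask) -> VoxelMask` and
#'   `(volume, brainMask, csfMask, plane) -> VoxelMask` replacing the
#'   classical methods (e.g. wrappers around trained models).
#' @return A list: `result` ([NWUResult-class], including
#'   `infarct_volume_ml`), plus the intermediate `infarct`, `csf`, `brain`
#'   masks and midline `plane` for QC.
#' @export
runFollowupPipeline <- function(ncct, config = nwuConfig(),
                                csf_segmenter = NULL,
                                infarct_segmenter = NULL) {
  stopifnot(is(ncct, "CTVolume"))
  .validateConfig(config)
  pre <- .preprocessNCCT(ncct, config, csf_segmenter)
  infarct <- if (is.null(infarct_segmenter)) {
    segmentInfarct(ncct, pre$brain, pre$csf, pre$plane,
      infarct_hu = c(config$infarct_hu_low, config$infarct_hu_high),
      delta_hu = config$delta_hu,
      plateau_fraction = config$plateau_fraction,
      smoothing_mm = config$smoothing_mm,
      min_component_ml = config$min_component_ml,
      connectivity = config$connectivity,
      exclusion_margin_mm = config$exclusion_margin_mm
    )
  } else {
    infarct_segmenter(ncct, pre$brain, pre$csf, pre$plane)
  }
  if (voxelCount(infarct) == 0L) stop("no visible infarct")
  result <- computeNWU(ncct, infarct, pre$csf, pre$plane,
    thresholds = .thresholdsFromConfig(config),
    mode = "followup-infarct", brainMask = pre$brain,
    min_voxels = config$min_voxels
  )
  list(result = result, infarct = infarct, csf = pre$csf,
       brain = pre$brain, plane = pre$plane)
}

#' Run the automated baseline NWU pipeline
#'
#' For baseline scans the ischemic region comes from CT perfusion: AIF
#' selection, truncated-SVD deconvolution, the CBF < 30%-of-normal core
#' rule, rigid registration of the core onto the NCCT, then NWU in
#' baseline-core mode (20-80 HU on both sides). When a visible-infarct mask
#' is supplied (baseline scans with already demarcated hypodensity) it is
#' used in place of the CTP core, with the follow-up 0-40 HU window.
#'
#' @param ncct The baseline [CTVolume-class].
#' @param ctp_series The same subject's [CTPSeries-class] (ignored when
#'   `infarctMask` is given).
#' @param config An [nwuConfig()] list.
#' @param infarctMask Optional visible-infarct [VoxelMask-class] on the
#'   NCCT grid.
#' @param csf_segmenter Optional plug-in CSF segmenter.
#' @return A list: `result` ([NWUResult-class]), the ischemic `core` mask
#'   on the NCCT grid, `maps` ([PerfusionMaps-class] or NULL), `csf`,
#'   `brain`, and midline `plane`.
#' @export
runBaselinePipeline <- function(ncct, ctp_series, config = nwuConfig(),
                                infarctMask = NULL, csf_segmenter = NULL) {
  stopifnot(is(ncct, "CTVolume"))
  .validateConfig(config)
  pre <- .preprocessNCCT(ncct, config, csf_segmenter)
  thresholds <- .thresholdsFromConfig(config)

  if (!is.null(infarctMask)) {
    result <- computeNWU(ncct, infarctMask, pre$csf, pre$plane,
      thresholds = thresholds, mode = "followup-infarct",
      brainMask = pre$brain, min_voxels = config$min_voxels
    )
    return(list(result = result, core = infarctMask, maps = NULL,
                csf = pre$csf, brain = pre$brain, plane = pre$plane))
  }

  stopifnot(is(ctp_series, "CTPSeries"))
  ctpBase <- .ctpBaselineVolume(ctp_series)
  brainCtp <- extractBrainMask(ctpBase)
  # restrict to parenchyma: non-enhancing CSF would deconvolve to zero flow
  # and be mislabelled core by the CBF-ratio rule; the CSF mask is dilated by
  # one voxel to cover its partial-volume rim
  csfCtp <- segmentCSF(ctpBase, brainCtp,
    csf_hu = c(config$csf_hu_low, config$csf_hu_high),
    min_component_ml = config$csf_min_component_ml
  )
  # perfusion-analysis domain: parenchymal voxels within the classical
  # 20-80 HU tissue window on the baseline volume -- CSF partial-volume
  # mixtures fall below 20 HU and would otherwise deconvolve to spuriously
  # low flow
  brainCtp <- .maskLike(
    brainCtp@voxels & !.dilateBall(csfCtp@voxels, 1L) &
      ctpBase@voxels >= config$normal_hu_low &
      ctpBase@voxels <= config$normal_hu_high,
    ctpBase
  )
  aif <- selectAIF(ctp_series, brainCtp,
    k = config$aif_k, min_enhancement = config$aif_min_enhancement
  )
  maps <- deconvolveCTP(ctp_series, aif, brainCtp,
    svd_threshold_fraction = config$svd_threshold_fraction
  )
  core <- coreMask(maps, new("CoreMaskConfig",
    cbf_core_fraction = config$cbf_core_fraction,
    tmax_normal_s = config$tmax_normal_s
  ))
  # partial-volume voxels at tissue boundaries carry fractional enhancement
  # and can satisfy the CBF ratio spuriously; a 1-voxel opening removes such
  # shell fragments while leaving any genuine (blob-like) core intact
  core <- .maskLike(.opening(core@voxels, 1L), core)
  if (infarctVolumeMl(core) < 1) stop("no measurable core")
  transform <- registerRigid(ctpBase, ncct)
  coreOnNcct <- applyTransformToMask(core, transform, ncct)
  coreOnNcct <- .maskLike(coreOnNcct@voxels & pre$brain@voxels, ncct)
  if (voxelCount(coreOnNcct) == 0L) stop("no measurable core")
  result <- computeNWU(ncct, coreOnNcct, pre$csf, pre$plane,
    thresholds = thresholds, mode = "baseline-core",
    brainMask = pre$brain, min_voxels = config$min_voxels
  )
  list(result = result, core = coreOnNcct, maps = maps,
       csf = pre$csf, brain = pre$brain, plane = pre$plane)
}
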