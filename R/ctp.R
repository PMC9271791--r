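#' Read a 4D CT-perfusion series from NIfTI
#'
#' Frame times are taken from the fourth pixdim entry (frame spacing in s),
#' starting at 0.
#'
#' @param path Path to a 4D `.nii` / `.nii.gz` file.
#' @return A [CTPSeries-class].
#' @export
readCTPSeries <- function(path) {
  img <- .readNiftiChecked(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected a 4D perfusion series, got ", length(d), " dimensions")
  }
  hdr <- RNifti::niftiHeader(img)
  dt <- hdr$pixdim[5L]
  if (!is.finite(dt) || dt <= 0) {
    stop("invalid frame spacing in NIfTI header: pixdim[4] ",
         "is missing or non-positive")
  }
  new("CTPSeries",
    voxels = array(as.numeric(img), dim = d),
    times = (seq_len(d[4L]) - 1) * dt,
    spacing = hdr$pixdim[2:4], origin = c(0, 0, 0)
  )
}

#' Write a CT-perfusion series to NIfTI
#'
#' @param series A [CTPSeries-class] with uniform frame spacing.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
writeCTPSeries <- function(series, path) {
  stopifnot(is(series, "CTPSeries"))
  img <- RNifti::asNifti(series@voxels)
  dt <- series@times[2L] - series@times[1L]
  RNifti::pixdim(img) <- c(series@spacing, dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# mean volume of the pre-bolus frames; used for brain extraction and as the
# moving image when registering CTP-derived masks onto the NCCT
.ctpBaselineVolume <- function(series) {
  gm <- apply(series@voxels, 4L, mean)
  enh <- gm - min(gm)
  nbase <- max(2L, which(enh >= 0.1 * max(enh))[1L] - 1L)
  base <- apply(series@voxels[, , , seq_len(nbase), drop = FALSE], 1:3, mean)
  .ctVolume(base, series@spacing, series@origin)
}

#' Select an arterial input function from a CTP series
#'
#' Scores every brain voxel's baseline-subtracted time-attenuation curve by
#' peak enhancement (high), peak time (early) and full-width at half
#' maximum (narrow), and averages the `k` best-ranked curves. The score is
#' invariant to positive rescaling of the enhancement, so a global contrast
#' scale change selects the same voxels.
#'
#' @param series A [CTPSeries-class].
#' @param brainMask A [VoxelMask-class] on the series' spatial grid.
#' @param k Number of top-ranked voxels averaged.
#' @param min_enhancement Minimum peak enhancement (HU) for a bolus to be
#'   considered present; if no voxel reaches it the function stops with
#'   "no bolus detected".
#' @return Numeric vector: the arterial time-enhancement curve on
#'   `series@times`.
#' @export
selectAIF <- function(series, brainMask, k = 9L, min_enhancement = 5) {
  stopifnot(is(series, "CTPSeries"), is(brainMask, "VoxelMask"))
  d <- dim(series@voxels)
  if (!identical(dim(brainMask@voxels), d[1:3])) {
    stop("brainMask is not on the series grid")
  }
  nT <- d[4L]
  flat <- matrix(series@voxels, ncol = nT)[which(brainMask@voxels), ,
                                           drop = FALSE]
  gm <- colMeans(flat)
  enh <- gm - min(gm)
  nbase <- max(2L, which(enh >= 0.1 * max(enh))[1L] - 1L)
  curves <- flat - rowMeans(flat[, seq_len(nbase), drop = FALSE])
  peak <- apply(curves, 1L, max)
  if (max(peak) < min_enhancement) stop("no bolus detected")
  tpk <- apply(curves, 1L, which.max)
  fwhm <- rowSums(curves >= 0.5 * peak)
  score <- peak / ((tpk + 1) * (fwhm + 1))
  top <- order(score, decreasing = TRUE)[seq_len(min(k, nrow(curves)))]
  aif <- colMeans(curves[top, , drop = FALSE])
  aif - mean(aif[seq_len(nbase)])
}

#' Deconvolve a CTP series into CBF and Tmax maps
#'
#' Per-voxel residue functions are recovered by truncated-SVD inversion of
#' the AIF convolution matrix (standard non-circulant, delay-sensitive
#' formulation; singular values below `svd_threshold_fraction` of the
#' maximum are zeroed). Pre-bolus baseline frames -- all frames before the
#' AIF reaches 10% of its peak -- are averaged and subtracted from each
#' voxel first. CBF is the residue maximum (arbitrary units proportional to
#' flow), Tmax its time of maximum in seconds. Non-uniform acquisitions are
#' resampled to a uniform time grid by linear interpolation first.
#'
#' @param series A [CTPSeries-class].
#' @param aif Arterial curve on `series@times` (e.g. from [selectAIF()]).
#' @param brainMask A [VoxelMask-class]; maps are computed on these voxels.
#' @param svd_threshold_fraction Truncation threshold as a fraction of the
#'   largest singular value.
#' @return A [PerfusionMaps-class].
#' @export
deconvolveCTP <- function(series, aif, brainMask,
                          svd_threshold_fraction = 0.2) {
  stopifnot(is(series, "CTPSeries"), is(brainMask, "VoxelMask"))
  d <- dim(series@voxels)
  if (length(aif) != d[4L]) stop("aif and series must share the time axis")
  times <- series@times
  vox <- series@voxels
  if (length(unique(round(diff(times), 9))) > 1L) {
    ut <- seq(min(times), max(times), length.out = length(times))
    flat0 <- matrix(vox, ncol = d[4L])
    flat0 <- t(apply(flat0, 1L, function(y) stats::approx(times, y, ut)$y))
    vox <- array(flat0, dim = d)
    aif <- stats::approx(times, aif, ut)$y
    times <- ut
  }
  dt <- times[2L] - times[1L]
  nT <- length(times)

  pk <- max(aif)
  nbase <- max(1L, which(aif >= 0.1 * pk)[1L] - 1L)

  A <- matrix(0, nT, nT)
  for (j in seq_len(nT)) A[j:nT, j] <- aif[seq_len(nT - j + 1L)]
  A <- A * dt
  sv <- svd(A)
  keep <- sv$d >= svd_threshold_fraction * max(sv$d)
  if (!any(keep)) stop("AIF convolution matrix is singular after truncation")
  Ainv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])

  idx <- which(brainMask@voxels)
  flat <- matrix(vox, ncol = nT)[idx, , drop = FALSE]
  flat <- flat - rowMeans(flat[, seq_len(nbase), drop = FALSE])
  K <- Ainv %*% t(flat)                       # nT x nVox residue functions
  cbfv <- apply(K, 2L, max)
  tmaxv <- times[apply(K, 2L, which.max)] - times[1L]

  cbf <- array(0, dim = d[1:3])
  tmax <- array(0, dim = d[1:3])
  cbf[idx] <- pmax(cbfv, 0)
  tmax[idx] <- tmaxv
  new("PerfusionMaps",
    cbf = cbf, tmax = tmax, brainMask = brainMask,
    spacing = series@spacing, origin = series@origin
  )
}

#' Extract the infarct core mask from perfusion maps
#'
#' Core infarct is tissue with CBF strictly below `cbf_core_fraction`
#' (default 30%) of normal, where the normal reference is the median CBF of
#' tissue with Tmax below `tmax_normal_s` (default 4 s). The median (rather
#' than mean) reference is robust to residual lesion voxels inside the
#' normal-Tmax tissue. An empty core is a valid result.
#'
#' @param maps A [PerfusionMaps-class].
#' @param cfg A [CoreMaskConfig-class].
#' @return A [VoxelMask-class] on the map grid (possibly empty).
#' @export
coreMask <- function(maps, cfg = new("CoreMaskConfig")) {
  stopifnot(is(maps, "PerfusionMaps"), is(cfg, "CoreMaskConfig"))
  validObject(cfg)
  bm <- maps@brainMask@voxels
  normal <- bm & maps@tmax < cfg@tmax_normal_s
  if (!any(normal)) stop("no normal tissue reference (no voxel with Tmax < ",
                         cfg@tmax_normal_s, " s)")
  ref <- stats::median(maps@cbf[normal])
  out <- bm & maps@cbf < cfg@cbf_core_fraction * ref
  .voxelMask(out, maps@spacing, maps@origin)
}
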