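#' Construct a phantom specification
#'
#' Defaults describe a realistic adult stroke head at desk scale: parenchyma
#' 38 +/- 2 HU, CSF 8 +/- 3 HU, skull ~700 HU on an air background, a single
#' large middle-cerebral-artery-territory infarct of 110 ml (the median
#' automated infarct volume reported for large-vessel-occlusion follow-up
#' CT), scanner noise of 2 HU, and isotropic 1.2 mm voxels (thin-slice
#' reconstruction; fine enough that partial-volume edge bias on region means
#' stays well below the uptake signal, see the package vignette).
#'
#' @param shape Grid extents (integer length 3).
#' @param spacing Voxel size in mm (length 3).
#' @param tissue_hu_mean,tissue_hu_sd Parenchymal density (HU).
#' @param csf_hu_mean,csf_hu_sd CSF density (HU).
#' @param uptake_fraction Water-uptake fraction w in \[0, 1): infarct voxel
#'   densities are tissue draws scaled by (1 - w), so the true NWU is 100 w.
#' @param infarct_volume_ml Target infarct volume (ml).
#' @param ht_fraction Fraction of infarct voxels replaced by hyperdense
#'   (petechial) hemorrhagic-transformation voxels, in \[0, 1).
#' @param ht_hu_range HU interval the HT voxels are drawn from.
#' @param tilt_deg Head rotation about the inferior-superior axis (degrees).
#' @param noise_sd Additive Gaussian scanner noise (HU).
#' @param infarct_side Hemisphere carrying the infarct ("left" by
#'   convention).
#' @param seed Integer RNG seed; same spec + same seed gives a bit-identical
#'   phantom.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(156L, 188L, 134L),
                        spacing = c(1.0, 1.0, 1.0),
                        tissue_hu_mean = 38, tissue_hu_sd = 2,
                        csf_hu_mean = 8, csf_hu_sd = 3,
                        uptake_fraction = 0.25,
                        infarct_volume_ml = 110,
                        ht_fraction = 0, ht_hu_range = c(50, 80),
                        tilt_deg = 0, noise_sd = 2,
                        infarct_side = "left", seed = 42L) {
  new("PhantomSpec",
    shape = as.integer(shape), spacing = as.numeric(spacing),
    tissue_hu_mean = tissue_hu_mean, tissue_hu_sd = tissue_hu_sd,
    csf_hu_mean = csf_hu_mean, csf_hu_sd = csf_hu_sd,
    uptake_fraction = uptake_fraction,
    infarct_volume_ml = infarct_volume_ml,
    ht_fraction = ht_fraction, ht_hu_range = as.numeric(ht_hu_range),
    tilt_deg = tilt_deg, noise_sd = noise_sd,
    infarct_side = infarct_side, seed = as.integer(seed)
  )
}

# run expr with a private, restored RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# quadratic form Q(p) = sum(((p - center) / semi)^2) over the whole grid,
# returned as a 3D array; mask is Q < 1
.ellipsoidQ <- function(xs, ys, zs, center, semi) {
  e1 <- ((xs - center[1L]) / semi[1L])^2
  e2 <- ((ys - center[2L]) / semi[2L])^2
  e3 <- ((zs - center[3L]) / semi[3L])^2
  outer(outer(e1, e2, "+"), e3, "+")
}

.ellipsoidMask <- function(xs, ys, zs, center, semi) {
  .ellipsoidQ(xs, ys, zs, center, semi) < 1
}

# internal geometry of the head model, all derived from the field of view so
# small test phantoms scale down consistently
.phantomGeometry <- function(spec) {
  fov <- spec@shape * spec@spacing
  center <- (spec@shape - 1) / 2 * spec@spacing  # origin = (0,0,0)
  outer_skull <- 0.47 * fov
  inner_skull <- pmax(outer_skull - 5, outer_skull * 0.7)
  parenchyma <- inner_skull
  list(
    fov = fov, center = center,
    outer_skull = outer_skull, inner_skull = inner_skull,
    parenchyma = parenchyma,
    ventricle_offset = c(0.26, 0.06, 0.15) * parenchyma,
    ventricle_semi = c(0.20, 0.34, 0.26) * parenchyma,
    fissure_halfwidth = 4,
    sulcus_halfwidth = 4,
    sulcus_angles = c(40, 90, 140),   # azimuth of radial sulcal planes (deg)
    sulcus_band = c(0.82, 0.96),      # rim band of the parenchyma
    infarct_center_rel = c(0.50, -0.38, 0.12),
    infarct_axis_ratio = c(0.88, 0.95, 0.90),
    margin_skull_mm = 5,              # keeps skull blur out of the lesion
    margin_csf_mm = 3,
    margin_midline_mm = 5
  )
}

#' Generate a synthetic head phantom with known water uptake
#'
#' Builds an ellipsoidal brain inside a skull shell on an air background,
#' with symmetric lateral ventricles, an interhemispheric fissure and
#' paired sulcal CSF wedges; one ellipsoidal infarct whose density is the
#' tissue density scaled by (1 - w) is carved into the chosen hemisphere,
#' sized by binary search so the carved volume matches
#' `infarct_volume_ml`. Partial-volume blur is simulated by smoothing the
#' label-wise mean image with a 1-voxel-sigma Gaussian; optional petechial
#' hemorrhagic-transformation voxels (drawn from `ht_hu_range`) are inserted
#' after the blur so that every HT voxel is unambiguously hyperdense, giving
#' an exact accounting oracle for threshold exclusions; Gaussian tissue
#' texture and scanner noise are added last. An optional head tilt rotates
#' image and masks about the inferior-superior axis through the image
#' center.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [PhantomBundle-class] with the NCCT, ground-truth masks, the
#'   true NWU (100 w) and the construction midline.
#' @examples
#' ph <- makePhantom(phantomSpec(
#'   shape = c(40L, 48L, 34L),
#'   spacing = c(3.5, 3.5, 3.5), infarct_volume_ml = 30
#' ))
#' ph
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .makePhantomImpl(spec))
}

.makePhantomImpl <- function(spec) {
  g <- .phantomGeometry(spec)
  dm <- spec@shape
  sp <- spec@spacing
  xs <- (seq_len(dm[1L]) - 1) * sp[1L]
  ys <- (seq_len(dm[2L]) - 1) * sp[2L]
  zs <- (seq_len(dm[3L]) - 1) * sp[3L]
  C <- g$center
  sideSign <- if (spec@infarct_side == "left") -1 else 1

  headMask <- .ellipsoidMask(xs, ys, zs, C, g$outer_skull)
  brainMask <- .ellipsoidMask(xs, ys, zs, C, g$inner_skull)

  # CSF compartments: paired lateral ventricles, interhemispheric fissure,
  # paired radial sulcal wedges -- all mirror-symmetric about the midline
  vOff <- g$ventricle_offset
  ventL <- .ellipsoidMask(xs, ys, zs, C + c(-vOff[1L], vOff[2L], vOff[3L]),
                          g$ventricle_semi)
  ventR <- .ellipsoidMask(xs, ys, zs, C + c(vOff[1L], vOff[2L], vOff[3L]),
                          g$ventricle_semi)
  parQ <- .ellipsoidQ(xs, ys, zs, C, g$parenchyma)
  X <- outer(outer(xs - C[1L], rep(1, dm[2L])), rep(1, dm[3L]))
  Y <- outer(outer(rep(1, dm[1L]), ys - C[2L]), rep(1, dm[3L]))
  Zup <- outer(outer(rep(0, dm[1L]), rep(0, dm[2L]), "+"), zs - C[3L], "+")
  fissure <- abs(X) <= g$fissure_halfwidth & parQ < 0.88 &
    Zup > 0.25 * g$parenchyma[3L]
  rim <- parQ < g$sulcus_band[2L]^2 & parQ >= g$sulcus_band[1L]^2 &
    Zup > -0.2 * g$parenchyma[3L]
  sulci <- array(FALSE, dim = dm)
  for (ang in g$sulcus_angles) {
    n2 <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    sulci <- sulci | (abs(X * n2[1L] + Y * n2[2L]) <= g$sulcus_halfwidth & rim)
  }
  csfMask <- (ventL | ventR | fissure | sulci) & brainMask

  # infarct: ellipsoid scaled so the carved volume hits the target, kept
  # clear of skull, CSF and midline by safety margins
  safe <- parQ < 1 &
    .ellipsoidQ(xs, ys, zs, C, pmax(g$parenchyma - g$margin_skull_mm, 1)) < 1 &
    !.ellipsoidMask(xs, ys, zs, C + c(-vOff[1L], vOff[2L], vOff[3L]),
                    g$ventricle_semi + g$margin_csf_mm) &
    !.ellipsoidMask(xs, ys, zs, C + c(vOff[1L], vOff[2L], vOff[3L]),
                    g$ventricle_semi + g$margin_csf_mm) &
    !(abs(X) <= g$fissure_halfwidth + g$margin_csf_mm & parQ < 0.92 &
        Zup > 0.25 * g$parenchyma[3L] - g$margin_csf_mm) &
    (sideSign * X >= g$margin_midline_mm)
  for (ang in g$sulcus_angles) {
    n2 <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    safe <- safe & !(abs(X * n2[1L] + Y * n2[2L]) <=
                       g$sulcus_halfwidth + g$margin_csf_mm &
                       parQ >= (g$sulcus_band[1L] - 0.06)^2)
  }

  infCenter <- C + c(
    sideSign * g$infarct_center_rel[1L] * g$parenchyma[1L],
    g$infarct_center_rel[2L] * g$parenchyma[2L],
    g$infarct_center_rel[3L] * g$parenchyma[3L]
  )
  voxMl <- prod(sp) / 1000
  targetVox <- round(spec@infarct_volume_ml / voxMl)
  infQ1 <- .ellipsoidQ(xs, ys, zs, infCenter, g$infarct_axis_ratio)
  countAt <- function(t) sum(infQ1 < t^2 & safe)   # semi = t * axis_ratio
  tMax <- 1.2 * max(g$parenchyma)
  if (countAt(tMax) < targetVox) {
    stop("infarct_volume_ml too large to fit the hemisphere")
  }
  lo <- 0; hi <- tMax
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (countAt(mid) < targetVox) lo <- mid else hi <- mid
  }
  infarctMask <- infQ1 < hi^2 & safe

  # label-wise mean image, then partial-volume blur (1 voxel sigma)
  w <- spec@uptake_fraction
  field <- array(-1024, dim = dm)
  field[headMask] <- 700
  field[brainMask] <- spec@tissue_hu_mean
  field[csfMask] <- spec@csf_hu_mean
  field[infarctMask] <- spec@tissue_hu_mean * (1 - w)
  field <- .gaussSmooth(field, 1)

  # optional head tilt about the inferior-superior axis through the center
  plane <- new("MidlinePlane", point = C, normal = c(1, 0, 0))
  if (spec@tilt_deg != 0) {
    Rinv <- .rotZ(-spec@tilt_deg)
    mapFun <- function(W) sweep(sweep(W, 2, C, "-") %*% t(Rinv), 2, C, "+")
    field <- .resampleArray(field, sp, c(0, 0, 0), dm, sp, c(0, 0, 0),
                            mapFun, "linear", fill = -1024)
    rot <- function(m) {
      .resampleArray(m, sp, c(0, 0, 0), dm, sp, c(0, 0, 0),
                     mapFun, "nearest", fill = FALSE) > 0
    }
    brainMask <- rot(brainMask); csfMask <- rot(csfMask)
    infarctMask <- rot(infarctMask)
    infarctMask <- infarctMask & !csfMask & brainMask
    Rfwd <- .rotZ(spec@tilt_deg)
    plane <- new("MidlinePlane", point = C,
                 normal = as.numeric(Rfwd %*% c(1, 0, 0)))
  }

  # petechial hemorrhagic transformation: scattered infarct voxels replaced
  # by hyperdense draws, inserted after the blur so every HT voxel stays
  # above the infarct HU ceiling
  htMask <- array(FALSE, dim = dm)
  infIdx <- which(infarctMask)
  nHT <- round(spec@ht_fraction * length(infIdx))
  if (nHT > 0L) {
    htIdx <- sample(infIdx, nHT)
    htMask[htIdx] <- TRUE
    field[htIdx] <- stats::runif(nHT, spec@ht_hu_range[1L],
                                 spec@ht_hu_range[2L])
  }

  # tissue texture + scanner noise in a single Gaussian draw per voxel
  sdMap <- array(spec@noise_sd, dim = dm)
  tx <- sqrt(spec@tissue_hu_sd^2 + spec@noise_sd^2)
  sdMap[brainMask] <- tx
  sdMap[csfMask] <- sqrt(spec@csf_hu_sd^2 + spec@noise_sd^2)
  sdMap[infarctMask] <- sqrt((spec@tissue_hu_sd * (1 - w))^2 + spec@noise_sd^2)
  sdMap[htMask] <- spec@noise_sd
  field <- field + stats::rnorm(length(field)) * sdMap

  ncct <- .ctVolume(array(field, dim = dm), sp, origin = c(0, 0, 0))
  new("PhantomBundle",
    ncct = ncct,
    brainMask = .voxelMask(brainMask, sp),
    csfMask = .voxelMask(csfMask, sp),
    infarctMask = .voxelMask(infarctMask, sp),
    htMask = .voxelMask(htMask, sp),
    trueNWUPercent = 100 * w,
    midlineTruth = plane,
    spec = spec
  )
}

#' Generate a CT-perfusion series for a phantom
#'
#' Forward model of a dynamic contrast acquisition on a coarser grid (every
#' `downsample`-th voxel of the phantom, emulating the lower resolution of
#' perfusion imaging): each tissue voxel's time-attenuation curve is
#' CBF x (AIF convolved with an exponential residue R(t) = exp(-t/MTT)),
#' shifted by the voxel's bolus delay and superimposed on the baseline NCCT
#' density. Infarct-core voxels receive `cbf_normal * cbf_core_ratio` and
#' `delay_core_s`; normal brain receives `cbf_normal` with zero delay. A
#' small arterial "vessel" block carries the undiluted gamma-variate AIF for
#' AIF selection. Gaussian noise of `noise_sd` HU is added to every frame.
#'
#' The gamma-variate AIF is `A ((t-t0)/tp)^alpha exp(alpha (1 - (t-t0)/tp))`
#' with fixed shape `t0 = 8 s`, `tp = 2.5 s`, `alpha = 3`, `A = 200` HU -- a
#' compact power-injector first-pass bolus (~4 s full width at half
#' maximum). Non-enhancing CSF is excluded from the returned brain mask, so
#' perfusion maps are computed over parenchyma only.
#'
#' @param bundle A [PhantomBundle-class].
#' @param cbf_normal Normal-tissue flow (nominal ml/100g/min; only ratios
#'   matter downstream).
#' @param cbf_core_ratio Core/normal flow ratio in (0, 1).
#' @param mtt_s Mean transit time of the exponential residue (s).
#' @param delay_core_s Bolus delay of core voxels (s); the ground-truth core
#'   Tmax.
#' @param time_step_s Frame spacing (s), > 0.
#' @param duration_s Acquisition length (s); must cover the bolus.
#' @param noise_sd Frame noise (HU).
#' @param downsample Integer grid decimation factor relative to the phantom.
#' @param seed RNG seed for the frame noise.
#' @return A list with elements `series` ([CTPSeries-class]), `aif` (the
#'   true arterial curve), ground-truth `cbfTruth` and `tmaxTruth` arrays,
#'   `coreTruth`, `brainMask` and `vesselMask` ([VoxelMask-class]) on the
#'   CTP grid.
#' @export
makeCTPSeries <- function(bundle, cbf_normal = 50, cbf_core_ratio = 0.2,
                          mtt_s = 4, delay_core_s = 6, time_step_s = 2,
                          duration_s = 50, noise_sd = 1, downsample = 3L,
                          seed = bundle@spec@seed + 1L) {
  stopifnot(is(bundle, "PhantomBundle"))
  if (time_step_s <= 0) stop("time_step_s must be > 0")
  if (cbf_core_ratio <= 0 || cbf_core_ratio >= 1) {
    stop("cbf_core_ratio must lie in (0, 1)")
  }
  times <- seq(0, duration_s, by = time_step_s)
  aif <- .gammaVariateAIF(times)
  if (max(aif) < 1e-6 || which.max(aif) > length(times) - 3L) {
    stop("duration_s does not cover the AIF bolus")
  }
  .withSeed(seed, .makeCTPImpl(bundle, cbf_normal, cbf_core_ratio, mtt_s,
                               delay_core_s, times, aif, noise_sd,
                               as.integer(downsample)))
}

.gammaVariateAIF <- function(times, t0 = 8, tp = 2.5, alpha = 3, A = 200) {
  tt <- pmax(times - t0, 0) / tp
  A * tt^alpha * exp(alpha * (1 - tt))
}

.makeCTPImpl <- function(bundle, cbf_normal, ratio, mtt, delay, times, aif,
                         noise_sd, ds) {
  # block-mean downsampling: a CTP voxel averages the underlying fine
  # voxels, so tissue fractions (and with them enhancement amplitudes)
  # follow the partial-volume mixing of a genuinely coarser acquisition
  sp <- bundle@ncct@spacing * ds
  org <- bundle@ncct@origin + (ds - 1) / 2 * bundle@ncct@spacing
  base <- .blockMean(bundle@ncct@voxels, ds)
  fBrain <- .blockMean(bundle@brainMask@voxels, ds)
  fCore <- .blockMean(bundle@infarctMask@voxels, ds)
  fCsf <- .blockMean(bundle@csfMask@voxels, ds)
  fNorm <- pmax(fBrain - fCsf - fCore, 0)
  dm <- dim(base)
  brain <- fBrain >= 0.5
  core <- fCore >= 0.5
  parench <- (fNorm + fCore) >= 0.5

  # arterial block: a small parenchymal region near the anterior midline
  g <- .phantomGeometry(bundle@spec)
  vc <- g$center + c(0, 0.55 * g$parenchyma[2L], -0.1 * g$parenchyma[3L])
  vi <- round((vc - org) / sp) + 1
  rad <- 1L
  vessel <- array(FALSE, dim = dm)
  vx <- pmax(1L, vi[1L] - rad):pmin(dm[1L], vi[1L] + rad)
  vy <- pmax(1L, vi[2L] - rad):pmin(dm[2L], vi[2L] + rad)
  vz <- pmax(1L, vi[3L] - rad):pmin(dm[3L], vi[3L] + rad)
  vessel[vx, vy, vz] <- TRUE
  vessel <- vessel & brain

  nT <- length(times)
  dt <- times[2L] - times[1L]
  # convolution matrix of the AIF (lower-triangular Toeplitz)
  A <- matrix(0, nT, nT)
  for (j in seq_len(nT)) A[j:nT, j] <- aif[seq_len(nT - j + 1L)]
  A <- A * dt

  cbfTruth <- cbf_normal * fNorm + cbf_normal * ratio * fCore
  tmaxTruth <- array(0, dim = dm)
  tmaxTruth[core] <- delay

  # residue curves for the two tissue classes
  resCurve <- function(f, d) {
    r <- ifelse(times >= d, exp(-(times - d) / mtt), 0)
    as.numeric(A %*% (f * r))
  }
  normCurve <- resCurve(cbf_normal, 0)
  coreCurve <- resCurve(cbf_normal * ratio, delay)
  scale <- 30 / max(normCurve)   # normal tissue peaks at ~30 HU enhancement

  flat <- scale * (as.numeric(fNorm) %o% normCurve +
                     as.numeric(fCore) %o% coreCurve)
  idxV <- which(vessel)
  flat[idxV, ] <- matrix(aif, length(idxV), nT, byrow = TRUE)
  flat <- flat + as.numeric(base)
  if (noise_sd > 0) flat <- flat + stats::rnorm(length(flat), sd = noise_sd)
  series <- array(flat, dim = c(dm, nT))

  list(
    series = new("CTPSeries", voxels = series, times = times,
                 spacing = sp, origin = org),
    aif = aif,
    cbfTruth = cbfTruth,
    tmaxTruth = tmaxTruth,
    coreTruth = .voxelMask(core, sp, org),
    brainMask = .voxelMask(parench, sp, org),
    vesselMask = .voxelMask(vessel, sp, org)
  )
}
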