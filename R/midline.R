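#' Estimate the brain midline plane by reflection symmetry
#'
#' Finds the plane that maximises the normalized cross-correlation between
#' the brain image and its reflection across the plane, over voxels of
#' `brainMask`. The plane is parameterised by a lateral offset from the
#' mid-sagittal grid plane plus yaw (rotation about the inferior-superior
#' axis) and roll (rotation about the posterior-anterior axis). A coarse
#' yaw/offset grid search seeds a Nelder-Mead refinement of all three
#' parameters; both stages run on a subsampled voxel set for speed while
#' sampling the full-resolution image.
#'
#' This symmetry-based estimator stands in for atlas-based midline
#' delineation: it honours the same contract (a midline usable on every
#' slice) without requiring external atlas data. If an atlas midline is
#' available it can be supplied directly as a [MidlinePlane-class] wherever
#' a plane is accepted.
#'
#' @param volume A [CTVolume-class].
#' @param brainMask Nonempty [VoxelMask-class] on the same grid.
#' @param max_tilt_deg Half-width of the yaw search range (degrees).
#' @param max_offset_mm Half-width of the lateral offset search (mm).
#' @param max_points Approximate number of brain voxels used per objective
#'   evaluation.
#' @return A [MidlinePlane-class]; its `converged` slot is FALSE (with a
#'   warning) when the optimiser could not improve on the initial
#'   mid-sagittal plane.
#' @export
estimateMidline <- function(volume, brainMask, max_tilt_deg = 12,
                            max_offset_mm = 8, max_points = 60000L) {
  stopifnot(is(volume, "CTVolume"), is(brainMask, "VoxelMask"))
  if (!sameGrid(brainMask, volume)) stop("brainMask is not on the volume grid")
  if (voxelCount(brainMask) == 0L) stop("brainMask is empty")
  dm <- dim(volume@voxels)
  ctr <- .gridCenter(dm, volume@spacing, volume@origin)

  idxAll <- which(brainMask@voxels)
  pick <- function(n) {
    if (length(idxAll) <= n) idxAll
    else idxAll[seq.int(1L, length(idxAll),
                        by = ceiling(length(idxAll) / n))]
  }
  objectiveFor <- function(idx) {
    W <- .linearToWorld(idx, dm, volume@spacing, volume@origin)
    I <- volume@voxels[idx]
    function(par) {  # par = (dx_mm, yaw_deg, roll_deg)
      n <- as.numeric(.rotZ(par[2L]) %*% .rotY(par[3L]) %*% c(1, 0, 0))
      p <- ctr + c(par[1L], 0, 0)
      Wr <- .reflectPoints(W, p, n)
      Ir <- .trilinear(volume@voxels,
                       .worldToVoxel(Wr, volume@spacing, volume@origin))
      ok <- !is.na(Ir)
      if (sum(ok) < 50L) return(1)
      -stats::cor(I[ok], Ir[ok])
    }
  }

  objCoarse <- objectiveFor(pick(ceiling(max_points / 4)))
  grid <- expand.grid(
    dx = seq(-max_offset_mm, max_offset_mm, by = 2),
    yaw = seq(-max_tilt_deg, max_tilt_deg, by = 2)
  )
  vals <- apply(grid, 1L, function(r) objCoarse(c(r[[1L]], r[[2L]], 0)))
  best <- which.min(vals)
  start <- c(grid$dx[best], grid$yaw[best], 0)

  objFine <- objectiveFor(pick(max_points))
  fit <- stats::optim(start, objFine,
    method = "Nelder-Mead",
    control = list(
      maxit = 200, reltol = 1e-6,
      parscale = c(2, 2, 2)
    )
  )
  initVal <- objFine(c(0, 0, 0))
  converged <- fit$value < initVal - 1e-9
  par <- if (converged) fit$par else c(0, 0, 0)
  if (!converged) {
    warning("midline optimiser did not improve on the mid-sagittal plane; ",
            "returning the initialisation")
  }
  normal <- as.numeric(.rotZ(par[2L]) %*% .rotY(par[3L]) %*% c(1, 0, 0))
  new("MidlinePlane",
    point = ctr + c(par[1L], 0, 0), normal = normal,
    converged = converged
  )
}

#' Split a brain mask into hemispheres along a midline plane
#'
#' Partitions the mask by the signed distance of each voxel center to the
#' plane; voxels within half a voxel of the plane are assigned to neither
#' hemisphere. The plane normal points to the patient's right, so "left" is
#' the negative side.
#'
#' @param brainMask A [VoxelMask-class].
#' @param plane A [MidlinePlane-class].
#' @return A list with [VoxelMask-class] elements `left` and `right`.
#' @export
splitHemispheres <- function(brainMask, plane) {
  stopifnot(is(brainMask, "VoxelMask"), is(plane, "MidlinePlane"))
  validObject(plane)
  dm <- dim(brainMask@voxels)
  idx <- which(brainMask@voxels)
  W <- .linearToWorld(idx, dm, brainMask@spacing, brainMask@origin)
  d <- .planeDistance(W, plane@point, plane@normal)
  h <- 0.5 * sum(abs(plane@normal) * brainMask@spacing)
  left <- array(FALSE, dim = dm)
  right <- array(FALSE, dim = dm)
  left[idx[d < -h]] <- TRUE
  right[idx[d > h]] <- TRUE
  list(
    left = .maskLike(left, brainMask),
    right = .maskLike(right, brainMask)
  )
}

#' Mirror a mask across the midline plane
#'
#' Reflects each inside-voxel's physical center across the plane and maps
#' the reflected points back to voxels by nearest neighbour. The result is a
#' purely geometric reflection: clipping to the brain (dropping mirrored
#' voxels that land outside it) is left to the caller.
#'
#' @param mask A [VoxelMask-class].
#' @param plane A [MidlinePlane-class].
#' @return The mirrored [VoxelMask-class] on the same grid.
#' @export
mirrorMask <- function(mask, plane) {
  stopifnot(is(mask, "VoxelMask"), is(plane, "MidlinePlane"))
  validObject(plane)
  dm <- dim(mask@voxels)
  idx <- which(mask@voxels)
  out <- array(FALSE, dim = dm)
  if (length(idx) == 0L) return(.maskLike(out, mask))
  W <- .linearToWorld(idx, dm, mask@spacing, mask@origin)
  Wr <- .reflectPoints(W, plane@point, plane@normal)
  V <- round(.worldToVoxel(Wr, mask@spacing, mask@origin))
  ok <- V[, 1L] >= 1 & V[, 1L] <= dm[1L] &
    V[, 2L] >= 1 & V[, 2L] <= dm[2L] &
    V[, 3L] >= 1 & V[, 3L] <= dm[3L]
  if (!any(ok)) stop("mirrored region falls entirely outside the grid")
  lin <- (V[ok, 1L] - 1) + (V[ok, 2L] - 1) * dm[1L] +
    (V[ok, 3L] - 1) * dm[1L] * dm[2L] + 1
  out[lin] <- TRUE
  .maskLike(out, mask)
}

#' Rigid CT-to-CT registration by normalized mutual information
#'
#' Estimates the 6-parameter rigid transform (3 rotations, 3 translations)
#' aligning `moving` to `fixed`, maximising normalized mutual information
#' over a subsampled set of fixed-image head voxels, by multi-resolution
#' Nelder-Mead. Intended for same-subject CT-to-CT alignment such as
#' transferring a CTP-derived core mask onto the NCCT.
#'
#' @param moving,fixed [CTVolume-class] objects covering the head.
#' @param max_points Number of fixed-image samples per objective evaluation.
#' @param bins Joint-histogram bins per axis.
#' @return A [RigidTransform-class] mapping fixed-image physical points into
#'   the moving image; `converged` is FALSE (with a warning) when the
#'   similarity could not be improved over identity.
#' @seealso [applyTransformToMask()], [applyTransformToVolume()]
#' @export
registerRigid <- function(moving, fixed, max_points = 40000L, bins = 32L) {
  stopifnot(is(moving, "CTVolume"), is(fixed, "CTVolume"))
  dmF <- dim(fixed@voxels)
  ctr <- .gridCenter(dmF, fixed@spacing, fixed@origin)
  head <- which(fixed@voxels > -500)
  if (length(head) < 100L) stop("fixed volume does not appear to cover a head")

  nmi <- function(a, b) {
    ra <- range(a); rb <- range(b)
    if (diff(ra) == 0 || diff(rb) == 0) return(0)
    ia <- pmin(bins, 1L + floor((a - ra[1L]) / diff(ra) * bins))
    ib <- pmin(bins, 1L + floor((b - rb[1L]) / diff(rb) * bins))
    jo <- tabulate(ia + (ib - 1L) * bins, bins * bins) / length(a)
    pa <- tabulate(ia, bins) / length(a)
    pb <- tabulate(ib, bins) / length(b)
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    (H(pa) + H(pb)) / H(jo)
  }

  makeObjective <- function(n) {
    idx <- if (length(head) <= n) head
    else head[seq.int(1L, length(head), by = ceiling(length(head) / n))]
    W <- .linearToWorld(idx, dmF, fixed@spacing, fixed@origin)
    I <- fixed@voxels[idx]
    function(par) {  # (rx, ry, rz in deg, tx, ty, tz in mm)
      R <- .eulerRotation(par[1L], par[2L], par[3L])
      Wm <- sweep(sweep(W, 2, ctr, "-") %*% t(R), 2, ctr + par[4:6], "+")
      Im <- .trilinear(moving@voxels,
                       .worldToVoxel(Wm, moving@spacing, moving@origin))
      ok <- !is.na(Im)
      if (sum(ok) < 200L) return(0)
      -nmi(I[ok], Im[ok])
    }
  }

  # translation initialised from the head centers of mass; rotations from a
  # coarse grid -- NMI is too flat on low-contrast CT for a single local
  # search from identity
  com <- function(v, sp, org) {
    idx <- which(v > -500)
    colMeans(.linearToWorld(idx, dim(v), sp, org))
  }
  t0 <- com(moving@voxels, moving@spacing, moving@origin) -
    com(fixed@voxels, fixed@spacing, fixed@origin)

  objCoarse <- makeObjective(ceiling(max_points / 2))
  best <- c(0, 0, 0, t0)
  bestVal <- objCoarse(best)
  for (rz in seq(-9, 9, by = 1.5)) {
    for (ry in seq(-6, 6, by = 3)) {
      for (rx in seq(-6, 6, by = 3)) {
        val <- objCoarse(c(rx, ry, rz, t0))
        if (val < bestVal) {
          bestVal <- val
          best <- c(rx, ry, rz, t0)
        }
      }
    }
  }
  fit1 <- stats::optim(best, objCoarse,
    method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-8,
                   parscale = c(2, 2, 2, 2, 2, 2))
  )
  objFine <- makeObjective(max_points)
  fit2 <- stats::optim(fit1$par, objFine,
    method = "Nelder-Mead",
    control = list(maxit = 300, reltol = 1e-9,
                   parscale = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  )
  identVal <- objFine(rep(0, 6L))
  converged <- fit2$value < identVal - 1e-10
  if (!converged && max(abs(fit2$par[1:3])) < 1 &&
      sqrt(sum(fit2$par[4:6]^2)) < 1) {
    # the optimum *is* (numerically) the identity; not a failure
    converged <- TRUE
  }
  par <- if (converged) fit2$par else rep(0, 6L)
  if (!converged) {
    warning("registration did not improve on identity; returning identity")
  }
  new("RigidTransform",
    rotation = .eulerRotation(par[1L], par[2L], par[3L]),
    translation = par[4:6], center = ctr, converged = converged
  )
}

.mapFixedToMoving <- function(transform) {
  function(W) {
    sweep(
      sweep(W, 2, transform@center, "-") %*% t(transform@rotation),
      2, transform@center + transform@translation, "+"
    )
  }
}

#' Resample a mask through a rigid transform onto a target grid
#'
#' Nearest-neighbour interpolation, preserving binarity.
#'
#' @param mask A [VoxelMask-class] on the moving image's grid.
#' @param transform A [RigidTransform-class] from [registerRigid()].
#' @param grid A [CTVolume-class] (or [VoxelMask-class]) defining the fixed
#'   target grid.
#' @return A [VoxelMask-class] on `grid`.
#' @export
applyTransformToMask <- function(mask, transform, grid) {
  stopifnot(is(mask, "VoxelMask"), is(transform, "RigidTransform"))
  dmT <- dim(voxels(grid))
  out <- .resampleArray(
    mask@voxels, mask@spacing, mask@origin,
    dmT, spacing(grid), origin(grid),
    .mapFixedToMoving(transform), "nearest", fill = FALSE
  )
  .voxelMask(out > 0, spacing(grid), origin(grid))
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' Trilinear interpolation, preserving densitometry.
#'
#' @inheritParams applyTransformToMask
#' @param volume A [CTVolume-class] on the moving image's grid.
#' @return A [CTVolume-class] on `grid` (outside voxels filled with air,
#'   -1024 HU).
#' @export
applyTransformToVolume <- function(volume, transform, grid) {
  stopifnot(is(volume, "CTVolume"), is(transform, "RigidTransform"))
  dmT <- dim(voxels(grid))
  out <- .resampleArray(
    volume@voxels, volume@spacing, volume@origin,
    dmT, spacing(grid), origin(grid),
    .mapFixedToMoving(transform), "linear", fill = -1024
  )
  .ctVolume(out, spacing(grid), origin(grid))
}

#' Extract a brain mask from a head CT
#'
#' Classical HU/morphology brain extraction: voxels in the soft-tissue/CSF
#' window (0-80 HU with a small noise margin) are opened to remove speckle,
#' the largest 3D connected component is kept (discarding scalp and other
#' soft tissue outside the skull) and closed to fill noise holes. This is a
#' deliberately simple helper sufficient for skull-enclosed brain
#' extraction; it is not a general skull-stripping tool.
#'
#' @param volume A [CTVolume-class].
#' @param hu_window Inclusion window in HU.
#' @return A [VoxelMask-class].
#' @export
extractBrainMask <- function(volume, hu_window = c(-10, 85)) {
  stopifnot(is(volume, "CTVolume"))
  m <- volume@voxels >= hu_window[1L] & volume@voxels <= hu_window[2L]
  m <- .opening(m, 1L)
  lab <- .labelComponents(m, 26L)
  if (length(lab$sizes) == 0L) {
    return(.maskLike(array(FALSE, dim(volume@voxels)), volume))
  }
  keep <- which.max(lab$sizes)
  out <- array(FALSE, dim(volume@voxels))
  out[lab$indices[[keep]]] <- TRUE
  out <- .closing(out, 1L)
  .maskLike(out, volume)
}
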