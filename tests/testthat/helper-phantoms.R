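# Shared fixtures: phantoms are expensive, so they are built once per session
# and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# coarse phantom for cheap unit tests (2 mm isotropic, 60 ml lesion)
smallSpec <- function(infarct_volume_ml = 60, ...) {
  phantomSpec(
    shape = c(80L, 94L, 68L), spacing = c(2, 2, 2),
    infarct_volume_ml = infarct_volume_ml, ...
  )
}

smallPhantom <- function(w = 0.25, seed = 5L, ...) {
  key <- paste("small", w, seed, ...)
  cached(key, makePhantom(smallSpec(uptake_fraction = w, seed = seed, ...)))
}

# the standard phantom at full working resolution
stdPhantom <- function(w = 0.25, seed = 42L, ...) {
  key <- paste("std", w, seed, ...)
  cached(key, makePhantom(phantomSpec(uptake_fraction = w, seed = seed, ...)))
}

stdBrain <- function(ph, key) {
  cached(paste0("brain-", key), extractBrainMask(ph@ncct))
}

# angle between two plane normals, in degrees (sign-insensitive)
angleErrDeg <- function(n1, n2) {
  acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
}

# a bare uniform-tissue head for synthetic segmentation cases:
# ellipsoidal brain of `tissue_hu` on air, no CSF, no skull detail
uniformHead <- function(dim = c(60L, 70L, 50L), spacing = c(2, 2, 2),
                        tissue_hu = 38, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  ctr <- (dim - 1) / 2 * spacing
  semi <- 0.45 * dim * spacing
  xs <- (seq_len(dim[1L]) - 1) * spacing[1L]
  ys <- (seq_len(dim[2L]) - 1) * spacing[2L]
  zs <- (seq_len(dim[3L]) - 1) * spacing[3L]
  q <- outer(outer(((xs - ctr[1L]) / semi[1L])^2,
                   ((ys - ctr[2L]) / semi[2L])^2, "+"),
             ((zs - ctr[3L]) / semi[3L])^2, "+")
  brain <- q < 1
  vox <- array(-1024, dim = dim)
  vox[brain] <- tissue_hu
  if (noise_sd > 0) vox <- vox + rnorm(length(vox), sd = noise_sd)
  vox <- pmin(pmax(vox, -1024), 3071)
  vol <- new("CTVolume",
    voxels = vox, spacing = as.numeric(spacing),
    origin = c(0, 0, 0), orientation = "RAS", nativeOrientation = "RAS"
  )
  list(
    volume = vol,
    brain = new("VoxelMask", voxels = brain, spacing = as.numeric(spacing),
                origin = c(0, 0, 0)),
    center = ctr
  )
}

emptyMaskLike <- function(vol) {
  new("VoxelMask",
    voxels = array(FALSE, dim(voxels(vol))),
    spacing = spacing(vol), origin = origin(vol)
  )
}

maskFrom <- function(arr, like) {
  new("VoxelMask",
    voxels = arr, spacing = spacing(like), origin = origin(like)
  )
}

midSagittalPlane <- function(vol) {
  dm <- dim(voxels(vol))
  ctr <- origin(vol) + (dm - 1) / 2 * spacing(vol)
  new("MidlinePlane", point = ctr, normal = c(1, 0, 0))
}
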