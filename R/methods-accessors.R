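#' @describeIn voxels HU array of a CT volume.
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @describeIn voxels Logical array of a mask.
#' @export
setMethod("voxels", "VoxelMask", function(x) x@voxels)

#' @describeIn voxels 4D HU array of a perfusion series.
#' @export
setMethod("voxels", "CTPSeries", function(x) x@voxels)

#' @describeIn spacing Spacing of a CT volume.
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @describeIn spacing Spacing of a mask.
#' @export
setMethod("spacing", "VoxelMask", function(x) x@spacing)

#' @describeIn spacing Spatial spacing of a perfusion series.
#' @export
setMethod("spacing", "CTPSeries", function(x) x@spacing)

#' @describeIn spacing Spacing of perfusion maps.
#' @export
setMethod("spacing", "PerfusionMaps", function(x) x@spacing)

#' @describeIn origin Origin of a CT volume.
#' @export
setMethod("origin", "CTVolume", function(x) x@origin)

#' @describeIn origin Origin of a mask.
#' @export
setMethod("origin", "VoxelMask", function(x) x@origin)

#' @describeIn origin Origin of a perfusion series.
#' @export
setMethod("origin", "CTPSeries", function(x) x@origin)

#' @describeIn voxelCount Foreground count of a mask.
#' @export
setMethod("voxelCount", "VoxelMask", function(x) sum(x@voxels))

#' @describeIn nwuPercent NWU percentage of a result.
#' @export
setMethod("nwuPercent", "NWUResult", function(x) x@nwu_percent)

.gridsAgree <- function(dimA, spA, orA, dimB, spB, orB) {
  identical(dimA, dimB) &&
    all(abs(spA - spB) <= 1e-3 * spA) &&
    all(abs(orA - orB) <= 1e-3 * spA)
}

#' @describeIn sameGrid Volume vs volume.
#' @export
setMethod("sameGrid", signature("CTVolume", "CTVolume"), function(x, y) {
  .gridsAgree(dim(x@voxels), x@spacing, x@origin,
              dim(y@voxels), y@spacing, y@origin)
})

#' @describeIn sameGrid Mask vs volume.
#' @export
setMethod("sameGrid", signature("VoxelMask", "CTVolume"), function(x, y) {
  .gridsAgree(dim(x@voxels), x@spacing, x@origin,
              dim(y@voxels), y@spacing, y@origin)
})

#' @describeIn sameGrid Volume vs mask.
#' @export
setMethod("sameGrid", signature("CTVolume", "VoxelMask"), function(x, y) {
  sameGrid(y, x)
})

#' @describeIn sameGrid Mask vs mask.
#' @export
setMethod("sameGrid", signature("VoxelMask", "VoxelMask"), function(x, y) {
  .gridsAgree(dim(x@voxels), x@spacing, x@origin,
              dim(y@voxels), y@spacing, y@origin)
})

# internal constructors -------------------------------------------------------

.ctVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                      nativeOrientation = "RAS") {
  voxels[voxels < HU_FLOOR] <- HU_FLOOR
  voxels[voxels > HU_CEILING] <- HU_CEILING
  new("CTVolume",
    voxels = voxels, spacing = as.numeric(spacing),
    origin = as.numeric(origin), orientation = "RAS",
    nativeOrientation = nativeOrientation
  )
}

.voxelMask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "logical"
  new("VoxelMask",
    voxels = voxels, spacing = as.numeric(spacing),
    origin = as.numeric(origin)
  )
}

# mask on the same grid as `like` (CTVolume or VoxelMask)
.maskLike <- function(voxels, like) {
  .voxelMask(voxels, spacing(like), origin(like))
}

.voxelVolumeMl <- function(x) prod(spacing(x)) / 1000
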