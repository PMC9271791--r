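#' Access the voxel array of a volume, mask or series
#'
#' @param x A [CTVolume-class], [VoxelMask-class] or [CTPSeries-class].
#' @return The underlying array (logical for masks).
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Access the voxel spacing in mm
#' @param x An object carrying grid geometry.
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Access the physical origin (mm) of the first voxel center
#' @param x An object carrying grid geometry.
#' @return Numeric length-3 origin in mm.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Number of foreground voxels of a mask
#' @param x A [VoxelMask-class].
#' @return Integer voxel count.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Test whether two objects share the same voxel grid
#'
#' Grids match when dimensions are identical and spacing and origin agree
#' within a small tolerance (1e-3 of a voxel).
#'
#' @param x,y Objects carrying grid geometry.
#' @return TRUE or FALSE.
#' @export
setGeneric("sameGrid", function(x, y) standardGeneric("sameGrid"))

#' Net water uptake of a measurement, in percent
#' @param x An [NWUResult-class].
#' @return NWU in percent.
#' @export
setGeneric("nwuPercent", function(x) standardGeneric("nwuPercent"))
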