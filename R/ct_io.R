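#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI-1 image, validates the header geometry and returns a
#' [CTVolume-class] in the canonical RAS orientation, so that the first axis
#' runs left to right, the second posterior to anterior and the third
#' inferior to superior. HU values are clamped to \[-1024, 3071\] on load to
#' remove scanner padding values. The source orientation is remembered and
#' restored by [writeVolume()].
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [CTVolume-class].
#' @examples
#' spec <- phantomSpec(shape = c(32L, 32L, 24L), spacing = c(4, 4, 4),
#'                     infarct_volume_ml = 4)
#' ph <- makePhantom(spec)
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ph@ncct, f)
#' vol <- readCTVolume(f)
#' @export
readCTVolume <- function(path) {
  img <- .readNiftiChecked(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  }
  native <- RNifti::orientation(img)
  img <- .canonicalise(img)
  pd <- RNifti::pixdim(img)
  vox <- array(as.numeric(img), dim = dim(img))
  .ctVolume(vox,
    spacing = pd, origin = .niftiOrigin(img),
    nativeOrientation = native
  )
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel counts as inside. The mask must match the geometry of
#' the reference grid (same dimensions; spacing and origin within tolerance).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param grid The reference [CTVolume-class] the mask indexes.
#' @return A [VoxelMask-class] on `grid`'s geometry.
#' @export
readMask <- function(path, grid) {
  stopifnot(is(grid, "CTVolume"))
  img <- .readNiftiChecked(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D mask, got ", length(dim(img)), " dimensions in ", path)
  }
  img <- .canonicalise(img)
  m <- .voxelMask(array(img != 0, dim = dim(img)),
    spacing = RNifti::pixdim(img), origin = .niftiOrigin(img)
  )
  if (!sameGrid(m, grid)) {
    stop(
      "mask geometry mismatch with reference grid: mask is ",
      paste(dim(m@voxels), collapse = "x"), " at ",
      paste(signif(m@spacing, 4), collapse = "x"), " mm, grid is ",
      paste(dim(grid@voxels), collapse = "x"), " at ",
      paste(signif(grid@spacing, 4), collapse = "x"), " mm"
    )
  }
  m
}

#' Write a volume or mask to NIfTI
#'
#' Geometry (spacing, origin) is preserved; volumes read from disk are
#' written back in their native orientation. Masks are written as uint8.
#'
#' @param x A [CTVolume-class] or [VoxelMask-class].
#' @param path Destination `.nii` or `.nii.gz` path; the parent directory
#'   must exist.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(x, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  if (is(x, "CTVolume")) {
    arr <- x@voxels
    native <- x@nativeOrientation
    datatype <- "float"
  } else if (is(x, "VoxelMask")) {
    arr <- array(as.integer(x@voxels), dim = dim(x@voxels))
    native <- "RAS"
    datatype <- "uint8"
  } else {
    stop("can only write CTVolume or VoxelMask objects")
  }
  img <- RNifti::asNifti(arr)
  xf <- diag(c(spacing(x), 1))
  xf[1:3, 4L] <- origin(x)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::pixdim(img) <- spacing(x)
  if (!identical(native, "RAS")) {
    RNifti::orientation(img) <- native
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# -- internal ----------------------------------------------------------------

# Raw NIfTI-1 header pixdim, read directly from the file: the nifti library
# silently repairs non-positive spacings on load, but a scan whose header
# lacks voxel geometry must be rejected, not repaired.
.rawPixdim <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 120L)
  if (length(hdr) < 120L) return(NULL)
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1L, 4L, endian = "little") != 348L) {
    if (readBin(hdr[1:4], "integer", 1L, 4L, endian = "big") != 348L) {
      return(NULL)  # not a NIfTI-1 header; leave validation to the parser
    }
    endian <- "big"
  }
  ndim <- readBin(hdr[41:42], "integer", 1L, 2L, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", 8L, 4L, endian = endian)
  list(ndim = ndim, pixdim = pixdim[-1L])  # drop qfac
}

.readNiftiChecked <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- .rawPixdim(path)
  if (!is.null(raw)) {
    nspatial <- min(3L, raw$ndim)
    pd <- raw$pixdim[seq_len(nspatial)]
    if (any(!is.finite(pd)) || any(pd <= 0)) {
      bad <- which(!is.finite(pd) | pd <= 0)
      stop(
        "invalid voxel spacing in NIfTI header of ", path,
        ": pixdim[", paste(bad, collapse = ","),
        "] is missing or non-positive"
      )
    }
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (any(!is.finite(pd)) || any(pd <= 0)) {
    stop(
      "invalid voxel spacing in NIfTI header of ", path,
      ": pixdim is missing or non-positive"
    )
  }
  img
}

# Reorient to RAS when the header carries an xform; images without any
# qform/sform are taken as already RAS (with a warning), since there is no
# information to reorient by.
.canonicalise <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L) {
    warning("image has no qform/sform; assuming it is already in RAS")
    return(img)
  }
  if (!identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  img
}

.niftiOrigin <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L) {
    return(c(0, 0, 0))
  }
  as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
}
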