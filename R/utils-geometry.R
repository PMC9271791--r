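# Low-level grid geometry helpers shared by all modules.
#
# Conventions: voxel (i, j, k) has its *center* at the physical point
#   world = origin + (index - 1) * spacing      (mm, canonical RAS axes)
# so indexing is 1-based in R but the first voxel center sits exactly at
# `origin`. All sampling below works in continuous 1-based voxel coordinates.

# world <-> voxel coordinate conversion for axis-aligned canonical grids
.worldToVoxel <- function(p, spacing, origin) {
  p <- matrix(p, ncol = 3)
  sweep(sweep(p, 2, origin, "-"), 2, spacing, "/") + 1
}

.voxelToWorld <- function(v, spacing, origin) {
  v <- matrix(v, ncol = 3)
  sweep(sweep(v - 1, 2, spacing, "*"), 2, origin, "+")
}

# physical center of the grid (mm)
.gridCenter <- function(dim, spacing, origin) {
  origin + (dim - 1) / 2 * spacing
}

# N x 3 matrix of voxel-center world coordinates for linear indices `lin`
.linearToWorld <- function(lin, dim, spacing, origin) {
  .voxelToWorld(arrayInd(lin, dim), spacing, origin)
}

# Trilinear interpolation of 3D array `a` at continuous voxel coords `v`
# (N x 3, 1-based). Points outside the grid return `fill`.
.trilinear <- function(a, v, fill = NA_real_) {
  d <- dim(a)
  x <- v[, 1L]; y <- v[, 2L]; z <- v[, 3L]
  inside <- x >= 1 & x <= d[1L] & y >= 1 & y <= d[2L] & z >= 1 & z <= d[3L]
  out <- rep.int(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1L] - 1L); y0 <- pmin(floor(y), d[2L] - 1L)
  z0 <- pmin(floor(z), d[3L] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1L]; n12 <- d[1L] * d[2L]
  base <- (x0 - 1) + (y0 - 1) * n1 + (z0 - 1) * n12
  v000 <- a[base + 1]
  v100 <- a[base + 2]
  v010 <- a[base + 1 + n1]
  v110 <- a[base + 2 + n1]
  v001 <- a[base + 1 + n12]
  v101 <- a[base + 2 + n12]
  v011 <- a[base + 1 + n1 + n12]
  v111 <- a[base + 2 + n1 + n12]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Nearest-neighbour sampling; preserves binarity for masks.
.nearest <- function(a, v, fill = 0) {
  d <- dim(a)
  i <- round(v[, 1L]); j <- round(v[, 2L]); k <- round(v[, 3L])
  inside <- i >= 1 & i <= d[1L] & j >= 1 & j <= d[2L] & k >= 1 & k <= d[3L]
  out <- rep.int(fill, nrow(v))
  lin <- (i[inside] - 1) + (j[inside] - 1) * d[1L] +
    (k[inside] - 1) * d[1L] * d[2L] + 1
  out[inside] <- a[lin]
  out
}

# Elementary rotation matrices (degrees, right-handed about canonical axes).
.rotX <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
.rotY <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
.rotZ <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Combined Euler rotation R = Rz %*% Ry %*% Rx (degrees)
.eulerRotation <- function(rx, ry, rz) .rotZ(rz) %*% .rotY(ry) %*% .rotX(rx)

# Reflect world points P (N x 3) across the plane through `point` with unit
# `normal`: p' = p - 2 ((p - point) . n) n
.reflectPoints <- function(P, point, normal) {
  s <- (P[, 1L] - point[1L]) * normal[1L] +
    (P[, 2L] - point[2L]) * normal[2L] +
    (P[, 3L] - point[3L]) * normal[3L]
  P - 2 * outer(s, normal)
}

# Signed distance of world points to a plane (mm); positive on the side the
# normal points to.
.planeDistance <- function(P, point, normal) {
  (P[, 1L] - point[1L]) * normal[1L] +
    (P[, 2L] - point[2L]) * normal[2L] +
    (P[, 3L] - point[3L]) * normal[3L]
}

# Resample array `a` (grid: spacingA/originA) at the voxel centers of the
# target grid after mapping target world points through `mapFun`
# (world -> world). Used for head rotation and rigid resampling.
.resampleArray <- function(a, spacingA, originA, dimT, spacingT, originT,
                           mapFun = identity, method = c("linear", "nearest"),
                           fill = 0) {
  method <- match.arg(method)
  W <- .voxelToWorld(arrayInd(seq_len(prod(dimT)), dimT), spacingT, originT)
  W <- mapFun(W)
  V <- .worldToVoxel(W, spacingA, originA)
  vals <- if (method == "linear") .trilinear(a, V, fill = fill)
  else .nearest(a, V, fill = fill)
  array(vals, dim = dimT)
}
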