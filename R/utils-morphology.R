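# 3D binary morphology and smoothing primitives.
#
# Structuring element for erosion/dilation is the 6-connected cross (the
# digital ball of radius 1); radius > 1 is obtained by iteration. Connected
# component labelling supports 6/18/26 connectivity and is built on an
# adjacency graph of the foreground voxels.

# Shift a 3D array by k voxels along dimension d, padding with `fill`
# ("replicate" pads with the edge slab instead).
.shiftArray <- function(a, d, k, fill = 0) {
  if (k == 0L) return(a)
  dm <- dim(a)
  n <- dm[d]
  if (abs(k) >= n) {
    if (identical(fill, "replicate")) stop("shift exceeds extent")
    return(array(fill, dim = dm))
  }
  src <- if (k > 0L) seq_len(n - k) else seq.int(1L - k, n)
  pad <- if (identical(fill, "replicate")) {
    rep.int(if (k > 0L) 1L else n, abs(k))
  } else NULL
  idx <- vector("list", 3L)
  for (i in 1:3) idx[[i]] <- seq_len(dm[i])
  if (is.null(pad)) {
    out <- array(fill, dim = dm)
    dst <- if (k > 0L) seq.int(1L + k, n) else seq_len(n + k)
    idxd <- idx; idxd[[d]] <- dst
    idxs <- idx; idxs[[d]] <- src
    out[idxd[[1L]], idxd[[2L]], idxd[[3L]]] <-
      a[idxs[[1L]], idxs[[2L]], idxs[[3L]]]
    out
  } else {
    ord <- if (k > 0L) c(pad, src) else c(src, pad)
    idx[[d]] <- ord
    a[idx[[1L]], idx[[2L]], idx[[3L]]]
  }
}

.dilate1 <- function(m) {
  out <- m
  for (d in 1:3) {
    out <- out | .shiftArray(m, d, 1L, FALSE) | .shiftArray(m, d, -1L, FALSE)
  }
  out
}

.erode1 <- function(m) {
  out <- m
  for (d in 1:3) {
    out <- out & .shiftArray(m, d, 1L, TRUE) & .shiftArray(m, d, -1L, TRUE)
  }
  out
}

.dilateBall <- function(m, r = 1L) {
  for (i in seq_len(r)) m <- .dilate1(m)
  m
}

.erodeBall <- function(m, r = 1L) {
  for (i in seq_len(r)) m <- .erode1(m)
  m
}

.opening <- function(m, r = 1L) .dilateBall(.erodeBall(m, r), r)
.closing <- function(m, r = 1L) .erodeBall(.dilateBall(m, r), r)

# Separable Gaussian smoothing; sigma in voxels per axis (length 1 or 3).
# Edge handling replicates border slabs, which preserves flat regions.
.gaussSmooth <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (d in 1:3) {
    s <- sigma[d]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq.int(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (i in seq.int(-r, r)) {
      acc <- acc + w[i + r + 1L] * .shiftArray(a, d, i, "replicate")
    }
    a <- acc
  }
  a
}

# Block-mean downsampling by an integer factor per axis (the first
# floor(d/ds)*ds voxels are used). Emulates the coarser point-spread of a
# lower-resolution acquisition.
.blockMean <- function(a, ds) {
  d <- dim(a)
  n <- d %/% ds
  a <- a[seq_len(n[1L] * ds), seq_len(n[2L] * ds), seq_len(n[3L] * ds)]
  storage.mode(a) <- "double"
  dim(a) <- c(ds, n[1L], ds, n[2L], ds, n[3L])
  a <- colMeans(a, dims = 1L)                  # (nx, ds, ny, ds, nz)
  a <- colMeans(aperm(a, c(2L, 1L, 3L, 4L, 5L)), dims = 1L)  # (nx, ny, ds, nz)
  a <- colMeans(aperm(a, c(3L, 1L, 2L, 4L)), dims = 1L)      # (nx, ny, nz)
  a
}

# Neighbour offsets (as index triplet deltas) for a connectivity class,
# restricted to the lexicographically positive half so each undirected
# adjacency is enumerated once.
.halfOffsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1L] == 0 & off[, 2L] == 0 & off[, 3L] == 0), , drop = FALSE]
  ord <- abs(off[, 1L]) + abs(off[, 2L]) + abs(off[, 3L])
  keep <- switch(as.character(connectivity),
    "6" = ord == 1L, "18" = ord <= 2L, "26" = rep(TRUE, nrow(off)),
    stop("connectivity must be 6, 18 or 26")
  )
  off <- off[keep, , drop = FALSE]
  pos <- off[, 3L] > 0 | (off[, 3L] == 0 & off[, 2L] > 0) |
    (off[, 3L] == 0 & off[, 2L] == 0 & off[, 1L] > 0)
  off[pos, , drop = FALSE]
}

# Label foreground of a logical 3D array. Returns list(labels = integer array
# with 0 background, sizes = voxel count per label, indices = list of linear
# index vectors per label). Labels are ordered by first (lowest) linear index.
.labelComponents <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  fg <- which(mask)
  labels <- array(0L, dim = dm)
  if (length(fg) == 0L) {
    return(list(labels = labels, sizes = integer(0), indices = list()))
  }
  ai <- arrayInd(fg, dm)
  off <- .halfOffsets(connectivity)
  n1 <- dm[1L]; n12 <- dm[1L] * dm[2L]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    dx <- off[r, 1L]; dy <- off[r, 2L]; dz <- off[r, 3L]
    ok <- ai[, 1L] + dx >= 1L & ai[, 1L] + dx <= dm[1L] &
      ai[, 2L] + dy >= 1L & ai[, 2L] + dy <= dm[2L] &
      ai[, 3L] + dz >= 1L & ai[, 3L] + dz <= dm[3L]
    nb <- fg[ok] + dx + dy * n1 + dz * n12
    j <- match(nb, fg)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  # reorder labels by first occurrence so numbering is deterministic
  first <- match(seq_len(comp$no), memb)
  ord <- order(fg[first])
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  memb <- relabel[memb]
  labels[fg] <- memb
  sizes <- tabulate(memb, comp$no)
  indices <- split(fg, memb)
  list(labels = labels, sizes = sizes, indices = indices)
}
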