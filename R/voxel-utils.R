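#' Construct a voxel stack
#'
#' A `voxel_stack` bundles a 3D scalar array with its isotropic voxel edge
#' length. Arrays are indexed `[z, y, x]` (slice, row, column), 1-based, so
#' `data[i, , ]` is the i-th section of the stack.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, all >= 1.
#' @param voxel_size_um positive scalar, isotropic voxel edge length in
#'   micrometres. The tomographic datasets this package targets use
#'   1.48 um voxels; phantoms may use any size.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1L))
    stop("all three stack dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_stack> %d x %d x %d voxels (z,y,x), %.4g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size_um))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$data)

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(voxel_size_um) voxel_size_um^3 * 1e-9

# Vectorised BFS flood fill on a 3D logical array under 6-connectivity.
# Returns a logical array marking the connected component containing any of
# `seed_idx` (linear indices). Seeds falling outside `mask` are ignored.
flood_fill6 <- function(mask, seed_idx) {
  d <- dim(mask)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  nzy <- nz * ny
  visited <- logical(length(mask))
  frontier <- as.integer(seed_idx)
  frontier <- frontier[mask[frontier]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    i0 <- frontier - 1L
    z <- i0 %% nz
    y <- (i0 %/% nz) %% ny
    x <- i0 %/% nzy
    nb <- c(frontier[z > 0L] - 1L,
            frontier[z < nz - 1L] + 1L,
            frontier[y > 0L] - nz,
            frontier[y < ny - 1L] + nz,
            frontier[x > 0L] - nzy,
            frontier[x < nx - 1L] + nzy)
    nb <- unique(nb)
    nb <- nb[!visited[nb]]
    nb <- nb[mask[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dim = d)
}

# Number of 6-connected components of a 3D logical array.
count_components6 <- function(mask) {
  remaining <- mask
  n <- 0L
  repeat {
    seed <- which(remaining)
    if (!length(seed)) break
    comp <- flood_fill6(remaining, seed[1L])
    remaining <- remaining & !comp
    n <- n + 1L
  }
  n
}

# Linear index from (z, y, x) triples (rows of a matrix or a length-3 vector).
vox_index <- function(zyx, dims) {
  if (is.null(dim(zyx))) zyx <- matrix(zyx, nrow = 1L)
  stopifnot(ncol(zyx) == 3L)
  if (any(zyx < 1L) || any(t(zyx) > dims))
    stop("voxel coordinates out of bounds")
  as.integer(zyx[, 1L] + (zyx[, 2L] - 1L) * dims[1L] +
               (zyx[, 3L] - 1L) * dims[1L] * dims[2L])
}

# Linear indices of voxels whose centres lie within `radius_vox` of
# `center_vox` (both in voxel units, centre may be fractional).
sphere_voxels <- function(center_vox, radius_vox, dims) {
  lo <- pmax(1L, floor(center_vox - radius_vox))
  hi <- pmin(dims, ceiling(center_vox + radius_vox))
  if (any(lo > hi)) return(integer(0))
  z <- seq.int(lo[1L], hi[1L]); y <- seq.int(lo[2L], hi[2L])
  x <- seq.int(lo[3L], hi[3L])
  dz2 <- (z - center_vox[1L])^2
  dy2 <- (y - center_vox[2L])^2
  dx2 <- (x - center_vox[3L])^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= radius_vox^2
  sub <- which(inside, arr.ind = TRUE)
  if (!nrow(sub)) return(integer(0))
  zyx <- cbind(z[sub[, 1L]], y[sub[, 2L]], x[sub[, 3L]])
  vox_index(zyx, dims)
}

# Linear indices of voxels whose centres lie within `radius_vox` of the
# segment a--b (capsule), a/b in (z,y,x) voxel units.
capsule_voxels <- function(a, b, radius_vox, dims) {
  lo <- pmax(1L, floor(pmin(a, b) - radius_vox))
  hi <- pmin(dims, ceiling(pmax(a, b) + radius_vox))
  if (any(lo > hi)) return(integer(0))
  z <- seq.int(lo[1L], hi[1L]); y <- seq.int(lo[2L], hi[2L])
  x <- seq.int(lo[3L], hi[3L])
  g <- as.matrix(expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE))
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(g, 2L, a)
  t <- if (len2 > 0) pmin(1, pmax(0, as.vector(rel %*% ab) / len2)) else 0
  proj <- outer(t, ab) + matrix(a, nrow(g), 3L, byrow = TRUE)
  d2 <- rowSums((g - proj)^2)
  keep <- d2 <= radius_vox^2
  if (!any(keep)) return(integer(0))
  vox_index(g[keep, , drop = FALSE], dims)
}
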