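#' Voxel grid geometry
#'
#' A `dmn_grid` describes the common acquisition grid every run of a cohort
#' lives on: integer dimensions, isotropic voxel size in mm, and the world
#' (scanner/MNI-like) coordinate of the centre of voxel `(1,1,1)`.  All
#' voxel indices in the package are 1-based; world coordinates are mm with a
#' plain scaled-translation (RAS) affine.
#'
#' @param dims integer vector of length 3, voxels per axis.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param origin_mm world coordinate (mm) of the centre of voxel `(1,1,1)`.
#' @return An object of class `dmn_grid`.
#' @export
make_grid <- function(dims, voxel_mm = 3, origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_mm > 0,
            length(origin_mm) == 3L)
  structure(list(dims = dims, voxel_mm = as.numeric(voxel_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "dmn_grid")
}

#' @export
print.dmn_grid <- function(x, ...) {
  cat(sprintf("<dmn_grid %dx%dx%d @ %g mm, origin (%g, %g, %g) mm>\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a `dmn_grid`.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Convert between linear voxel indices, (i,j,k) triplets and world mm
#'
#' Linear indices follow R's column-major array order (x fastest).
#'
#' @param grid a `dmn_grid`.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @param idx integer vector of linear voxel indices.
#' @return `voxel_to_mm` returns an n x 3 matrix of mm coordinates;
#'   `ijk_to_index` / `index_to_ijk` convert representations.
#' @export
ijk_to_index <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  d <- grid$dims
  stopifnot(all(ijk >= 1L), all(ijk[, 1] <= d[1]), all(ijk[, 2] <= d[2]),
            all(ijk[, 3] <= d[3]))
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] - 1L) + d[1] * d[2] * (ijk[, 3] - 1L))
}

#' @rdname ijk_to_index
#' @export
index_to_ijk <- function(grid, idx) {
  d <- grid$dims
  idx0 <- as.integer(idx) - 1L
  k <- idx0 %/% (d[1] * d[2])
  j <- (idx0 - k * d[1] * d[2]) %/% d[1]
  i <- idx0 - k * d[1] * d[2] - j * d[1]
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

#' @rdname ijk_to_index
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep((ijk - 1) * grid$voxel_mm, 2L, grid$origin_mm, "+")
}

#' @rdname ijk_to_index
#' @param mm numeric matrix (n x 3) of world coordinates.
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  sweep(mm, 2L, grid$origin_mm, "-") / grid$voxel_mm + 1
}

#' 4x4 RAS affine of a grid (for NIfTI export)
#' @param grid a `dmn_grid`.
#' @return a 4x4 matrix mapping 0-based voxel indices to mm.
#' @export
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_mm, 3), 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' Voxels of an axis-aligned block
#'
#' @param grid a `dmn_grid`.
#' @param corner 1-based (i,j,k) of the block's low corner.
#' @param size block edge lengths in voxels (scalar or length 3).
#' @return integer vector of linear voxel indices.
#' @export
block_voxels <- function(grid, corner, size) {
  size <- rep(as.integer(size), length.out = 3L)
  corner <- as.integer(corner)
  stopifnot(all(corner >= 1L), all(corner + size - 1L <= grid$dims))
  ijk <- as.matrix(expand.grid(i = corner[1]:(corner[1] + size[1] - 1L),
                               j = corner[2]:(corner[2] + size[2] - 1L),
                               k = corner[3]:(corner[3] + size[3] - 1L)))
  sort(ijk_to_index(grid, ijk))
}

#' Voxels whose centres fall within a sphere
#'
#' Brute-force enumeration over the bounding box; exact for any radius.
#'
#' @param grid a `dmn_grid`.
#' @param center_mm sphere centre in world mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @return integer vector of linear voxel indices (possibly empty).
#' @export
sphere_voxels <- function(grid, center_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  cv <- mm_to_voxel(grid, matrix(center_mm, 1L))
  r_vox <- radius_mm / grid$voxel_mm
  lo <- pmax(1L, floor(cv - r_vox))
  hi <- pmin(grid$dims, ceiling(cv + r_vox))
  if (any(lo > hi)) return(integer(0))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  mm <- voxel_to_mm(grid, ijk)
  d2 <- rowSums(sweep(mm, 2L, as.numeric(center_mm), "-")^2)
  sort(ijk_to_index(grid, ijk[d2 <= radius_mm^2, , drop = FALSE]))
}

#' Neighbourhood offsets for 3D connectivity
#' @param connectivity 6 (face) or 26 (face+edge+vertex) adjacency.
#' @return integer matrix (m x 3) of ijk offsets.
#' @keywords internal
neighbour_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  unname(off)
}
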