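#' Define an isotropic image grid
#'
#' A grid is the common sampling lattice of the phantom, the reconstructed
#' frames and all masks: a (possibly anisotropic in count, always isotropic in
#' spacing) 3D voxel lattice. Voxel coordinates are 0-based indices; physical
#' coordinates place the grid centre at index `(n - 1) / 2` on every axis, and
#' the midsagittal mirror plane is that central plane of axis 1 (left-right).
#'
#' @param n Matrix size per axis, a single integer or a length-3 integer
#'   vector. Must be at least 8 per axis.
#' @param voxel_mm Isotropic voxel edge length in mm. The default 7.5 mm is
#'   the nominal resolution of the dynamic 17O protocol.
#' @return An object of class `grid_spec` with elements `n`, `voxel_mm` and
#'   `fov_mm` (field of view, `n * voxel_mm`).
#' @examples
#' g <- grid_spec(32, 7.5)
#' g$fov_mm
#' @export
grid_spec <- function(n = 32, voxel_mm = 7.5) {
  if (length(n) == 1) n <- rep(n, 3)
  n <- as.integer(n)
  if (length(n) != 3 || any(is.na(n)) || any(n < 8))
    stop("matrix size must be >= 8 per axis")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1 || voxel_mm <= 0)
    stop("voxel size must be a single positive number")
  structure(list(n = n, voxel_mm = voxel_mm, fov_mm = n * voxel_mm),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %g mm (FOV %g x %g x %g mm)\n",
              x$n[1], x$n[2], x$n[3], x$voxel_mm,
              x$fov_mm[1], x$fov_mm[2], x$fov_mm[3]))
  invisible(x)
}

# Centre-relative voxel coordinates along one axis, in voxel units.
axis_coords <- function(grid, axis) {
  n <- grid$n[axis]
  seq_len(n) - 1 - (n - 1) / 2
}

# m x 3 matrix of centre-relative voxel coordinates for the voxels where
# `mask` is TRUE (or for all voxels when mask is NULL), in voxel units.
grid_coords <- function(grid, mask = NULL) {
  n <- grid$n
  idx <- if (is.null(mask)) seq_len(prod(n)) else which(mask)
  i <- (idx - 1) %% n[1]
  j <- ((idx - 1) %/% n[1]) %% n[2]
  k <- (idx - 1) %/% (n[1] * n[2])
  cbind(i - (n[1] - 1) / 2, j - (n[2] - 1) / 2, k - (n[3] - 1) / 2)
}

same_grid <- function(a, b) {
  all(a$n == b$n) && isTRUE(all.equal(a$voxel_mm, b$voxel_mm))
}
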