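#' Regular voxel grid
#'
#' Describes the discretization of the tissue domain: a regular 3D lattice of
#' voxels with physical spacing in millimetres. World coordinates are in mm,
#' axes aligned with the voxel axes; `origin_mm` is the world coordinate of
#' the *center* of the first voxel (R index `[1, 1, 1]`, i.e. 0-based voxel
#' `(0, 0, 0)`).
#'
#' @param shape integer vector of length 3, voxels per axis; each `>= 3` so a
#'   7-point Laplacian stencil fits.
#' @param spacing_mm positive numeric vector of length 3, voxel edge lengths
#'   in mm (a scalar is recycled).
#' @param origin_mm numeric vector of length 3, world position (mm) of the
#'   first voxel center.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(32, 32, 32), spacing_mm = 1)
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(shape, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 3L))
    stop("'shape' must be 3 integers, each >= 3 (room for a Laplacian stencil)")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive finite numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite numbers")
  structure(list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing_mm), collapse = " x "),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param grid a [voxel_grid()].
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing_mm)

#' World coordinates of voxel centers along each axis
#'
#' @param grid a [voxel_grid()].
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin_mm[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing_mm[1],
       y = grid$origin_mm[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing_mm[2],
       z = grid$origin_mm[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing_mm[3])
}

#' Per-voxel world coordinates as three arrays
#'
#' @param grid a [voxel_grid()].
#' @return list of three arrays (`x`, `y`, `z`), each of dimension
#'   `grid$shape`, holding the world coordinate (mm) of every voxel center.
#' @export
grid_coordinates <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$shape
  list(x = array(rep(ax$x, times = n[2] * n[3]), dim = n),
       y = array(rep(rep(ax$y, each = n[1]), times = n[3]), dim = n),
       z = array(rep(ax$z, each = n[1] * n[2]), dim = n))
}

#' Convert world coordinates (mm) to fractional R voxel indices
#' @param grid a [voxel_grid()].
#' @param points numeric matrix (n x 3) or vector of length 3, world mm.
#' @return matrix (n x 3) of 1-based fractional indices.
#' @export
world_to_index <- function(grid, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  sweep(sweep(p, 2, grid$origin_mm, "-"), 2, grid$spacing_mm, "/") + 1
}

#' Test whether world points fall inside the grid extent
#' @inheritParams world_to_index
#' @return logical vector.
#' @export
points_in_grid <- function(grid, points) {
  idx <- world_to_index(grid, points)
  ok <- rep(TRUE, nrow(idx))
  for (a in 1:3) ok <- ok & idx[, a] >= 0.5 & idx[, a] <= grid$shape[a] + 0.5
  ok
}

#' Compare two grids for geometric equality
#' @param g1,g2 [voxel_grid()] objects.
#' @param tol_mm tolerance on spacing and origin, mm.
#' @return logical scalar.
#' @export
grids_equal <- function(g1, g2, tol_mm = 1e-6) {
  identical(g1$shape, g2$shape) &&
    all(abs(g1$spacing_mm - g2$spacing_mm) < tol_mm) &&
    all(abs(g1$origin_mm - g2$origin_mm) < tol_mm)
}

format_grid <- function(g) {
  sprintf("shape (%s), spacing (%s) mm, origin (%s) mm",
          paste(g$shape, collapse = ", "),
          paste(format(g$spacing_mm, digits = 8), collapse = ", "),
          paste(format(g$origin_mm, digits = 8), collapse = ", "))
}
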