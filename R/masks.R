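#' Binary volumetric mask on a voxel grid
#'
#' Wraps a logical 3D array with its grid geometry and a semantic label
#' (simulated zone `sigma`, reference zone `s`, `tumor`, `kidney`,
#' `iceball`, or any other tag).
#'
#' @param voxels logical (or coercible) array with the grid's shape.
#' @param grid a [voxel_grid()].
#' @param label character tag.
#' @return An object of class `ablation_mask`.
#' @export
ablation_mask <- function(voxels, grid, label = "mask") {
  v <- array(as.logical(voxels) & !is.na(voxels), dim = dim(voxels))
  if (!identical(dim(v), as.integer(grid$shape)))
    stop("mask shape does not match the grid")
  structure(list(grid = grid, voxels = v, label = as.character(label)),
            class = "ablation_mask")
}

#' @export
print.ablation_mask <- function(x, ...) {
  cat(sprintf("<ablation_mask> '%s': %d voxels, %.2f cm^3 on %s\n", x$label,
              sum(x$voxels), volume_cm3(x), format_grid(x$grid)))
  invisible(x)
}

#' Mask volume in cm^3
#' @param mask an [ablation_mask()].
#' @return scalar volume, cm^3 (voxel count times voxel volume).
#' @export
volume_cm3 <- function(mask) sum(mask$voxels) * voxel_volume_mm3(mask$grid) / 1000

#' Face-connected boundary of a mask
#'
#' A mask voxel is a boundary voxel when at least one of its 6 face
#' neighbours is outside the mask (voxels beyond the grid edge count as
#' outside).
#'
#' @param mask an [ablation_mask()].
#' @return logical array flagging boundary voxels.
#' @export
mask_boundary <- function(mask) {
  v <- mask$voxels
  n <- dim(v)
  all_in <- array(TRUE, dim = n)
  # neighbour-inside test per axis; out-of-grid neighbours are outside
  inb <- array(FALSE, dim = n); inb[1:(n[1] - 1), , ] <- v[2:n[1], , , drop = FALSE]
  all_in <- all_in & inb
  inb <- array(FALSE, dim = n); inb[2:n[1], , ] <- v[1:(n[1] - 1), , , drop = FALSE]
  all_in <- all_in & inb
  inb <- array(FALSE, dim = n); inb[, 1:(n[2] - 1), ] <- v[, 2:n[2], , drop = FALSE]
  all_in <- all_in & inb
  inb <- array(FALSE, dim = n); inb[, 2:n[2], ] <- v[, 1:(n[2] - 1), , drop = FALSE]
  all_in <- all_in & inb
  inb <- array(FALSE, dim = n); inb[, , 1:(n[3] - 1)] <- v[, , 2:n[3], drop = FALSE]
  all_in <- all_in & inb
  inb <- array(FALSE, dim = n); inb[, , 2:n[3]] <- v[, , 1:(n[3] - 1), drop = FALSE]
  all_in <- all_in & inb
  v & !all_in
}

#' World coordinates (mm) of the centers of a set of voxels
#' @param grid a [voxel_grid()].
#' @param which_voxels logical array (grid shape) or integer linear indices.
#' @return numeric matrix (n x 3), mm.
#' @export
voxel_centers <- function(grid, which_voxels) {
  idx <- if (is.logical(which_voxels)) which(which_voxels) else as.integer(which_voxels)
  ai <- arrayInd(idx, grid$shape)
  sweep(sweep(ai - 1, 2, grid$spacing_mm, "*"), 2, grid$origin_mm, "+")
}

#' Morphological erosion / dilation with the 6-connected cross
#'
#' `erode_mask()` removes boundary voxels; `dilate_mask()` adds face
#' neighbours. One iteration moves the surface by one voxel along each axis;
#' `iterations` applies the operation repeatedly.
#'
#' @param mask an [ablation_mask()].
#' @param iterations non-negative integer.
#' @return an [ablation_mask()].
#' @export
erode_mask <- function(mask, iterations = 1) {
  m <- mask
  for (i in seq_len(iterations)) m$voxels <- m$voxels & !mask_boundary(m)
  m
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iterations = 1) {
  v <- mask$voxels
  n <- dim(v)
  for (i in seq_len(iterations)) {
    grow <- v
    grow[1:(n[1] - 1), , ] <- grow[1:(n[1] - 1), , , drop = FALSE] | v[2:n[1], , , drop = FALSE]
    grow[2:n[1], , ] <- grow[2:n[1], , , drop = FALSE] | v[1:(n[1] - 1), , , drop = FALSE]
    grow[, 1:(n[2] - 1), ] <- grow[, 1:(n[2] - 1), , drop = FALSE] | v[, 2:n[2], , drop = FALSE]
    grow[, 2:n[2], ] <- grow[, 2:n[2], , drop = FALSE] | v[, 1:(n[2] - 1), , drop = FALSE]
    grow[, , 1:(n[3] - 1)] <- grow[, , 1:(n[3] - 1), drop = FALSE] | v[, , 2:n[3], drop = FALSE]
    grow[, , 2:n[3]] <- grow[, , 2:n[3], drop = FALSE] | v[, , 1:(n[3] - 1), drop = FALSE]
    v <- grow
  }
  mask$voxels <- v
  mask
}
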