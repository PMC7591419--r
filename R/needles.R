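#' Cryoprobe needle plan
#'
#' A plan of 1 to 9 cryoprobes. Each needle has a type (`IceSeed` or
#' `IceRod`), a tip position and an orientation in world mm coordinates, an
#' active-tip length and radius, and a freezing power expressed as a fraction
#' of the maximal freezing power. The active tip is the cylinder extending
#' from the tip backwards along the (unit) insertion direction. Directions
#' are normalized by the constructor; geometry defaults come from the
#' configuration (see [default_config()]), not from code.
#'
#' @param type character vector, `"IceSeed"` or `"IceRod"`.
#' @param tip_mm numeric matrix (n x 3) of tip world coordinates, mm (a
#'   length-3 vector for a single needle).
#' @param direction_mm numeric matrix (n x 3) of insertion directions
#'   (tip points along `+direction`); normalized to unit length.
#' @param power_fraction numeric in `(0, 1]`, per needle (recycled).
#' @param active_length_mm,radius_mm optional overrides of the per-type
#'   defaults from `config`.
#' @param config configuration list used for geometry defaults.
#' @return A `needle_plan`: a data frame with columns `type`, `tip_x`,
#'   `tip_y`, `tip_z`, `dir_x`, `dir_y`, `dir_z`, `active_length_mm`,
#'   `radius_mm`, `power_fraction`.
#' @examples
#' needle_plan("IceRod", tip_mm = c(20, 20, 20), direction_mm = c(0, 0, 1))
#' @export
needle_plan <- function(type, tip_mm, direction_mm, power_fraction = 1,
                        active_length_mm = NULL, radius_mm = NULL,
                        config = default_config()) {
  tip <- matrix(as.numeric(tip_mm), ncol = 3)
  dir <- matrix(as.numeric(direction_mm), ncol = 3)
  n <- nrow(tip)
  type <- rep_len(as.character(type), n)
  if (!all(type %in% c("IceSeed", "IceRod")))
    stop("needle 'type' must be \"IceSeed\" or \"IceRod\"")
  if (n < 1L || n > 9L) stop("a needle plan holds between 1 and 9 needles")
  if (nrow(dir) != n) stop("'direction_mm' must have one row per needle")
  nrm <- sqrt(rowSums(dir^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) stop("needle directions must be nonzero")
  dir <- dir / nrm
  power_fraction <- rep_len(as.numeric(power_fraction), n)
  if (any(!is.finite(power_fraction)) || any(power_fraction <= 0) || any(power_fraction > 1))
    stop("'power_fraction' must lie in (0, 1]")
  nd <- config$needle_defaults
  if (is.null(active_length_mm))
    active_length_mm <- ifelse(type == "IceSeed",
                               nd$iceseed_active_length_mm, nd$icerod_active_length_mm)
  if (is.null(radius_mm)) radius_mm <- nd$radius_mm
  active_length_mm <- rep_len(as.numeric(active_length_mm), n)
  radius_mm <- rep_len(as.numeric(radius_mm), n)
  if (any(active_length_mm <= 0) || any(radius_mm <= 0))
    stop("'active_length_mm' and 'radius_mm' must be positive")
  plan <- data.frame(type = type,
                     tip_x = tip[, 1], tip_y = tip[, 2], tip_z = tip[, 3],
                     dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3],
                     active_length_mm = active_length_mm,
                     radius_mm = radius_mm,
                     power_fraction = power_fraction)
  class(plan) <- c("needle_plan", "data.frame")
  plan
}

#' Validate an object as a needle plan
#' @param plan a data frame with `needle_plan` columns.
#' @return the validated `needle_plan` (directions checked to unit norm).
#' @export
as_needle_plan <- function(plan) {
  cols <- c("type", "tip_x", "tip_y", "tip_z", "dir_x", "dir_y", "dir_z",
            "active_length_mm", "radius_mm", "power_fraction")
  if (!is.data.frame(plan) || !all(cols %in% names(plan)))
    stop("a needle plan needs columns: ", paste(cols, collapse = ", "))
  nrm <- sqrt(plan$dir_x^2 + plan$dir_y^2 + plan$dir_z^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop("needle directions must be unit vectors (|norm - 1| <= 1e-6)")
  if (nrow(plan) < 1L || nrow(plan) > 9L)
    stop("a needle plan holds between 1 and 9 needles")
  if (any(plan$power_fraction <= 0) || any(plan$power_fraction > 1))
    stop("'power_fraction' must lie in (0, 1]")
  class(plan) <- unique(c("needle_plan", class(plan)))
  plan
}

#' Rasterize needle active tips onto a grid
#'
#' Marks every voxel whose center lies within the active-tip cylinder of a
#' needle: within `radius_mm` of the segment from the tip back along the
#' insertion direction by `active_length_mm`. Because clinical cryoprobes
#' (17 G, radius 0.735 mm) can be thinner than a voxel, the effective radius
#' is floored at the half-diagonal of a voxel cross-section so a needle
#' always has support on the grid.
#'
#' @param plan a [needle_plan()].
#' @param grid a [voxel_grid()].
#' @return list with one element per needle, each an integer vector of linear
#'   voxel indices.
#' @export
rasterize_needles <- function(plan, grid) {
  plan <- as_needle_plan(plan)
  tips <- as.matrix(plan[, c("tip_x", "tip_y", "tip_z")])
  if (!all(points_in_grid(grid, tips)))
    stop("every needle tip must lie inside the grid")
  co <- grid_coordinates(grid)
  lapply(seq_len(nrow(plan)), function(i) {
    tip <- c(plan$tip_x[i], plan$tip_y[i], plan$tip_z[i])
    u <- c(plan$dir_x[i], plan$dir_y[i], plan$dir_z[i])
    L <- plan$active_length_mm[i]
    # floor at the half-diagonal of a voxel cross-section so an axis passing
    # between voxel centers still gets support
    r_eff <- max(plan$radius_mm[i], 0.5 * sqrt(2) * max(grid$spacing_mm))
    # project voxel centers onto the tip segment [tip - L*u, tip]
    px <- co$x - tip[1]; py <- co$y - tip[2]; pz <- co$z - tip[3]
    t <- px * u[1] + py * u[2] + pz * u[3]       # signed distance along u from tip
    tc <- pmin(pmax(t, -L), 0)                    # clamp to active segment
    d2 <- (px - tc * u[1])^2 + (py - tc * u[2])^2 + (pz - tc * u[3])^2
    which(d2 <= r_eff^2)
  })
}

# Dirichlet conditions for a protocol phase: freezing scales the probe
# surface temperature linearly from body temperature toward T_freeze by the
# power fraction; active thaw imposes T_thaw regardless of power. Where
# needles overlap, the coldest prescription wins.
probe_conditions <- function(plan, grid, mode, props, solver) {
  if (mode == "passive_thaw") return(NULL)
  vox <- rasterize_needles(plan, grid)
  temps <- switch(mode,
    freeze = props$T_body + plan$power_fraction * (solver$T_freeze_C - props$T_body),
    active_thaw = rep(solver$T_thaw_C, nrow(plan)),
    stop("unknown protocol mode: ", mode))
  idx <- unlist(vox, use.names = FALSE)
  val <- rep(temps, lengths(vox))
  o <- order(idx, val)                            # coldest first within voxel
  idx <- idx[o]; val <- val[o]
  keep <- !duplicated(idx)
  list(index = idx[keep], values = val[keep])
}
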