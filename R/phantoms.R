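#' Ellipsoidal phantom mask
#'
#' Voxelizes an axis-aligned ellipsoid: a voxel belongs to the mask when its
#' center satisfies the ellipsoid inequality. At spacings fine relative to
#' the semi-axes the voxelized volume approaches `(4/3) pi a b c`.
#'
#' @param grid a [voxel_grid()].
#' @param center_mm ellipsoid center, world mm (length 3).
#' @param semi_axes_mm positive semi-axes, mm (length 3 or scalar).
#' @param label mask label.
#' @return an [ablation_mask()] (possibly empty if the ellipsoid is smaller
#'   than a voxel).
#' @export
make_ellipsoid_mask <- function(grid, center_mm, semi_axes_mm, label = "mask") {
  if (length(semi_axes_mm) == 1L) semi_axes_mm <- rep(semi_axes_mm, 3L)
  semi_axes_mm <- as.numeric(semi_axes_mm)
  if (length(semi_axes_mm) != 3L || any(!is.finite(semi_axes_mm)) ||
      any(semi_axes_mm <= 0))
    stop("degenerate ellipsoid: semi-axes must be positive")
  ax <- grid_axes(grid)
  lo <- center_mm - semi_axes_mm; hi <- center_mm + semi_axes_mm
  if (any(hi < c(ax$x[1], ax$y[1], ax$z[1]) - grid$spacing_mm / 2) ||
      any(lo > c(max(ax$x), max(ax$y), max(ax$z)) + grid$spacing_mm / 2))
    stop("ellipsoid does not intersect the grid")
  co <- grid_coordinates(grid)
  q <- ((co$x - center_mm[1]) / semi_axes_mm[1])^2 +
       ((co$y - center_mm[2]) / semi_axes_mm[2])^2 +
       ((co$z - center_mm[3]) / semi_axes_mm[3])^2
  ablation_mask(q <= 1, grid, label)
}

#' Construct a mask pair with prescribed volumes and overlap
#'
#' Builds two masks whose voxel-measured volumes and overlap volume each
#' match the request to within one voxel. The construction is deterministic
#' given the seed: a core overlap region is grown voxel-by-voxel around the
#' grid center in increasing-distance order (ties broken by linear index),
#' and each mask is completed by a disjoint appendage grown around a
#' laterally displaced center, so all three voxel counts are hit exactly.
#'
#' @param grid a [voxel_grid()].
#' @param vol_S_cm3,vol_Sigma_cm3,vol_overlap_cm3 requested volumes, cm^3;
#'   `0 <= overlap <= min(vol_S, vol_Sigma)` and each mask at least one
#'   voxel.
#' @param seed integer; jitters the appendage centers reproducibly.
#' @return list with [ablation_mask()] elements `S` and `Sigma`.
#' @export
make_overlap_pair <- function(grid, vol_S_cm3, vol_Sigma_cm3, vol_overlap_cm3,
                              seed = 0) {
  vv <- voxel_volume_mm3(grid) / 1000
  n_S <- round(vol_S_cm3 / vv); n_Sig <- round(vol_Sigma_cm3 / vv)
  n_ov <- round(vol_overlap_cm3 / vv)
  if (n_S < 1 || n_Sig < 1) stop("each mask must contain at least one voxel")
  if (vol_overlap_cm3 < 0 || n_ov > min(n_S, n_Sig))
    stop("infeasible request: overlap exceeds a mask volume")
  ntot <- prod(grid$shape)
  if (n_S + n_Sig - n_ov > ntot)
    stop("infeasible request: volumes exceed the grid")
  rs <- with_seed(seed, stats::runif(6, -0.5, 0.5))
  ax <- grid_axes(grid)
  cgrid <- c(mean(range(ax$x)), mean(range(ax$y)), mean(range(ax$z)))
  co <- grid_coordinates(grid)
  pick_nearest <- function(center, n, excluded) {
    d2 <- (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2
    d2[excluded] <- Inf
    if (n == 0) return(integer(0))
    ord <- order(d2, seq_along(d2))        # deterministic tie-break
    ord[seq_len(n)]
  }
  excluded <- logical(ntot)
  core <- pick_nearest(cgrid, n_ov, excluded)
  excluded[core] <- TRUE
  r_core <- (3 * max(n_ov, 1) * voxel_volume_mm3(grid) / (4 * pi))^(1 / 3)
  cS <- cgrid + c(-0.75 * r_core, 0, 0) + rs[1:3]
  cSig <- cgrid + c(+0.75 * r_core, 0, 0) + rs[4:6]
  s_extra <- pick_nearest(cS, n_S - n_ov, excluded)
  excluded[s_extra] <- TRUE
  sig_extra <- pick_nearest(cSig, n_Sig - n_ov, excluded)
  vS <- logical(ntot); vS[c(core, s_extra)] <- TRUE
  vSig <- logical(ntot); vSig[c(core, sig_extra)] <- TRUE
  list(S = ablation_mask(array(vS, grid$shape), grid, "s"),
       Sigma = ablation_mask(array(vSig, grid$shape), grid, "sigma"))
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a complete synthetic case fixture
#'
#' Writes a self-contained test scenario to a directory: ellipsoidal kidney
#' and tumor masks as NIfTI volumes, a needle plan (needles passing through
#' the tumor centroid, fanned in the x-z plane), and a configuration file.
#' The tumor is checked to lie within the kidney after voxelization, and
#' tumor diameter is capped at 45 mm (the clinical inclusion scale).
#'
#' @param dir output directory (created if needed).
#' @param grid a [voxel_grid()]; default 96 mm cube at 1 mm.
#' @param kidney_center_mm,kidney_semi_axes_mm kidney ellipsoid, mm.
#' @param tumor_center_mm,tumor_semi_axes_mm tumor ellipsoid, mm.
#' @param n_needles number of needles, 2 to 4 by default usage.
#' @param needle_type `"IceSeed"` or `"IceRod"`.
#' @param seed integer; jitters needle placement deterministically.
#' @param config configuration list written alongside the masks.
#' @return invisibly, a list with the written `paths`, the `plan` and the
#'   masks.
#' @export
make_case_fixture <- function(dir,
                              grid = voxel_grid(c(96, 96, 96), 1),
                              kidney_center_mm = c(48, 48, 48),
                              kidney_semi_axes_mm = c(30, 22, 38),
                              tumor_center_mm = c(56, 48, 56),
                              tumor_semi_axes_mm = c(12, 10, 11),
                              n_needles = 3, needle_type = "IceRod",
                              seed = 0, config = default_config()) {
  if (2 * max(tumor_semi_axes_mm) > 45)
    stop("tumor diameter exceeds 4.5 cm")
  kidney <- make_ellipsoid_mask(grid, kidney_center_mm, kidney_semi_axes_mm, "kidney")
  tumor <- make_ellipsoid_mask(grid, tumor_center_mm, tumor_semi_axes_mm, "tumor")
  if (any(tumor$voxels & !kidney$voxels))
    stop("tumor must lie inside the kidney after voxelization")
  jit <- with_seed(seed, matrix(stats::runif(3 * n_needles, -1, 1), ncol = 3))
  # fan needles in the x-z plane through the tumor centroid, entering along -z
  offs <- seq(-1, 1, length.out = n_needles) * 0.5 * tumor_semi_axes_mm[1]
  tips <- cbind(tumor_center_mm[1] + offs + jit[, 1],
                tumor_center_mm[2] + jit[, 2],
                tumor_center_mm[3] + 0.25 * tumor_semi_axes_mm[3] + jit[, 3])
  if (!all(points_in_grid(grid, tips))) stop("needle tips fall outside the grid")
  plan <- needle_plan(needle_type, tips,
                      matrix(rep(c(0, 0, 1), n_needles), ncol = 3, byrow = TRUE),
                      power_fraction = 1, config = config)
  in_tumor <- points_in_grid(grid, tips) &
    tips[, 1] >= tumor_center_mm[1] - tumor_semi_axes_mm[1] &
    tips[, 1] <= tumor_center_mm[1] + tumor_semi_axes_mm[1]
  if (!all(in_tumor))
    warning("some needle tips miss the tumor bounding box")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(kidney = file.path(dir, "kidney.nii.gz"),
                tumor = file.path(dir, "tumor.nii.gz"),
                plan = file.path(dir, "plan.tsv"),
                config = file.path(dir, "config.yaml"))
  write_mask(kidney, paths$kidney)
  write_mask(tumor, paths$tumor)
  write_needle_plan(plan, paths$plan)
  write_config(config, paths$config)
  invisible(list(paths = paths, plan = plan, kidney = kidney, tumor = tumor))
}
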