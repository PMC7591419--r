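#' Lethal-isotherm cell-death update
#'
#' Simple empirical isotherm model for cryogenic cell death: a voxel whose
#' minimum temperature over the whole thermal history has reached the lethal
#' isotherm is considered dead. Death is committed (the field never
#' decreases) and the update is idempotent for a fixed history.
#'
#' @param D dead-cell fraction array in `[0, 1]`.
#' @param T_min per-voxel minimum-temperature history, deg C (same shape).
#' @param T_lethal_C lethal isotherm, deg C; must be sub-freezing (`< 0`).
#' @return updated dead-fraction array.
#' @export
update_death <- function(D, T_min, T_lethal_C) {
  if (T_lethal_C >= 0) stop("the lethal isotherm must be sub-freezing (T_lethal_C < 0)")
  if (!identical(dim(D), dim(T_min)))
    stop("dead-fraction and temperature-history fields have different shapes")
  pmax(D, as.numeric(T_min <= T_lethal_C))
}

#' Extract a thresholded zone as a binary mask
#'
#' Thresholds a scalar field into an [ablation_mask()]. The simulated
#' ablation zone is the `D >= 1` region of the dead-fraction field; the ice
#' ball is the `T_min <= 0` region.
#'
#' @param field numeric array (the grid's shape).
#' @param threshold scalar threshold.
#' @param sense `"le"` (field `<=` threshold) or `"ge"` (field `>=`).
#' @param grid a [voxel_grid()].
#' @param label label for the resulting mask.
#' @return an [ablation_mask()].
#' @export
extract_zone <- function(field, threshold, sense = c("le", "ge"), grid,
                         label = "zone") {
  sense <- match.arg(sense)
  if (any(!is.finite(field))) stop("non-finite values in field")
  v <- if (sense == "le") field <= threshold else field >= threshold
  ablation_mask(v, grid, label)
}

#' Simulated ablation zone and ice ball from a finished run
#'
#' @param result the list returned by [run_protocol()].
#' @return list with masks `sigma` (lethal zone, from the dead-cell field)
#'   and `iceball` (0 deg C isotherm of the minimum-temperature history).
#' @export
ablation_zones <- function(result) {
  grid <- result$state$grid
  list(sigma = extract_zone(result$D, 1, "ge", grid, "sigma"),
       iceball = extract_zone(result$state$T_min, 0, "le", grid, "iceball"))
}

#' Fraction of the tumor covered by a zone
#'
#' @param zone,tumor [ablation_mask()] objects on the same grid.
#' @return `|zone intersect tumor| / |tumor|` in `[0, 1]`.
#' @export
tumor_coverage <- function(zone, tumor) {
  if (!grids_equal(zone$grid, tumor$grid))
    stop("zone and tumor masks live on different grids")
  nt <- sum(tumor$voxels)
  if (nt == 0) stop("tumor mask is empty")
  sum(zone$voxels & tumor$voxels) / nt
}

#' Diameter of the minimal sphere circumscribing a mask
#'
#' Exact smallest enclosing sphere (Welzl's move-to-front algorithm) of the
#' mask's voxel centers, reported as a diameter in cm. Only boundary voxels
#' are fed to the solver: the extreme points of the voxel-center cloud lie on
#' its convex hull, which is a subset of the face-connected boundary.
#'
#' @param mask a non-empty [ablation_mask()].
#' @return diameter in cm.
#' @export
circumscribing_sphere_diameter <- function(mask) {
  if (sum(mask$voxels) == 0) stop("mask is empty")
  pts <- voxel_centers(mask$grid, mask_boundary(mask))
   2 * miniball(pts)$radius / 10
}

#' Smallest enclosing sphere of a 3D point set
#'
#' Welzl's move-to-front algorithm (exact, expected linear time); the sphere
#' is supported by at most 4 points.
#'
#' @param pts numeric matrix (n x 3).
#' @return list with `center` (length 3) and `radius`.
#' @export
miniball <- function(pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  n <- nrow(pts)
  if (n == 0) stop("empty point set")
  ord <- seq_len(n)
  eps <- 1e-10
  # move-to-front over support sets of growing size (recursion depth <= 4)
  mtf <- function(upto, support) {
    b <- sphere_of(support)
    if (nrow(support) == 4L) return(b)
    i <- 1L
    while (i <= upto) {
      p <- pts[ord[i], ]
      if (sqrt(sum((p - b$center)^2)) > b$radius * (1 + eps) + eps) {
        b <- mtf(i - 1L, rbind(support, p))
        if (i > 1L) ord[c(1L, 2:i)] <<- ord[c(i, 1:(i - 1L))]  # move to front
      }
      i <- i + 1L
    }
    b
  }
  mtf(n, pts[integer(0), , drop = FALSE])
}

# Smallest sphere with 0..4 given points on (or within) its boundary:
# enumerate circumspheres of subsets and keep the smallest that encloses all.
sphere_of <- function(P) {
  m <- nrow(P)
  if (m == 0) return(list(center = c(0, 0, 0), radius = 0))
  if (m == 1) return(list(center = P[1, ], radius = 0))
  best <- NULL
  tol <- 1e-9
  consider <- function(center, radius) {
    if (is.null(center)) return()
    d <- sqrt(rowSums(sweep(P, 2, center)^2))
    if (all(d <= radius + tol * (1 + radius)) &&
        (is.null(best) || radius < best$radius))
      best <<- list(center = center, radius = radius)
  }
  idx <- seq_len(m)
  for (i in idx) for (j in idx[idx > i]) {
    c2 <- (P[i, ] + P[j, ]) / 2
    consider(c2, sqrt(sum((P[i, ] - c2)^2)))
  }
  if (m >= 3) for (i in idx) for (j in idx[idx > i]) for (k in idx[idx > j]) {
    cc <- circumcircle3(P[i, ], P[j, ], P[k, ])
    consider(cc$center, cc$radius)
  }
  if (m >= 4) {
    cc <- circumsphere4(P[1, ], P[2, ], P[3, ], P[4, ])
    consider(cc$center, cc$radius)
  }
  if (is.null(best)) stop("degenerate support set in miniball")
  best
}

# circumcenter of 3 points within their plane
circumcircle3 <- function(a, b, c) {
  ab <- b - a; ac <- c - a
  abab <- sum(ab^2); acac <- sum(ac^2); abac <- sum(ab * ac)
  d <- 2 * (abab * acac - abac^2)
  if (abs(d) < 1e-14 * max(abab, acac, 1)) return(list(center = NULL, radius = Inf))
  s <- (acac * (abab - abac)) / d
  t <- (abab * (acac - abac)) / d
  center <- a + s * ab + t * ac
  list(center = center, radius = sqrt(sum((a - center)^2)))
}

# circumsphere of 4 points (equidistance linear system)
circumsphere4 <- function(a, b, c, d) {
  A <- rbind(b - a, c - a, d - a) * 2
  rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2), sum(d^2) - sum(a^2))
  det <- det(A)
  if (abs(det) < 1e-12 * max(abs(A), 1)^3) return(list(center = NULL, radius = Inf))
  center <- solve(A, rhs)
  list(center = center, radius = sqrt(sum((a - center)^2)))
}
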