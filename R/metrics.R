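#' Volumetric overlap metrics between reference and simulated zones
#'
#' For a reference ablation zone `S` and a simulated zone `Sigma`:
#' * `dsc()` — Dice similarity coefficient `2|S n Sigma| / (|S| + |Sigma|)`,
#'   symmetric volumetric agreement in `[0, 1]`;
#' * `target_overlap()` — `|S n Sigma| / |S|` ("sensitivity"); low values
#'   mean the simulation underestimates the real zone;
#' * `ppv()` — positive predictive value `|S n Sigma| / |Sigma|`; low values
#'   mean the simulation overestimates the real zone.
#'
#' @param S,Sigma [ablation_mask()] objects on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(S, Sigma) {
  check_pair(S, Sigma)
  a <- sum(S$voxels); b <- sum(Sigma$voxels)
  if (a + b == 0) stop("both masks are empty")
  2 * sum(S$voxels & Sigma$voxels) / (a + b)
}

#' @rdname dsc
#' @export
target_overlap <- function(S, Sigma) {
  check_pair(S, Sigma)
  a <- sum(S$voxels)
  if (a == 0) stop("reference mask S is empty")
  sum(S$voxels & Sigma$voxels) / a
}

#' @rdname dsc
#' @export
ppv <- function(S, Sigma) {
  check_pair(S, Sigma)
  b <- sum(Sigma$voxels)
  if (b == 0) stop("simulated mask Sigma is empty")
  sum(S$voxels & Sigma$voxels) / b
}

check_pair <- function(S, Sigma) {
  if (!inherits(S, "ablation_mask") || !inherits(Sigma, "ablation_mask"))
    stop("both arguments must be ablation_mask objects")
  if (!grids_equal(S$grid, Sigma$grid))
    stop(sprintf("masks live on different grids:\n  S:     %s\n  Sigma: %s",
                 format_grid(S$grid), format_grid(Sigma$grid)))
  invisible(TRUE)
}

#' Absolute average surface error
#'
#' Symmetric mean surface distance between the boundaries of two masks, in
#' mm: boundary voxels (6-connectivity face boundary, voxel centers as the
#' surface point set) are extracted from both masks; for every point of each
#' surface the Euclidean distance to the nearest point of the other surface
#' is found, and all distances are averaged with weight proportional to the
#' point counts. Zero for identical masks.
#'
#' @param S,Sigma non-empty [ablation_mask()] objects on the same grid.
#' @return mean surface distance, mm.
#' @export
aae <- function(S, Sigma) {
  check_pair(S, Sigma)
  if (sum(S$voxels) == 0 || sum(Sigma$voxels) == 0)
    stop("surface distance requires two non-empty masks")
  ps <- voxel_centers(S$grid, mask_boundary(S))
  pt <- voxel_centers(Sigma$grid, mask_boundary(Sigma))
  d1 <- nearest_distances(ps, pt)
  d2 <- nearest_distances(pt, ps)
  (sum(d1) + sum(d2)) / (length(d1) + length(d2))
}

# for each row of A, distance to the nearest row of B (chunked BLAS)
nearest_distances <- function(A, B, chunk = 2048L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(A))
    Ai <- A[ii, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), nb2, "+") - 2 * tcrossprod(Ai, B)
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Ordinal rating of an overlap metric
#'
#' Maps a metric value in `[0, 1]` to the ordinal quality scale:
#' `excellent` for values `>= 0.8` (including a perfect 1.0), `good` for
#' `[0.7, 0.8)`, `adequate` for `[0.6, 0.7)`, `inadequate` for `[0.5, 0.6)`
#' and `poor` below 0.5.
#'
#' @param value numeric in `[0, 1]` (vectorized).
#' @return ordered factor with levels `poor < inadequate < adequate < good <
#'   excellent`.
#' @export
rate_score <- function(value) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1))
    stop("metric values must lie in [0, 1]")
  lv <- c("poor", "inadequate", "adequate", "good", "excellent")
  out <- cut(value, breaks = c(-Inf, 0.5, 0.6, 0.7, 0.8, Inf),
             labels = lv, right = FALSE)
  factor(out, levels = lv, ordered = TRUE)
}

#' Validation result container
#'
#' @param vol_S_cm3,vol_Sigma_cm3,vol_overlap_cm3 volumes in cm^3.
#' @param aae_mm symmetric mean surface distance in mm, or `NA` when masks
#'   were not available (volumes-only input).
#' @param case optional case identifier.
#' @return object of class `validation_result` with the volumes, `dsc`,
#'   `to`, `ppv`, `aae_mm` and ordinal ratings `rating_dsc`, `rating_to`,
#'   `rating_ppv`.
#' @export
validation_result <- function(vol_S_cm3, vol_Sigma_cm3, vol_overlap_cm3,
                              aae_mm = NA_real_, case = NA_character_) {
  if (vol_S_cm3 <= 0 || vol_Sigma_cm3 <= 0)
    stop("volumes of S and Sigma must be positive")
  if (vol_overlap_cm3 < 0 ||
      vol_overlap_cm3 > min(vol_S_cm3, vol_Sigma_cm3) * (1 + 1e-9))
    stop("overlap volume cannot exceed either mask volume")
  r <- list(case = case,
            vol_S_cm3 = vol_S_cm3, vol_Sigma_cm3 = vol_Sigma_cm3,
            vol_overlap_cm3 = vol_overlap_cm3,
            dsc = 2 * vol_overlap_cm3 / (vol_S_cm3 + vol_Sigma_cm3),
            to = vol_overlap_cm3 / vol_S_cm3,
            ppv = vol_overlap_cm3 / vol_Sigma_cm3,
            aae_mm = aae_mm)
  r$rating_dsc <- rate_score(r$dsc)
  r$rating_to <- rate_score(r$to)
  r$rating_ppv <- rate_score(r$ppv)
  structure(r, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", if (!is.na(x$case)) x$case else "", "\n")
  cat(sprintf("  |S| = %.2f cm^3, |Sigma| = %.2f cm^3, overlap = %.2f cm^3\n",
              x$vol_S_cm3, x$vol_Sigma_cm3, x$vol_overlap_cm3))
  cat(sprintf("  DSC %.2f (%s), TO %.2f (%s), PPV %.2f (%s)\n",
              x$dsc, x$rating_dsc, x$to, x$rating_to, x$ppv, x$rating_ppv))
  if (!is.na(x$aae_mm)) cat(sprintf("  AAE %.2f mm\n", x$aae_mm))
  invisible(x)
}

#' Overlap metrics from volumes alone
#'
#' Computes DSC, target overlap and PPV directly from the three volumes, as
#' printed in case reports, without masks. The surface error is flagged
#' unavailable (`NA`).
#'
#' @inheritParams validation_result
#' @return a [validation_result()].
#' @export
metrics_from_volumes <- function(vol_S_cm3, vol_Sigma_cm3, vol_overlap_cm3,
                                 case = NA_character_) {
  validation_result(vol_S_cm3, vol_Sigma_cm3, vol_overlap_cm3,
                    aae_mm = NA_real_, case = case)
}

#' Full validation of a simulated zone against a reference zone
#'
#' @param S,Sigma non-empty [ablation_mask()] objects on the same grid.
#' @param compute_aae set `FALSE` to skip the surface-distance computation.
#' @param case optional case identifier.
#' @return a [validation_result()].
#' @export
validate_masks <- function(S, Sigma, compute_aae = TRUE, case = NA_character_) {
  check_pair(S, Sigma)
  vv <- voxel_volume_mm3(S$grid) / 1000
  validation_result(sum(S$voxels) * vv, sum(Sigma$voxels) * vv,
                    sum(S$voxels & Sigma$voxels) * vv,
                    aae_mm = if (compute_aae) aae(S, Sigma) else NA_real_,
                    case = case)
}

#' Cohort summary of validation results
#'
#' Means and standard deviations of each metric plus per-rating-bin counts
#' and percentages, over a list of [validation_result()] objects.
#'
#' @param results non-empty list of [validation_result()] objects.
#' @return list of class `cohort_summary` with data frames `stats` (metric,
#'   n, mean, sd) and `ratings` (metric, rating, n, percent).
#' @export
summarize_cohort <- function(results) {
  if (!length(results)) stop("empty result list")
  if (inherits(results, "validation_result")) results <- list(results)
  get <- function(f) vapply(results, function(r) as.numeric(r[[f]]), numeric(1))
  metrics <- list(dsc = get("dsc"), to = get("to"), ppv = get("ppv"),
                  aae_mm = get("aae_mm"),
                  vol_S_cm3 = get("vol_S_cm3"), vol_Sigma_cm3 = get("vol_Sigma_cm3"))
  stats <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- metrics[[m]][!is.na(metrics[[m]])]
    data.frame(metric = m, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else 0)
  }))
  lv <- c("poor", "inadequate", "adequate", "good", "excellent")
  ratings <- do.call(rbind, lapply(c("dsc", "to", "ppv"), function(m) {
    rr <- factor(vapply(results, function(r)
      as.character(r[[paste0("rating_", m)]]), character(1)), levels = lv)
    tab <- table(rr)
    data.frame(metric = m, rating = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(results))
  }))
  structure(list(stats = stats, ratings = ratings), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$stats, row.names = FALSE)
  cat("\n")
  print(x$ratings[x$ratings$n > 0, ], row.names = FALSE)
  invisible(x)
}
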