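grid32 <- function() voxel_grid(c(32, 32, 32), 1)

test_that("overlap metrics hit their exact boundary cases", {
  g <- grid32()
  a <- make_ellipsoid_mask(g, c(16, 16, 16), 8, "s")
  expect_equal(dsc(a, a), 1)
  expect_equal(target_overlap(a, a), 1)
  expect_equal(ppv(a, a), 1)
  b <- make_ellipsoid_mask(g, c(26, 26, 26), 4, "sigma")
  expect_equal(dsc(a, b), 0)
  expect_equal(target_overlap(a, b), 0)
  inner <- make_ellipsoid_mask(g, c(16, 16, 16), 4, "sigma")
  expect_equal(target_overlap(inner, a), 1)   # S inside Sigma
  expect_equal(ppv(a, inner), 1)              # Sigma inside S
  expect_equal(dsc(a, b), dsc(b, a))          # symmetry
  expect_equal(target_overlap(a, inner), ppv(inner, a))
  empty <- ablation_mask(array(FALSE, g$shape), g)
  expect_error(dsc(empty, empty), "empty")
  expect_error(target_overlap(empty, a), "empty")
  expect_error(ppv(a, empty), "empty")
})

test_that("printed volume triples reproduce the documented metric values", {
  # strong-overlap example: TO excellent, PPV adequate, DSC rounds to 0.8
  r7 <- metrics_from_volumes(13.64, 19.47, 0.95 * 13.64)
  expect_equal(round(r7$to, 2), 0.95)
  expect_equal(round(r7$ppv, 2), 0.67)
  expect_equal(round(r7$dsc, 1), 0.8)
  expect_equal(as.character(r7$rating_to), "excellent")
  expect_equal(as.character(r7$rating_ppv), "adequate")
  expect_true(is.na(r7$aae_mm))
  # overestimation example: TO excellent but DSC/PPV poor
  r9 <- metrics_from_volumes(10.95, 43.49, 0.97 * 10.95)
  expect_equal(round(r9$dsc, 2), 0.39)
  expect_equal(round(r9$ppv, 2), 0.24)
  expect_equal(round(r9$to, 2), 0.97)
  expect_equal(as.character(r9$rating_dsc), "poor")
  # identical volumes: all three metrics are 1
  r1 <- metrics_from_volumes(10, 10, 10)
  expect_equal(c(r1$dsc, r1$to, r1$ppv), c(1, 1, 1))
  expect_error(metrics_from_volumes(10, 10, 11), "overlap")
})

test_that("DSC is the harmonic mean of TO and PPV", {
  g <- grid32()
  set.seed(5)
  for (i in 1:10) {
    vols <- sort(runif(2, 2, 12))
    ov <- runif(1, 0.2, 1) * vols[1]
    pr <- make_overlap_pair(g, vols[1], vols[2], ov, seed = i)
    to <- target_overlap(pr$S, pr$Sigma); pv <- ppv(pr$S, pr$Sigma)
    expect_equal(dsc(pr$S, pr$Sigma), 2 * to * pv / (to + pv), tolerance = 1e-12)
  }
})

test_that("surface error is zero for identity, symmetric, and matches shell separation", {
  g <- voxel_grid(c(64, 64, 64), 0.5)
  a <- make_ellipsoid_mask(g, c(16, 16, 16), 10, "s")
  expect_equal(aae(a, a), 0)
  b <- make_ellipsoid_mask(g, c(16, 16, 16), 13, "sigma")
  d <- aae(a, b)
  expect_equal(d, aae(b, a))                 # symmetric definition
  expect_lt(abs(d - 3.0), 0.3)               # concentric spheres 10 vs 13 mm
  expect_error(aae(a, ablation_mask(array(FALSE, g$shape), g)), "non-empty")
})

test_that("nearest-surface distances agree with an all-pairs oracle", {
  g <- voxel_grid(c(24, 24, 24), 1)
  m1 <- random_blob(g, 120, seed = 21)
  m2 <- random_blob(g, 90, seed = 22)
  A <- voxel_centers(g, mask_boundary(m1))
  B <- voxel_centers(g, mask_boundary(m2))
  expect_equal(cryoplan:::nearest_distances(A, B), oracle_nearest(A, B),
               tolerance = 1e-12)
  want <- (sum(oracle_nearest(A, B)) + sum(oracle_nearest(B, A))) /
    (nrow(A) + nrow(B))
  expect_equal(aae(m1, m2), want, tolerance = 1e-12)
})

test_that("growing the simulated zone by dilation never lowers target overlap", {
  g <- grid32()
  S <- make_ellipsoid_mask(g, c(16, 16, 16), c(7, 6, 5), "s")
  Sigma <- make_ellipsoid_mask(g, c(18, 16, 16), c(5, 5, 5), "sigma")
  tos <- numeric(4)
  for (i in 1:4) {
    tos[i] <- target_overlap(S, Sigma)
    Sigma <- dilate_mask(Sigma)
  }
  expect_true(all(diff(tos) >= 0))
})

test_that("ordinal ratings follow the quality bins with an inclusive top", {
  expect_equal(as.character(rate_score(c(0.8, 1.0))), c("excellent", "excellent"))
  expect_equal(as.character(rate_score(0.75)), "good")
  expect_equal(as.character(rate_score(0.65)), "adequate")
  expect_equal(as.character(rate_score(0.55)), "inadequate")
  expect_equal(as.character(rate_score(c(0.49999, 0))), c("poor", "poor"))
  expect_equal(as.character(rate_score(0.7)), "good")      # closed lower edges
  expect_true(is.ordered(rate_score(0.5)))
  expect_error(rate_score(1.2), "\\[0, 1\\]")
})

test_that("cohort summaries aggregate means, SDs and rating counts correctly", {
  r <- list(metrics_from_volumes(10, 10, 8), metrics_from_volumes(10, 20, 4))
  s1 <- summarize_cohort(r[1])
  expect_equal(s1$stats$mean[s1$stats$metric == "dsc"], r[[1]]$dsc)
  expect_equal(s1$stats$sd[s1$stats$metric == "dsc"], 0)
  s2 <- summarize_cohort(r)
  expect_equal(s2$stats$mean[s2$stats$metric == "to"], mean(c(0.8, 0.4)))
  # recount oracle over the rating table
  lv <- c("poor", "inadequate", "adequate", "good", "excellent")
  for (m in c("dsc", "to", "ppv")) {
    want <- table(factor(vapply(r, function(x)
      as.character(x[[paste0("rating_", m)]]), character(1)), levels = lv))
    got <- s2$ratings[s2$ratings$metric == m, ]
    expect_equal(got$n[match(lv, got$rating)], as.integer(want))
  }
  expect_error(summarize_cohort(list()), "empty")
})
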