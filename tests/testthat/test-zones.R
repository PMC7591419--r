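test_that("the lethal-isotherm death update is committed, idempotent and guarded", {
  g <- voxel_grid(c(6, 6, 6))
  D <- array(0, g$shape)
  T_hist <- array(37, g$shape)
  expect_identical(update_death(D, T_hist, -20), D)        # warm history: unchanged
  expect_true(all(update_death(D, array(-60, g$shape), -20) == 1))
  set.seed(3)
  Tm <- array(runif(216, -50, 37), g$shape)
  D1 <- update_death(D, Tm, -20)
  expect_identical(update_death(D1, Tm, -20), D1)          # idempotent
  expect_true(all(D1 >= D))
  # order-insensitive for a fixed history: partial then full == full
  Tpart <- pmax(Tm, -10)
  expect_identical(update_death(update_death(D, Tpart, -20), Tm, -20), D1)
  expect_error(update_death(D, Tm, 5), "sub-freezing")
  expect_error(update_death(D, array(0, c(2, 2, 2)), -20), "shapes")
})

test_that("zone extraction thresholds correctly and the lethal zone sits inside the ice ball", {
  p <- test_props()
  g <- voxel_grid(c(16, 16, 16), 2)
  plan <- needle_plan("IceSeed", tip_mm = c(15, 15, 22), direction_mm = c(0, 0, 1))
  sim <- run_protocol(g, plan, cryo_protocol(cycles = 1, freeze_s = 240,
                                             passive_s = 30, active_s = 30), p)
  z <- ablation_zones(sim)
  expect_true(all(!z$sigma$voxels | z$iceball$voxels))     # sigma subset of iceball
  expect_gt(sum(z$sigma$voxels), 0)
  # empty extraction below the field minimum
  empty <- extract_zone(sim$state$T_min, min(sim$state$T_min) - 1, "le", g)
  expect_equal(sum(empty$voxels), 0)
  # single connected component around a single centered needle (6-connectivity labelling)
  lab <- label_components(z$iceball$voxels)
  expect_equal(max(lab), 1L)
})

test_that("lower lethal isotherms never enlarge the simulated zone", {
  p <- test_props()
  g <- voxel_grid(c(14, 14, 14), 2)
  plan <- needle_plan("IceSeed", tip_mm = c(13, 13, 18), direction_mm = c(0, 0, 1))
  sim <- run_protocol(g, plan, cryo_protocol(cycles = 1, freeze_s = 180,
                                             passive_s = 30, active_s = 30), p)
  vols <- vapply(c(-5, -20, -40), function(tl)
    sum(sim$state$T_min <= tl), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("tumor coverage is the covered fraction with exact edge cases", {
  g <- voxel_grid(c(40, 40, 40), 1)
  tumor <- make_ellipsoid_mask(g, c(20, 20, 20), c(8, 7, 6), "tumor")
  zone_all <- make_ellipsoid_mask(g, c(20, 20, 20), c(12, 12, 12), "sigma")
  expect_equal(tumor_coverage(zone_all, tumor), 1)
  zone_away <- make_ellipsoid_mask(g, c(33, 33, 33), c(4, 4, 4), "sigma")
  expect_equal(tumor_coverage(zone_away, tumor), 0)
  # half-plane cut through an ellipsoid centered between voxel columns covers
  # exactly half of it (voxelization tolerance)
  tum2 <- make_ellipsoid_mask(g, c(19.5, 20, 20), c(8, 7, 6), "tumor")
  co <- grid_coordinates(g)
  half <- ablation_mask(co$x < 19.5, g, "half")
  cov <- tumor_coverage(half, tum2)
  expect_lt(abs(cov - 0.5), 0.02)
  empty <- ablation_mask(array(FALSE, g$shape), g, "tumor")
  expect_error(tumor_coverage(zone_all, empty), "empty")
})

test_that("minimal enclosing sphere is exact against a brute-force subset oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(runif(20 * 3, 0, 50), ncol = 3)
    got <- miniball(pts)
    want <- oracle_miniball(pts)
    expect_equal(got$radius, want$radius, tolerance = 1e-9)
    d <- sqrt(rowSums(sweep(pts, 2, got$center)^2))
    expect_true(all(d <= got$radius * (1 + 1e-9) + 1e-9))
  }
})

test_that("enclosing sphere of a random voxel blob is valid, tight and order-invariant", {
  g <- voxel_grid(c(40, 40, 40), 1)
  blob <- random_blob(g, 200, seed = 7)
  pts <- voxel_centers(g, blob$voxels)
  ball <- miniball(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ball$center)^2))
  expect_true(all(d <= ball$radius * (1 + 1e-9) + 1e-9))   # encloses every center
  expect_gte(sum(d >= ball$radius - 1e-7), 2)              # supported by >= 2 points
  fp <- max(dist(pts))                                     # farthest pair, O(n^2) oracle
  expect_gte(ball$radius, fp / 2 - 1e-9)                   # lower bound
  expect_lte(ball$radius, fp / sqrt(2) + 1e-9)             # Jung bound in 3D (< sqrt(3/8) fp)
  set.seed(1)
  ball2 <- miniball(pts[sample(nrow(pts)), ])
  expect_equal(ball2$radius, ball$radius, tolerance = 1e-9)
  expect_equal(circumscribing_sphere_diameter(blob), 2 * ball$radius / 10,
               tolerance = 1e-9)
})

test_that("circumscribing sphere diameter handles degenerate masks", {
  g <- voxel_grid(c(40, 40, 40), 1)
  single <- array(FALSE, g$shape); single[20, 20, 20] <- TRUE
  expect_equal(circumscribing_sphere_diameter(ablation_mask(single, g)), 0)
  two <- array(FALSE, g$shape); two[20, 20, 5] <- TRUE; two[20, 20, 35] <- TRUE
  expect_equal(circumscribing_sphere_diameter(ablation_mask(two, g)), 3.0)
  expect_error(circumscribing_sphere_diameter(
    ablation_mask(array(FALSE, g$shape), g)), "empty")
})
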