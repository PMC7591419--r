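# Independent oracles and small fixtures used across the suite.

test_props <- function(...) {
  args <- list(...)
  base <- default_config()$tissue
  base[names(args)] <- args
  do.call(tissue_properties, base)
}

# constant-coefficient material: no phase-change kink, no perfusion
constant_props <- function(k = 0.52, c = 3600, rho = 1050, omega = 0) {
  tissue_properties(rho_tissue = rho, c_unfrozen = c, c_frozen = c,
                    k_unfrozen = k, k_frozen = k, latent_heat = 1e-6,
                    T_liquidus = -200, T_solidus = -201,
                    omega_perfusion = omega, rho_blood = 1060, c_blood = 3600,
                    T_body = 37)
}

# Brute-force dense triple-loop step of the bioheat equation: same contract
# as step_temperature (7-point stencil, arithmetic-mean face conductivity,
# zero-flux boundaries, Dirichlet fixed voxels, coefficients at current T,
# conservative enthalpy update), written as an explicit per-voxel loop.
oracle_step <- function(T, D, Q, props, dt, spacing_mm, fixed = NULL) {
  n <- dim(T)
  d2 <- (spacing_mm * 1e-3)^2
  kf <- effective_conductivity(T, props)
  Tn <- T
  for (i in 1:n[1]) for (j in 1:n[2]) for (l in 1:n[3]) {
    acc <- 0
    if (i > 1)     acc <- acc + 0.5 * (kf[i, j, l] + kf[i - 1, j, l]) * (T[i - 1, j, l] - T[i, j, l]) / d2[1]
    if (i < n[1])  acc <- acc + 0.5 * (kf[i, j, l] + kf[i + 1, j, l]) * (T[i + 1, j, l] - T[i, j, l]) / d2[1]
    if (j > 1)     acc <- acc + 0.5 * (kf[i, j, l] + kf[i, j - 1, l]) * (T[i, j - 1, l] - T[i, j, l]) / d2[2]
    if (j < n[2])  acc <- acc + 0.5 * (kf[i, j, l] + kf[i, j + 1, l]) * (T[i, j + 1, l] - T[i, j, l]) / d2[2]
    if (l > 1)     acc <- acc + 0.5 * (kf[i, j, l] + kf[i, j, l - 1]) * (T[i, j, l - 1] - T[i, j, l]) / d2[3]
    if (l < n[3])  acc <- acc + 0.5 * (kf[i, j, l] + kf[i, j, l + 1]) * (T[i, j, l + 1] - T[i, j, l]) / d2[3]
    perf <- if (T[i, j, l] <= props$T_solidus) 0 else
      (1 - D[i, j, l]) * props$omega_perfusion * props$rho_blood *
        props$c_blood * (props$T_body - T[i, j, l])
    h <- enthalpy_density(T[i, j, l], props, props$T_solidus) +
      dt * (acc + perf + Q[i, j, l])
    Tn[i, j, l] <- temperature_from_enthalpy(h, props)
  }
  if (!is.null(fixed)) Tn[fixed$index] <- fixed$values
  Tn
}

# O(n^2) nearest-neighbour distances, plain double loop
oracle_nearest <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min(colSums((t(B) - A[i, ])^2))), numeric(1))
}

# exhaustive smallest enclosing sphere: try every circumsphere of subsets of
# size 2..4, keep the smallest that encloses all points
oracle_miniball <- function(pts) {
  n <- nrow(pts)
  best <- list(radius = Inf)
  tol <- 1e-9
  try_sphere <- function(sub) {
    s <- cryoplan:::sphere_of(pts[sub, , drop = FALSE])
    d <- sqrt(rowSums(sweep(pts, 2, s$center)^2))
    if (all(d <= s$radius + tol) && s$radius < best$radius) best <<- s
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) try_sphere(c(i, j))
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    try_sphere(c(i, j, k))
  if (n >= 4) {
    cmb <- utils::combn(n, 4)
    for (q in seq_len(ncol(cmb))) try_sphere(cmb[, q])
  }
  best
}

# 6-connectivity component labelling by BFS flood fill
label_components <- function(v) {
  n <- dim(v)
  lab <- array(0L, n)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  todo <- which(v & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      ijk <- arrayInd(queue, n)
      queue <- integer(0)
      for (s in 1:6) {
        nb <- sweep(ijk, 2, shifts[s, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
          nb[, 3] >= 1 & nb[, 3] <= n[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * n[1] + (nb[ok, 3] - 1L) * n[1] * n[2]
        lin <- lin[v[lin] & lab[lin] == 0L]
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
      queue <- unique(queue)
    }
    todo <- which(v & lab == 0L)
  }
  lab
}

# deterministic random blob mask: seed voxel + random face-connected growth
random_blob <- function(grid, n_voxels, seed) {
  set.seed(seed)
  n <- grid$shape
  center <- ceiling(n / 2)
  v <- array(FALSE, n)
  v[center[1], center[2], center[3]] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (sum(v) < n_voxels) {
    occ <- which(v, arr.ind = TRUE)
    cand <- occ[sample(nrow(occ), 1), ] + shifts[sample(6, 1), ]
    if (all(cand >= 1) && all(cand <= n) && !v[cand[1], cand[2], cand[3]])
      v[cand[1], cand[2], cand[3]] <- TRUE
  }
  ablation_mask(v, grid, "blob")
}
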