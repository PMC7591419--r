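#' Thermal state of the tissue domain
#'
#' Holds the current temperature field, the running per-voxel minimum
#' temperature (the thermal history that the lethal-isotherm death model
#' consumes), and the elapsed simulated time.
#'
#' @param grid a [voxel_grid()].
#' @param T_init initial temperature, degrees C; a scalar or an array of the
#'   grid's shape.
#' @return An object of class `thermal_state` with elements `grid`, `T`,
#'   `T_min` (both arrays, degrees C) and `t_elapsed` (s).
#' @export
thermal_state <- function(grid, T_init = 37) {
  if (!inherits(grid, "voxel_grid")) stop("'grid' must be a voxel_grid")
  T <- if (length(T_init) == 1L) array(as.numeric(T_init), dim = grid$shape)
       else T_init
  if (!identical(dim(T), as.integer(grid$shape)))
    stop("initial temperature shape does not match the grid")
  if (any(!is.finite(T))) stop("non-finite initial temperature")
  structure(list(grid = grid, T = T, T_min = T, t_elapsed = 0),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> t = %.1f s, T in [%.2f, %.2f] C, T_min floor %.2f C\n",
              x$t_elapsed, min(x$T), max(x$T), min(x$T_min)))
  invisible(x)
}

#' Pennes perfusion source attenuated by dead tissue
#'
#' Volumetric heat source from blood perfusion,
#' `(1 - D) * omega * rho_blood * c_blood * (T_body - T)` in W/m^3. Dead
#' tissue (`D = 1`) is no longer perfused, and the source is clamped to zero
#' wherever the tissue is fully frozen (`T <= T_solidus`): no blood flows
#' through ice. The term heats wherever tissue is below body temperature.
#'
#' @param T temperature array, degrees C.
#' @param D dead-cell fraction array in `[0, 1]`, same shape as `T`.
#' @param props a [tissue_properties()] object.
#' @return array, W/m^3.
#' @export
perfusion_term <- function(T, D, props) {
  if (!identical(dim(T), dim(D)) || length(T) != length(D))
    stop("temperature and dead-fraction fields have different shapes")
  src <- (1 - D) * props$omega_perfusion * props$rho_blood * props$c_blood *
    (props$T_body - T)
  src[T <= props$T_solidus] <- 0
  src
}

#' Largest stable explicit time step
#'
#' Conservative stability bound for the explicit forward-Euler scheme:
#' `dt <= C_min / (2 * k_max * (1/dx^2 + 1/dy^2 + 1/dz^2))`, evaluated with
#' the smallest heat capacity and largest conductivity the material can take
#' over all temperatures (so one bound holds for a whole simulation).
#'
#' @param props a [tissue_properties()] object.
#' @param spacing_mm voxel spacing, mm (length 3 or scalar).
#' @return maximal admissible `dt` in seconds.
#' @export
stability_dt <- function(props, spacing_mm) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  d <- spacing_mm * 1e-3                       # m
  C_min <- props$rho_tissue * min(props$c_frozen, props$c_unfrozen)
  k_max <- max(props$k_frozen, props$k_unfrozen)
  C_min / (2 * k_max * sum(1 / d^2))
}

# 7-point variable-coefficient divergence of k grad T, W/m^3.
# Face conductivity is the arithmetic mean of adjacent voxel values; outer
# boundary faces carry no flux (insulated domain edge).
diffusion_term <- function(T, k, spacing_mm) {
  n <- dim(T)
  d2 <- (spacing_mm * 1e-3)^2                  # m^2
  div <- array(0, dim = n)
  i1 <- 1:(n[1] - 1); i2 <- 2:n[1]
  f <- 0.5 * (k[i1, , , drop = FALSE] + k[i2, , , drop = FALSE]) *
    (T[i2, , , drop = FALSE] - T[i1, , , drop = FALSE]) / d2[1]
  div[i1, , ] <- div[i1, , , drop = FALSE] + f
  div[i2, , ] <- div[i2, , , drop = FALSE] - f
  j1 <- 1:(n[2] - 1); j2 <- 2:n[2]
  f <- 0.5 * (k[, j1, , drop = FALSE] + k[, j2, , drop = FALSE]) *
    (T[, j2, , drop = FALSE] - T[, j1, , drop = FALSE]) / d2[2]
  div[, j1, ] <- div[, j1, , drop = FALSE] + f
  div[, j2, ] <- div[, j2, , drop = FALSE] - f
  k1 <- 1:(n[3] - 1); k2 <- 2:n[3]
  f <- 0.5 * (k[, , k1, drop = FALSE] + k[, , k2, drop = FALSE]) *
    (T[, , k2, drop = FALSE] - T[, , k1, drop = FALSE]) / d2[3]
  div[, , k1] <- div[, , k1, drop = FALSE] + f
  div[, , k2] <- div[, , k2, drop = FALSE] - f
  div
}

#' Advance the bioheat equation one explicit step
#'
#' One forward-Euler step of
#' `C_eff(T) dT/dt = div(k_eff(T) grad T) + perfusion + Q`
#' on the voxel grid, with a 7-point finite-difference Laplacian, insulated
#' (zero-flux) outer boundaries, and Dirichlet (fixed-temperature) conditions
#' at probe voxels. The step is taken in conservative enthalpy form: the
#' volumetric enthalpy (whose derivative is the apparent heat capacity
#' `C_eff`) is advanced by the flux divergence and sources, then inverted
#' back to temperature via [temperature_from_enthalpy()]. This conserves
#' total energy exactly under insulated boundaries and never skips latent
#' heat when a voxel crosses the mushy zone within one step. Coefficients
#' are evaluated at the current temperature; the per-voxel
#' minimum-temperature history is updated after the step.
#'
#' @param state a [thermal_state()].
#' @param D dead-cell fraction array (same shape); attenuates perfusion.
#' @param Q optional applied volumetric source array, W/m^3 (negative while
#'   freezing). `NULL` means zero.
#' @param props a [tissue_properties()] object.
#' @param dt time step, s; must satisfy the explicit stability bound (see
#'   [stability_dt()]) or an error naming the maximal admissible step is
#'   raised.
#' @param fixed optional Dirichlet conditions: a list with integer `index`
#'   (linear voxel indices) and numeric `values` (degrees C, recycled).
#' @return the advanced `thermal_state`.
#' @export
step_temperature <- function(state, D, Q = NULL, props, dt, fixed = NULL) {
  T <- state$T
  if (!identical(dim(T), dim(D))) stop("dead-fraction shape does not match the state")
  C <- effective_heat_capacity(T, props)
  k <- effective_conductivity(T, props)
  sp <- state$grid$spacing_mm
  dt_max <- min(C) / (2 * max(k) * sum(1 / (sp * 1e-3)^2))
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("explicit stability violated: dt = %g s exceeds the maximal admissible dt = %g s",
                 dt, dt_max))
  rhs <- diffusion_term(T, k, sp) + perfusion_term(T, D, props)
  if (!is.null(Q)) rhs <- rhs + Q
  H <- enthalpy_density(T, props, props$T_solidus)
  T_new <- temperature_from_enthalpy(H + dt * rhs, props)
  if (!is.null(fixed) && length(fixed$index))
    T_new[fixed$index] <- fixed$values
  state$T <- T_new
  state$T_min <- pmin(state$T_min, T_new)
  state$t_elapsed <- state$t_elapsed + dt
  state
}
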