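#' Thermophysical tissue properties
#'
#' Bundles the material constants of the perfused tissue and of blood used by
#' the bioheat stepper. Phase change is represented by an apparent heat
#' capacity spread over a "mushy" temperature interval
#' `[T_solidus, T_liquidus]` in which the latent heat of fusion is released.
#' There are deliberately no default values here: numbers live in the
#' configuration file (see [default_config()]), never in the physics code.
#'
#' @param rho_tissue tissue density, kg/m^3.
#' @param c_unfrozen,c_frozen specific heat capacity above the liquidus /
#'   below the solidus, J/(kg K).
#' @param k_unfrozen,k_frozen thermal conductivity above the liquidus / below
#'   the solidus, W/(m K).
#' @param latent_heat latent heat of fusion, J/kg.
#' @param T_liquidus,T_solidus mushy-zone bounds, degrees C; must satisfy
#'   `T_solidus < T_liquidus <= 0`.
#' @param omega_perfusion blood perfusion coefficient, 1/s.
#' @param rho_blood blood density, kg/m^3.
#' @param c_blood blood specific heat capacity, J/(kg K).
#' @param T_body core body temperature, degrees C.
#' @return An object of class `tissue_properties`.
#' @seealso [effective_heat_capacity()], [effective_conductivity()]
#' @export
tissue_properties <- function(rho_tissue, c_unfrozen, c_frozen,
                              k_unfrozen, k_frozen, latent_heat,
                              T_liquidus, T_solidus, omega_perfusion,
                              rho_blood, c_blood, T_body = 37) {
  p <- list(rho_tissue = rho_tissue, c_unfrozen = c_unfrozen,
            c_frozen = c_frozen, k_unfrozen = k_unfrozen,
            k_frozen = k_frozen, latent_heat = latent_heat,
            T_liquidus = T_liquidus, T_solidus = T_solidus,
            omega_perfusion = omega_perfusion, rho_blood = rho_blood,
            c_blood = c_blood, T_body = T_body)
  p <- lapply(p, as.numeric)
  num <- vapply(p, function(v) length(v) == 1L && is.finite(v), logical(1))
  if (!all(num)) stop("all tissue properties must be single finite numbers: ",
                      paste(names(p)[!num], collapse = ", "))
  pos <- c("rho_tissue", "c_unfrozen", "c_frozen", "k_unfrozen", "k_frozen",
           "latent_heat", "rho_blood", "c_blood")
  bad <- pos[vapply(pos, function(n) p[[n]] <= 0, logical(1))]
  if (length(bad)) stop("tissue properties must be > 0: ", paste(bad, collapse = ", "))
  if (p$omega_perfusion < 0) stop("'omega_perfusion' must be >= 0")
  if (!(p$T_solidus < p$T_liquidus)) stop("'T_solidus' must be below 'T_liquidus'")
  if (p$T_liquidus > 0) stop("'T_liquidus' must be <= 0 degrees C")
  structure(p, class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("<tissue_properties>\n")
  cat(sprintf("  rho %g kg/m^3; c %g/%g J/(kg K); k %g/%g W/(m K) (unfrozen/frozen)\n",
              x$rho_tissue, x$c_unfrozen, x$c_frozen, x$k_unfrozen, x$k_frozen))
  cat(sprintf("  latent heat %g J/kg over mushy zone [%g, %g] C\n",
              x$latent_heat, x$T_solidus, x$T_liquidus))
  cat(sprintf("  perfusion omega %g 1/s; blood rho %g kg/m^3, c %g J/(kg K); T_body %g C\n",
              x$omega_perfusion, x$rho_blood, x$c_blood, x$T_body))
  invisible(x)
}

#' Apparent volumetric heat capacity
#'
#' Effective volumetric heat capacity `C_eff(T)` in J/(m^3 K), including the
#' latent heat of fusion spread uniformly over the mushy zone
#' (apparent-heat-capacity / enthalpy-spreading method). Above the liquidus it
#' is `rho * c_unfrozen`; below the solidus `rho * c_frozen`; in between,
#' `rho * (c_mix + L / (T_liquidus - T_solidus))` where `c_mix` interpolates
#' linearly from frozen to unfrozen capacity. The integral of `C_eff` across
#' the mushy zone therefore recovers the full latent heat.
#'
#' @param T temperature, degrees C (vectorized; arrays allowed).
#' @param props a [tissue_properties()] object.
#' @return numeric of the same shape as `T`, J/(m^3 K); always positive.
#' @export
effective_heat_capacity <- function(T, props) {
  if (!all(is.finite(T))) stop("non-finite temperature")
  Ts <- props$T_solidus; Tl <- props$T_liquidus; rho <- props$rho_tissue
  out <- rep(rho * props$c_unfrozen, length(T))
  frozen <- T <= Ts
  out[frozen] <- rho * props$c_frozen
  mushy <- !frozen & T < Tl
  if (any(mushy)) {
    frac <- (T[mushy] - Ts) / (Tl - Ts)                 # 0 frozen .. 1 unfrozen
    out[mushy] <- rho * (props$c_frozen + frac * (props$c_unfrozen - props$c_frozen) +
                           props$latent_heat / (Tl - Ts))
  }
  if (is.array(T)) dim(out) <- dim(T)
  out
}

#' Effective thermal conductivity
#'
#' `k_unfrozen` above the liquidus, `k_frozen` below the solidus, and a linear
#' interpolation across the mushy zone. For ice-like tissue
#' (`k_frozen > k_unfrozen`) this is monotone non-increasing in temperature.
#'
#' @inheritParams effective_heat_capacity
#' @return numeric of the same shape as `T`, W/(m K).
#' @export
effective_conductivity <- function(T, props) {
  if (!all(is.finite(T))) stop("non-finite temperature")
  Ts <- props$T_solidus; Tl <- props$T_liquidus
  out <- rep(props$k_unfrozen, length(T))
  frozen <- T <= Ts
  out[frozen] <- props$k_frozen
  mushy <- !frozen & T < Tl
  if (any(mushy))
    out[mushy] <- props$k_frozen + (T[mushy] - Ts) / (Tl - Ts) *
      (props$k_unfrozen - props$k_frozen)
  if (is.array(T)) dim(out) <- dim(T)
  out
}

#' Volumetric enthalpy relative to a reference temperature
#'
#' Closed-form integral of [effective_heat_capacity()] from `T_ref` to `T`,
#' in J/m^3. Used for energy bookkeeping in conservation checks.
#'
#' @inheritParams effective_heat_capacity
#' @param T_ref reference temperature, degrees C.
#' @return numeric of the same shape as `T`, J/m^3.
#' @export
enthalpy_density <- function(T, props, T_ref = -273.15) {
  if (anyNA(T) || any(!is.finite(T))) stop("non-finite temperature")
  Ts <- props$T_solidus; Tl <- props$T_liquidus; rho <- props$rho_tissue
  w <- Tl - Ts
  # enthalpy measured from Ts, piecewise in T
  h_at <- function(Ti) {
    below <- pmin(Ti, Ts)
    frozen_part <- props$c_frozen * (below - Ts)
    f <- pmin(pmax((Ti - Ts) / w, 0), 1)               # mushy progress
    mushy_part <- f * w * props$c_frozen +
      0.5 * f^2 * w * (props$c_unfrozen - props$c_frozen) +
      f * props$latent_heat
    warm_part <- props$c_unfrozen * pmax(Ti - Tl, 0)
    rho * (frozen_part + mushy_part + warm_part)
  }
  out <- h_at(T) - h_at(T_ref)
  if (is.array(T)) dim(out) <- dim(T)
  out
}

#' Invert the enthalpy-temperature relation
#'
#' Exact inverse of [enthalpy_density()] with the solidus as reference
#' temperature: given volumetric enthalpy in J/m^3 (zero at `T_solidus`),
#' returns the temperature in degrees C. Piecewise: linear in the frozen and
#' unfrozen branches, the root of a quadratic across the mushy zone (where
#' the mixture capacity varies linearly and latent heat accrues).
#'
#' @param H volumetric enthalpy relative to the solidus, J/m^3 (vectorized).
#' @param props a [tissue_properties()] object.
#' @return temperature, degrees C, same shape as `H`.
#' @export
temperature_from_enthalpy <- function(H, props) {
  if (!all(is.finite(H))) stop("non-finite enthalpy")
  Ts <- props$T_solidus; Tl <- props$T_liquidus; rho <- props$rho_tissue
  w <- Tl - Ts
  Hm <- rho * (w * (props$c_frozen + props$c_unfrozen) / 2 + props$latent_heat)
  out <- numeric(length(H))
  frozen <- H <= 0
  out[frozen] <- Ts + H[frozen] / (rho * props$c_frozen)
  warm <- H >= Hm
  out[warm] <- Tl + (H[warm] - Hm) / (rho * props$c_unfrozen)
  mid <- !frozen & !warm
  if (any(mid)) {
    a <- 0.5 * w * (props$c_unfrozen - props$c_frozen)
    b <- w * props$c_frozen + props$latent_heat
    hh <- H[mid] / rho
    f <- if (abs(a) < 1e-12 * b) hh / b
         else (-b + sqrt(b^2 + 4 * a * hh)) / (2 * a)
    out[mid] <- Ts + f * w
  }
  if (is.array(H)) dim(out) <- dim(H)
  out
}
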