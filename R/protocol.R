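#' Freeze-thaw protocol
#'
#' Builds the cyclic treatment protocol. The clinical default is two cycles,
#' each of 10 min active freezing, 2 min passive thawing and 1 min active
#' thawing; any phase sequence can also be given explicitly.
#'
#' @param cycles number of freeze-thaw cycles (0 allowed: an empty protocol
#'   that leaves the tissue untouched).
#' @param freeze_s,passive_s,active_s phase durations in seconds.
#' @param phases optional explicit list of phases, each a list with `name`,
#'   `mode` (one of `"freeze"`, `"passive_thaw"`, `"active_thaw"`) and
#'   `duration_s`; overrides the cycle arguments.
#' @return An object of class `cryo_protocol`: a list of phases.
#' @examples
#' default_protocol()
#' @export
cryo_protocol <- function(cycles = 2, freeze_s = 600, passive_s = 120,
                          active_s = 60, phases = NULL) {
  if (is.null(phases)) {
    cycles <- as.integer(cycles)
    if (is.na(cycles) || cycles < 0) stop("'cycles' must be a non-negative integer")
    phases <- list()
    for (cy in seq_len(cycles)) {
      phases <- c(phases, list(
        list(name = sprintf("cycle%d_freeze", cy), mode = "freeze",
             duration_s = freeze_s),
        list(name = sprintf("cycle%d_passive_thaw", cy), mode = "passive_thaw",
             duration_s = passive_s),
        list(name = sprintf("cycle%d_active_thaw", cy), mode = "active_thaw",
             duration_s = active_s)))
    }
  }
  for (ph in phases) {
    if (!all(c("name", "mode", "duration_s") %in% names(ph)))
      stop("each phase needs 'name', 'mode' and 'duration_s'")
    if (!ph$mode %in% c("freeze", "passive_thaw", "active_thaw"))
      stop("unknown phase mode: ", ph$mode)
    if (!is.finite(ph$duration_s) || ph$duration_s <= 0)
      stop("phase durations must be positive")
  }
  structure(phases, class = "cryo_protocol")
}

#' @rdname cryo_protocol
#' @export
default_protocol <- function() cryo_protocol()

#' @export
print.cryo_protocol <- function(x, ...) {
  cat(sprintf("<cryo_protocol> %d phase(s), total %.0f s\n", length(x),
              sum(vapply(x, `[[`, numeric(1), "duration_s"))))
  for (ph in x) cat(sprintf("  %-22s %-13s %6.0f s\n", ph$name, ph$mode, ph$duration_s))
  invisible(x)
}

#' Solver controls
#'
#' Numerical and probe-boundary settings for the explicit stepper.
#'
#' @param T_freeze_C probe surface temperature at full freezing power, deg C.
#' @param T_thaw_C probe surface temperature during active thaw, deg C.
#' @param safety fraction of the stability bound used for the automatic time
#'   step, in `(0, 1]`.
#' @param dt_s fixed time step in seconds, or `NULL` for automatic selection
#'   from [stability_dt()].
#' @return list of class `solver_controls`.
#' @export
solver_controls <- function(T_freeze_C = -140, T_thaw_C = 20, safety = 0.9,
                            dt_s = NULL) {
  if (!is.finite(safety) || safety <= 0 || safety > 1)
    stop("'safety' must lie in (0, 1]")
  structure(list(T_freeze_C = T_freeze_C, T_thaw_C = T_thaw_C,
                 safety = safety, dt_s = dt_s), class = "solver_controls")
}

#' Run a freeze-thaw protocol
#'
#' Executes the protocol phase by phase on a shared temperature field (so
#' multiple needles interact through the physics rather than through an
#' ice-ball union approximation). Freezing phases hold each probe's active
#' tip at `T_body + p * (T_freeze - T_body)` for power fraction `p`; passive
#' thaw releases the probes; active thaw holds them at `T_thaw`. The
#' dead-cell field is updated after every step from the minimum-temperature
#' history via the lethal isotherm.
#'
#' @param grid a [voxel_grid()].
#' @param needles a [needle_plan()]; every tip must be inside the grid.
#' @param protocol a [cryo_protocol()].
#' @param props a [tissue_properties()].
#' @param solver a [solver_controls()].
#' @param T_lethal_C lethal isotherm, deg C (must be `< 0`).
#' @param record_history if `TRUE`, keep per-step frozen/dead voxel counts.
#' @param verbose if `TRUE`, message at phase boundaries.
#' @return list with `state` (final [thermal_state()]), `D` (dead-fraction
#'   array) and `history` (data frame with columns `phase`, `mode`, `t_s`,
#'   `frozen_voxels`, `dead_voxels`, or `NULL`).
#' @export
run_protocol <- function(grid, needles, protocol, props,
                         solver = solver_controls(), T_lethal_C = -20,
                         record_history = FALSE, verbose = FALSE) {
  if (!inherits(protocol, "cryo_protocol"))
    stop("'protocol' must be a cryo_protocol (empty or malformed protocol)")
  needles <- as_needle_plan(needles)
  tips <- as.matrix(needles[, c("tip_x", "tip_y", "tip_z")])
  if (!all(points_in_grid(grid, tips)))
    stop("every needle tip must lie inside the grid")
  state <- thermal_state(grid, props$T_body)
  D <- array(0, dim = grid$shape)
  dt0 <- if (is.null(solver$dt_s)) solver$safety * stability_dt(props, grid$spacing_mm)
         else solver$dt_s
  hist <- if (record_history) list() else NULL
  for (ph in protocol) {
    fixed <- probe_conditions(needles, grid, ph$mode, props, solver)
    nstep <- max(1L, ceiling(ph$duration_s / dt0))
    dt <- ph$duration_s / nstep
    if (verbose)
      message(sprintf("[%8.1f s] phase %s (%s): %d steps of %.3f s",
                      state$t_elapsed, ph$name, ph$mode, nstep, dt))
    if (!is.null(fixed)) {                      # impose probes before stepping
      state$T[fixed$index] <- fixed$values
      state$T_min <- pmin(state$T_min, state$T)
    }
    frozen <- dead <- t_s <- numeric(nstep)
    for (s in seq_len(nstep)) {
      state <- step_temperature(state, D, NULL, props, dt, fixed)
      D <- update_death(D, state$T_min, T_lethal_C)
      if (record_history) {
        frozen[s] <- sum(state$T < 0)
        dead[s] <- sum(D >= 1)
        t_s[s] <- state$t_elapsed
      }
    }
    if (record_history)
      hist[[length(hist) + 1L]] <- data.frame(phase = ph$name, mode = ph$mode,
                                              t_s = t_s, frozen_voxels = frozen,
                                              dead_voxels = dead)
  }
  if (verbose)
    message(sprintf("[%8.1f s] protocol complete; coldest voxel reached %.1f C",
                    state$t_elapsed, min(state$T_min)))
  list(state = state, D = D,
       history = if (record_history) do.call(rbind, hist) else NULL)
}
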