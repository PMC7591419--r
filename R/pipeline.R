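#' Case bundle: the inputs of one end-to-end run
#'
#' Collects the file paths of one case — kidney, tumor and (optionally) a
#' reference ablation-zone mask `S`, the needle plan and the configuration —
#' plus an output directory. All masks must share the same grid geometry to
#' within 1e-6 mm.
#'
#' @param plan path to the needle-plan table.
#' @param config path to the configuration YAML.
#' @param out_dir output directory.
#' @param kidney,tumor,s optional paths to NIfTI masks (`s` is the reference
#'   ablation zone; when present the run is validated against it).
#' @return a list of class `case_bundle`.
#' @export
case_bundle <- function(plan, config, out_dir, kidney = NULL, tumor = NULL,
                        s = NULL) {
  paths <- c(plan = plan, config = config, kidney = kidney, tumor = tumor, s = s)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(list(plan = plan, config = config, out_dir = out_dir,
                 kidney = kidney, tumor = tumor, s = s),
            class = "case_bundle")
}

load_bundle_masks <- function(bundle) {
  masks <- list()
  for (nm in c("kidney", "tumor", "s"))
    if (!is.null(bundle[[nm]])) masks[[nm]] <- read_mask(bundle[[nm]], nm)
  if (length(masks) > 1) {
    g0 <- masks[[1]]$grid
    for (i in seq_along(masks)[-1])
      if (!grids_equal(g0, masks[[i]]$grid))
        stop(sprintf("mask geometries disagree:\n  %s: %s\n  %s: %s",
                     names(masks)[1], format_grid(g0),
                     names(masks)[i], format_grid(masks[[i]]$grid)))
  }
  masks
}

#' Run one case end to end: simulate, extract, validate
#'
#' Runs the freeze-thaw protocol with the plan's needle coordinates on the
#' grid of the case's masks, extracts the simulated ablation zone and the
#' ice ball, computes tumor coverage and — when a reference zone `S` is part
#' of the bundle — the full validation metrics, and writes the simulated
#' zone, optional field snapshots and a JSON report to the output directory.
#' The pipeline is deterministic: rerunning an identical bundle reproduces
#' the report bit for bit.
#'
#' @param bundle a [case_bundle()].
#' @param grid optional [voxel_grid()] override; by default the grid of the
#'   bundle's masks (a mask is then required).
#' @param write_fields if `TRUE`, also write minimum-temperature and
#'   dead-fraction volumes.
#' @param verbose logical; phase-boundary log messages.
#' @return invisibly, a list with `result` (a [validation_result()] or
#'   `NULL` when no reference zone was given), `coverage`, `zones`, and the
#'   output `paths`.
#' @export
run_case <- function(bundle, grid = NULL, write_fields = FALSE,
                     verbose = FALSE) {
  config <- read_config(bundle$config)
  plan <- read_needle_plan(bundle$plan)
  masks <- load_bundle_masks(bundle)
  if (is.null(grid)) {
    if (!length(masks))
      stop("no grid: give a grid or at least one mask in the bundle")
    grid <- masks[[1]]$grid
  }
  props <- config_tissue(config)
  sim <- run_protocol(grid, plan, config_protocol(config), props,
                      solver = config_solver(config),
                      T_lethal_C = config_lethal(config), verbose = verbose)
  zones <- ablation_zones(sim)
  coverage <- if (!is.null(masks$tumor))
    tumor_coverage(zones$sigma, masks$tumor) else NA_real_
  result <- if (!is.null(masks$s))
    validate_masks(masks$s, zones$sigma, case = basename(bundle$out_dir))
  else NULL
  dir.create(bundle$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(sigma = file.path(bundle$out_dir, "sigma.nii.gz"),
                iceball = file.path(bundle$out_dir, "iceball.nii.gz"),
                report = file.path(bundle$out_dir, "report.json"))
  write_mask(zones$sigma, paths$sigma)
  write_mask(zones$iceball, paths$iceball)
  if (write_fields) {
    paths$t_min <- file.path(bundle$out_dir, "t_min.nii.gz")
    paths$dead <- file.path(bundle$out_dir, "dead_fraction.nii.gz")
    write_field(sim$state$T_min, grid, paths$t_min)
    write_field(sim$D, grid, paths$dead)
  }
  write_report(result, coverage, zones, paths$report)
  invisible(list(result = result, coverage = coverage, zones = zones,
                 sim = sim, paths = paths))
}

#' Write a machine-readable case report
#'
#' JSON schema: `volumes_cm3` (s, sigma, overlap, iceball; absent entries
#' for missing inputs), `metrics` (dsc, to, ppv, aae_mm), `ratings`, and
#' `tumor_coverage`. Every number is recomputable from the stored masks.
#'
#' @param result a [validation_result()] or `NULL`.
#' @param coverage tumor coverage fraction or `NA`.
#' @param zones list with `sigma` (and optionally `iceball`) masks.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_report <- function(result, coverage, zones, path) {
  rep <- list(volumes_cm3 = list(sigma = volume_cm3(zones$sigma)))
  if (!is.null(zones$iceball))
    rep$volumes_cm3$iceball <- volume_cm3(zones$iceball)
  if (!is.null(result)) {
    rep$volumes_cm3$s <- result$vol_S_cm3
    rep$volumes_cm3$overlap <- result$vol_overlap_cm3
    rep$metrics <- list(dsc = result$dsc, to = result$to, ppv = result$ppv,
                        aae_mm = result$aae_mm)
    rep$ratings <- list(dsc = as.character(result$rating_dsc),
                        to = as.character(result$rating_to),
                        ppv = as.character(result$rating_ppv))
  }
  if (!is.na(coverage)) rep$tumor_coverage <- coverage
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
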