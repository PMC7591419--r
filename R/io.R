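#' Configuration files
#'
#' All tunable numbers — tissue constants, needle geometry defaults, the
#' freeze-thaw protocol, solver controls and the lethal isotherm — live in a
#' YAML configuration file with sections `tissue`, `needle_defaults`,
#' `protocol`, `solver` and `death`. `default_config()` loads the copy
#' shipped with the package.
#'
#' @param path file path.
#' @return a nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("tissue", "needle_defaults", "protocol", "solver", "death")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("configuration is missing section(s): ",
                         paste(miss, collapse = ", "))
  invisible(config_tissue(cfg))      # validate eagerly
  cfg
}

#' @rdname read_config
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "cryoplan", mustWork = TRUE))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Materialize configuration sections as package objects
#'
#' @param config a configuration list (see [read_config()]).
#' @return `config_tissue()` a [tissue_properties()]; `config_protocol()` a
#'   [cryo_protocol()]; `config_solver()` a [solver_controls()];
#'   `config_lethal()` the lethal isotherm in deg C.
#' @export
config_tissue <- function(config) do.call(tissue_properties, config$tissue)

#' @rdname config_tissue
#' @export
config_protocol <- function(config) {
  p <- config$protocol
  if (!is.null(p$phases)) cryo_protocol(phases = p$phases)
  else cryo_protocol(cycles = p$cycles, freeze_s = p$freeze_s,
                     passive_s = p$passive_s, active_s = p$active_s)
}

#' @rdname config_tissue
#' @export
config_solver <- function(config) {
  s <- config$solver
  solver_controls(T_freeze_C = s$T_freeze_C, T_thaw_C = s$T_thaw_C,
                  safety = s$safety,
                  dt_s = if (identical(s$dt_s, "auto")) NULL else s$dt_s)
}

#' @rdname config_tissue
#' @export
config_lethal <- function(config) as.numeric(config$death$T_lethal_C)

#' Read a binary mask from a NIfTI file
#'
#' Any nonzero voxel maps to `TRUE`. The grid geometry (spacing, origin) is
#' taken from the NIfTI transform, which must be axis-aligned (diagonal,
#' positive scales); world mm coordinates follow the package convention of
#' the first voxel center at `origin_mm`.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param label label for the mask.
#' @return an [ablation_mask()].
#' @export
read_mask <- function(path, label = "mask") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D mask, got %dD in %s", length(d), path))
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-6) || any(diag(rot) <= 0))
    stop("mask transform must be axis-aligned with positive spacing: ", path)
  grid <- voxel_grid(d, spacing_mm = diag(rot), origin_mm = m[1:3, 4])
  ablation_mask(array(as.array(img) != 0, dim = d), grid, label)
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask an [ablation_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  write_field(array(as.integer(mask$voxels), dim = mask$grid$shape),
              mask$grid, path, datatype = "uint8")
  invisible(path)
}

#' Write a scalar field (e.g. temperature) to a NIfTI file
#'
#' @param field numeric array with the grid's shape.
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @param datatype NIfTI datatype for storage.
#' @return invisibly, `path`.
#' @export
write_field <- function(field, grid, path, datatype = "float") {
  img <- RNifti::asNifti(field)
  m <- diag(c(grid$spacing_mm, 1))
  m[1:3, 4] <- grid$origin_mm
  img <- RNifti::`pixdim<-`(img, grid$spacing_mm)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Needle-plan tables
#'
#' Plain-text (tab-separated) needle plans with columns `type`, `tip_x`,
#' `tip_y`, `tip_z`, `dir_x`, `dir_y`, `dir_z`, `active_length_mm`,
#' `radius_mm`, `power_fraction`; world coordinates in mm.
#'
#' @param path file path.
#' @return a [needle_plan()].
#' @export
read_needle_plan <- function(path) {
  if (!file.exists(path)) stop("needle plan not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_needle_plan(df)
}

#' @rdname read_needle_plan
#' @param plan a [needle_plan()].
#' @export
write_needle_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
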