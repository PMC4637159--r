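#' Volume input/output and run configuration
#'
#' Volumes (phase fields, masks, activation maps) travel as NIfTI files with
#' mandatory spacing in pixdim and a description string carrying the cylinder
#' axis and role (\code{purkinjemap:axis=<n>;role=<role>}).  Values are stored
#' as float64 so round trips are bit-exact.  Run configurations are YAML;
#' curves are JSON control-point lists.
#'
#' @name io_cli
NULL

meta_string <- function(axis, role) sprintf("purkinjemap:axis=%d;role=%s", axis, role)

parse_meta <- function(desc) {
  if (!is.character(desc) || !grepl("^purkinjemap:", desc)) return(NULL)
  body <- sub("^purkinjemap:", "", desc)
  kv <- strsplit(strsplit(body, ";")[[1]], "=")
  out <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  out
}

#' Write a volume to NIfTI
#'
#' @param obj a \code{phase_field}, \code{voxel_mask}, \code{activation_map}
#'   or plain 3D array.
#' @param path output path (.nii).
#' @param spacing voxel spacing, required for plain arrays.
#' @param axis cylinder axis recorded in the metadata (plain arrays only).
#' @export
write_volume <- function(obj, path, spacing = NULL, axis = 3L) {
  if (inherits(obj, "phase_field")) {
    vals <- obj$values; spacing <- obj$spacing; axis <- obj$axis; role <- "phase"
  } else if (inherits(obj, "voxel_mask")) {
    vals <- obj$flags + 0; spacing <- obj$spacing; role <- obj$role
    if (is.null(spacing)) stop("voxel_mask carries no spacing; supply one at construction")
  } else if (inherits(obj, "activation_map")) {
    vals <- obj$times; role <- "activation"
    if (is.null(spacing)) stop("spacing required to write an activation map")
  } else {
    vals <- obj; role <- "array"
    if (is.null(spacing)) stop("spacing required to write a plain array")
  }
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(-1, rep(spacing, 3), 0, 0, 0, 0),
    descrip = meta_string(as.integer(axis), role),
    datatype = 64L, bitpix = 64L))
  img <- RNifti::asNifti(vals + 0, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume written by \code{\link{write_volume}}
#'
#' @param path NIfTI path.
#' @return a \code{phase_field}, \code{voxel_mask}, or (for activation maps
#'   and plain arrays) a list with \code{values}, \code{spacing},
#'   \code{axis}, \code{role}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  meta <- parse_meta(hdr$descrip)
  if (is.null(meta))
    stop("volume lacks spacing/axis metadata (not written by write_volume)")
  spacing <- RNifti::pixdim(img)[1]
  if (!is.finite(spacing) || spacing <= 0) stop("volume lacks a positive voxel spacing")
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img))
  axis <- as.integer(meta$axis)
  role <- meta$role
  if (role == "phase") return(phase_field(vals, spacing, axis))
  if (role %in% c("chamber", "shell", "tissue", "network"))
    return(voxel_mask(vals != 0, role, spacing = spacing))
  if (role == "activation") vals[vals < 0] <- NA  # sentinel for never-activated
  list(values = vals, spacing = spacing, axis = axis, role = role)
}

#' Write an activation map volume (NA encoded as -1)
#' @param map an \code{activation_map}.
#' @param path output path.
#' @param spacing voxel spacing.
#' @export
write_activation <- function(map, path, spacing) {
  tm <- map$times
  tm[!is.finite(tm)] <- -1
  write_volume(tm, path, spacing = spacing, axis = 3L)
  # role tag fix: rewrite with activation role
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(-1, rep(spacing, 3), 0, 0, 0, 0),
    descrip = meta_string(3L, "activation"),
    datatype = 64L, bitpix = 64L))
  RNifti::writeNifti(RNifti::asNifti(tm, hdr), path)
  invisible(path)
}

#' Read an activation map volume
#' @param path NIfTI path written by \code{\link{write_activation}}.
#' @export
read_activation <- function(path) {
  vol <- read_volume(path)
  if (!identical(vol$role, "activation")) stop("not an activation volume")
  activation_map(vol$values, stim_start = -Inf)
}

#' Write curve control points as JSON
#' @param control_points n x 2 matrix.
#' @param path output path.
#' @param axis cylinder-axis index stored with the curve.
#' @export
write_curve <- function(control_points, path, axis = 3L) {
  jsonlite::write_json(list(axis = axis,
                            control_points = unname(as.matrix(control_points))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read curve control points from JSON
#' @param path JSON path.
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- obj$control_points
  if (!is.matrix(cp)) cp <- do.call(rbind, cp)
  list(control_points = cp, axis = as.integer(obj$axis))
}

#' Read a run configuration
#' @param path YAML path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a run configuration
#' @param config named list.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
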