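#' End-to-end reconstruction pipeline
#'
#' Convenience drivers chaining the stages: chamber isolation, shell
#' extraction, curve fitting, chart construction, texture placement and
#' network projection, then coupled-model assembly and simulation.  The same
#' drivers back the command-line interface.
#'
#' @name pipeline
NULL

#' Run the reconstruction (map) stage
#'
#' @param phase a \code{phase_field}.
#' @param chamber_seed c(i, j, k) cavity seed voxel.
#' @param control_points approximating-curve control points (planar physical
#'   coordinates), e.g. from \code{\link{synth_curve_for}}.
#' @param network a \code{network_image}.
#' @param config named list of stage parameters: \code{kernel_radius},
#'   \code{tissue_threshold}, \code{cavity_threshold}, \code{chart}
#'   (\code{n_seeds}, \code{quadrature_n}, \code{max_extent_vox},
#'   \code{bounds_margin_vox}), \code{placement} (\code{full_wrap},
#'   \code{axial_margin_vox}, or explicit \code{a}, \code{b}, \code{c},
#'   \code{d}).
#' @return list with \code{chamber}, \code{shell}, \code{curve},
#'   \code{field}, \code{chart}, \code{rect}, \code{projected}.
#' @export
map_network <- function(phase, chamber_seed, control_points, network,
                        config = list()) {
  cfg <- utils::modifyList(list(
    kernel_radius = 3, tissue_threshold = 0.5, cavity_threshold = 0.5,
    chart = list(n_seeds = 256L, quadrature_n = 1024L,
                 max_extent_vox = NULL, bounds_margin_vox = 4L),
    placement = list(full_wrap = TRUE, axial_margin_vox = 2L)), config)
  h <- phase$spacing
  ax <- split_axes(phase$axis)
  chamber <- suppressWarnings(
    isolate_chamber(phase, chamber_seed, cfg$cavity_threshold))
  shell <- extract_shell(phase, chamber, cfg$kernel_radius, cfg$tissue_threshold)
  curve <- fit_closed_spline(control_points)
  # field bounds: the full planar extent of the grid plus a margin
  m <- cfg$chart$bounds_margin_vox * h
  np <- phase$dim[ax$planar]
  bounds <- c(-m, np[1] * h + m, -m, np[2] * h + m)
  field <- precompute_field_grid(curve, bounds, h,
                                 quadrature_n = cfg$chart$quadrature_n)
  # chart must reach every shell voxel's planar footprint
  shell_ijk <- arrayInd(which(shell$flags), phase$dim)
  pl <- cbind((shell_ijk[, ax$planar[1]] - 0.5) * h,
              (shell_ijk[, ax$planar[2]] - 0.5) * h)
  if (is.null(cfg$chart$max_extent_vox)) {
    cs <- curve_samples(curve, 512)
    dmax <- 0
    for (lo in seq(1, nrow(pl), by = 4096)) {
      hi <- min(lo + 4095, nrow(pl))
      D <- outer(pl[lo:hi, 1], cs$pts[, 1], "-")^2 +
           outer(pl[lo:hi, 2], cs$pts[, 2], "-")^2
      dmax <- max(dmax, sqrt(max(do.call(pmin, as.data.frame(D)))))
    }
    max_extent <- dmax + 3 * h
  } else max_extent <- cfg$chart$max_extent_vox * h
  chart <- suppressWarnings(
    build_chart(field, n_seeds = cfg$chart$n_seeds, step = h / 2,
                max_extent = max_extent))
  zr <- range((shell_ijk[, ax$axial] - 0.5) * h)
  pm <- cfg$placement
  trim <- if (is.null(pm$axial_trim_frac)) 0 else pm$axial_trim_frac
  zr <- zr + c(+1, -1) * trim * diff(zr)  # keep off closed pole caps
  rect <- if (!is.null(pm[["a"]])) placement_rect(pm[["a"]], pm[["b"]], pm[["c"]], pm[["d"]])
          else placement_rect(0, curve$L,
                              zr[1] - pm$axial_margin_vox * h,
                              zr[2] + pm$axial_margin_vox * h)
  projected <- project_network(chart, rect, network, shell, phase)
  list(chamber = chamber, shell = shell, curve = curve, field = field,
       chart = chart, rect = rect, projected = projected)
}

#' Build and run one coupled model on a mapped fixture
#'
#' @param phase the \code{phase_field}.
#' @param mapped a \code{\link{map_network}} result.
#' @param network the \code{network_image}.
#' @param model "3d3d" or "3d2d".
#' @param ep_config electrophysiology overrides (see \code{\link{build_3d3d}}).
#' @param t_end simulation horizon (ms).
#' @param ... passed to \code{\link{run_simulation}}.
#' @return the \code{\link{run_simulation}} result plus the built model.
#' @export
simulate_model <- function(phase, mapped, network, model = c("3d3d", "3d2d"),
                           ep_config = list(), t_end = 200, ...) {
  model <- match.arg(model)
  built <- if (model == "3d3d") {
    build_3d3d(phase, mapped$shell, mapped$projected, ep_config)
  } else {
    build_3d2d(phase, mapped$shell, mapped$chart, mapped$rect, network,
               ep_config, projected = mapped$projected)
  }
  cfg <- built$config
  stim_radius <- if (is.null(cfg$stim_radius)) 0.4 else cfg$stim_radius
  proto <- apply_stimulus_protocol(built$purkinje,
                                   bundle_branch_region(built, stim_radius),
                                   amplitude = cfg$stim_amplitude,
                                   duration = cfg$stim_duration,
                                   start = cfg$stim_start)
  res <- run_simulation(built, proto, t_end, ...)
  res$model <- built
  res
}
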