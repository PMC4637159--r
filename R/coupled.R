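#' Coupled ventricle-Purkinje models
#'
#' Two constructions couple the excitable ventricle to its Purkinje network:
#' \describe{
#'   \item{3D-3D}{both systems are voxel domains on the same grid; the
#'     Purkinje domain is the projected network mask (diffusing only within
#'     itself) and the two systems exchange current at the coupling-site
#'     voxels.}
#'   \item{3D-2D}{the ventricles stay three-dimensional while the Purkinje
#'     network is solved on its own 2D pixel raster (one node per texture
#'     pixel, physical spacing from the placement rectangle); coupling links
#'     each 2D site pixel with its corresponding shell voxel under the
#'     texture map.}
#' }
#' Each time step has two phases: both domains advance one monodomain step
#' independently, then every coupled node pair exchanges current
#' symmetrically, v_v += dt g_c (v_p - v_v) and v_p += dt g_c (v_v - v_p),
#' computed from the phase-1 values so the pairwise sum is conserved.
#'
#' @name coupled
NULL

default_ep_config <- function() {
  list(D0 = 0.001, ratio = 20, g_c = 10, dt = NULL, tissue_threshold = 0.5,
       v_thresh = 0.5, membrane = membrane_params(),
       stim_amplitude = 2, stim_duration = 1, stim_start = 0,
       stim_radius = 0.4)
}

resolve_ep_config <- function(ep_config) {
  cfg <- utils::modifyList(default_ep_config(), ep_config)
  if (!inherits(cfg$membrane, "membrane_params"))
    cfg$membrane <- do.call(membrane_params, as.list(cfg$membrane))
  cfg
}

# dt defaulting: 80% of the tightest stability bound across domains.
resolve_dt <- function(cfg, domains) {
  if (!is.null(cfg$dt)) return(cfg$dt)
  0.8 * min(vapply(domains, stability_dt, numeric(1)))
}

#' Assemble the 3D-3D coupled model
#'
#' @param phase the ventricular \code{phase_field}.
#' @param shell endocardial shell \code{voxel_mask}.
#' @param projected a \code{\link{project_network}} result with mapped sites.
#' @param ep_config named list overriding electrophysiology defaults
#'   (\code{D0}, \code{ratio}, \code{g_c}, \code{dt}, \code{tissue_threshold},
#'   \code{membrane}, stimulus settings).
#' @return an object of class \code{coupled_3d3d}.
#' @export
build_3d3d <- function(phase, shell, projected, ep_config = list()) {
  cfg <- resolve_ep_config(ep_config)
  if (!any(projected$voxels$flags)) stop("projected network is empty")
  if (nrow(projected$site_voxels) == 0)
    stop("no mapped coupling sites: the ventricles could never activate")
  tissue <- phase$values >= cfg$tissue_threshold
  vent <- tissue_domain(tissue, phase = pmax(phase$values, 0) * tissue,
                        spacing = phase$spacing, diffusivity = cfg$D0,
                        params = cfg$membrane)
  purk <- tissue_domain(projected$voxels$flags, spacing = phase$spacing,
                        diffusivity = cfg$ratio * cfg$D0,
                        params = cfg$membrane, connectivity = "full")
  # the bundle-branch entry is a stimulus marker, not a Purkinje-myocardial
  # junction (the His bundle is electrically insulated from the myocardium)
  junctions <- projected$site_voxels[projected$site_voxels$bundle_branch == 0, ,
                                     drop = FALSE]
  if (nrow(junctions) == 0)
    stop("no mapped coupling sites: the ventricles could never activate")
  structure(list(ventricle = vent, purkinje = purk,
                 coupled_nodes = junctions,
                 g_c = cfg$g_c, config = cfg, phase = phase,
                 projected = projected),
            class = c("coupled_3d3d", "coupled_model"))
}

#' Assemble the 3D-2D coupled model
#'
#' @inheritParams build_3d3d
#' @param chart the \code{curvilinear_chart}.
#' @param rect the \code{placement_rect}.
#' @param network the \code{network_image}.
#' @param projected optional precomputed \code{\link{project_network}} result
#'   (recomputed when missing); supplies the site-to-voxel mapping, which is
#'   identical to the 3D-3D mapping rule.
#' @return an object of class \code{coupled_3d2d}.
#' @export
build_3d2d <- function(phase, shell, chart, rect, network, ep_config = list(),
                       projected = NULL) {
  cfg <- resolve_ep_config(ep_config)
  if (is.null(projected))
    projected <- project_network(chart, rect, network, shell, phase)
  if (nrow(projected$site_voxels) == 0)
    stop("no mapped coupling sites: the ventricles could never activate")
  tissue <- phase$values >= cfg$tissue_threshold
  vent <- tissue_domain(tissue, phase = pmax(phase$values, 0) * tissue,
                        spacing = phase$spacing, diffusivity = cfg$D0,
                        params = cfg$membrane)
  sp2 <- grid_spacing_2d(rect, network$W, network$H, phase$spacing)
  purk <- tissue_domain(network$mask, spacing = sp2,
                        diffusivity = cfg$ratio * cfg$D0,
                        params = cfg$membrane, connectivity = "full")
  # pair each mapped site's fiber pixel node with its shell voxel (the
  # bundle-branch marker is excluded: it is not a junction)
  sv <- projected$site_voxels[projected$site_voxels$bundle_branch == 0, ,
                              drop = FALSE]
  if (nrow(sv) == 0)
    stop("no mapped coupling sites: the ventricles could never activate")
  sites <- network$sites[match(sv$site_id, network$sites$site_id), ]
  px <- site_pixel_nodes(network, sites)
  pairs <- data.frame(site_id = sv$site_id, pixel_linear = px,
                      voxel_linear = sv$linear,
                      bundle_branch = sv$bundle_branch)
  structure(list(ventricle = vent, purkinje = purk, pairs = pairs,
                 g_c = cfg$g_c, config = cfg, phase = phase,
                 projected = projected, rect = rect, network = network),
            class = c("coupled_3d2d", "coupled_model"))
}

# Snap site pixel coordinates to their nearest fiber pixel and return the
# linear index into the W x H raster.
site_pixel_nodes <- function(network, sites) {
  fib <- which(network$mask, arr.ind = TRUE)
  vapply(seq_len(nrow(sites)), function(r) {
    d2 <- (fib[, 1] - 0.5 - sites$u1[r])^2 + (fib[, 2] - 0.5 - sites$u2[r])^2
    best <- which(d2 == min(d2))
    lin <- fib[best, 1] + (fib[best, 2] - 1L) * network$W
    min(lin)  # tie-break: lowest linear index
  }, numeric(1))
}

#' @export
print.coupled_model <- function(x, ...) {
  kind <- if (inherits(x, "coupled_3d3d")) "3D-3D" else "3D-2D"
  np <- if (inherits(x, "coupled_3d3d")) nrow(x$coupled_nodes) else nrow(x$pairs)
  cat(sprintf("%s coupled model: ventricle %d nodes, purkinje %d nodes, %d coupling sites, g_c = %.3g/ms\n",
              kind, x$ventricle$n_active, x$purkinje$n_active, np, x$g_c))
  invisible(x)
}

# Packed (0-based) coupling index pairs for the C++ stepper.
coupling_pairs_packed <- function(model) {
  packed_v <- array(0L, model$ventricle$dim)
  packed_v[model$ventricle$stencil$act] <- seq_len(model$ventricle$n_active)
  packed_p <- array(0L, model$purkinje$dim)
  packed_p[model$purkinje$stencil$act] <- seq_len(model$purkinje$n_active)
  if (inherits(model, "coupled_3d3d")) {
    lin <- model$coupled_nodes$linear
    ia <- packed_v[lin]; ib <- packed_p[lin]
  } else {
    ia <- packed_v[model$pairs$voxel_linear]
    ib <- packed_p[model$pairs$pixel_linear]
  }
  if (any(ia == 0) || any(ib == 0))
    stop("coupling site addresses an inactive node")
  list(a = ia - 1L, b = ib - 1L)
}

#' Bundle-branch stimulus nodes of a coupled model
#'
#' Returns the Purkinje-domain linear node indices flagged bundle_branch in
#' the site list (the His-bundle entry of the network).
#'
#' @param model a coupled model.
#' @export
bundle_branch_nodes <- function(model) {
  if (inherits(model, "coupled_3d3d")) {
    sv <- model$projected$site_voxels
    sel <- sv$bundle_branch > 0
    if (!any(sel)) stop("no bundle_branch-flagged site in the model")
    sv$linear[sel]
  } else {
    sel <- model$network$sites$bundle_branch > 0
    if (!any(sel)) stop("no bundle_branch-flagged site in the network")
    site_pixel_nodes(model$network, model$network$sites[sel, , drop = FALSE])
  }
}

#' Bundle-branch stimulus region
#'
#' All Purkinje-domain nodes within \code{radius} (cm) of a
#' bundle-branch-flagged node.  A point stimulus cannot ignite the
#' fast-conducting network (the diffusive load of the 20x diffusivity sets a
#' space constant of several millimeters), so the protocol excites the
#' proximal bundle region, as a physical His-bundle stimulus would.
#'
#' @param model a coupled model.
#' @param radius region radius in cm (default 0.4).
#' @return linear node indices in the Purkinje domain.
#' @export
bundle_branch_region <- function(model, radius = 0.4) {
  bb <- bundle_branch_nodes(model)
  dom <- model$purkinje
  act <- dom$stencil$act
  ijk <- arrayInd(act, dom$dim)
  ctr <- sweep(ijk - 0.5, 2, dom$spacing[seq_len(ncol(ijk))], `*`)
  bb_ijk <- arrayInd(bb, dom$dim)
  bb_ctr <- sweep(matrix(bb_ijk, ncol = ncol(ijk)) - 0.5, 2,
                  dom$spacing[seq_len(ncol(ijk))], `*`)
  keep <- rep(FALSE, nrow(ctr))
  for (r in seq_len(nrow(bb_ctr))) {
    d2 <- rowSums(sweep(ctr, 2, bb_ctr[r, ], `-`)^2)
    keep <- keep | d2 <= radius^2
  }
  act[keep]
}

#' Advance a coupled model one time step
#'
#' @param model a \code{coupled_3d3d} or \code{coupled_3d2d}.
#' @param states list with \code{ventricle} and \code{purkinje}
#'   \code{ep_state}s.
#' @param dt time step (ms), checked against both domains' stability bounds.
#' @param protocol optional \code{stim_protocol} on the Purkinje domain.
#' @return the advanced state pair.
#' @export
coupled_step <- function(model, states, dt, protocol = NULL) {
  check_dt(model$ventricle, dt)
  check_dt(model$purkinje, dt)
  pr <- coupling_pairs_packed(model)
  pdA <- pack_domain(model$ventricle, states$ventricle)
  pdB <- pack_domain(model$purkinje, states$purkinje, protocol)
  res <- cpp_run(pdA, pdB, pr$a, pr$b, model$g_c, dt,
                 states$ventricle$time, 1L, model$config$v_thresh,
                 TRUE, FALSE, 0L)
  sv <- states$ventricle; sp <- states$purkinje
  sv$v[model$ventricle$stencil$act] <- res$vA
  sv$h[model$ventricle$stencil$act] <- res$hA
  sp$v[model$purkinje$stencil$act] <- res$vB
  sp$h[model$purkinje$stencil$act] <- res$hB
  sv$time <- sp$time <- res$time
  list(ventricle = sv, purkinje = sp)
}

#' Run a coupled ventricle-Purkinje simulation
#'
#' Advances the coupled model to \code{t_end} (stopping early once every
#' active node in both domains has activated), recording the first upward
#' crossing of the activation threshold per node with sub-step linear
#' interpolation.
#'
#' @param model a coupled model.
#' @param protocol a \code{stim_protocol} on Purkinje-domain nodes (use
#'   \code{\link{bundle_branch_nodes}} for the physiological entry point), or
#'   NULL for an unstimulated run.
#' @param t_end final time (ms).
#' @param record "activation" (default) or "full" (also keeps voltage
#'   snapshots every \code{snapshot_every} steps).
#' @param dt time step; defaults to the model configuration (80 percent of
#'   the tightest stability bound when unset).
#' @param snapshot_every snapshot cadence in steps for \code{record = "full"}.
#' @param stop_when_activated stop as soon as both domains are fully
#'   activated (default TRUE).
#' @return list with \code{activation} (ventricle and purkinje
#'   \code{\link{activation_map}}s), \code{fraction_activated} (ventricular),
#'   \code{states}, \code{steps}, and snapshots when requested.
#' @export
run_simulation <- function(model, protocol, t_end,
                           record = c("activation", "full"), dt = NULL,
                           snapshot_every = 100L, stop_when_activated = TRUE) {
  record <- match.arg(record)
  cfg <- model$config
  dt <- if (is.null(dt)) resolve_dt(cfg, list(model$ventricle, model$purkinje)) else dt
  check_dt(model$ventricle, dt)
  check_dt(model$purkinje, dt)
  pr <- coupling_pairs_packed(model)
  states <- list(ventricle = ep_state(model$ventricle),
                 purkinje = ep_state(model$purkinje))
  pdA <- pack_domain(model$ventricle, states$ventricle)
  pdB <- pack_domain(model$purkinje, states$purkinje, protocol)
  n_steps <- ceiling(t_end / dt)
  res <- cpp_run(pdA, pdB, pr$a, pr$b, model$g_c, dt, 0, n_steps,
                 cfg$v_thresh, TRUE, stop_when_activated,
                 if (record == "full") as.integer(snapshot_every) else 0L)
  actV <- array(NA_real_, model$ventricle$dim)
  actV[model$ventricle$stencil$act] <- res$actA
  actP <- array(NA_real_, model$purkinje$dim)
  actP[model$purkinje$stencil$act] <- res$actB
  frac <- mean(!is.na(res$actA))
  stim_start <- if (is.null(protocol) || !length(protocol$start)) 0 else min(protocol$start)
  if (frac == 0 && !is.null(protocol))
    warning("no ventricular node activated before t_end")
  sv <- states$ventricle; sp <- states$purkinje
  sv$v[model$ventricle$stencil$act] <- res$vA
  sv$h[model$ventricle$stencil$act] <- res$hA
  sp$v[model$purkinje$stencil$act] <- res$vB
  sp$h[model$purkinje$stencil$act] <- res$hB
  sv$time <- sp$time <- res$time
  out <- list(activation = list(
                ventricle = activation_map(actV, threshold = cfg$v_thresh,
                                           stim_start = stim_start,
                                           mask = model$ventricle$mask),
                purkinje = activation_map(actP, threshold = cfg$v_thresh,
                                          stim_start = stim_start,
                                          mask = model$purkinje$mask)),
              fraction_activated = frac,
              states = list(ventricle = sv, purkinje = sp),
              steps = res$steps, dt = dt)
  if (record == "full") out$snapshots <- list(ventricle = res$snapsA,
                                              purkinje = res$snapsB)
  out
}
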