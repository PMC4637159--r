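#' Excitable-tissue electrophysiology
#'
#' Tissue excitability follows the monodomain reaction-diffusion equation
#'   dv/dt = -I_ion(v, h) + div(D grad v),
#' with the two-variable excitable membrane model of Mitchell and Schaeffer
#' supplying I_ion: a fast inward current h v^2 (1 - v) / tau_in, a linear
#' outward current v / tau_out, and a recovery gate h that closes above
#' v_gate with time constant tau_close and reopens below it with tau_open.
#' The diffusion operator is discretized with phase-field-weighted central
#' differences,
#'   dv_i = (1 / phi_i) sum_faces phi_face D_face (v_j - v_i) / h^2,
#' which imposes no-flux boundary conditions at tissue boundaries on a
#' regular grid and conserves the phase-weighted total of v exactly.
#' Purkinje tissue uses the same membrane model with diffusivity 20 times
#' the ventricular value, reproducing the much faster conduction of the
#' specialized fibers (conduction velocity scales with sqrt(D), so the
#' Purkinje wave travels about 4.5 times faster).
#'
#' @name ep
NULL

#' Membrane model parameters
#'
#' Defaults (ms units): tau_in = 0.3, tau_out = 6, tau_open = 120,
#' tau_close = 150, v_gate = 0.13.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms), all > 0.
#' @param v_gate dimensionless gate threshold in (0, 1).
#' @export
membrane_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                            tau_close = 150, v_gate = 0.13) {
  p <- list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
            tau_close = tau_close, v_gate = v_gate)
  if (any(unlist(p[1:4]) <= 0)) stop("all time constants must be positive")
  if (v_gate <= 0 || v_gate >= 1) stop("v_gate must lie in (0, 1)")
  structure(p, class = "membrane_params")
}

#' Membrane reaction rates
#'
#' @param v membrane variable (dimensionless).
#' @param h gate variable in [0, 1].
#' @param params a \code{\link{membrane_params}}.
#' @return list with \code{dv_reaction} and \code{dh} (1/ms).
#' @export
membrane_rates <- function(v, h, params = membrane_params()) {
  dv <- h * v^2 * (1 - v) / params$tau_in - v / params$tau_out
  dh <- ifelse(v < params$v_gate, (1 - h) / params$tau_open, -h / params$tau_close)
  list(dv_reaction = dv, dh = dh)
}

# Build the packed stencil for a masked 2D/3D grid: active-node indices,
# 0-based packed neighbor indices per direction, face conductances.
# connectivity "face" couples axis neighbors only (the bulk-tissue Laplacian);
# "full" couples the complete 8/26-neighborhood with conductance scaled by the
# squared center distance, the appropriate coupling for thin voxelized fiber
# networks whose chains run diagonally.
build_stencil <- function(mask, phase, spacing, diffusivity,
                          connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  dm <- dim(mask)
  ndim <- length(dm)
  if (!ndim %in% c(2L, 3L)) stop("mask must be a 2D or 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, ndim)
  if (any(spacing <= 0)) stop("spacing components must be positive")
  act <- which(mask)
  n <- length(act)
  if (n == 0) stop("domain mask is empty")
  packed <- array(0L, dm)
  packed[act] <- seq_len(n)
  Dnode <- if (length(diffusivity) == 1) rep(diffusivity, n) else diffusivity[act]
  phi <- phase[act]
  if (any(phi <= 0)) stop("active nodes must have positive phase value")
  strides <- cumprod(c(1L, dm[-ndim]))
  coords <- arrayInd(act, dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), ndim)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == "face") offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  ndirs <- nrow(offs)
  nb <- matrix(-1L, n, ndirs)
  g <- matrix(0, n, ndirs)
  for (col in seq_len(ndirs)) {
    off <- offs[col, ]
    ok <- rep(TRUE, n)
    for (ax in seq_len(ndim)) {
      if (off[ax] == 1L) ok <- ok & coords[, ax] < dm[ax]
      else if (off[ax] == -1L) ok <- ok & coords[, ax] > 1L
    }
    nidx <- act[ok] + as.integer(sum(off * strides))
    pj <- packed[nidx]
    has <- pj > 0L
    rows <- which(ok)[has]
    if (!length(rows)) next
    nb[rows, col] <- pj[has] - 1L
    phij <- phase[nidx[has]]
    Dj <- if (length(diffusivity) == 1) diffusivity else diffusivity[nidx[has]]
    dist2 <- sum((off * spacing)^2)
    g[rows, col] <- (phi[rows] + phij) / 2 * (Dnode[rows] + Dj) / 2 / dist2
  }
  list(act = act, nb = nb, g = g, inv_phi = 1 / phi, n = n, dim = dm,
       ndim = ndim, spacing = spacing, max_D = max(Dnode),
       connectivity = connectivity)
}

#' Construct a masked excitable tissue domain
#'
#' @param mask logical 2D or 3D array of active nodes (or a
#'   \code{voxel_mask}).
#' @param phase smoothed tissue indicator used for the no-flux boundary
#'   weighting; defaults to the sharp mask indicator.  Must be positive at
#'   every active node.
#' @param spacing node spacing (cm); scalar for uniform grids or per-axis
#'   vector (the 2D Purkinje raster typically carries nonuniform spacing).
#' @param diffusivity scalar or per-node array (cm^2/ms).  Isotropic only;
#'   anisotropic fiber tensors are not supported by this discretization.
#' @param params a \code{\link{membrane_params}}.
#' @param connectivity "face" (axis neighbors; the bulk-tissue default) or
#'   "full" (complete 8/26-neighborhood with distance-scaled conductances;
#'   used for thin voxelized fiber networks whose chains run diagonally).
#' @return an object of class \code{tissue_domain}.
#' @export
tissue_domain <- function(mask, phase = NULL, spacing, diffusivity = 0.001,
                          params = membrane_params(),
                          connectivity = c("face", "full")) {
  if (inherits(mask, "voxel_mask")) mask <- mask$flags
  if (is.null(phase)) phase <- mask + 0
  if (!identical(dim(phase), dim(mask))) stop("phase and mask dimensions differ")
  if (is.matrix(diffusivity) || (is.array(diffusivity) &&
      length(dim(diffusivity)) > length(dim(mask))))
    stop("anisotropic diffusion tensors are not supported; supply a scalar or per-node diffusivity")
  if (any(phase[mask] <= 0)) stop("mask must be a subset of {phase > 0}")
  st <- build_stencil(mask, phase, spacing, diffusivity, connectivity)
  structure(list(mask = mask, phase = phase, spacing = st$spacing,
                 diffusivity = diffusivity, params = params, stencil = st,
                 dim = st$dim, ndim = st$ndim, n_active = st$n),
            class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("tissue_domain: %s grid, %d active nodes, spacing (%s) cm, max D %.4g cm^2/ms\n",
              paste(x$dim, collapse = " x "), x$n_active,
              paste(signif(x$spacing, 4), collapse = ", "), x$stencil$max_D))
  invisible(x)
}

#' Explicit-diffusion stability bound for a domain
#'
#' Gershgorin bound on the assembled diffusion operator:
#' dt <= 1 / max_i (sum_d g_id / phi_i).  For a uniform face stencil this
#' equals the textbook bound min_axis(spacing^2) / (2 ndim max(D)); for the
#' full-neighborhood fiber stencil it accounts for the extra couplings.
#'
#' @param domain a \code{tissue_domain}.
#' @export
stability_dt <- function(domain) {
  st <- domain$stencil
  1 / max(rowSums(st$g) * st$inv_phi)
}

#' Initialize the membrane state of a domain
#'
#' @param domain a \code{tissue_domain}.
#' @param v0,h0 initial values (scalars or full arrays).
#' @export
ep_state <- function(domain, v0 = 0, h0 = 1) {
  va <- array(0, domain$dim); va[domain$stencil$act] <-
    if (length(v0) == 1) v0 else v0[domain$stencil$act]
  ha <- array(1, domain$dim); ha[domain$stencil$act] <-
    if (length(h0) == 1) h0 else h0[domain$stencil$act]
  structure(list(v = va, h = ha, time = 0), class = "ep_state")
}

#' Build a stimulus protocol
#'
#' Constant current of the given amplitude on the listed nodes over
#' [start, start + duration).  Protocols combine additively via
#' \code{rbind}-ing their schedules with \code{c()}.
#'
#' @param domain a \code{tissue_domain}.
#' @param site_nodes linear array indices of stimulated nodes (must be active).
#' @param amplitude current amplitude (1/ms, on the dimensionless v scale).
#' @param duration stimulus duration (ms).
#' @param start onset time (ms).
#' @export
apply_stimulus_protocol <- function(domain, site_nodes, amplitude = 2,
                                    duration = 1, start = 0) {
  site_nodes <- as.integer(site_nodes)
  if (!length(site_nodes)) stop("site_nodes must be nonempty")
  if (any(site_nodes < 1 | site_nodes > prod(domain$dim)))
    stop("stimulus targets inactive nodes (outside the grid)")
  packed <- array(0L, domain$dim); packed[domain$stencil$act] <- seq_len(domain$n_active)
  pk <- packed[site_nodes]
  if (any(pk == 0)) stop("stimulus targets inactive nodes")
  structure(list(node = pk - 1L,
                 amp = rep(amplitude, length.out = length(pk)),
                 start = rep(start, length.out = length(pk)),
                 dur = rep(duration, length.out = length(pk))),
            class = "stim_protocol")
}

#' Combine stimulus protocols
#' @param ... \code{stim_protocol} objects; currents add.
#' @export
combine_protocols <- function(...) {
  ps <- list(...)
  structure(list(node = unlist(lapply(ps, `[[`, "node")),
                 amp = unlist(lapply(ps, `[[`, "amp")),
                 start = unlist(lapply(ps, `[[`, "start")),
                 dur = unlist(lapply(ps, `[[`, "dur"))),
            class = "stim_protocol")
}

empty_protocol <- function() {
  structure(list(node = integer(0), amp = numeric(0), start = numeric(0),
                 dur = numeric(0)), class = "stim_protocol")
}

# Pack a domain + state (+ protocol) into the list the C++ stepper consumes.
pack_domain <- function(domain, state, protocol = NULL) {
  if (is.null(protocol)) protocol <- empty_protocol()
  st <- domain$stencil
  list(v = state$v[st$act], h = state$h[st$act], inv_phi = st$inv_phi,
       act = rep(NA_real_, st$n), nb = st$nb, g = st$g,
       pars = unlist(domain$params, use.names = FALSE),
       stim_node = protocol$node, stim_amp = protocol$amp,
       stim_start = protocol$start, stim_dur = protocol$dur, n = st$n)
}

check_dt <- function(domain, dt) {
  bound <- stability_dt(domain)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %.4g ms violates the explicit stability bound %.4g ms", dt, bound))
}

#' Advance a single monodomain one time step
#'
#' Forward-Euler update of v (reaction + stimulus + phase-field diffusion) and
#' exact-exponential update of the gate.  Inactive nodes are untouched.
#'
#' @param state an \code{ep_state}.
#' @param domain a \code{tissue_domain}.
#' @param dt time step (ms); checked against \code{\link{stability_dt}}.
#' @param stimulus optional \code{stim_protocol}.
#' @param reaction set FALSE to disable I_ion (diffusion-only stepping).
#' @return the advanced \code{ep_state}.
#' @export
monodomain_step <- function(state, domain, dt, stimulus = NULL, reaction = TRUE) {
  check_dt(domain, dt)
  pd <- pack_domain(domain, state, stimulus)
  res <- cpp_run(pd, list(n = 0L), integer(0), integer(0), 0, dt, state$time,
                 1L, 0.5, reaction, FALSE, 0L)
  out <- state
  out$v[domain$stencil$act] <- res$vA
  out$h[domain$stencil$act] <- res$hA
  out$time <- res$time
  out
}

#' Run a single monodomain to a final time
#'
#' @inheritParams monodomain_step
#' @param protocol a \code{stim_protocol} (or NULL).
#' @param t_end final time (ms).
#' @param v_thresh activation threshold (default 0.5, first upward crossing).
#' @param stop_when_activated stop early once every active node has activated.
#' @return list with the final \code{state}, an \code{activation} array
#'   (NA = never activated) and \code{steps} taken.
#' @export
run_monodomain <- function(domain, protocol = NULL, t_end, dt,
                           state = ep_state(domain), v_thresh = 0.5,
                           reaction = TRUE, stop_when_activated = FALSE) {
  check_dt(domain, dt)
  pd <- pack_domain(domain, state, protocol)
  n_steps <- ceiling((t_end - state$time) / dt)
  res <- cpp_run(pd, list(n = 0L), integer(0), integer(0), 0, dt, state$time,
                 n_steps, v_thresh, reaction, stop_when_activated, 0L)
  final <- state
  final$v[domain$stencil$act] <- res$vA
  final$h[domain$stencil$act] <- res$hA
  final$time <- res$time
  act <- array(NA_real_, domain$dim)
  act[domain$stencil$act] <- res$actA
  list(state = final, activation = act, steps = res$steps)
}

#' Nonuniform 2D Purkinje grid spacing from the texture placement
#'
#' The 2D network model puts one computational node on each texture pixel;
#' the physical spacing follows from the placement rectangle: with the
#' curvilinear bounds a, b, c, d expressed in ventricular-grid-index units
#' (physical length divided by the ventricular spacing), the spacings are
#' ((b - a) / W) and ((d - c) / H) times the ventricular spacing -- i.e. the
#' physical extent of the placement rectangle divided by the pixel count.
#'
#' @param rect a \code{\link{placement_rect}} (bounds in cm).
#' @param W,H texture pixel dimensions.
#' @param dv_spacing ventricular grid spacing (cm), the unit in which the
#'   bounds are re-expressed.
#' @return c(dx, dy) in cm.
#' @export
grid_spacing_2d <- function(rect, W, H, dv_spacing) {
  if (W <= 0 || H <= 0) stop("pixel dimensions must be positive")
  ab_idx <- (rect$b - rect$a) / dv_spacing
  cd_idx <- (rect$d - rect$c) / dv_spacing
  c(ab_idx / W * dv_spacing, cd_idx / H * dv_spacing)
}
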