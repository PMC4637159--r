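#' Deterministic synthetic fixtures
#'
#' No anatomical datasets or photograph digitizations ship with the package;
#' every stage is exercised on synthetic stand-ins: analytic phase-field
#' ventricles (\code{\link{synth_ventricles}}), toy branching network images
#' with terminal coupling sites emulating a digitized Purkinje branch, and
#' automatically fitted approximating curves.  All fixtures are bit-exactly
#' reproducible from their parameters and seed.
#'
#' @name fixtures
NULL

# Bresenham-style raster line between two pixel centers; returns ij matrix.
raster_line <- function(p0, p1) {
  n <- max(abs(p1 - p0)) + 1
  t <- seq(0, 1, length.out = max(n, 2))
  cbind(round(p0[1] + t * (p1[1] - p0[1])),
        round(p0[2] + t * (p1[2] - p0[2])))
}

#' Synthesize a branching network image
#'
#' Draws a recursive binary tree with one-pixel-wide strokes, rooted at the
#' top center of the raster (the bundle-branch entry) and branching downward
#' \code{depth} times; each of the 2^depth leaf tips carries a coupling site
#' and the root is flagged \code{bundle_branch}.  The drawn mask is a single
#' 8-connected component by construction.
#'
#' @param W,H raster dimensions in pixels.
#' @param depth branching depth (>= 1).
#' @param seed RNG seed for the small deterministic angle jitter.
#' @return a \code{network_image}.
#' @export
synth_network_image <- function(W = 96, H = 96, depth = 4, seed = 1L) {
  if (depth < 1) stop("depth must be at least 1")
  set.seed(seed)
  mask <- matrix(FALSE, W, H)
  leaves <- list()
  root <- c(round(W / 2), H - 1)
  trunk_len <- H / (depth + 2.5)
  stroke <- function(p0, p1) {
    seg <- raster_line(round(p0), round(p1))
    if (any(seg[, 1] < 1 | seg[, 1] > W | seg[, 2] < 1 | seg[, 2] > H))
      stop("tree exceeds the raster; enlarge W/H or reduce depth")
    mask[seg] <<- TRUE
  }
  grow <- function(p, angle, len, level) {
    tip <- p + len * c(sin(angle), -cos(angle))  # downward growth
    stroke(p, tip)
    if (level >= depth) {
      leaves[[length(leaves) + 1]] <<- tip
      return(invisible())
    }
    spread <- 0.62 * 0.92^level + stats::runif(1, -0.04, 0.04)
    grow(tip, angle - spread, len * 0.88, level + 1)
    grow(tip, angle + spread, len * 0.88, level + 1)
  }
  # trunk, then first split
  neck <- root + trunk_len * c(0, -1)
  stroke(root, neck)
  spread0 <- 0.62
  grow(neck, -spread0, trunk_len, 1)
  grow(neck, +spread0, trunk_len, 1)
  lv <- do.call(rbind, leaves)
  sites <- data.frame(site_id = seq_len(nrow(lv)),
                      u1 = pmin(pmax(lv[, 1], 0.5), W - 0.5) - 0.5,
                      u2 = pmin(pmax(lv[, 2], 0.5), H - 0.5) - 0.5,
                      bundle_branch = 0L)
  # site coordinates are pixel-center based: pixel (i, j) covers
  # [i-1, i] x [j-1, j], center (i - 0.5, j - 0.5)
  sites$u1 <- round(lv[, 1]) - 0.5
  sites$u2 <- round(lv[, 2]) - 0.5
  root_site <- data.frame(site_id = nrow(lv) + 1L, u1 = root[1] - 0.5,
                          u2 = root[2] - 0.5, bundle_branch = 1L)
  network_image(mask, rbind(sites, root_site))
}

#' Fit an approximating curve to a chamber cross-section
#'
#' Samples the chamber's mid-axis cross-section along 16 rays from its
#' centroid and places one control point per ray at the outermost chamber
#' pixel (plus half a voxel), producing a counterclockwise control polygon
#' that approximates -- and encloses -- the endocardial cross-section.
#'
#' @param phase a \code{phase_field} (supplies spacing and cylinder axis).
#' @param chamber a chamber \code{voxel_mask}.
#' @param n_rays number of centroid rays (default 16).
#' @return an n_rays x 2 matrix of control points (planar physical coords).
#' @export
synth_curve_for <- function(phase, chamber, n_rays = 16) {
  if (!any(chamber$flags)) stop("chamber mask is empty")
  ax <- split_axes(phase$axis)
  h <- phase$spacing
  ijk <- arrayInd(which(chamber$flags), phase$dim)
  kmid <- round(stats::median(ijk[, ax$axial]))
  sl <- ijk[ijk[, ax$axial] == kmid, , drop = FALSE]
  if (nrow(sl) < 8) stop("degenerate chamber cross-section at the mid-axis slice")
  px <- (sl[, ax$planar[1]] - 0.5) * h
  py <- (sl[, ax$planar[2]] - 0.5) * h
  ctr <- c(mean(px), mean(py))
  ang <- atan2(py - ctr[2], px - ctr[1])
  rad <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
  th <- seq(-pi, pi, length.out = n_rays + 1)[-(n_rays + 1)] + pi / n_rays
  cp <- matrix(0, n_rays, 2)
  for (q in seq_len(n_rays)) {
    dth <- abs(((ang - th[q] + pi) %% (2 * pi)) - pi)
    bin <- dth <= pi / n_rays + 1e-9
    if (!any(bin)) stop("degenerate chamber cross-section: empty angular bin")
    r <- max(rad[bin]) + 0.5 * h
    cp[q, ] <- ctr + r * c(cos(th[q]), sin(th[q]))
  }
  cp
}

#' Generate and write the frozen reference fixture
#'
#' Produces the complete end-to-end input bundle: an ellipsoid-pair phase
#' field on an 80^3 grid at 0.025 cm spacing, an exact-cylinder phase field,
#' a depth-4 branching network image (16 leaf coupling sites plus the
#' bundle-branch root) with its site CSV, approximating-curve control points
#' for both geometries, a run configuration, and a checksum manifest.
#'
#' @param seed fixture seed.
#' @param dir output directory (created if missing); when NULL nothing is
#'   written and the objects are returned only.
#' @return list with the in-memory objects, file paths (when written) and
#'   the checksum manifest.
#' @export
reference_fixture <- function(seed = 7L, dir = NULL) {
  ell <- synth_ventricles("ellipsoid_pair", seed = seed)
  cyl <- synth_ventricles("cylinder", seed = seed)
  net <- synth_network_image(W = 96, H = 96, depth = 4, seed = seed)
  ch_e <- suppressWarnings(isolate_chamber(ell$phase, ell$chamber_seeds[[1]]))
  ch_c <- suppressWarnings(isolate_chamber(cyl$phase, cyl$chamber_seeds[[1]]))
  cp_e <- synth_curve_for(ell$phase, ch_e)
  cp_c <- synth_curve_for(cyl$phase, ch_c)
  cfg <- list(
    spacing = ell$phase$spacing, axis = 3L, seed = as.integer(seed),
    chamber_seed = as.integer(ell$chamber_seeds[[1]]),
    chamber_seed_cylinder = as.integer(cyl$chamber_seeds[[1]]),
    kernel_radius = 3, tissue_threshold = 0.5, cavity_threshold = 0.5,
    chart = list(n_seeds = 256L, quadrature_n = 1024L,
                 max_extent_vox = 26L, bounds_margin_vox = 4L),
    placement = list(full_wrap = TRUE, axial_margin_vox = 0L,
                     axial_trim_frac = 0.15),
    ep = list(D0 = 0.001, ratio = 20, g_c = 10,
              stim_amplitude = 2, stim_duration = 1, stim_start = 0,
              v_thresh = 0.5,
              membrane = list(tau_in = 0.3, tau_out = 6, tau_open = 120,
                              tau_close = 150, v_gate = 0.13)),
    t_end = 200)
  manifest <- list(
    seed = as.integer(seed),
    ellipsoid_phase = digest::digest(ell$phase$values),
    cylinder_phase = digest::digest(cyl$phase$values),
    network_mask = digest::digest(net$mask),
    network_sites = digest::digest(net$sites),
    curve_ellipsoid = digest::digest(signif(cp_e, 12)),
    curve_cylinder = digest::digest(signif(cp_c, 12)))
  out <- list(ellipsoid = ell, cylinder = cyl, network = net,
              chamber_ellipsoid = ch_e, chamber_cylinder = ch_c,
              curve_ellipsoid = cp_e, curve_cylinder = cp_c,
              config = cfg, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      ellipsoid_phase = file.path(dir, "ellipsoid_phase.nii"),
      cylinder_phase = file.path(dir, "cylinder_phase.nii"),
      network_image = file.path(dir, "network.png"),
      network_sites = file.path(dir, "sites.csv"),
      curve_ellipsoid = file.path(dir, "curve_ellipsoid.json"),
      curve_cylinder = file.path(dir, "curve_cylinder.json"),
      config = file.path(dir, "run.yaml"),
      manifest = file.path(dir, "manifest.json"))
    write_volume(ell$phase, paths$ellipsoid_phase)
    write_volume(cyl$phase, paths$cylinder_phase)
    write_network(net, paths$network_image, paths$network_sites)
    write_curve(cp_e, paths$curve_ellipsoid)
    write_curve(cp_c, paths$curve_cylinder)
    cfg$paths <- lapply(paths, normalizePath, mustWork = FALSE)
    write_config(cfg, paths$config)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
    out$paths <- paths
    out$config <- cfg
  }
  out
}
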