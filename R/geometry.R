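#' Phase-field ventricular geometry
#'
#' Ventricular anatomy enters as a phase field: a smooth scalar volume in
#' [0, 1] that is 1 inside tissue and 0 outside, with a thin smoothed
#' transition at the boundary.  The phase field serves two purposes: it
#' defines the tissue mask (phi >= threshold) and it imposes no-flux boundary
#' conditions in the monodomain solver without requiring a boundary-fitted
#' mesh.  The chamber cavity is isolated by flood fill below a threshold, and
#' the endocardial layer is extracted as a thin shell by convolving the
#' chamber indicator with a spherical kernel, keeping entries greater than 1,
#' and intersecting with tissue.
#'
#' @name geometry
NULL

#' Construct a phase field
#'
#' @param values 3D numeric array with values in [0, 1] (1 = tissue interior).
#' @param spacing uniform voxel edge length (cm).
#' @param axis which principal grid axis (1, 2 or 3) plays the cylinder axis;
#'   the chart plane is spanned by the other two axes in order.
#' @return an object of class \code{phase_field}.
#' @export
phase_field <- function(values, spacing, axis = 3L) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 1) stop("phase-field values must lie in [0, 1]")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  structure(list(values = values, spacing = spacing, axis = axis,
                 dim = dim(values)),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("phase_field: %d x %d x %d, spacing %.4g cm, cylinder axis %d\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, x$axis))
  invisible(x)
}

#' Construct a voxel mask congruent with a phase field
#'
#' @param flags logical 3D array.
#' @param role one of "chamber", "shell", "tissue", "network".
#' @param spacing voxel spacing carried along for convenience.
#' @export
voxel_mask <- function(flags, role = c("chamber", "shell", "tissue", "network"),
                       spacing = NULL) {
  role <- match.arg(role)
  if (!is.logical(flags) || length(dim(flags)) != 3)
    stop("flags must be a logical 3D array")
  structure(list(flags = flags, role = role, dim = dim(flags),
                 spacing = spacing),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask (%s): %d x %d x %d, %d voxels set\n",
              x$role, x$dim[1], x$dim[2], x$dim[3], sum(x$flags)))
  invisible(x)
}

# 6-connected flood fill over a logical array from a seed voxel.
flood_fill6 <- function(open, seed_idx) {
  dm <- dim(open)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  visited <- array(FALSE, dm)
  frontier <- seed_idx
  visited[frontier] <- TRUE
  sxy <- nx * ny
  repeat {
    # neighbor linear indices in the 6 axis directions, with face guards
    k0 <- frontier - 1L
    ii <- k0 %% nx
    jj <- (k0 %/% nx) %% ny
    kk <- k0 %/% sxy
    nbrs <- c(frontier[ii > 0] - 1L, frontier[ii < nx - 1] + 1L,
              frontier[jj > 0] - nx, frontier[jj < ny - 1] + nx,
              frontier[kk > 0] - sxy, frontier[kk < nz - 1] + sxy)
    nbrs <- unique(nbrs)
    nbrs <- nbrs[open[nbrs] & !visited[nbrs]]
    if (!length(nbrs)) break
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  visited
}

#' Isolate a ventricular chamber cavity
#'
#' Flood-fills the 6-connected component of \{phi < threshold\} containing the
#' seed voxel.  The default threshold is phi = 0.5.
#'
#' @param phase a \code{phase_field}.
#' @param seed_voxel integer c(i, j, k) index inside the cavity.
#' @param threshold cavity threshold (default 0.5).
#' @return a \code{voxel_mask} with role "chamber".
#' @export
isolate_chamber <- function(phase, seed_voxel, threshold = 0.5) {
  sv <- as.integer(seed_voxel)
  if (phase$values[sv[1], sv[2], sv[3]] >= threshold)
    stop("seed voxel lies in tissue (phase >= threshold), not in the cavity")
  open <- phase$values < threshold
  seed_lin <- sv[1] + (sv[2] - 1L) * phase$dim[1] +
    (sv[3] - 1L) * phase$dim[1] * phase$dim[2]
  comp <- flood_fill6(open, seed_lin)
  dm <- phase$dim
  touches <- any(comp[1, , ]) || any(comp[dm[1], , ]) ||
    any(comp[, 1, ]) || any(comp[, dm[2], ]) ||
    any(comp[, , 1]) || any(comp[, , dm[3]])
  if (touches)
    warning("chamber component touches the array boundary; cavity may be open")
  voxel_mask(comp, "chamber", spacing = phase$spacing)
}

# Voxelized indicator of a ball of given radius (in voxels); odd-sized array.
spherical_kernel <- function(radius_vox) {
  r <- ceiling(radius_vox)
  ax <- (-r):r
  g <- expand.grid(ax, ax, ax)
  k <- array(as.numeric(g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= radius_vox^2),
             dim = rep(2L * r + 1L, 3))
  k
}

# 3D convolution by FFT, same-size output, zero padding.  Inputs are
# indicator arrays, so the exact result is integer-valued; rounding removes
# FFT noise.
conv3_fft <- function(a, kern) {
  da <- dim(a); dk <- dim(kern)
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[1:da[1], 1:da[2], 1:da[3]] <- a
  pk <- array(0, dp); pk[1:dk[1], 1:dk[2], 1:dk[3]] <- kern
  conv <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  conv[off[1] + 1:da[1], off[2] + 1:da[2], off[3] + 1:da[3]]
}

#' Extract the thin endocardial shell
#'
#' Convolves the chamber indicator with a voxelized spherical kernel, keeps
#' entries strictly greater than 1 (an expanded volume overlapping the wall by
#' roughly the kernel radius), and intersects with tissue
#' \{phi >= tissue_threshold\}.
#'
#' @param phase a \code{phase_field}.
#' @param chamber a chamber \code{voxel_mask}.
#' @param kernel_radius kernel radius in voxels (>= 1; default 3).
#' @param tissue_threshold tissue threshold on the phase field (default 0.5).
#' @return a \code{voxel_mask} with role "shell".
#' @export
extract_shell <- function(phase, chamber, kernel_radius = 3,
                          tissue_threshold = 0.5) {
  if (kernel_radius < 1) stop("kernel_radius must be at least 1 voxel")
  if (!any(chamber$flags)) {
    warning("empty chamber mask; returning empty shell")
    return(voxel_mask(array(FALSE, phase$dim), "shell", spacing = phase$spacing))
  }
  conv <- round(conv3_fft(chamber$flags + 0, spherical_kernel(kernel_radius)))
  shell <- (conv > 1) & (phase$values >= tissue_threshold)
  if (!any(shell)) warning("shell is empty; kernel may not reach the tissue")
  # warn when the shell swallowed the full wall thickness
  tissue <- phase$values >= tissue_threshold
  if (sum(shell) > 0.95 * sum(tissue))
    warning("kernel radius exceeds wall thickness; shell covers nearly the full wall")
  voxel_mask(shell, "shell", spacing = phase$spacing)
}

# Smooth indicator via tanh of a signed-distance-like level function.
# d < 0 inside tissue; width is the full transition width in cm.
tanh_profile <- function(d, width) 0.5 * (1 - tanh(2 * d / width))

#' Synthesize phase-field ventricle fixtures
#'
#' Deterministic analytic geometries standing in for real anatomical volumes:
#' \describe{
#'   \item{hollow_sphere}{spherical wall between inner and outer radii.}
#'   \item{cylinder}{an annular wall spanning the full axial extent, whose
#'     cavity is an exact right circular cylinder, so a circular approximating
#'     curve incurs zero mapping distortion.}
#'   \item{ellipsoid_pair}{two ellipsoidal cavities with walls, side by side
#'     and sharing a septal wall, emulating a two-chamber ventricle pair.}
#' }
#'
#' @param kind geometry kind.
#' @param params named list of geometric parameters; see Details.  All lengths
#'   in cm.  Defaults give desk-scale fixtures on an approximately 80^3 grid
#'   at 0.025 cm spacing.
#' @param seed RNG seed recorded with the fixture (the geometries themselves
#'   are analytic and deterministic).
#' @return a list with \code{phase} (a \code{phase_field}) and
#'   \code{chamber_seeds} (list of c(i, j, k) cavity seed voxels).
#' @details Parameters: \code{n} grid size (scalar or length 3),
#'   \code{spacing}, \code{smooth_width} (phase transition width, default 2
#'   voxels); hollow_sphere: \code{r_inner}, \code{r_outer}; cylinder:
#'   \code{r_cavity}, \code{r_outer}; ellipsoid_pair: \code{cavity_semi}
#'   (length-3 cavity semi-axes), \code{wall} (wall thickness),
#'   \code{separation} (center-to-center x offset).
#' @export
synth_ventricles <- function(kind = c("ellipsoid_pair", "cylinder", "hollow_sphere"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(switch(kind,
    hollow_sphere = list(n = 64L, spacing = 0.025, r_inner = 0.35, r_outer = 0.55),
    cylinder = list(n = 64L, spacing = 0.025, r_cavity = 0.45, r_outer = 0.65),
    ellipsoid_pair = list(n = 80L, spacing = 0.025,
                          cavity_semi = c(0.38, 0.33, 0.55),
                          wall = 0.125, separation = 0.80)),
    params)
  n <- if (length(p$n) == 1) rep(as.integer(p$n), 3) else as.integer(p$n)
  h <- p$spacing
  smooth_w <- if (is.null(p$smooth_width)) 2 * h else p$smooth_width
  ctr <- n / 2 * h  # physical domain center (voxel centers at (i - 0.5) h)
  xs <- ((1:n[1]) - 0.5) * h; ys <- ((1:n[2]) - 0.5) * h; zs <- ((1:n[3]) - 0.5) * h
  X <- array(rep(xs, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)
  vox_of <- function(pt) pmin(pmax(round(pt / h + 0.5), 1L), n)

  if (kind == "hollow_sphere") {
    if (p$r_inner <= 0 || p$r_outer <= p$r_inner) stop("need 0 < r_inner < r_outer")
    r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
    d <- pmax(p$r_inner - r, r - p$r_outer)  # negative inside the wall
    phi <- tanh_profile(d, smooth_w)
    seeds <- list(vox_of(ctr))
  } else if (kind == "cylinder") {
    if (p$r_cavity <= 0 || p$r_outer <= p$r_cavity) stop("need 0 < r_cavity < r_outer")
    rho <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
    d <- pmax(p$r_cavity - rho, rho - p$r_outer)
    phi <- tanh_profile(d, smooth_w)
    seeds <- list(vox_of(ctr))
  } else {
    cs <- p$cavity_semi
    if (any(cs <= 0) || p$wall <= 0) stop("degenerate ellipsoid parameters")
    c1 <- ctr + c(-p$separation / 2, 0, 0)
    c2 <- ctr + c(+p$separation / 2, 0, 0)
    if (p$separation <= 2 * cs[1] - p$wall)
      stop("cavities overlap: separation too small for the given semi-axes")
    # approximate signed distance to an ellipsoid surface via the normalized
    # level function scaled by the local gradient norm
    elld <- function(cx, semi) {
      q <- sqrt(((X - cx[1]) / semi[1])^2 + ((Y - cx[2]) / semi[2])^2 +
                  ((Z - cx[3]) / semi[3])^2)
      (q - 1) * min(semi)  # conservative length scale
    }
    din1 <- elld(c1, cs); din2 <- elld(c2, cs)
    dout1 <- elld(c1, cs + p$wall); dout2 <- elld(c2, cs + p$wall)
    # tissue = union of the two walls = (union of outers) minus (union of cavities)
    d_out <- pmin(dout1, dout2)        # negative inside either outer ellipsoid
    d_in  <- pmin(din1, din2)          # negative inside either cavity
    d <- pmax(d_out, -d_in)            # negative exactly in the wall
    phi <- tanh_profile(d, smooth_w)
    seeds <- list(vox_of(c1), vox_of(c2))
  }
  list(phase = phase_field(phi, h, axis = 3L), chamber_seeds = seeds,
       kind = kind, params = p, seed = as.integer(seed))
}
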