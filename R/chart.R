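#' Curvilinear cylinder chart
#'
#' The chart generalizes polar coordinates to an arbitrary smooth closed curve
#' C.  A vector field V is formed at every planar point as the inverse-distance
#' weighted average of the curve's outward normals,
#'   V(x) = [integral N(s) / d(x, C(s)) ds] / [integral 1 / d(x, C(s)) ds],
#' which converges to N(s) as x approaches C(s).  Integrating dx/dt = V(x)
#' forward (outward) and backward (inward) from seeds on C traces trajectories
#' along which the arc-length coordinate s is constant; interpolating s and the
#' signed path-length coordinate t over all trajectory points yields an
#' invertible curvilinear coordinate system (s, t) covering the charted region.
#' Texture values placed on the approximating cylinder are constant along
#' trajectories, which is what carries a flat network image onto a curved
#' endocardial surface.
#'
#' @name chart
NULL

# Direct quadrature of the normal-average field at arbitrary points.
# Periodic trapezoid rule (= equal-weight mean over equally spaced s samples).
# points: m x 2.  Returns m x 2 field values; on-curve points get N(nearest s).
normal_average_quadrature <- function(curve, points, quadrature_n = 1024,
                                      on_curve_eps = 1e-9) {
  qs <- curve_samples(curve, quadrature_n)
  m <- nrow(points)
  out <- matrix(0, m, 2)
  for (i in seq_len(m)) {
    dx <- points[i, 1] - qs$pts[, 1]
    dy <- points[i, 2] - qs$pts[, 2]
    d <- sqrt(dx * dx + dy * dy)
    if (min(d) < on_curve_eps) {
      out[i, ] <- qs$normals[which.min(d), ]
    } else {
      w <- 1 / d
      sw <- sum(w)
      out[i, ] <- c(sum(qs$normals[, 1] * w), sum(qs$normals[, 2] * w)) / sw
    }
  }
  out
}

#' Precompute the normal-average vector field on a regular grid
#'
#' Evaluates the field by periodic-trapezoid quadrature over the curve at every
#' node of a regular planar grid; later queries (\code{\link{field_at}},
#' trajectory integration) bilinearly interpolate this grid.  Grid nodes lying
#' on the curve (within numerical epsilon) are assigned the limiting value
#' N(s) of the nearest curve point.
#'
#' @param curve a \code{\link{fit_closed_spline}} result.
#' @param bounds numeric c(xmin, xmax, ymin, ymax); must enclose the curve.
#' @param spacing grid spacing (cm); typically the ventricular voxel spacing.
#' @param quadrature_n number of curve quadrature nodes (default 1024).
#' @return an object of class \code{normal_average_field}.
#' @export
precompute_field_grid <- function(curve, bounds, spacing, quadrature_n = 1024) {
  if (spacing <= 0) stop("spacing must be positive")
  if (bounds[1] > min(curve$pts[, 1]) || bounds[2] < max(curve$pts[, 1]) ||
      bounds[3] > min(curve$pts[, 2]) || bounds[4] < max(curve$pts[, 2]))
    stop("bounds must enclose the curve")
  xs <- seq(bounds[1], bounds[2], by = spacing)
  ys <- seq(bounds[3], bounds[4], by = spacing)
  qs <- curve_samples(curve, quadrature_n)
  nx <- length(xs); ny <- length(ys)
  Vx <- matrix(0, nx, ny)
  Vy <- matrix(0, nx, ny)
  # vectorized over the grid, chunked in y-columns to bound memory
  for (j in seq_len(ny)) {
    dx <- outer(xs, qs$pts[, 1], "-")
    dy <- ys[j] - matrix(qs$pts[, 2], nx, quadrature_n, byrow = TRUE)
    d <- sqrt(dx * dx + dy * dy)
    onc <- d < 1e-9
    if (any(onc)) d[onc] <- NA  # handled below
    w <- 1 / d
    sw <- rowSums(w)
    Vx[, j] <- (w %*% qs$normals[, 1]) / sw
    Vy[, j] <- (w %*% qs$normals[, 2]) / sw
    if (any(onc)) {
      rows <- unique(which(onc, arr.ind = TRUE)[, 1])
      for (r in rows) {
        k <- which.min(replace(d[r, ], is.na(d[r, ]), 0))
        k <- which(onc[r, ])[1]
        Vx[r, j] <- qs$normals[k, 1]
        Vy[r, j] <- qs$normals[k, 2]
        message(sprintf("grid node (%.4g, %.4g) lies on the curve; stored its limit value N(s)",
                        xs[r], ys[j]))
      }
    }
  }
  # near-curve refinement: within a few sample spacings of the curve the
  # 1/d integrand peaks narrowly and the base rule under-resolves it;
  # re-evaluate those nodes with an 8x finer quadrature
  near_lim <- 6 * curve$L / quadrature_n
  grid_pts <- cbind(rep(xs, ny), rep(ys, each = nx))
  dense <- curve_samples(curve, max(8192L, 2L * quadrature_n))
  dmin <- rep(Inf, nrow(grid_pts))
  imin <- rep(1L, nrow(grid_pts))
  for (lo in seq(1, nrow(grid_pts), by = 2048)) {
    hi <- min(lo + 2047, nrow(grid_pts))
    D <- outer(grid_pts[lo:hi, 1], dense$pts[, 1], "-")^2 +
         outer(grid_pts[lo:hi, 2], dense$pts[, 2], "-")^2
    jm <- max.col(-D, ties.method = "first")
    imin[lo:hi] <- jm
    dmin[lo:hi] <- sqrt(D[cbind(seq_len(hi - lo + 1), jm)])
  }
  on_curve <- dmin < 1e-8
  if (any(on_curve)) {
    Vx[on_curve] <- dense$normals[imin[on_curve], 1]
    Vy[on_curve] <- dense$normals[imin[on_curve], 2]
    message(sprintf("%d grid node(s) lie on the curve; stored the limit value N(s)",
                    sum(on_curve)))
  }
  near <- which(!on_curve & dmin < near_lim)
  if (length(near)) {
    # refined quadrature resolving the 1/d peak: the periodic trapezoid rule
    # converges like exp(-2 pi n d / L), so n is scaled to the node distance
    n_ref <- 2^pmin(ceiling(log2(16 * curve$L / pmax(dmin[near], 1e-4))), 17)
    for (nn in unique(n_ref)) {
      sel <- near[n_ref == nn]
      ref <- normal_average_quadrature(curve, grid_pts[sel, , drop = FALSE], nn)
      Vx[sel] <- ref[, 1]
      Vy[sel] <- ref[, 2]
    }
  }
  structure(list(curve = curve, xs = xs, ys = ys, Vx = Vx, Vy = Vy,
                 bounds = c(xs[1], xs[nx], ys[1], ys[ny]), spacing = spacing,
                 quadrature_n = quadrature_n),
            class = "normal_average_field")
}

#' @export
print.normal_average_field <- function(x, ...) {
  cat(sprintf("normal_average_field: %d x %d grid, spacing %.4g, %d quadrature nodes\n",
              length(x$xs), length(x$ys), x$spacing, x$quadrature_n))
  invisible(x)
}

# Bilinear interpolation of the stored field grid at points (m x 2).
bilinear_field <- function(field, points) {
  x <- points[, 1]; y <- points[, 2]
  xs <- field$xs; ys <- field$ys
  fx <- (x - xs[1]) / field$spacing
  fy <- (y - ys[1]) / field$spacing
  i <- pmin(pmax(floor(fx), 0), length(xs) - 2)
  j <- pmin(pmax(floor(fy), 0), length(ys) - 2)
  ax <- fx - i; ay <- fy - j
  i1 <- i + 1L; j1 <- j + 1L  # 1-based lower corner
  n <- length(xs)
  idx <- function(ii, jj) ii + (jj - 1L) * n
  w00 <- (1 - ax) * (1 - ay); w10 <- ax * (1 - ay)
  w01 <- (1 - ax) * ay;       w11 <- ax * ay
  vx <- w00 * field$Vx[idx(i1, j1)] + w10 * field$Vx[idx(i1 + 1L, j1)] +
        w01 * field$Vx[idx(i1, j1 + 1L)] + w11 * field$Vx[idx(i1 + 1L, j1 + 1L)]
  vy <- w00 * field$Vy[idx(i1, j1)] + w10 * field$Vy[idx(i1 + 1L, j1)] +
        w01 * field$Vy[idx(i1, j1 + 1L)] + w11 * field$Vy[idx(i1 + 1L, j1 + 1L)]
  cbind(vx, vy)
}

#' Query the normal-average field
#'
#' By default interpolates the precomputed grid bilinearly (the production
#' path); \code{exact = TRUE} re-evaluates the defining quadrature at the
#' query points (slow, used for verification), returning the limit value
#' N(s) for on-curve points.
#'
#' @param field a \code{normal_average_field}.
#' @param point numeric length-2 point or m x 2 matrix.
#' @param exact evaluate the curve quadrature directly instead of
#'   interpolating the grid.
#' @return m x 2 matrix of field vectors.
#' @export
field_at <- function(field, point, exact = FALSE) {
  p <- if (is.null(dim(point))) matrix(point, 1, 2) else as.matrix(point)
  b <- field$bounds
  bad <- p[, 1] < b[1] | p[, 1] > b[2] | p[, 2] < b[3] | p[, 2] > b[4]
  if (any(bad))
    stop(sprintf("point outside field bounds [%.4g, %.4g] x [%.4g, %.4g]",
                 b[1], b[2], b[3], b[4]))
  if (exact) normal_average_quadrature(field$curve, p, field$quadrature_n)
  else bilinear_field(field, p)
}

#' Export chart coordinate maps as volumes
#'
#' Writes \code{s_map} and \code{t_map} as single-slice volumes (NA encoded
#' as a large negative sentinel) with the chart metadata, for reuse across
#' runs.
#'
#' @param chart a \code{curvilinear_chart}.
#' @param dir output directory.
#' @export
export_chart <- function(chart, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- function(M) {
    M[is.na(M)] <- -1e30
    array(M, c(dim(M), 1L))
  }
  write_volume(enc(chart$s_map), file.path(dir, "s_map.nii"),
               spacing = chart$spacing)
  write_volume(enc(chart$t_map), file.path(dir, "t_map.nii"),
               spacing = chart$spacing)
  jsonlite::write_json(list(L = chart$wrap_length, n_seeds = chart$n_seeds,
                            step = chart$step, max_extent = chart$max_extent,
                            origin = c(chart$xs[1], chart$ys[1]),
                            spacing = chart$spacing),
                       file.path(dir, "chart_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

inside_bounds <- function(field, p, margin = 0) {
  b <- field$bounds
  p[, 1] >= b[1] + margin & p[, 1] <= b[2] - margin &
    p[, 2] >= b[3] + margin & p[, 2] <= b[4] - margin
}

# RK4 advance of many trajectories at once through the normalized field.
# pos: m x 2 active positions.  dir = +1 outward, -1 inward.
rk4_step_many <- function(field, pos, step, dir) {
  f <- function(p) {
    v <- bilinear_field(field, p)
    nrm <- sqrt(rowSums(v^2))
    nrm[nrm < 1e-12] <- Inf  # stagnation: zero velocity
    dir * v / nrm
  }
  k1 <- f(pos)
  k2 <- f(pos + step / 2 * k1)
  k3 <- f(pos + step / 2 * k2)
  k4 <- f(pos + step * k3)
  pos + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Integrate one branch (all seeds at once).  Returns list of recorded point
# matrices per step and a stagnation flag per seed.
integrate_branch <- function(field, start, step, max_extent, dir) {
  n_steps <- ceiling(max_extent / step)
  m <- nrow(start)
  pos <- start
  active <- rep(TRUE, m)
  stagn <- rep(FALSE, m)
  margin <- field$spacing  # stop before leaving the interpolable grid
  rec <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    if (!any(active)) { rec <- rec[seq_len(k - 1)]; break }
    newpos <- pos
    idx <- which(active)
    stepped <- rk4_step_many(field, pos[idx, , drop = FALSE], step, dir)
    disp <- sqrt(rowSums((stepped - pos[idx, , drop = FALSE])^2))
    halted <- disp < 1e-6 * step
    stagn[idx[halted]] <- TRUE
    out <- !inside_bounds(field, stepped, margin)
    keep <- !halted & !out
    newpos[idx, ] <- stepped
    active[idx[halted | out]] <- FALSE
    pos[idx[keep], ] <- stepped[keep, , drop = FALSE]
    if (any(keep))
      rec[[k]] <- cbind(newpos[idx[keep], 1], newpos[idx[keep], 2],
                        seed = idx[keep], t = rep(dir * k * step, sum(keep)))
  }
  list(points = do.call(rbind, rec), stagnated = stagn)
}

#' Integrate a single chart trajectory
#'
#' Traces the trajectory through the normal-average field seeded at C(s0):
#' backward in artificial time (inward, t < 0) and forward (outward, t > 0).
#' The field is normalized to unit magnitude during integration, so the step
#' is a path-length step and t is a signed path length; this reparameterization
#' leaves the traced path unchanged.  Inward branches stop when the field
#' stagnates (e.g. at the center of a circle); both branches stop at
#' \code{max_extent} or at the field grid boundary.
#'
#' @param field a \code{normal_average_field}.
#' @param s0 seed arc length in [0, L).
#' @param step path-length step (default: field grid spacing / 2).
#' @param max_extent maximum traced path length per branch.
#' @return a matrix with columns x, y, t ordered by increasing t, containing
#'   the seed point at t = 0; attribute \code{stagnated} flags a truncated
#'   inward branch.
#' @export
integrate_trajectory <- function(field, s0, step = field$spacing / 2,
                                 max_extent = 10 * field$spacing) {
  start <- curve_point(field$curve, s0)
  fw <- integrate_branch(field, start, step, max_extent, +1)
  bw <- integrate_branch(field, start, step, max_extent, -1)
  take_xyt <- function(b) if (is.null(b$points)) NULL else b$points[, c(1, 2, 4), drop = FALSE]
  pts <- rbind(take_xyt(bw),
               cbind(start[, 1], start[, 2], 0),
               take_xyt(fw))
  colnames(pts) <- c("x", "y", "t")
  pts <- pts[order(pts[, "t"]), , drop = FALSE]
  attr(pts, "stagnated") <- bw$stagnated[1] || fw$stagnated[1]
  pts
}

#' Build the curvilinear chart
#'
#' Integrates trajectories from \code{n_seeds} equally spaced arc lengths
#' s_k = k L / n_seeds, then assigns every field grid node an (s, t) pair by
#' inverse-distance weighting over its k = 4 nearest trajectory points.  The
#' s coordinate is interpolated through the unit-circle embedding
#' (cos 2 pi s / L, sin 2 pi s / L) so the s = 0/L branch cut leaves no seam.
#' Grid cells farther than two cells from every trajectory point stay
#' uncharted (NA) and are counted in \code{coverage_gaps}.
#'
#' @param field a \code{normal_average_field}.
#' @param n_seeds number of trajectory seeds (>= 16; default 256).
#' @param step trajectory path-length step.
#' @param max_extent maximum traced path length per branch.
#' @return an object of class \code{curvilinear_chart} with gridded
#'   \code{s_map} and \code{t_map} (NA = uncharted) on the field grid.
#' @export
build_chart <- function(field, n_seeds = 256, step = field$spacing / 2,
                        max_extent = 10 * field$spacing) {
  if (n_seeds < 16) stop("n_seeds must be at least 16")
  curve <- field$curve
  L <- curve$L
  seeds_s <- (seq_len(n_seeds) - 1) * L / n_seeds
  start <- curve_point(curve, seeds_s)
  fw <- integrate_branch(field, start, step, max_extent, +1)
  bw <- integrate_branch(field, start, step, max_extent, -1)
  traj <- rbind(cbind(start[, 1], start[, 2], seq_len(n_seeds), 0),
                fw$points, bw$points)
  tp <- cbind(traj[, 1], traj[, 2])
  ts <- seeds_s[traj[, 3]]
  tt <- traj[, 4]
  emb_cos <- cos(2 * pi * ts / L)
  emb_sin <- sin(2 * pi * ts / L)

  xs <- field$xs; ys <- field$ys
  nx <- length(xs); ny <- length(ys)
  grid <- cbind(rep(xs, ny), rep(ys, each = nx))
  kk <- 4L
  npts <- nrow(tp)
  s_vals <- rep(NA_real_, nrow(grid))
  t_vals <- rep(NA_real_, nrow(grid))
  near_d <- rep(NA_real_, nrow(grid))
  chunk <- max(1L, floor(4e6 / npts))
  for (lo in seq(1, nrow(grid), by = chunk)) {
    hi <- min(lo + chunk - 1, nrow(grid))
    g <- grid[lo:hi, , drop = FALSE]
    D <- outer(g[, 1], tp[, 1], "-")^2 + outer(g[, 2], tp[, 2], "-")^2
    nbi <- matrix(0L, nrow(g), kk)
    nbd <- matrix(0, nrow(g), kk)
    for (q in seq_len(kk)) {
      jmin <- max.col(-D, ties.method = "first")
      rows <- seq_len(nrow(g))
      nbi[, q] <- jmin
      nbd[, q] <- D[cbind(rows, jmin)]
      D[cbind(rows, jmin)] <- Inf
    }
    nbd <- sqrt(nbd)
    w <- 1 / pmax(nbd, 1e-12)
    sw <- rowSums(w)
    csum <- rowSums(matrix(emb_cos[nbi], ncol = kk) * w) / sw
    ssum <- rowSums(matrix(emb_sin[nbi], ncol = kk) * w) / sw
    s_vals[lo:hi] <- wrap_s(atan2(ssum, csum) / (2 * pi) * L, L)
    t_vals[lo:hi] <- rowSums(matrix(tt[nbi], ncol = kk) * w) / sw
    near_d[lo:hi] <- nbd[, 1]
  }
  covered <- near_d <= 2 * field$spacing
  s_vals[!covered] <- NA
  t_vals[!covered] <- NA
  # coverage gaps: nodes within max_extent of the curve but no trajectory
  # point within two grid cells
  cs <- curve_samples(curve, 512)
  d_curve <- rep(Inf, nrow(grid))
  for (lo in seq(1, nrow(grid), by = 4096)) {
    hi <- min(lo + 4095, nrow(grid))
    D <- outer(grid[lo:hi, 1], cs$pts[, 1], "-")^2 +
         outer(grid[lo:hi, 2], cs$pts[, 2], "-")^2
    d_curve[lo:hi] <- sqrt(do.call(pmin, as.data.frame(D)))
  }
  n_gap <- sum(!covered & d_curve <= max_extent)
  if (n_gap > 0)
    warning(sprintf("chart coverage gaps: %d grid cells within reach have no nearby trajectory point", n_gap))
  structure(list(field = field, curve = curve, wrap_length = L,
                 n_seeds = n_seeds, seed_spacing = L / n_seeds,
                 step = step, max_extent = max_extent,
                 s_map = matrix(s_vals, nx, ny),
                 t_map = matrix(t_vals, nx, ny),
                 xs = xs, ys = ys, spacing = field$spacing,
                 traj_points = tp, traj_s = ts, traj_t = tt,
                 stagnated_seeds = which(bw$stagnated | fw$stagnated)),
            class = "curvilinear_chart")
}

#' @export
print.curvilinear_chart <- function(x, ...) {
  cat(sprintf("curvilinear_chart: L = %.4f, %d seeds (spacing %.4g), %d x %d grid, max_extent %.4g\n",
              x$wrap_length, x$n_seeds, x$seed_spacing,
              length(x$xs), length(x$ys), x$max_extent))
  invisible(x)
}

# Bilinear interpolation of the (s, t) maps; s through the circular embedding.
interp_chart <- function(chart, points) {
  x <- points[, 1]; y <- points[, 2]
  fx <- (x - chart$xs[1]) / chart$spacing
  fy <- (y - chart$ys[1]) / chart$spacing
  nx <- length(chart$xs); ny <- length(chart$ys)
  i <- pmin(pmax(floor(fx), 0), nx - 2)
  j <- pmin(pmax(floor(fy), 0), ny - 2)
  ax <- fx - i; ay <- fy - j
  idx <- function(ii, jj) ii + (jj - 1L) * nx
  i1 <- i + 1L; j1 <- j + 1L
  L <- chart$wrap_length
  sc <- cos(2 * pi * chart$s_map / L); ss <- sin(2 * pi * chart$s_map / L)
  gather <- function(M) cbind(M[idx(i1, j1)], M[idx(i1 + 1L, j1)],
                              M[idx(i1, j1 + 1L)], M[idx(i1 + 1L, j1 + 1L)])
  W <- cbind((1 - ax) * (1 - ay), ax * (1 - ay), (1 - ax) * ay, ax * ay)
  Gc <- gather(sc); Gs <- gather(ss); Gt <- gather(chart$t_map)
  # drop NA corners, renormalizing weights (edge of charted region)
  ok <- !is.na(Gt)
  W[!ok] <- 0
  sw <- rowSums(W)
  uncharted <- sw < 1e-12
  W <- W / pmax(sw, 1e-12)
  Gc[!ok] <- 0; Gs[!ok] <- 0; Gt[!ok] <- 0
  s <- wrap_s(atan2(rowSums(Gs * W), rowSums(Gc * W)) / (2 * pi) * L, L)
  t <- rowSums(Gt * W)
  s[uncharted] <- NA; t[uncharted] <- NA
  cbind(s = s, t = t)
}

#' Convert planar points to curvilinear coordinates
#'
#' @param chart a \code{curvilinear_chart}.
#' @param point length-2 point or m x 2 matrix.
#' @return m x 2 matrix with columns s (in [0, L)) and t (signed path length;
#'   negative inside the curve, positive outside).
#' @export
to_curvilinear <- function(chart, point) {
  p <- if (is.null(dim(point))) matrix(point, 1, 2) else as.matrix(point)
  st <- interp_chart(chart, p)
  if (anyNA(st[, 1]))
    stop(sprintf("point outside charted region (max_extent %.4g from the curve)",
                 chart$max_extent))
  st
}

#' Convert curvilinear coordinates back to planar points
#'
#' Inverse-distance weighting in (s, t) space over the chart's trajectory
#' points, with the circular s metric scaled so one seed spacing matches one
#' trajectory step.
#'
#' @param chart a \code{curvilinear_chart}.
#' @param s,t coordinate vectors.
#' @return m x 2 matrix of planar points.
#' @export
from_curvilinear <- function(chart, s, t) {
  L <- chart$wrap_length
  m <- length(s)
  out <- matrix(NA_real_, m, 2)
  # circular s distance scaled to length units along the curve
  for (i in seq_len(m)) {
    ds <- abs(chart$traj_s - wrap_s(s[i], L))
    ds <- pmin(ds, L - ds)
    d2 <- ds^2 + (chart$traj_t - t[i])^2
    nb <- order(d2)[1:4]
    w <- 1 / pmax(sqrt(d2[nb]), 1e-12)
    out[i, ] <- c(sum(chart$traj_points[nb, 1] * w),
                  sum(chart$traj_points[nb, 2] * w)) / sum(w)
  }
  out
}
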