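#' Closed approximating curves
#'
#' The texture-mapping chart is anchored to a smooth closed plane curve C that
#' approximates the endocardial cross-section of one ventricular chamber.  The
#' curve is a closed piecewise-cubic Bezier spline passing through user-supplied
#' control points, reparameterized by arc length s in [0, L].  All downstream
#' geometry (the normal-average field, the curvilinear (s, t) chart, texture
#' placement) addresses the curve through s.
#'
#' @name curves
NULL

# Evaluate one cubic Bezier segment (4x2 control matrix) at parameter u in [0,1].
bezier_eval <- function(P, u) {
  b0 <- (1 - u)^3; b1 <- 3 * u * (1 - u)^2; b2 <- 3 * u^2 * (1 - u); b3 <- u^3
  cbind(b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1],
        b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2])
}

# Derivative dC/du of a cubic Bezier segment.
bezier_deriv <- function(P, u) {
  d0 <- 3 * (1 - u)^2; d1 <- 6 * u * (1 - u); d2 <- 3 * u^2
  cbind(d0 * (P[2, 1] - P[1, 1]) + d1 * (P[3, 1] - P[2, 1]) + d2 * (P[4, 1] - P[3, 1]),
        d0 * (P[2, 2] - P[1, 2]) + d1 * (P[3, 2] - P[2, 2]) + d2 * (P[4, 2] - P[3, 2]))
}

# Shoelace signed area of a polygon (rows are vertices, not repeated).
signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Segment-pair intersection test on a polygonal approximation of the curve.
# Returns NULL when simple, else the offending pair of arc-length ranges.
polygon_self_intersection <- function(pts, s_of_pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  # test all non-adjacent segment pairs i < j
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # first and last segments are adjacent
    if (!length(js)) next
    p <- a[i, ]; r <- b[i, ] - p
    q <- a[js, , drop = FALSE]
    s <- b[js, , drop = FALSE] - q
    rxs <- r[1] * s[, 2] - r[2] * s[, 1]
    qp <- cbind(q[, 1] - p[1], q[, 2] - p[2])
    t1 <- (qp[, 1] * s[, 2] - qp[, 2] * s[, 1]) / rxs
    t2 <- (qp[, 1] * r[2] - qp[, 2] * r[1]) / (-rxs)
    hit <- is.finite(t1) & is.finite(t2) & t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
    if (any(hit)) {
      j <- js[which(hit)[1]]
      return(c(s_of_pts[i], s_of_pts[j]))
    }
  }
  NULL
}

#' Fit a closed Bezier spline through ordered control points
#'
#' Builds a smooth closed curve interpolating the control points: one cubic
#' Bezier segment per consecutive point pair, with inner Bezier handles chosen
#' from Catmull-Rom tangents so the spline is C1 across joins.  The curve is
#' densely sampled (\code{samples_per_segment} points per segment) to build a
#' monotone arc-length table; the reported total length \code{L} is the
#' cumulative chordal length of that sampling.  Clockwise input is silently
#' reversed so the stored curve is always counterclockwise (the chart
#' construction requires outward normals on its left-rotation convention).
#'
#' @param control_points numeric n x 2 matrix (n >= 3) of ordered planar points
#'   in physical units (cm).
#' @param samples_per_segment dense samples per Bezier segment (default 200).
#' @return an object of class \code{closed_curve} with elements
#'   \code{control_points}, \code{L} (total arc length), and the dense
#'   arc-length table used by \code{\link{curve_point}} and
#'   \code{\link{curve_normal}}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' cc <- fit_closed_spline(cbind(2 * cos(th), 2 * sin(th)))
#' abs(cc$L - 4 * pi) / (4 * pi) < 0.02
#' @export
fit_closed_spline <- function(control_points, samples_per_segment = 200) {
  cp <- as.matrix(control_points)
  if (!is.numeric(cp) || ncol(cp) != 2 || nrow(cp) < 3)
    stop("need at least 3 two-dimensional control points")
  if (anyDuplicated(cp) && nrow(unique(cp)) < 3)
    stop("need at least 3 distinct control points")
  if (signed_area(cp) < 0) {
    message("control points are ordered clockwise; reversing to counterclockwise")
    cp <- cp[rev(seq_len(nrow(cp))), , drop = FALSE]
  }
  n <- nrow(cp)
  prev <- cp[c(n, 1:(n - 1)), , drop = FALSE]
  nxt  <- cp[c(2:n, 1), , drop = FALSE]
  tang <- (nxt - prev) / 2  # uniform Catmull-Rom tangents
  # segment i runs cp[i] -> cp[i+1]
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    segs[[i]] <- rbind(cp[i, ],
                       cp[i, ] + tang[i, ] / 3,
                       cp[j, ] - tang[j, ] / 3,
                       cp[j, ])
  }
  m <- samples_per_segment
  u <- seq(0, 1, length.out = m + 1)[-(m + 1)]
  pts <- do.call(rbind, lapply(segs, bezier_eval, u = u))
  seg_id <- rep(seq_len(n), each = m)
  u_loc <- rep(u, n)
  # cumulative chordal arc length, with closure back to the first sample
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  s <- c(0, cumsum(d[-length(d)]))
  L <- sum(d)
  if (any(diff(s) <= 0)) stop("degenerate curve: arc-length table is not strictly increasing")
  # simplicity check on a decimated polygon (keeps the pair test quadratic-small)
  keep <- unique(c(seq(1, nrow(pts), by = max(1L, floor(m / 25))), nrow(pts)))
  bad <- polygon_self_intersection(pts[keep, , drop = FALSE], s[keep])
  if (!is.null(bad))
    stop(sprintf("curve is self-intersecting near arc lengths s = %.4g and s = %.4g", bad[1], bad[2]))
  structure(list(control_points = cp, segments = segs, L = L,
                 s = s, pts = pts, seg_id = seg_id, u_loc = u_loc,
                 samples_per_segment = m),
            class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("closed_curve: %d control points, %d Bezier segments, L = %.4f\n",
              nrow(x$control_points), length(x$segments), x$L))
  invisible(x)
}

wrap_s <- function(s, L) {
  s <- s %% L
  s[s < 0] <- s[s < 0] + L
  s
}

# Locate arc lengths on the dense table: returns segment id and local Bezier
# parameter, linearly interpolated between bracketing dense samples.
locate_s <- function(curve, s) {
  s <- wrap_s(s, curve$L)
  tab <- curve$s
  i <- findInterval(s, tab, rightmost.closed = FALSE, all.inside = FALSE)
  i[i < 1] <- 1L
  n <- length(tab)
  s_lo <- tab[i]
  s_hi <- ifelse(i < n, tab[pmin(i + 1L, n)], curve$L)
  frac <- ifelse(s_hi > s_lo, (s - s_lo) / (s_hi - s_lo), 0)
  list(i = i, frac = frac)
}

#' Evaluate the curve at arc length s
#'
#' Unit-speed evaluation: \code{curve_point(curve, s)} moves one length unit
#' along the curve per unit of \code{s}.  Values outside \code{[0, L]} wrap
#' modulo L.
#'
#' @param curve a \code{closed_curve}.
#' @param s numeric vector of arc lengths.
#' @return an \code{length(s)} x 2 matrix of planar points.
#' @export
curve_point <- function(curve, s) {
  loc <- locate_s(curve, s)
  u <- curve$u_loc[loc$i] + loc$frac * (1 / curve$samples_per_segment)
  seg <- curve$seg_id[loc$i]
  out <- matrix(0, length(u), 2)
  for (sg in unique(seg)) {
    sel <- seg == sg
    out[sel, ] <- bezier_eval(curve$segments[[sg]], pmin(u[sel], 1))
  }
  out
}

#' Outward unit normal at arc length s
#'
#' The normal is the 90-degree clockwise rotation of the unit tangent,
#' N(s) = [[0, 1], [-1, 0]] C'(s), which points outward on a counterclockwise
#' curve.  The tangent is the analytic Bezier derivative at the parameter
#' located through the arc-length table.
#'
#' @inheritParams curve_point
#' @return a \code{length(s)} x 2 matrix of unit vectors.
#' @export
curve_normal <- function(curve, s) {
  loc <- locate_s(curve, s)
  u <- curve$u_loc[loc$i] + loc$frac * (1 / curve$samples_per_segment)
  seg <- curve$seg_id[loc$i]
  # samples within a segment are equally spaced in u, so frac interpolates u;
  # crossing a segment join lands at u = 1 of the same segment
  der <- matrix(0, length(s), 2)
  for (sg in unique(seg)) {
    sel <- seg == sg
    der[sel, ] <- bezier_deriv(curve$segments[[sg]], pmin(u[sel], 1))
  }
  nrm <- sqrt(rowSums(der^2))
  tang <- der / nrm
  cbind(tang[, 2], -tang[, 1])
}

# Dense resampling at n equally spaced arc lengths; used by the field quadrature.
curve_samples <- function(curve, n) {
  s <- (seq_len(n) - 1) * curve$L / n
  list(s = s, pts = curve_point(curve, s), normals = curve_normal(curve, s),
       ds = curve$L / n)
}
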