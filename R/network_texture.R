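#' Purkinje network textures and projection
#'
#' A digitized Purkinje network is a binary texture image T on [0, W] x [0, H]
#' (1 = fiber) together with coupling sites at the apparent fiber endings.
#' The texture is placed on a rectangle [a, b] x [c, d] of the approximating
#' cylinder (s along the curve, z along the cylinder axis) and extended to 3D
#' by holding its value constant along chart trajectories:
#'   F(x, y, z) = T(((s - a) / (b - a)) W, ((z - c) / (d - c)) H),
#' where s is the curvilinear coordinate of (x, y).  Evaluating F inside the
#' thin endocardial shell yields the voxelized three-dimensional network.
#'
#' Pixel convention: origin at the lower-left, u1 rightward (increasing s),
#' u2 upward (increasing z).  Image files, which store rows top-down, are
#' flipped on read.  Texture lookups use the nearest pixel (no interpolation
#' of a binary palette).
#'
#' @name network_texture
NULL

#' Construct a network image
#'
#' @param mask W x H binary matrix (first index = u1 rightward, second = u2
#'   upward); nonzero = fiber.
#' @param sites data.frame with columns \code{site_id}, \code{u1}, \code{u2}
#'   (pixel coordinates in [0, W] x [0, H]) and optionally
#'   \code{bundle_branch} (0/1 flag for the stimulus entry node).
#' @export
network_image <- function(mask, sites = data.frame(site_id = integer(0),
                                                   u1 = numeric(0),
                                                   u2 = numeric(0))) {
  mask <- (as.matrix(mask) != 0)
  W <- nrow(mask); H <- ncol(mask)
  if (is.null(sites$bundle_branch)) sites$bundle_branch <- rep(0L, nrow(sites))
  bad <- sites$u1 < 0 | sites$u1 > W | sites$u2 < 0 | sites$u2 > H
  if (any(bad))
    stop(sprintf("sites outside the [0, %d] x [0, %d] raster: %s",
                 W, H, paste(sites$site_id[bad], collapse = ", ")))
  if (!any(mask) && nrow(sites) == 0)
    warning("empty network mask")
  # sites should sit on or within one pixel of a fiber pixel
  if (nrow(sites) > 0 && any(mask)) {
    fib <- which(mask, arr.ind = TRUE)
    fx <- fib[, 1] - 0.5; fy <- fib[, 2] - 0.5
    for (r in seq_len(nrow(sites))) {
      d <- min(pmax(abs(fx - sites$u1[r]), abs(fy - sites$u2[r])))
      if (d > 1.5)
        warning(sprintf("site %s lies more than one pixel from any fiber pixel",
                        sites$site_id[r]))
    }
  }
  structure(list(mask = mask, sites = sites, W = W, H = H),
            class = "network_image")
}

#' @export
print.network_image <- function(x, ...) {
  cat(sprintf("network_image: %d x %d px, %d fiber px, %d coupling sites (%d bundle-branch)\n",
              x$W, x$H, sum(x$mask), nrow(x$sites), sum(x$sites$bundle_branch > 0)))
  invisible(x)
}

#' Read a network image and its coupling-site list
#'
#' The PNG is collapsed to a single channel (mean over channels), binarized at
#' 50 percent intensity, and flipped so that the first matrix index runs
#' rightward (u1) and the second upward (u2).  Bright pixels are fibers.
#' The site CSV must carry a header \code{site_id,u1,u2} with optional
#' \code{bundle_branch} column.
#'
#' @param image_file path to a PNG.
#' @param sites_file path to the CSV of coupling sites (optional).
#' @return a \code{network_image}.
#' @export
read_network <- function(image_file, sites_file = NULL) {
  img <- png::readPNG(image_file)
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                                          c(1, 2), mean)
  # PNG rows run top-down; transpose to (column -> u1, row -> u2) and flip u2
  mask <- t(img[rev(seq_len(nrow(img))), , drop = FALSE] >= 0.5)
  sites <- if (is.null(sites_file)) {
    data.frame(site_id = integer(0), u1 = numeric(0), u2 = numeric(0))
  } else {
    utils::read.csv(sites_file)
  }
  if (!is.null(sites_file) && !all(c("site_id", "u1", "u2") %in% names(sites)))
    stop("sites CSV must have header site_id,u1,u2")
  network_image(mask, sites)
}

#' Write a network image and site list
#'
#' @param network a \code{network_image}.
#' @param image_file,sites_file output paths.
#' @export
write_network <- function(network, image_file, sites_file = NULL) {
  img <- t(network$mask + 0)
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  png::writePNG(img, image_file)
  if (!is.null(sites_file))
    utils::write.csv(network$sites, sites_file, row.names = FALSE)
  invisible(network)
}

#' Texture placement rectangle on the approximating cylinder
#'
#' @param a,b arc-length bounds, 0 <= a < b <= L (b - a = L wraps the full
#'   circumference).
#' @param c,d axial bounds (cm along the cylinder axis), c < d.
#' @param preserve_aspect if TRUE, require (b - a)/(d - c) = W/H when checked
#'   against a texture.
#' @export
placement_rect <- function(a, b, c, d, preserve_aspect = FALSE) {
  if (!(a < b)) stop("need a < b")
  if (!(c < d)) stop("need c < d")
  structure(list(a = a, b = b, c = c, d = d, preserve_aspect = preserve_aspect),
            class = "placement_rect")
}

check_rect <- function(rect, L, network = NULL) {
  if (rect$b > L + 1e-9) stop("placement bound b exceeds the curve length L")
  if (!is.null(network) && isTRUE(rect$preserve_aspect)) {
    ratio <- (rect$b - rect$a) / (rect$d - rect$c)
    want <- network$W / network$H
    if (abs(ratio - want) / want > 1e-6)
      stop("placement rectangle does not preserve the texture aspect ratio")
  }
  invisible(rect)
}

#' Map a texture pixel to cylinder coordinates
#'
#' The inverse of the pixel assignment: s = a + (u1 / W)(b - a) wrapped into
#' [0, L), z = c + (u2 / H)(d - c).
#'
#' @param rect a \code{placement_rect}.
#' @param W,H texture dimensions.
#' @param pixel numeric c(u1, u2) or m x 2 matrix.
#' @param L curve length for wrapping (optional; no wrap when missing).
#' @return m x 2 matrix with columns s, z.
#' @export
pixel_to_cylinder <- function(rect, W, H, pixel, L = NULL) {
  p <- if (is.null(dim(pixel))) matrix(pixel, ncol = 2) else as.matrix(pixel)
  if (any(p[, 1] < 0 | p[, 1] > W | p[, 2] < 0 | p[, 2] > H))
    stop("pixel outside [0, W] x [0, H]")
  s <- rect$a + p[, 1] / W * (rect$b - rect$a)
  if (!is.null(L)) s <- wrap_s(s, L)
  cbind(s = s, z = rect$c + p[, 2] / H * (rect$d - rect$c))
}

# Texture lookup in (s, z): nearest pixel; 0 outside the placement rectangle.
texture_lookup <- function(rect, network, s, z, L) {
  ba <- rect$b - rect$a
  s_rel <- wrap_s(s - rect$a, L)
  u1 <- s_rel / ba * network$W
  u2 <- (z - rect$c) / (rect$d - rect$c) * network$H
  inside <- s_rel <= ba & u2 >= 0 & u2 <= network$H
  i <- pmin(pmax(ceiling(u1), 1L), network$W)
  j <- pmin(pmax(ceiling(u2), 1L), network$H)
  val <- rep(0L, length(s))
  sel <- which(inside)
  if (length(sel))
    val[sel] <- network$mask[cbind(i[sel], j[sel])] + 0L
  list(value = val, u1 = u1, u2 = u2, inside = inside, px = i, py = j)
}

# Planar/axial decomposition of 3D physical points for a given cylinder axis.
split_axes <- function(axis) {
  planar <- setdiff(1:3, axis)
  list(planar = planar, axial = axis)
}

voxel_centers <- function(idx_mat, spacing) (idx_mat - 0.5) * spacing

#' Evaluate the extended texture function F at 3D points
#'
#' @param chart a \code{curvilinear_chart} over the plane perpendicular to
#'   the cylinder axis.
#' @param rect a \code{placement_rect}.
#' @param network a \code{network_image}.
#' @param point length-3 physical point or m x 3 matrix, coordinates ordered
#'   (planar1, planar2, axial).
#' @return integer vector of palette values (0 or 1).
#' @export
evaluate_F <- function(chart, rect, network, point) {
  p <- if (is.null(dim(point))) matrix(point, ncol = 3) else as.matrix(point)
  check_rect(rect, chart$wrap_length, network)
  st <- to_curvilinear(chart, p[, 1:2, drop = FALSE])
  texture_lookup(rect, network, st[, 1], p[, 3], chart$wrap_length)$value
}

# Nearest active voxel (by 3D Euclidean distance) to a trajectory at fixed z.
# traj: polyline matrix (x, y, t); cand_idx: voxel ijk matrix of candidates.
nearest_voxel_to_traj <- function(traj, z_site, cand_ijk, cand_lin, spacing,
                                  planar, axial, max_dist) {
  cx <- (cand_ijk[, planar[1]] - 0.5) * spacing
  cy <- (cand_ijk[, planar[2]] - 0.5) * spacing
  cz <- (cand_ijk[, axial] - 0.5) * spacing
  best <- rep(Inf, nrow(cand_ijk))
  for (r in seq_len(nrow(traj))) {
    d2 <- (cx - traj[r, 1])^2 + (cy - traj[r, 2])^2 + (cz - z_site)^2
    best <- pmin(best, d2)
  }
  best <- sqrt(best)
  ok <- best <= max_dist
  if (!any(ok)) return(NA_integer_)
  # nearest wins; ties broken by lowest linear voxel index
  cand <- which(ok)
  cand <- cand[order(best[cand], cand_lin[cand])]
  cand_lin[cand[1]]
}

#' Project a network texture into the endocardial shell
#'
#' Marks every shell voxel whose center evaluates to a fiber under F, then
#' applies one pass of connectivity repair: when two fiber pixels are
#' 8-adjacent in the texture but their voxel images are not 26-adjacent in
#' 3D, shell voxels adjacent to both images are added (a one-voxel bridging
#' dilation constrained to the shell), keeping the voxelized network
#' electrically connected on grids coarser than the texture.  Each coupling
#' site is mapped to the projected-network voxel nearest (3D Euclidean) to
#' the intersection of its (s, z) trajectory with the shell; sites with no
#' voxel within 3 voxel widths are reported unmapped.
#'
#' @param chart a \code{curvilinear_chart}.
#' @param rect a \code{placement_rect}.
#' @param network a \code{network_image}.
#' @param shell shell \code{voxel_mask}.
#' @param phase the \code{phase_field} (supplies spacing and cylinder axis).
#' @return an object of class \code{projected_network}: \code{voxels} (a
#'   network \code{voxel_mask}), \code{site_voxels} (data.frame site_id, i, j,
#'   k, linear), \code{unmapped_sites}, and the per-voxel source pixels.
#' @export
project_network <- function(chart, rect, network, shell, phase) {
  check_rect(rect, chart$wrap_length, network)
  ax <- split_axes(phase$axis)
  h <- phase$spacing
  dm <- phase$dim
  shell_lin <- which(shell$flags)
  shell_ijk <- arrayInd(shell_lin, dm)
  pl <- cbind((shell_ijk[, ax$planar[1]] - 0.5) * h,
              (shell_ijk[, ax$planar[2]] - 0.5) * h)
  st <- interp_chart(chart, pl)
  if (anyNA(st[, 1])) {
    n_bad <- sum(is.na(st[, 1]))
    stop(sprintf("chart does not cover the shell footprint: %d shell voxels uncharted", n_bad))
  }
  z <- (shell_ijk[, ax$axial] - 0.5) * h
  tl <- texture_lookup(rect, network, st[, 1], z, chart$wrap_length)
  hit <- tl$value == 1L
  net <- array(FALSE, dm)
  net[shell_lin[hit]] <- TRUE
  src_px <- cbind(tl$px[hit], tl$py[hit])
  vox_lin <- shell_lin[hit]

  # ---- per-pixel seeding --------------------------------------------------
  # Center sampling alone aliases one-pixel fibers when the texel size is
  # comparable to the voxel size; additionally map every fiber pixel to its
  # nearest shell voxel in the (s, z) metric so the full network transfers.
  fib <- which(network$mask, arr.ind = TRUE)
  if (nrow(fib) > 0) {
    L <- chart$wrap_length
    psz <- pixel_to_cylinder(rect, network$W, network$H,
                             cbind(fib[, 1] - 0.5, fib[, 2] - 0.5), L)
    seed_lin <- integer(nrow(fib))
    for (r in seq_len(nrow(fib))) {
      ds <- abs(st[, 1] - psz[r, 1]); ds <- pmin(ds, L - ds)
      d2 <- ds^2 + (z - psz[r, 2])^2
      best <- which(d2 == min(d2))
      cand <- shell_lin[best]
      seed_lin[r] <- if (min(d2) <= (3 * h)^2) min(cand) else NA_integer_
    }
    ok <- !is.na(seed_lin)
    net[seed_lin[ok]] <- TRUE
    # voxel/source-pixel attributions: center hits plus pixel seeds (a voxel
    # may carry several pixel attributions; the repair grouping uses all)
    src_px <- rbind(src_px, cbind(fib[ok, 1], fib[ok, 2]))
    vox_lin <- c(shell_lin[hit], seed_lin[ok])
  }

  # ---- connectivity repair ------------------------------------------------
  # group projected voxels by source pixel; for 8-adjacent pixel pairs whose
  # voxel groups are not 26-adjacent, add shell voxels adjacent to both.
  if (nrow(src_px) > 1) {
    pix_key <- paste(src_px[, 1], src_px[, 2])
    groups <- split(seq_along(vox_lin), pix_key)
    pix_tab <- do.call(rbind, lapply(strsplit(names(groups), " "), as.integer))
    added <- integer(0)
    vox_ijk <- arrayInd(vox_lin, dm)
    net_set <- net
    for (gi in seq_len(nrow(pix_tab))) {
      px <- pix_tab[gi, ]
      # 8-neighbors with a canonical ordering to test each pair once
      for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
        key2 <- paste(px[1] + off[1], px[2] + off[2])
        gj <- match(key2, names(groups))
        if (is.na(gj)) next
        A <- vox_ijk[groups[[gi]], , drop = FALSE]
        B <- vox_ijk[groups[[gj]], , drop = FALSE]
        adj <- FALSE
        for (r in seq_len(nrow(A))) {
          if (any(abs(B[, 1] - A[r, 1]) <= 1 & abs(B[, 2] - A[r, 2]) <= 1 &
                  abs(B[, 3] - A[r, 3]) <= 1)) { adj <- TRUE; break }
        }
        if (adj) next
        # bridge: shell voxels 26-adjacent to both groups
        bridge <- bridging_voxels(A, B, shell$flags, dm)
        if (length(bridge)) {
          net_set[bridge] <- TRUE
          added <- c(added, bridge)
        }
      }
    }
    net <- net_set
  }

  # ---- site mapping -------------------------------------------------------
  net_lin <- which(net)
  net_ijk <- arrayInd(net_lin, dm)
  sites <- network$sites
  mapped <- list(); unmapped <- integer(0)
  if (nrow(sites) > 0 && length(net_lin) > 0) {
    sz <- pixel_to_cylinder(rect, network$W, network$H,
                            cbind(sites$u1, sites$u2), chart$wrap_length)
    for (r in seq_len(nrow(sites))) {
      traj <- integrate_trajectory(chart$field, sz[r, 1], step = chart$step,
                                   max_extent = chart$max_extent)
      lin <- nearest_voxel_to_traj(traj, sz[r, 2], net_ijk, net_lin, h,
                                   ax$planar, ax$axial, max_dist = 3 * h)
      if (is.na(lin)) unmapped <- c(unmapped, r)
      else {
        ijk <- arrayInd(lin, dm)
        mapped[[length(mapped) + 1]] <-
          data.frame(site_id = sites$site_id[r], i = ijk[1], j = ijk[2],
                     k = ijk[3], linear = lin,
                     bundle_branch = sites$bundle_branch[r])
      }
    }
  } else if (nrow(sites) > 0) {
    unmapped <- seq_len(nrow(sites))
  }
  site_voxels <- if (length(mapped)) do.call(rbind, mapped) else
    data.frame(site_id = integer(0), i = integer(0), j = integer(0),
               k = integer(0), linear = integer(0), bundle_branch = integer(0))
  structure(list(voxels = voxel_mask(net, "network", spacing = h),
                 site_voxels = site_voxels,
                 unmapped_sites = if (length(unmapped)) sites$site_id[unmapped] else integer(0),
                 n_sites = nrow(sites), rect = rect, axis = phase$axis),
            class = "projected_network")
}

# Shell voxels 26-adjacent to both voxel groups A and B (ijk matrices).
bridging_voxels <- function(A, B, shell_flags, dm) {
  cand <- integer(0)
  for (r in seq_len(nrow(A))) {
    rng1 <- max(1, A[r, 1] - 1):min(dm[1], A[r, 1] + 1)
    rng2 <- max(1, A[r, 2] - 1):min(dm[2], A[r, 2] + 1)
    rng3 <- max(1, A[r, 3] - 1):min(dm[3], A[r, 3] + 1)
    g <- as.matrix(expand.grid(rng1, rng2, rng3))
    lin <- g[, 1] + (g[, 2] - 1L) * dm[1] + (g[, 3] - 1L) * dm[1] * dm[2]
    cand <- c(cand, lin[shell_flags[lin]])
  }
  cand <- unique(cand)
  if (!length(cand)) return(integer(0))
  cij <- arrayInd(cand, dm)
  near_b <- vapply(seq_len(nrow(cij)), function(q) {
    any(abs(B[, 1] - cij[q, 1]) <= 1 & abs(B[, 2] - cij[q, 2]) <= 1 &
          abs(B[, 3] - cij[q, 3]) <= 1)
  }, logical(1))
  sort(cand[near_b])
}

#' @export
print.projected_network <- function(x, ...) {
  cat(sprintf("projected_network: %d voxels, %d/%d sites mapped (%d unmapped)\n",
              sum(x$voxels$flags), nrow(x$site_voxels), x$n_sites,
              length(x$unmapped_sites)))
  invisible(x)
}
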