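# Shared in-code fixtures for the test suite.  Everything is generated at
# test time; nothing is read from disk except files the tests themselves
# write to tempdir().

circle_points <- function(n = 24, R = 1, ccw = TRUE) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (!ccw) th <- rev(th)
  cbind(R * cos(th), R * sin(th))
}

ellipse_points <- function(n = 24, a = 1.5, b = 0.8) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

circle_curve <- function(R = 1, n = 24) fit_closed_spline(circle_points(n, R))

# memoized circle field + chart used by several chart tests
.test_env <- new.env()

circle_field <- function() {
  if (is.null(.test_env$fld)) {
    cc <- circle_curve()
    .test_env$fld <- suppressMessages(
      precompute_field_grid(cc, c(-2, 2, -2, 2), 0.05))
  }
  .test_env$fld
}

circle_chart <- function() {
  if (is.null(.test_env$ch)) {
    .test_env$ch <- suppressWarnings(
      build_chart(circle_field(), n_seeds = 64, max_extent = 1.1))
  }
  .test_env$ch
}

# independent oracle: the normal-average field by adaptive quadrature over a
# finely resampled polygon of the curve (different scheme from the package's
# periodic trapezoid rule)
oracle_field <- function(curve, p, n = 8192) {
  s <- (seq_len(n) - 0.5) * curve$L / n
  pts <- curve_point(curve, s)
  nrm <- curve_normal(curve, s)
  d <- sqrt((p[1] - pts[, 1])^2 + (p[2] - pts[, 2])^2)
  w <- 1 / d
  c(sum(nrm[, 1] * w), sum(nrm[, 2] * w)) / sum(w)
}

angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

# minimal hand-built coupled cable model: a 3D bar of ventricular tissue with
# a Purkinje fiber line along it, coupled at chosen sites
cable_coupled <- function(n = 60, g_c = 10, sites = round(n * c(0.3, 0.6, 0.85)),
                          bundle = 2L, ep = list()) {
  dm <- c(n, 3L, 3L)
  tissue <- array(TRUE, dm)
  purk <- array(FALSE, dm)
  purk[, 2, 2] <- TRUE
  lin <- function(i, j, k) i + (j - 1L) * dm[1] + (k - 1L) * dm[1] * dm[2]
  cfg <- utils::modifyList(list(D0 = 0.001, ratio = 20, g_c = g_c), ep)
  cfg <- purkinjemap:::resolve_ep_config(cfg)
  vent <- tissue_domain(tissue, spacing = 0.025, diffusivity = cfg$D0,
                        params = cfg$membrane)
  pdom <- tissue_domain(purk, spacing = 0.025,
                        diffusivity = cfg$ratio * cfg$D0,
                        params = cfg$membrane, connectivity = "full")
  cn <- data.frame(site_id = seq_along(sites),
                   i = sites, j = 2L, k = 2L,
                   linear = lin(sites, 2L, 2L), bundle_branch = 0L)
  proj <- structure(list(site_voxels = rbind(cn,
                  data.frame(site_id = length(sites) + 1L, i = bundle, j = 2L,
                             k = 2L, linear = lin(bundle, 2L, 2L),
                             bundle_branch = 1L))),
                    class = "projected_network")
  structure(list(ventricle = vent, purkinje = pdom, coupled_nodes = cn,
                 g_c = cfg$g_c, config = cfg, projected = proj),
            class = c("coupled_3d3d", "coupled_model"))
}
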