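test_that("normal-average field respects circle symmetry", {
  fld <- circle_field()
  expect_equal(as.numeric(field_at(fld, c(2, 0), exact = TRUE)) /
                 sqrt(sum(field_at(fld, c(2, 0), exact = TRUE)^2)),
               c(1, 0), tolerance = 1e-6)
  expect_lt(sqrt(sum(field_at(fld, c(0, 0), exact = TRUE)^2)), 1e-6)
  # interpolated grid direction at (1.5, 0) within 1 degree of radial
  v <- as.numeric(field_at(fld, c(1.5, 0)))
  expect_lt(angle_between(v, c(1, 0)), 1)
})

test_that("field queries outside the grid bounds are rejected", {
  expect_error(field_at(circle_field(), c(5, 0)), "bounds")
})

test_that("exact field evaluation matches an independent quadrature oracle", {
  ee <- fit_closed_spline(ellipse_points(32))
  fld <- suppressMessages(precompute_field_grid(ee, c(-3, 3, -3, 3), 0.1,
                                                quadrature_n = 4096))
  set.seed(3)
  for (i in 1:5) {
    p <- c(runif(1, -2.5, 2.5), runif(1, -2.5, 2.5))
    v <- as.numeric(field_at(fld, p, exact = TRUE))
    o <- oracle_field(ee, p)
    expect_lt(max(abs(v - o)) / max(abs(o)), 1e-4)
  }
})

test_that("doubling the quadrature count leaves grid values converged", {
  cc <- circle_curve()
  f1 <- suppressMessages(precompute_field_grid(cc, c(-1.6, 1.6, -1.6, 1.6),
                                               0.2, quadrature_n = 512))
  f2 <- suppressMessages(precompute_field_grid(cc, c(-1.6, 1.6, -1.6, 1.6),
                                               0.2, quadrature_n = 1024))
  scale <- max(abs(f2$Vx), abs(f2$Vy))
  expect_lt(max(abs(f1$Vx - f2$Vx), abs(f1$Vy - f2$Vy)) / scale, 1e-3)
})

test_that("grid nodes on the curve store the limiting normal", {
  cc <- circle_curve()
  expect_message(
    fld <- precompute_field_grid(cc, c(-2, 2, -2, 2), 0.5),
    "limit value")
  # node (1, 0) lies on the unit circle: stored value must be N = (1, 0)
  i <- which(abs(fld$xs - 1) < 1e-12)
  j <- which(abs(fld$ys) < 1e-12)
  expect_equal(c(fld$Vx[i, j], fld$Vy[i, j]), c(1, 0), tolerance = 1e-3)
})

test_that("trajectories are radial on the circle and follow the field", {
  fld <- circle_field()
  tr <- integrate_trajectory(fld, 0, max_extent = 0.9)
  expect_lt(max(abs(tr[, "y"])), 1e-10)
  expect_true(any(abs(tr[, "t"]) < 1e-12))  # passes through C(s0)
  expect_true(all(diff(tr[, "t"]) > 0))
  # first forward step leaves along N(s0) for arbitrary seeds
  for (s0 in c(0.3, 1.7, 4.1)) {
    tr <- integrate_trajectory(fld, s0, max_extent = 0.3)
    p0 <- curve_point(fld$curve, s0)
    fw <- tr[tr[, "t"] > 0, , drop = FALSE]
    step_dir <- c(fw[1, "x"], fw[1, "y"]) - as.numeric(p0)
    expect_lt(angle_between(step_dir, as.numeric(curve_normal(fld$curve, s0))), 5)
  }
  # residual check on an ellipse: recorded points satisfy dx/dt parallel to V
  ee <- fit_closed_spline(ellipse_points(32))
  fe <- suppressMessages(precompute_field_grid(ee, c(-3, 3, -3, 3), 0.05))
  tr <- integrate_trajectory(fe, 1.0, step = 0.025, max_extent = 0.5)
  xy <- tr[, c("x", "y")]
  mid <- (xy[-1, ] + xy[-nrow(xy), ]) / 2
  seg <- xy[-1, ] - xy[-nrow(xy), ]
  v <- field_at(fe, mid)
  ang <- vapply(seq_len(nrow(seg)),
                function(r) angle_between(seg[r, ], v[r, ]), numeric(1))
  expect_lt(max(ang), 2)
})

test_that("inward trajectories stagnate at the circle center and are flagged", {
  fld <- circle_field()
  tr <- integrate_trajectory(fld, 0, max_extent = 5)
  expect_true(attr(tr, "stagnated"))
  expect_gt(min(tr[, "x"]), -0.2)  # inward branch stops near the center
})

test_that("the chart reproduces polar coordinates on a circle", {
  ch <- circle_chart()
  L <- ch$wrap_length
  seed_sp <- ch$seed_spacing
  # quarter-turn probes
  st <- to_curvilinear(ch, rbind(c(0, 1.5), c(-1.5, 0), c(0, -1.5)))
  expect_lt(abs(st[1, 1] - L / 4), seed_sp)
  expect_lt(abs(st[2, 1] - L / 2), seed_sp)
  expect_lt(abs(st[3, 1] - 3 * L / 4), seed_sp)
  # points on C get |t| below one step
  on_c <- curve_point(ch$curve, c(0.2, 2.5, 5.0))
  st2 <- to_curvilinear(ch, on_c)
  expect_true(all(abs(st2[, 2]) < ch$step))
  # s equals R * theta within one seed spacing at random annulus points
  set.seed(11)
  th <- runif(200, 0, 2 * pi); r <- runif(200, 0.5, 1.6)
  st3 <- to_curvilinear(ch, cbind(r * cos(th), r * sin(th)))
  s_ref <- th / (2 * pi) * L
  err <- abs(st3[, 1] - s_ref)
  err <- pmin(err, L - err)
  expect_lt(max(err), seed_sp + 1e-9)
  # t signs: negative inside, positive outside
  expect_lt(to_curvilinear(ch, c(0.5, 0))[2], 0)
  expect_gt(to_curvilinear(ch, c(1.5, 0))[2], 0)
})

test_that("s interpolation is seamless across the 0/L branch cut", {
  ch <- circle_chart()
  L <- ch$wrap_length
  eps <- 0.02
  below <- to_curvilinear(ch, c(cos(-eps) * 1.2, sin(-eps) * 1.2))[1]
  above <- to_curvilinear(ch, c(cos(eps) * 1.2, sin(eps) * 1.2))[1]
  gap <- abs(above - below)
  expect_lt(min(gap, L - gap), 3 * ch$seed_spacing)
})

test_that("chart coordinates agree with a refined-chart oracle", {
  fld <- circle_field()
  coarse <- suppressWarnings(build_chart(fld, n_seeds = 32, max_extent = 1.1))
  fine <- suppressWarnings(build_chart(fld, n_seeds = 256, max_extent = 1.1))
  set.seed(5)
  th <- runif(50, 0, 2 * pi); r <- runif(50, 0.6, 1.5)
  p <- cbind(r * cos(th), r * sin(th))
  s_c <- to_curvilinear(coarse, p)[, 1]
  # oracle: nearest trajectory point of the 8x-seeded chart
  s_o <- vapply(seq_len(nrow(p)), function(q) {
    d2 <- (fine$traj_points[, 1] - p[q, 1])^2 + (fine$traj_points[, 2] - p[q, 2])^2
    fine$traj_s[which.min(d2)]
  }, numeric(1))
  L <- coarse$wrap_length
  err <- abs(s_c - s_o); err <- pmin(err, L - err)
  expect_lt(max(err), coarse$seed_spacing + 1e-9)
})

test_that("round trips through the chart return to the starting point", {
  ch <- circle_chart()
  set.seed(9)
  th <- runif(40, 0, 2 * pi); r <- runif(40, 0.6, 1.5)
  p <- cbind(r * cos(th), r * sin(th))
  st <- to_curvilinear(ch, p)
  back <- from_curvilinear(ch, st[, 1], st[, 2])
  expect_lt(max(sqrt(rowSums((back - p)^2))), ch$spacing * sqrt(2))
})

test_that("uncharted points are rejected by name of the extent", {
  ch <- circle_chart()
  expect_error(to_curvilinear(ch, c(1.95, 1.95)), "max_extent")
})

test_that("chart maps export to volumes with their metadata", {
  ch <- circle_chart()
  dir <- withr::local_tempdir()
  export_chart(ch, dir)
  s_back <- read_volume(file.path(dir, "s_map.nii"))
  expect_equal(drop(s_back$values)[!is.na(ch$s_map)],
               ch$s_map[!is.na(ch$s_map)])
  meta <- jsonlite::read_json(file.path(dir, "chart_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$L, ch$wrap_length)
  expect_equal(meta$n_seeds, ch$n_seeds)
})
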