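test_that("network images validate sites against the raster", {
  m <- matrix(FALSE, 10, 10); m[5, ] <- TRUE
  ni <- network_image(m, data.frame(site_id = 1, u1 = 4.5, u2 = 9.5))
  expect_equal(ni$W, 10)
  expect_error(network_image(m, data.frame(site_id = 1, u1 = 12, u2 = 2)),
               "outside")
  expect_warning(network_image(m, data.frame(site_id = 1, u1 = 9.5, u2 = 0.5)),
                 "fiber")
  expect_warning(ne <- network_image(matrix(FALSE, 4, 4)), "empty")
  expect_equal(nrow(ne$sites), 0)
})

test_that("PNG + CSV round trip preserves the raster and the site list", {
  net <- synth_network_image(W = 48, H = 40, depth = 3, seed = 2)
  img <- withr::local_tempfile(fileext = ".png")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, img, csv)
  back <- read_network(img, csv)
  expect_identical(back$mask, net$mask)
  expect_equal(back$sites$u1, net$sites$u1)
  expect_equal(back$sites$bundle_branch, net$sites$bundle_branch)
})

test_that("the reader returns one site per row of the supplied site list", {
  # the digitized left and right branch site lists carry 130 and 100
  # coupling sites; synthetic site lists of those sizes exercise the reader
  m <- matrix(FALSE, 200, 200)
  m[, 100] <- TRUE
  img <- withr::local_tempfile(fileext = ".png")
  for (n_sites in c(130, 100)) {
    csv <- withr::local_tempfile(fileext = ".csv")
    set.seed(n_sites)
    sites <- data.frame(site_id = seq_len(n_sites),
                        u1 = runif(n_sites, 0, 200), u2 = 99.5)
    write.csv(sites, csv, row.names = FALSE)
    write_network(network_image(m, sites), img)
    expect_equal(nrow(read_network(img, csv)$sites), n_sites)
  }
  expect_error(read_network(img, {
    bad <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
    bad
  }), "header")
})

test_that("pixel_to_cylinder is the linear inverse of the pixel assignment", {
  rect <- placement_rect(1, 3, -0.5, 0.5)
  expect_equal(as.numeric(pixel_to_cylinder(rect, 40, 20, c(0, 0))), c(1, -0.5))
  expect_equal(as.numeric(pixel_to_cylinder(rect, 40, 20, c(40, 20))), c(3, 0.5))
  expect_equal(as.numeric(pixel_to_cylinder(rect, 40, 20, c(20, 10))), c(2, 0))
  # wrapping into [0, L)
  rect2 <- placement_rect(5, 8, 0, 1)
  expect_equal(unname(pixel_to_cylinder(rect2, 10, 10, c(10, 0), L = 6)[1, "s"]),
               2)
  expect_error(pixel_to_cylinder(rect, 40, 20, c(-1, 5)), "pixel")
})

test_that("placement rectangles enforce their bounds and aspect ratio", {
  expect_error(placement_rect(2, 1, 0, 1), "a < b")
  expect_error(placement_rect(0, 1, 1, 0), "c < d")
  net <- network_image(matrix(TRUE, 20, 10))
  ok <- placement_rect(0, 2, 0, 1, preserve_aspect = TRUE)
  expect_silent(purkinjemap:::check_rect(ok, L = 4, net))
  bad <- placement_rect(0, 1, 0, 1, preserve_aspect = TRUE)
  expect_error(purkinjemap:::check_rect(bad, L = 4, net), "aspect")
})

test_that("F vanishes off the placement rectangle and is trajectory-constant", {
  ch <- circle_chart()
  L <- ch$wrap_length
  m <- matrix(FALSE, 16, 16); m[, 8] <- TRUE  # horizontal fiber band
  net <- network_image(m)
  rect <- placement_rect(0, L / 2, 0, 1)
  # z outside [c, d] and s outside [a, b] both give 0
  expect_equal(evaluate_F(ch, rect, net, c(1, 0, 2)), 0L)
  p_opposite <- c(-1.2, -0.4, 0.5)   # s near 0.55 L, outside [0, L/2]
  expect_equal(evaluate_F(ch, rect, net, p_opposite), 0L)
  # constancy along a trajectory (radial ray on the circle chart)
  z0 <- 0.47
  vals <- evaluate_F(ch, rect, net,
                     cbind(c(0.7, 1.0, 1.3), 0, z0) *
                       cbind(1, 0, c(1, 1, 1)))
  expect_true(length(unique(vals)) == 1)
})

test_that("F matches a direct cylindrical wrap on the circle chart", {
  ch <- suppressWarnings(build_chart(circle_field(), n_seeds = 256,
                                     max_extent = 1.1))
  L <- ch$wrap_length
  set.seed(21)
  # 4 x 4 block checkerboard: disagreements can only occur at block edges
  blocks <- outer((0:31) %/% 4, (0:31) %/% 4, "+") %% 2 == 0
  net <- network_image(blocks)
  rect <- placement_rect(0, L, 0, 1)
  th <- runif(1000, 0, 2 * pi)
  z <- runif(1000, 0.01, 0.99)
  r <- runif(1000, 0.8, 1.3)  # on and around the unit-cylinder surface
  pts <- cbind(r * cos(th), r * sin(th), z)
  got <- evaluate_F(ch, rect, net, pts)
  # analytic wrap: s = theta / 2pi * L, nearest pixel
  u1 <- pmin(pmax(ceiling(th / (2 * pi) * 32), 1), 32)
  u2 <- pmin(pmax(ceiling(z * 32), 1), 32)
  want <- net$mask[cbind(u1, u2)] + 0L
  expect_gte(mean(got == want), 0.99)
})

test_that("projection conserves sites and projects an axial fiber line", {
  sv <- synth_ventricles("cylinder", list(n = 48L, r_cavity = 0.35,
                                          r_outer = 0.5))
  ph <- sv$phase
  ch <- suppressWarnings(isolate_chamber(ph, sv$chamber_seeds[[1]]))
  cp <- synth_curve_for(ph, ch)
  mp_cfg <- list(chart = list(n_seeds = 128L, quadrature_n = 512L,
                              max_extent_vox = 10L, bounds_margin_vox = 2L))
  # single vertical fiber at u1 = 12 of 48
  m <- matrix(FALSE, 48, 48); m[12, ] <- TRUE
  sites <- data.frame(site_id = 1:2, u1 = 11.5, u2 = c(0.5, 47.5))
  net <- network_image(m, sites)
  mp <- map_network(ph, sv$chamber_seeds[[1]], cp, net, mp_cfg)
  pj <- mp$projected
  expect_equal(nrow(pj$site_voxels) + length(pj$unmapped_sites), 2)
  # all projected voxels concentrate at one angular position
  dm <- ph$dim
  ijk <- arrayInd(which(pj$voxels$flags), dm)
  ctr <- dm[1:2] / 2 + 0.5
  ang <- atan2(ijk[, 2] - ctr[2], ijk[, 1] - ctr[1])
  spread <- diff(range(((ang - mean(ang) + pi) %% (2 * pi)) - pi))
  expect_lt(spread, 0.35)  # ~1 voxel wide at the cavity radius
  # axial span covers the placement band
  expect_gt(diff(range(ijk[, 3])), 0.6 * dm[3])
  # network voxels stay inside the shell
  expect_true(all(mp$shell$flags[pj$voxels$flags]))
})

test_that("an empty texture projects to nothing with all sites unmapped", {
  sv <- synth_ventricles("cylinder", list(n = 40L, r_cavity = 0.3,
                                          r_outer = 0.45))
  ph <- sv$phase
  cp <- synth_curve_for(ph, suppressWarnings(
    isolate_chamber(ph, sv$chamber_seeds[[1]])))
  suppressWarnings(
    net <- network_image(matrix(FALSE, 24, 24),
                         data.frame(site_id = 1:3, u1 = c(2, 12, 20),
                                    u2 = c(5, 12, 18))))
  mp <- suppressWarnings(map_network(ph, sv$chamber_seeds[[1]], cp, net,
                    list(chart = list(n_seeds = 96L, quadrature_n = 512L,
                                      max_extent_vox = 8L,
                                      bounds_margin_vox = 2L))))
  expect_equal(sum(mp$projected$voxels$flags), 0)
  expect_equal(length(mp$projected$unmapped_sites), 3)
  expect_equal(nrow(mp$projected$site_voxels), 0)
})

test_that("coverage never shrinks when the placement rectangle grows", {
  sv <- synth_ventricles("cylinder", list(n = 40L, r_cavity = 0.3,
                                          r_outer = 0.45))
  ph <- sv$phase
  chm <- suppressWarnings(isolate_chamber(ph, sv$chamber_seeds[[1]]))
  cp <- synth_curve_for(ph, chm)
  net <- synth_network_image(W = 32, H = 32, depth = 2, seed = 4)
  cfg <- list(chart = list(n_seeds = 96L, quadrature_n = 512L,
                           max_extent_vox = 8L, bounds_margin_vox = 2L))
  mp <- map_network(ph, sv$chamber_seeds[[1]], cp, net, cfg)
  L <- mp$chart$wrap_length
  zr <- range((arrayInd(which(mp$shell$flags), ph$dim)[, 3] - 0.5) * ph$spacing)
  small <- placement_rect(0, L / 2, zr[1] + 0.2, zr[2] - 0.2)
  large <- placement_rect(0, L, zr[1], zr[2])
  n_small <- sum(project_network(mp$chart, small, net, mp$shell, ph)$voxels$flags)
  n_large <- sum(project_network(mp$chart, large, net, mp$shell, ph)$voxels$flags)
  expect_gte(n_large, n_small)
})
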