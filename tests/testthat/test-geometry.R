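test_that("phase fields and masks validate their invariants", {
  expect_error(phase_field(array(2, c(4, 4, 4)), 0.025), "\\[0, 1\\]")
  expect_error(phase_field(array(0.5, c(4, 4, 4)), -1), "spacing")
  expect_error(phase_field(array(0.5, c(4, 4, 4)), 0.025, axis = 5), "axis")
  expect_error(voxel_mask(array(1, c(2, 2, 2)), "shell"), "logical")
})

test_that("chamber isolation recovers the analytic cavity volume", {
  sv <- synth_ventricles("hollow_sphere",
                         list(n = 48L, r_inner = 0.25, r_outer = 0.4))
  ch <- isolate_chamber(sv$phase, sv$chamber_seeds[[1]])
  analytic <- 4 / 3 * pi * (0.25 / 0.025)^3
  expect_lt(abs(sum(ch$flags) - analytic) / analytic, 0.05)
})

test_that("a seed in tissue is rejected and open cavities warn", {
  solid <- phase_field(array(1, c(10, 10, 10)), 0.025)
  expect_error(isolate_chamber(solid, c(5, 5, 5)), "tissue")
  cyl <- synth_ventricles("cylinder", list(n = 32L, r_cavity = 0.2,
                                           r_outer = 0.3))
  expect_warning(isolate_chamber(cyl$phase, cyl$chamber_seeds[[1]]),
                 "boundary")
})

test_that("flood fill stays inside one cavity of a two-cavity geometry", {
  sv <- synth_ventricles("ellipsoid_pair", list(n = 64L))
  c1 <- isolate_chamber(sv$phase, sv$chamber_seeds[[1]])
  c2 <- isolate_chamber(sv$phase, sv$chamber_seeds[[2]])
  expect_gt(sum(c1$flags), 0)
  expect_gt(sum(c2$flags), 0)
  expect_false(any(c1$flags & c2$flags))
  # exactly two cavity components: their union is all sub-threshold interior
  # voxels reachable from either seed
  expect_false(c1$flags[sv$chamber_seeds[[2]][1], sv$chamber_seeds[[2]][2],
                        sv$chamber_seeds[[2]][3]])
})

test_that("shell thickness follows the kernel radius", {
  sv <- synth_ventricles("hollow_sphere",
                         list(n = 48L, r_inner = 0.25, r_outer = 0.45))
  ch <- isolate_chamber(sv$phase, sv$chamber_seeds[[1]])
  sh <- extract_shell(sv$phase, ch, kernel_radius = 3)
  # ray-cast thickness: count shell voxels along radial rays from the center
  ctr <- (dim(sv$phase$values) + 1) / 2
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                c(0, -1, 0), c(0, 0, -1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  thick <- apply(dirs, 1, function(d) {
    r <- seq(0, 22, by = 0.25)
    pts <- round(sweep(outer(r, d), 2, ctr, `+`))
    pts <- unique(pts)
    sum(sh$flags[pts])
  })
  expect_true(all(abs(thick - 3) <= 1.5))
})

test_that("the radius-1 kernel shell sits inside the one-voxel dilation", {
  sv <- synth_ventricles("hollow_sphere",
                         list(n = 32L, r_inner = 0.15, r_outer = 0.3))
  ch <- isolate_chamber(sv$phase, sv$chamber_seeds[[1]])
  sh <- extract_shell(sv$phase, ch, kernel_radius = 1)
  # oracle: 26-dilate the chamber by one voxel, intersect with tissue.  The
  # strictly-greater-than-1 count excludes dilation voxels touching exactly
  # one cavity voxel, so the shell is a (near-complete) subset of the
  # dilation, never larger.
  dm <- dim(ch$flags)
  dil <- array(FALSE, dm)
  ijk <- arrayInd(which(ch$flags), dm)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    ii <- pmin(pmax(ijk[, 1] + dx, 1), dm[1])
    jj <- pmin(pmax(ijk[, 2] + dy, 1), dm[2])
    kk <- pmin(pmax(ijk[, 3] + dz, 1), dm[3])
    dil[cbind(ii, jj, kk)] <- TRUE
  }
  oracle <- dil & (sv$phase$values >= 0.5)
  expect_true(all(oracle[sh$flags]))
  # exact oracle: direct neighbor counting under the radius-1 spherical
  # kernel (self + 6 face neighbors), strictly-greater-than-1 threshold
  cnt <- ch$flags + 0
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    shifted <- array(0, dm)
    src_i <- pmax(1 - d[1], 1):pmin(dm[1] - d[1], dm[1])
    src_j <- pmax(1 - d[2], 1):pmin(dm[2] - d[2], dm[2])
    src_k <- pmax(1 - d[3], 1):pmin(dm[3] - d[3], dm[3])
    shifted[src_i + d[1], src_j + d[2], src_k + d[3]] <-
      ch$flags[src_i, src_j, src_k]
    cnt <- cnt + shifted
  }
  direct <- (cnt > 1) & (sv$phase$values >= 0.5)
  expect_identical(sh$flags, direct)
})

test_that("empty chambers yield empty shells with a warning", {
  sv <- synth_ventricles("hollow_sphere", list(n = 24L, r_inner = 0.1,
                                               r_outer = 0.2))
  empty <- voxel_mask(array(FALSE, dim(sv$phase$values)), "chamber",
                      spacing = 0.025)
  expect_warning(sh <- extract_shell(sv$phase, empty), "empty")
  expect_equal(sum(sh$flags), 0)
})

test_that("shells are inside tissue, disjoint from the cavity, and watertight", {
  for (kind in c("hollow_sphere", "cylinder")) {
    sv <- synth_ventricles(kind, list(n = 40L))
    ch <- suppressWarnings(isolate_chamber(sv$phase, sv$chamber_seeds[[1]]))
    sh <- extract_shell(sv$phase, ch, kernel_radius = 3)
    expect_true(all(sv$phase$values[sh$flags] >= 0.5))
    expect_false(any(sh$flags & ch$flags))
    # watertight: every cavity voxel with a tissue face-neighbor must have a
    # 26-neighbor in the shell
    dm <- dim(ch$flags)
    idx <- which(ch$flags)
    ijk <- arrayInd(idx, dm)
    interior <- ijk[, 1] > 1 & ijk[, 1] < dm[1] & ijk[, 2] > 1 &
      ijk[, 2] < dm[2] & ijk[, 3] > 1 & ijk[, 3] < dm[3]
    ijk <- ijk[interior, , drop = FALSE]
    tissue <- sv$phase$values >= 0.5
    on_boundary <- rep(FALSE, nrow(ijk))
    has_shell_nb <- rep(FALSE, nrow(ijk))
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
      on_boundary <- on_boundary |
        tissue[cbind(ijk[, 1] + d[1], ijk[, 2] + d[2], ijk[, 3] + d[3])]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      has_shell_nb <- has_shell_nb |
        sh$flags[cbind(ijk[, 1] + dx, ijk[, 2] + dy, ijk[, 3] + dz)]
    expect_true(all(has_shell_nb[on_boundary]))
  }
})

test_that("synthetic geometries are valid and deterministic", {
  a <- synth_ventricles("cylinder", list(n = 32L), seed = 3)
  b <- synth_ventricles("cylinder", list(n = 32L), seed = 3)
  expect_identical(a$phase$values, b$phase$values)
  # exact cylinder: cavity-boundary voxels are equidistant from the axis
  ch <- suppressWarnings(isolate_chamber(a$phase, a$chamber_seeds[[1]]))
  dm <- dim(ch$flags)
  idx <- which(ch$flags)
  ijk <- arrayInd(idx, dm)
  tissue <- a$phase$values >= 0.5
  boundary <- rep(FALSE, nrow(ijk))
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0))) {
    ii <- pmin(pmax(ijk[, 1] + d[1], 1), dm[1])
    jj <- pmin(pmax(ijk[, 2] + d[2], 1), dm[2])
    boundary <- boundary | tissue[cbind(ii, jj, ijk[, 3])]
  }
  ctr <- dm[1:2] / 2 + 0.5  # voxel-index coordinate of the domain center
  rho <- sqrt((ijk[boundary, 1] - ctr[1])^2 + (ijk[boundary, 2] - ctr[2])^2)
  expect_lt(diff(range(rho)), 1 + 1e-9)
  expect_error(synth_ventricles("hollow_sphere", list(r_inner = 0.5,
                                                      r_outer = 0.3)),
               "r_inner")
})
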