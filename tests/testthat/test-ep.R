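test_that("membrane rates match the two-variable model formulas", {
  p <- membrane_params()
  r0 <- membrane_rates(0, 1, p)
  expect_equal(r0$dv_reaction, 0)
  expect_equal(r0$dh, 0)
  r1 <- membrane_rates(1, 0, p)
  expect_equal(r1$dv_reaction, -1 / p$tau_out)
  # above the gate the recovery variable closes
  expect_equal(membrane_rates(0.5, 0.8, p)$dh, -0.8 / p$tau_close)
  expect_error(membrane_params(tau_in = -1), "positive")
  expect_error(membrane_params(v_gate = 1.5), "v_gate")
})

test_that("the single-cell trajectory matches a reference ODE solution", {
  skip_if_not_installed("deSolve")
  p <- membrane_params()
  rhs <- function(t, y, parms) {
    r <- membrane_rates(y[1], y[2], p)
    list(c(r$dv_reaction, r$dh))
  }
  ref <- deSolve::ode(c(v = 0.3, h = 1), seq(0, 500, by = 0.5), rhs, NULL)
  # package path: a diffusion-free one-node domain stepped explicitly
  dom <- tissue_domain(array(TRUE, c(2, 1)), spacing = 0.025,
                       diffusivity = 0, params = p)
  st <- ep_state(dom, v0 = 0.3)
  res <- run_monodomain(dom, NULL, t_end = 500, dt = 0.01, state = st)
  # action potential: upstroke beyond 0.9 then full repolarization
  expect_gt(max(ref[, "v"]), 0.9)
  expect_gt(max(0.3, max(ref[, "v"])), 0.9)
  expect_lt(ref[nrow(ref), "v"], 0.05)
  expect_lt(res$state$v[1, 1], 0.05)
  expect_equal(res$activation[1, 1],
               unname(ref[min(which(ref[, "v"] >= 0.5)), "time"]),
               tolerance = 1)
})

test_that("a uniform state with reaction off is a fixed point", {
  set.seed(2)
  mask <- array(runif(18 * 18) > 0.25, c(18, 18))
  ph <- array(runif(18 * 18) * 0.6 + 0.4, c(18, 18)) * mask
  dom <- tissue_domain(mask, phase = ph, spacing = 0.025, diffusivity = 0.001)
  st <- ep_state(dom, v0 = 0.42)
  out <- monodomain_step(st, dom, dt = 0.1, reaction = FALSE)
  expect_identical(out$v[mask], st$v[mask])
})

test_that("diffusion conserves the phase-weighted total of v", {
  set.seed(3)
  mask <- array(runif(16 * 16 * 8) > 0.3, c(16, 16, 8))
  ph <- array(runif(16 * 16 * 8) * 0.7 + 0.3, c(16, 16, 8)) * mask
  dom <- tissue_domain(mask, phase = ph, spacing = 0.025, diffusivity = 0.001)
  st <- ep_state(dom, v0 = array(runif(16 * 16 * 8), c(16, 16, 8)))
  tot0 <- sum(ph[mask] * st$v[mask])
  s <- st
  dt <- 0.9 * stability_dt(dom)
  for (k in 1:25) {
    s <- monodomain_step(s, dom, dt = dt, reaction = FALSE)
    tot <- sum(ph[mask] * s$v[mask])
    expect_lt(abs(tot - tot0) / abs(tot0), 1e-10)
  }
})

test_that("time steps violating the stability bound are rejected", {
  dom <- tissue_domain(array(TRUE, c(10, 10)), spacing = 0.025,
                       diffusivity = 0.02)
  expect_error(monodomain_step(ep_state(dom), dom, dt = 0.05), "stability")
  # the face-stencil bound reduces to the textbook formula
  expect_equal(stability_dt(dom), 0.025^2 / (2 * 2 * 0.02))
})

test_that("gate variable stays in [0, 1] under prolonged stepping", {
  dom <- tissue_domain(array(TRUE, c(30, 1)), spacing = 0.025,
                       diffusivity = 0.001)
  proto <- apply_stimulus_protocol(dom, 1:5, amplitude = 2, duration = 1)
  res <- run_monodomain(dom, proto, t_end = 400, dt = 0.1)
  expect_true(all(res$state$h >= 0 & res$state$h <= 1))
})

test_that("stimulus currents are additive and zero-amplitude is inert", {
  dom <- tissue_domain(array(TRUE, c(40, 1)), spacing = 0.025,
                       diffusivity = 0.001)
  base <- run_monodomain(dom, NULL, t_end = 5, dt = 0.01)
  zero <- run_monodomain(dom, apply_stimulus_protocol(dom, 1:3, amplitude = 0),
                         t_end = 5, dt = 0.01)
  expect_identical(base$state$v, zero$state$v)
  p1 <- apply_stimulus_protocol(dom, 1:3, amplitude = 1, duration = 2)
  p2 <- combine_protocols(p1, p1)
  pd <- apply_stimulus_protocol(dom, 1:3, amplitude = 2, duration = 2)
  a <- run_monodomain(dom, p2, t_end = 1, dt = 0.01)
  b <- run_monodomain(dom, pd, t_end = 1, dt = 0.01)
  expect_equal(a$state$v, b$state$v, tolerance = 1e-12)
  expect_error(apply_stimulus_protocol(dom, 10000, 1), "inactive")
  expect_error(apply_stimulus_protocol(dom, integer(0), 1), "nonempty")
})

test_that("a stimulated cable propagates to the far end and returns to rest", {
  dom <- tissue_domain(array(TRUE, c(60, 1)), spacing = 0.025,
                       diffusivity = 0.001)
  proto <- apply_stimulus_protocol(dom, 1:5, amplitude = 2, duration = 1)
  res <- run_monodomain(dom, proto, t_end = 1000, dt = 0.1)
  expect_true(is.finite(res$activation[60, 1]))
  expect_lt(max(abs(res$state$v)), 1e-3)
})

test_that("plane-wave conduction speed is isotropic across 1D and 2D", {
  cv_1d <- local({
    dom <- tissue_domain(array(TRUE, c(200, 1)), spacing = 0.025,
                         diffusivity = 0.001)
    proto <- apply_stimulus_protocol(dom, 1:5, amplitude = 2, duration = 1)
    res <- run_monodomain(dom, proto, t_end = 150, dt = 0.05,
                          stop_when_activated = TRUE)
    a <- res$activation[, 1]
    (180 - 60) * 0.025 / (a[180] - a[60])
  })
  cv_2d <- local({
    dom <- tissue_domain(array(TRUE, c(200, 12)), spacing = 0.025,
                         diffusivity = 0.001)
    first_col <- seq_len(12) * 200 - 199
    proto <- apply_stimulus_protocol(dom, c(outer(1:5, (0:11) * 200, "+")),
                                     amplitude = 2, duration = 1)
    res <- run_monodomain(dom, proto, t_end = 150, dt = 0.05,
                          stop_when_activated = TRUE)
    a <- res$activation[, 6]
    (180 - 60) * 0.025 / (a[180] - a[60])
  })
  expect_lt(abs(cv_2d - cv_1d) / cv_1d, 0.03)
})

test_that("2D network spacing follows the placement rectangle arithmetic", {
  # a placement band spanning 200 ventricular cells, 400 px wide
  rect <- placement_rect(0, 200 * 0.025, 0, 100 * 0.025)
  sp <- grid_spacing_2d(rect, 400, 100, 0.025)
  expect_equal(sp[1], 0.0125)
  expect_equal(sp[2], 0.025)
  # aspect-preserving square band gives equal spacings
  rect2 <- placement_rect(0, 1, 0, 1, preserve_aspect = TRUE)
  sp2 <- grid_spacing_2d(rect2, 64, 64, 0.025)
  expect_equal(sp2[1], sp2[2])
  # doubling W halves the x spacing
  expect_equal(grid_spacing_2d(rect, 800, 100, 0.025)[1], 0.00625)
  expect_error(grid_spacing_2d(rect, 0, 100, 0.025), "positive")
})

test_that("anisotropic tensors are rejected with a clear message", {
  expect_error(
    tissue_domain(array(TRUE, c(4, 4)), spacing = 0.025,
                  diffusivity = array(1, c(4, 4, 3, 3))),
    "anisotropic")
})
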