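test_that("a pure-pressure stress state has zero tangential traction", {
  # sigma = -p0 I for several normals
  for (n in list(c(1, 0, 0), c(0, 1, 0), c(0.6, 0.8, 0),
                 c(1, 1, 1) / sqrt(3))) {
    w <- wss_vector(c(-250, -250, -250, 0, 0, 0), n)
    expect_equal(w$magnitude, 0, tolerance = 1e-12)
  }
})

test_that("uniform shear projects to mu*gamma along the flow direction", {
  mu <- 3.5e-3; gam <- 120
  sig <- c(-10, -10, -10, mu * gam, 0, 0)       # sigma_xy = sigma_yx
  w <- wss_vector(sig, c(0, 1, 0))
  expect_equal(w$vector[1, ], c(mu * gam, 0, 0), tolerance = 1e-15)
  expect_equal(w$magnitude, mu * gam, tolerance = 1e-15)
})

test_that("non-unit normals are normalized with a warning", {
  expect_warning(w <- wss_vector(c(0, 0, 0, 1, 0, 0), c(0, 2, 0)),
                 "normalized")
  expect_equal(w$vector[1, 1], 1)
})

test_that("wall stress of a sampled uniform shear field is the hand value", {
  fx <- tiny_straight()
  m <- fx$mesh
  gam <- 80
  fake <- fx$sol
  fake$velocity <- cbind(gam * m$nodes[, 2], 0, 0)   # v = (gamma y, 0, 0)
  fake$pressure <- rep(500, nrow(m$nodes))
  sig <- cauchy_stress_at_wall(fake, m)
  mu <- fx$props$mu
  expect_lt(max(abs(sig[, "xy"] - mu * gam)), 1e-9)
  expect_lt(max(abs(sig[, c("xx", "yy", "zz")] + 500)), 1e-9)
  expect_lt(max(abs(sig[, c("xz", "yz")])), 1e-9)
})

test_that("computed WSS vectors are tangent to the wall", {
  fx <- tiny_curved()
  field <- compute_wss(fx$sol, fx$mesh)
  dots <- abs(rowSums(field$wss_vector * field$normal))
  expect_lt(max(dots / pmax(field$wss_magnitude, 1e-30)), 1e-9)
  expect_true(all(field$wss_magnitude >= 0))
})

test_that("Stokes-mode WSS scales exactly with the flow", {
  fx <- tiny_straight()
  cfg <- solver_config(convective = FALSE)
  s1 <- solve_flow(fx$mesh, fx$bc, fx$props, cfg)
  bc2 <- boundary_conditions(q_in = 2 * fx$q_in, v_in = 2 * fx$v_in,
                             r_out = 1.2e9)
  s2 <- solve_flow(fx$mesh, bc2, fx$props, cfg)
  f1 <- compute_wss(s1, fx$mesh)
  f2 <- compute_wss(s2, fx$mesh)
  expect_equal(f2$wss_magnitude, 2 * f1$wss_magnitude, tolerance = 1e-9)
})

test_that("regional means weight faces by area", {
  f <- fake_wss_field(c(7.5, 7.5, 7.5))
  expect_equal(regional_mean_wss(f, 1:3), 7.5)
  f2 <- fake_wss_field(c(4, 8), area = c(1, 1))
  expect_equal(regional_mean_wss(f2, 1:2), 6)
  f3 <- fake_wss_field(c(4, 8), area = c(1, 3))
  expect_equal(regional_mean_wss(f3, 1:2), 7)
  expect_equal(regional_mean_wss(f3, 1:2, weighting = "uniform"), 6)
  expect_error(regional_mean_wss(f3, integer(0)), "empty")
})

test_that("cap-adjacent faces are excluded from regional means", {
  fx <- tiny_straight()
  field <- compute_wss(fx$sol, fx$mesh, cap_exclusion = 2)
  expect_true(any(field$excluded))
  L <- max(fx$mesh$meta$centerline$arclengths)
  expect_true(all(field$arclength[field$excluded] < 0.25 * L |
                  field$arclength[field$excluded] > 0.75 * L))
})

test_that("tube wall WSS approaches the Poiseuille value on the tiny mesh", {
  fx <- tiny_straight()
  field <- compute_wss(fx$sol, fx$mesh)
  wa <- 4 * fx$props$mu * fx$v_in / fx$r
  wm <- regional_mean_wss(field, seq_along(field$face_ids))
  expect_lt(abs(wm - wa) / wa, 0.15)   # refined oracle in the acceptance suite
})
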