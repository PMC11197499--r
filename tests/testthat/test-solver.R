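test_that("zero inflow and zero pressure give the trivial solution", {
  fx <- tiny_straight()
  bz <- boundary_conditions(q_in = 0, r_out = 1e9, allow_zero = TRUE)
  sz <- solve_flow(fx$mesh, bz, fx$props, solver_config())
  expect_equal(max(abs(sz$velocity)), 0)
  expect_equal(diff(range(sz$pressure)), 0)   # constant pressure
  expect_equal(check_mass_conservation(sz, fx$mesh), 0)
})

test_that("Stokes-mode solutions are exactly linear in the flow rate", {
  fx <- tiny_straight()
  cfg <- solver_config(convective = FALSE)
  s1 <- solve_flow(fx$mesh, fx$bc, fx$props, cfg)
  bc2 <- boundary_conditions(q_in = 3 * fx$q_in, v_in = 3 * fx$v_in,
                             r_out = 1.2e9)
  s2 <- solve_flow(fx$mesh, bc2, fx$props, cfg)
  expect_equal(s2$velocity, 3 * s1$velocity, tolerance = 1e-12)
})

test_that("converged solves conserve mass to well below 1e-3", {
  for (fx in list(tiny_straight(), tiny_curved())) {
    expect_true(fx$sol$converged)
    expect_lt(check_mass_conservation(fx$sol, fx$mesh), 1e-3)
  }
})

test_that("the transient backward-Euler path reaches the same steady state", {
  fx <- tiny_straight()
  tr <- solve_flow(fx$mesh, fx$bc, fx$props,
                   solver_config(steady = FALSE, dt = 0.01, t_end = 3,
                                 tol_nonlinear = 1e-4))
  expect_true(tr$converged)
  rel <- sqrt(sum((tr$velocity - fx$sol$velocity)^2) /
              sum(fx$sol$velocity^2))
  expect_lt(rel, 1e-3)
  # steady state independent of the time step
  tr2 <- solve_flow(fx$mesh, fx$bc, fx$props,
                    solver_config(steady = FALSE, dt = 0.005, t_end = 3,
                                  tol_nonlinear = 1e-4))
  rel_dt <- sqrt(sum((tr2$velocity - tr$velocity)^2) / sum(tr$velocity^2))
  expect_lt(rel_dt, 1e-3)
})

test_that("a pulsatile waveform advances stably from rest", {
  fx <- tiny_straight()
  bp <- boundary_conditions(q_in = fx$q_in, v_in = fx$v_in, r_out = 1.2e9,
                            waveform = "pulsatile", period = 1,
                            pulse_amplitude = 0.2)
  pu <- solve_flow(fx$mesh, bp, fx$props,
                   solver_config(steady = FALSE, dt = 0.01, t_end = 0.05))
  expect_true(all(is.finite(pu$velocity)))
  expect_equal(length(pu$times), 5L)
})

test_that("forward flow loses pressure from inlet to outlet", {
  fx <- tiny_straight()
  m <- fx$mesh
  inlet_nodes <- unique(as.integer(
    m$boundary_faces[m$face_label == "inlet", ]))
  outlet_nodes <- unique(as.integer(
    m$boundary_faces[m$face_label == "outlet_1", ]))
  expect_gt(mean(fx$sol$pressure[inlet_nodes]),
            mean(fx$sol$pressure[outlet_nodes]))
})

test_that("the resistance outlet satisfies P_out = R_out Q_out at steady state", {
  fx <- tiny_straight()
  expect_equal(unname(fx$sol$p_out), 1.2e9 * unname(fx$sol$q_out),
               tolerance = 1e-9)
  # and the measured outlet flux reproduces the stored q_out
  q_meas <- hemowss:::.face_flux(fx$mesh, fx$sol$velocity,
                                 fx$mesh$face_label == "outlet_1")
  expect_equal(unname(fx$sol$q_out), q_meas, tolerance = 1e-12)
})

test_that("Poiseuille centerline velocity emerges on the tiny mesh", {
  fx <- tiny_straight()
  m <- fx$mesh
  ns <- m$meta$n_z + 1L
  mid <- (ns %/% 2L) * (1L + m$meta$n_r * m$meta$n_theta) + 1L
  va <- 2 * fx$q_in / (pi * fx$r^2)
  # coarse mesh: generous band; the refined oracle lives in the acceptance
  # suite
  expect_lt(abs(fx$sol$velocity[mid, 1] - va) / va, 0.15)
})

test_that("solution VTU export carries velocity and pressure arrays", {
  fx <- tiny_straight()
  path <- tempfile(fileext = ".vtu")
  write_solution_vtu(fx$sol, fx$mesh, path)
  x <- xml2::read_xml(path)
  nms <- xml2::xml_attr(xml2::xml_find_all(x, "//PointData/DataArray"),
                        "Name")
  expect_setequal(nms, c("velocity", "pressure"))
  unlink(path)
})
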