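#' Blood material properties
#'
#' Constant-density, constant-viscosity Newtonian blood: density
#' 1.06e3 kg/m^3 and dynamic viscosity 3.5e-3 kg/(m s) by default.
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, kg m^-1 s^-1.
#' @return object of class `blood_properties`.
#' @export
blood_properties <- function(rho = 1.06e3, mu = 3.5e-3) {
  .assert_positive(rho, "rho"); .assert_positive(mu, "mu")
  structure(list(rho = rho, mu = mu), class = "blood_properties")
}

#' Characteristic scales and Reynolds number
#'
#' Characteristic length and velocity for the flow regime assessment; the
#' defaults are a carotid-artery diameter of 6.0e-3 m and 0.4 m/s. The
#' Reynolds number is always computed from the formula
#' \eqn{Re = \rho v D / \mu}.
#'
#' @param D characteristic length, m.
#' @param v_char characteristic velocity, m/s.
#' @param props a [blood_properties()].
#' @return object of class `characteristic_scales` with the derived `Re`.
#' @export
characteristic_scales <- function(D = 6.0e-3, v_char = 0.4,
                                  props = blood_properties()) {
  .assert_positive(D, "D"); if (v_char < 0) stop("`v_char` must be >= 0",
                                                 call. = FALSE)
  structure(list(D = D, v_char = v_char,
                 Re = props$rho * v_char * D / props$mu),
            class = "characteristic_scales")
}

#' Reynolds number and laminar-regime flag
#'
#' \eqn{Re = \rho v D / \mu}; the flow is flagged laminar below the pipe-flow
#' transition threshold of 2300. With the default blood constants and
#' characteristic scales this evaluates to about 727.
#'
#' @param props a [blood_properties()].
#' @param scales a [characteristic_scales()].
#' @return list(Re, laminar).
#' @export
#' @examples
#' reynolds_number()   # Re ~ 726.9, laminar
reynolds_number <- function(props = blood_properties(),
                            scales = characteristic_scales(props = props)) {
  Re <- props$rho * scales$v_char * scales$D / props$mu
  list(Re = Re, laminar = Re < 2300)
}

#' Mean inflow velocity from systolic and diastolic Doppler velocities
#'
#' Cycle-mean inflow velocity as a weighted combination
#' \eqn{V_{in} = w_{sys} V_{systole} + w_{dia} V_{diastole}}. The default
#' weights are (1/3, 2/3), the classical mean-velocity estimate whose weights
#' sum to one; the alternative literal weighting (1/2, 2/3) is available via
#' `weights` for sensitivity analyses (see the methods vignette on this
#' ambiguity).
#'
#' @param v_systole peak systolic velocity, m/s.
#' @param v_diastole diastolic velocity, m/s.
#' @param weights length-2 positive weights (systolic, diastolic).
#' @return V_in in m/s.
#' @export
#' @examples
#' mean_inlet_velocity(0.6, 0.3)                      # 0.4
#' mean_inlet_velocity(0.6, 0.3, c(1 / 2, 2 / 3))     # 0.5
mean_inlet_velocity <- function(v_systole, v_diastole,
                                weights = c(1 / 3, 2 / 3)) {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(v_diastole > v_systole))
    warning("v_diastole exceeds v_systole")
  weights[1] * v_systole + weights[2] * v_diastole
}

#' Inlet cross-sectional area and flow rate
#'
#' \eqn{A_{in}} from the measured lumen radius and \eqn{Q_{in} = V_{in} A_{in}}.
#' The default convention is the geometric cross-section \eqn{\pi r^2}; a
#' `paper_2pi_r2` convention (doubled area, e.g. for paired arteries treated
#' as one inflow) is available.
#'
#' @param v_in mean inflow velocity, m/s.
#' @param r lumen radius, m.
#' @param area_convention `"pi_r2"` (default) or `"paper_2pi_r2"`.
#' @return list(A_in (m^2), Q_in (m^3/s)).
#' @export
#' @examples
#' inlet_flow_rate(0.4, 0.003)   # A = 2.827e-5, Q = 1.131e-5
inlet_flow_rate <- function(v_in, r,
                            area_convention = c("pi_r2", "paper_2pi_r2")) {
  area_convention <- match.arg(area_convention)
  .assert_positive(r, "r")
  A <- pi * r^2 * if (area_convention == "paper_2pi_r2") 2 else 1
  list(A_in = A, Q_in = v_in * A)
}

#' Total and per-outlet flow resistance
#'
#' Total peripheral resistance \eqn{R_{total} = P / Q_{in}} from the brachial
#' pressure and the total inflow, distributed over the outlets so that the
#' parallel combination reproduces \eqn{R_{total}}. The flow split is
#' Murray-law-like: outlet flow fractions proportional to
#' \eqn{r_k^{3}} (equivalently \eqn{A_k^{3/2}}), with the exponent
#' configurable; each outlet then gets \eqn{R_{out,k} = R_{total} / f_k}
#' where \eqn{f_k} is its flow fraction (so \eqn{\sum 1/R_{out,k} =
#' 1/R_{total}}).
#'
#' @param p_brachial brachial pressure, Pa.
#' @param q_in_total total inflow, m^3/s.
#' @param outlet_areas outlet cross-sectional areas, m^2.
#' @param radius_exponent exponent on outlet radius in the split law.
#' @return list(R_total, R_out (per outlet), flow_fraction).
#' @export
#' @examples
#' total_and_outlet_resistance(12000, 1e-5, outlet_areas = 1e-5)
total_and_outlet_resistance <- function(p_brachial, q_in_total, outlet_areas,
                                        radius_exponent = 3) {
  .assert_positive(p_brachial, "p_brachial")
  if (!is.numeric(q_in_total) || q_in_total <= 0)
    stop("zero or negative total inflow: R_total = P/Q_in is undefined",
         call. = FALSE)
  .assert_positive(outlet_areas, "outlet_areas")
  R_total <- p_brachial / q_in_total
  r_eq <- sqrt(outlet_areas / pi)
  f <- r_eq^radius_exponent
  f <- f / sum(f)
  list(R_total = R_total, R_out = R_total / f, flow_fraction = f)
}

#' Assemble a boundary-condition set
#'
#' Bundles the inflow (flow rate, mean velocity, area), the per-outlet
#' resistances, the brachial pressure and the (zero by default) body force
#' into the structure consumed by [solve_flow()]. For the single-inlet
#' meshes produced by [tetrahedralize()] there is one inflow; the formulas
#' accept any number of inflow arteries when used standalone.
#'
#' @param q_in inflow rate, m^3/s (> 0 unless `allow_zero`).
#' @param v_in mean inflow velocity, m/s.
#' @param a_in inflow area, m^2.
#' @param r_out per-outlet resistance(s), Pa s/m^3.
#' @param r_total total resistance, Pa s/m^3.
#' @param p_brachial brachial pressure, Pa.
#' @param body_force length-3 body force per unit mass (default zero, stored
#'   explicitly).
#' @param waveform `"steady"` (default) or `"pulsatile"`.
#' @param pulse_amplitude relative sinusoidal modulation for the pulsatile
#'   waveform.
#' @param period cardiac period (s) for the pulsatile waveform.
#' @param allow_zero allow a degenerate zero-inflow condition (for trivial
#'   solution tests).
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(q_in, v_in = NULL, a_in = NULL, r_out,
                                r_total = sum(r_out) / length(r_out)^2,
                                p_brachial = NULL,
                                body_force = c(0, 0, 0),
                                waveform = c("steady", "pulsatile"),
                                pulse_amplitude = 0.2, period = 1,
                                allow_zero = FALSE) {
  waveform <- match.arg(waveform)
  if (q_in < 0 || (q_in == 0 && !allow_zero))
    stop("`q_in` must be positive at each inlet", call. = FALSE)
  if (any(r_out <= 0)) stop("`r_out` must be positive", call. = FALSE)
  structure(list(q_in = q_in, v_in = v_in, a_in = a_in, r_out = r_out,
                 r_total = r_total, p_brachial = p_brachial,
                 body_force = body_force, waveform = waveform,
                 pulse_amplitude = pulse_amplitude, period = period),
            class = "boundary_conditions")
}

#' Boundary conditions from a synthetic ultrasound panel
#'
#' Applies the measurement-to-boundary-condition chain to one inflow artery
#' of a panel: mean velocity from the Doppler pair, inflow from the lumen
#' area, total resistance from the brachial pressure, and the outlet split.
#'
#' @param panel list from [make_ultrasound_panel()] or [read_panel_csv()].
#' @param artery row index of the inflow artery in the panel.
#' @param outlet_areas outlet areas of the simulated vessel, m^2.
#' @param weights,area_convention passed to [mean_inlet_velocity()] /
#'   [inlet_flow_rate()].
#' @return a [boundary_conditions()] object.
#' @export
bc_from_panel <- function(panel, artery = 1L, outlet_areas,
                          weights = c(1 / 3, 2 / 3),
                          area_convention = "pi_r2") {
  row <- panel$panel[artery, ]
  v_in <- mean_inlet_velocity(row$v_systole_m_s, row$v_diastole_m_s, weights)
  fl <- inlet_flow_rate(v_in, row$radius_m, area_convention)
  res <- total_and_outlet_resistance(panel$pressure_pa, fl$Q_in, outlet_areas)
  boundary_conditions(q_in = fl$Q_in, v_in = v_in, a_in = fl$A_in,
                      r_out = res$R_out, r_total = res$R_total,
                      p_brachial = panel$pressure_pa)
}

#' Solver configuration
#'
#' Numerical controls for [solve_flow()]: the backward-Euler time step
#' (default 0.01 s), the end time, and the relative residual tolerances of
#' the linear (1e-4) and nonlinear (1e-6) solves. `max_picard` bounds the
#' nonlinear fixed-point iterations; `relax` is the under-relaxation of the
#' convective update.
#'
#' @param dt time step, s.
#' @param t_end end time, s (transient mode).
#' @param tol_linear relative linear-solver tolerance, in (0,1).
#' @param tol_nonlinear relative nonlinear tolerance, in (0,1).
#' @param max_picard maximum nonlinear iterations (per step, or total in
#'   steady mode).
#' @param relax under-relaxation factor in (0,1].
#' @param steady solve directly for the steady state (the dt -> infinity
#'   limit of backward Euler); the transient path is used when FALSE.
#' @param convective include the convective term (FALSE gives the Stokes
#'   linearity-test mode).
#' @param verbose print residual history.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.01, t_end = 1, tol_linear = 1e-4,
                          tol_nonlinear = 1e-6, max_picard = 60L,
                          relax = 0.7, steady = TRUE, convective = TRUE,
                          verbose = FALSE) {
  .assert_positive(dt, "dt")
  if (tol_linear <= 0 || tol_linear >= 1 || tol_nonlinear <= 0 ||
      tol_nonlinear >= 1)
    stop("tolerances must lie in (0, 1)", call. = FALSE)
  if (relax <= 0 || relax > 1) stop("`relax` must lie in (0, 1]",
                                    call. = FALSE)
  structure(list(dt = dt, t_end = t_end, tol_linear = tol_linear,
                 tol_nonlinear = tol_nonlinear,
                 max_picard = as.integer(max_picard), relax = relax,
                 steady = steady, convective = convective, verbose = verbose),
            class = "solver_config")
}
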