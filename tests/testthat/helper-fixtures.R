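# Shared fixtures, built lazily and cached for the duration of the run.
# All geometry is generated in code; solver fixtures use desk-scale meshes
# so individual files stay fast, while the acceptance file uses the
# resolutions its criteria specify.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# tiny straight tube + converged steady solve (Re ~ 50)
tiny_straight <- function() fixture("tiny_straight", function() {
  props <- blood_properties()
  r <- 0.002
  cl <- make_centerline("straight", length = 0.012, n_points = 20)
  vessel <- make_vessel_surface(cl, r)
  mesh <- tetrahedralize(vessel, target_edge = 1.1e-3)
  v_in <- 50 * props$mu / (props$rho * 2 * r)
  q_in <- v_in * pi * r^2
  bc <- boundary_conditions(q_in = q_in, v_in = v_in, r_out = 1.2e9)
  sol <- solve_flow(mesh, bc, props, solver_config())
  list(props = props, r = r, vessel = vessel, mesh = mesh, bc = bc,
       v_in = v_in, q_in = q_in, sol = sol)
})

# tiny curved tube + converged steady solve (Re ~ 60)
tiny_curved <- function() fixture("tiny_curved", function() {
  props <- blood_properties()
  r <- 0.002
  cl <- make_centerline("curved", length = 0.02, curve_radius = 0.012,
                        n_points = 60)
  vessel <- make_vessel_surface(cl, r)
  mesh <- tetrahedralize(vessel, target_edge = 9e-4)
  v_in <- 60 * props$mu / (props$rho * 2 * r)
  q_in <- v_in * pi * r^2
  bc <- boundary_conditions(q_in = q_in, v_in = v_in, r_out = 1.2e9)
  sol <- solve_flow(mesh, bc, props, solver_config())
  list(props = props, r = r, vessel = vessel, mesh = mesh, bc = bc,
       v_in = v_in, q_in = q_in, sol = sol)
})

# Poiseuille validation case at the resolution the wall-shear oracle needs
# (~5e4 cells): straight tube r = 2 mm, L = 30 mm, Re ~ 100
poiseuille_case <- function() fixture("poiseuille_case", function() {
  props <- blood_properties()
  r <- 0.002; L <- 0.03
  cl <- make_centerline("straight", length = L)
  vessel <- make_vessel_surface(cl, r)
  mesh <- tetrahedralize(vessel, target_edge = 5e-4)
  v_in <- 100 * props$mu / (props$rho * 2 * r)
  q_in <- v_in * pi * r^2
  bc <- boundary_conditions(q_in = q_in, v_in = v_in, r_out = 1.2e9)
  sol <- solve_flow(mesh, bc, props, solver_config())
  field <- compute_wss(sol, mesh)
  labels <- wall_labels(mesh)
  list(props = props, r = r, L = L, mesh = mesh, bc = bc, v_in = v_in,
       q_in = q_in, sol = sol, field = field, labels = labels)
})

# curved-tube case for the secondary-flow (Dean) direction check:
# curve radius 12 mm, Re ~ 121
curved_case <- function() fixture("curved_case", function() {
  props <- blood_properties()
  r <- 0.002; Rc <- 0.012; L <- 0.036
  cl <- make_centerline("curved", length = L, curve_radius = Rc,
                        n_points = 200)
  vessel <- make_vessel_surface(cl, r)
  mesh <- tetrahedralize(vessel, target_edge = 5.5e-4)
  v_in <- 121 * props$mu / (props$rho * 2 * r)
  q_in <- v_in * pi * r^2
  bc <- boundary_conditions(q_in = q_in, v_in = v_in, r_out = 1.2e9)
  sol <- solve_flow(mesh, bc, props, solver_config(max_picard = 80))
  field <- compute_wss(sol, mesh)
  labels <- wall_labels(mesh)
  list(props = props, r = r, Rc = Rc, L = L, mesh = mesh, bc = bc,
       v_in = v_in, q_in = q_in, sol = sol, field = field, labels = labels)
})

# hand-built wall shear field for weighting/ratio arithmetic tests
fake_wss_field <- function(magnitude, area = rep(1, length(magnitude)),
                           centroid = NULL, excluded = NULL) {
  n <- length(magnitude)
  structure(list(face_ids = seq_len(n),
                 sigma = matrix(0, n, 6),
                 normal = matrix(rep(c(0, 0, 1), each = n), n),
                 wss_vector = cbind(magnitude, 0, 0),
                 wss_magnitude = magnitude,
                 face_area = area,
                 centroid = centroid %||%
                   cbind(seq_len(n) * 1e-3, 0, 0),
                 arclength = seq_len(n) * 1e-3,
                 excluded = excluded %||% rep(FALSE, n)),
            class = "wss_field")
}

# matching label object for fake fields
fake_labels <- function(quadrant, segment = rep("middle", length(quadrant)),
                        curve_side = rep("undefined", length(quadrant)),
                        area = rep(1, length(quadrant))) {
  structure(list(labels = data.frame(
    segment = factor(segment, c("proximal", "middle", "distal")),
    quadrant = factor(quadrant,
                      c("ventral", "dorsal", "superior", "inferior")),
    curve_side = factor(curve_side, c("inner", "outer", "undefined")),
    area = area,
    arclength = seq_along(quadrant) * 1e-3),
    cuts = c(1, 2), wall_faces = seq_along(quadrant),
    centerline = NULL, axes = anatomical_axes()),
    class = "wall_labels")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force oracle for the two-sided Fisher exact p-value:
# enumerate every table with the observed margins and sum the hypergeometric
# probabilities of tables no more probable than the observed one
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- prob(a)
  xs <- lo:hi
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}
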