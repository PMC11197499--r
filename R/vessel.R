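#' Eccentric plaque specification
#'
#' Describes an inward, eccentric lumen narrowing placed on a named wall.
#' Plaque is modeled as wall thickening that reduces the lumen (the flow
#' domain is the lumen, so only lumen shape affects wall shear stress). The
#' thickening falls smoothly to zero at the opposite wall, so every generated
#' plaque satisfies the eccentricity identification rule used in vessel-wall
#' imaging: the thinnest thickening is less than 50% of the thickest.
#'
#' @param wall wall on which the plaque center sits: `"ventral"`, `"dorsal"`,
#'   `"superior"` or `"inferior"`.
#' @param center_arclength arclength (m) of the plaque center.
#' @param extent axial extent (m) of the thickened region.
#' @param depth maximal thickening as a fraction of the base radius, in
#'   (0, 0.9).
#' @param sharpness exponent of the circumferential cosine falloff (>= 1).
#' @return an object of class `plaque_spec`.
#' @export
plaque_spec <- function(wall = c("inferior", "superior", "ventral", "dorsal"),
                        center_arclength, extent, depth, sharpness = 2) {
  wall <- match.arg(wall)
  .assert_positive(extent, "extent")
  .assert_positive(center_arclength, "center_arclength")
  if (depth <= 0 || depth >= 0.9)
    stop("plaque `depth` must lie in (0, 0.9)", call. = FALSE)
  structure(list(wall = wall, center_arclength = center_arclength,
                 extent = extent, depth = depth, sharpness = sharpness),
            class = "plaque_spec")
}

# Anatomical direction vectors (RAS-style): +y anterior/ventral, +z superior.
.wall_direction <- function(wall) {
  switch(wall,
         ventral  = c(0, 1, 0),
         dorsal   = c(0, -1, 0),
         superior = c(0, 0, 1),
         inferior = c(0, 0, -1),
         stop("unknown wall label: ", wall, call. = FALSE))
}

# Thickening fraction at station i (arclength s) and frame angle theta.
# theta is measured in the rotation-minimizing frame (n1, n2).
.plaque_fraction <- function(vessel, i, theta) {
  ps <- vessel$plaque
  if (is.null(ps)) return(rep(0, length(theta)))
  cl <- vessel$centerline
  s <- cl$arclengths[i]
  ax <- abs(s - ps$center_arclength)
  if (ax >= ps$extent / 2) return(rep(0, length(theta)))
  f_ax <- 0.5 * (1 + cos(2 * pi * (s - ps$center_arclength) / ps$extent))
  # azimuth of the plaque wall direction in the local frame
  d <- .wall_direction(ps$wall)
  dp <- d - cl$tangents[i, ] * sum(d * cl$tangents[i, ])
  if (sqrt(sum(dp^2)) < 1e-12) return(rep(0, length(theta)))
  theta0 <- atan2(sum(dp * cl$n2[i, ]), sum(dp * cl$n1[i, ]))
  f_th <- (0.5 * (1 + cos(theta - theta0)))^ps$sharpness
  ps$depth * f_ax * f_th
}

#' Generate a vessel lumen surface swept along a centerline
#'
#' Sweeps a circular cross-section (optionally narrowed by an eccentric
#' plaque) along a centerline using its rotation-minimizing frame and
#' triangulates the lumen boundary. End caps are triangulated separately and
#' flagged, so the surface is watertight while the open inlet/outlet caps
#' remain identifiable.
#'
#' @param centerline a [make_centerline()] object.
#' @param base_radius lumen radius in meters (> 0).
#' @param plaque optional [plaque_spec()].
#' @param n_theta number of circumferential vertices (>= 12).
#' @return an object of class `vessel_geometry` with fields `centerline`,
#'   `base_radius`, `radius_profile`, `plaque`, `vertices`, `faces`
#'   (1-based triangle indices), and `face_type` (`"wall"`, `"cap_inlet"`,
#'   `"cap_outlet"`).
#' @export
#' @examples
#' cl <- make_centerline("straight", length = 0.03)
#' v <- make_vessel_surface(cl, base_radius = 0.002)
#' abs(enclosed_volume(v) - pi * 0.002^2 * 0.03) / (pi * 0.002^2 * 0.03)
make_vessel_surface <- function(centerline, base_radius, plaque = NULL,
                                n_theta = 32L) {
  stopifnot(inherits(centerline, "centerline"))
  .assert_positive(base_radius, "base_radius")
  if (n_theta < 12L) stop("`n_theta` must be >= 12", call. = FALSE)
  if (!is.null(plaque)) {
    stopifnot(inherits(plaque, "plaque_spec"))
    L <- max(centerline$arclengths)
    if (plaque$extent > L)
      stop("plaque extent exceeds vessel length", call. = FALSE)
    if (plaque$center_arclength > L)
      stop("plaque center lies beyond the vessel", call. = FALSE)
  }
  n_pts <- nrow(centerline$points)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  vessel <- list(centerline = centerline, base_radius = base_radius,
                 radius_profile = rep(base_radius, n_pts), plaque = plaque,
                 n_theta = n_theta)
  verts <- matrix(0, n_pts * n_theta, 3)
  for (i in seq_len(n_pts)) {
    frac <- .plaque_fraction(vessel, i, theta)
    r <- base_radius * (1 - frac)
    dir <- outer(cos(theta), centerline$n1[i, ]) +
      outer(sin(theta), centerline$n2[i, ])
    verts[(i - 1L) * n_theta + seq_len(n_theta), ] <-
      matrix(centerline$points[i, ], n_theta, 3, byrow = TRUE) + r * dir
  }
  # wall quads -> 2 triangles, oriented outward
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n_pts - 1L)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)
    b <- (i - 1L) * n_theta + c(seq_len(n_theta)[-1L], 1L)
    c_ <- a + n_theta
    d <- b + n_theta
    faces <- rbind(faces, cbind(a, b, d), cbind(a, d, c_))
  }
  face_type <- rep("wall", nrow(faces))
  # caps: fan around the centerline end points
  v_in <- nrow(verts) + 1L
  verts <- rbind(verts, centerline$points[1, ], centerline$points[n_pts, ])
  a <- seq_len(n_theta); b <- c(seq_len(n_theta)[-1L], 1L)
  faces <- rbind(faces, cbind(v_in, b, a))                       # inlet cap
  off <- (n_pts - 1L) * n_theta
  faces <- rbind(faces, cbind(v_in + 1L, off + a, off + b))      # outlet cap
  face_type <- c(face_type, rep("cap_inlet", n_theta),
                 rep("cap_outlet", n_theta))
  vessel$vertices <- verts
  vessel$faces <- faces
  vessel$face_type <- face_type
  structure(vessel, class = "vessel_geometry")
}

#' Lumen radius at given arclength stations and frame angles
#'
#' Evaluates the (possibly plaque-narrowed) lumen radius at centerline point
#' index `i` and azimuths `theta` in the rotation-minimizing frame.
#'
#' @param vessel a `vessel_geometry`.
#' @param i centerline point index.
#' @param theta azimuths (radians) in the local frame.
#' @return numeric vector of radii (m).
#' @export
lumen_radius <- function(vessel, i, theta) {
  vessel$radius_profile[i] * (1 - .plaque_fraction(vessel, i, theta))
}

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem volume: \eqn{V = \frac{1}{3}\oint x \cdot n \, dA},
#' evaluated exactly per triangle. Requires outward-oriented faces (as built
#' by [make_vessel_surface()]).
#'
#' @param vessel a `vessel_geometry`.
#' @return volume in m^3.
#' @export
enclosed_volume <- function(vessel) {
  v <- vessel$vertices; f <- vessel$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # signed tetra volume against the origin
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Check the eccentricity rule on a generated plaque
#'
#' Over the plaque's axial extent, compares the thinnest and thickest wall
#' thickening around the circumference and reports whether thinnest/thickest
#' is below 0.5 (the identification rule for an eccentric plaque).
#'
#' @param vessel a `vessel_geometry` with a plaque.
#' @return list with `ratio` and logical `eccentric`.
#' @export
plaque_eccentricity <- function(vessel) {
  if (is.null(vessel$plaque)) stop("vessel has no plaque", call. = FALSE)
  cl <- vessel$centerline
  ps <- vessel$plaque
  sel <- which(abs(cl$arclengths - ps$center_arclength) < ps$extent / 2)
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  thick <- vapply(sel, function(i)
    range(vessel$radius_profile[i] * .plaque_fraction(vessel, i, theta)),
    numeric(2))
  thinnest <- min(thick[1, ]); thickest <- max(thick[2, ])
  ratio <- thinnest / thickest
  list(ratio = ratio, eccentric = ratio < 0.5)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry: %s, r0 %.3g m, %d vertices, %d faces%s>\n",
              x$centerline$shape, x$base_radius, nrow(x$vertices),
              nrow(x$faces),
              if (is.null(x$plaque)) "" else
                sprintf(", plaque on %s wall (depth %.0f%%)",
                        x$plaque$wall, 100 * x$plaque$depth)))
  invisible(x)
}

#' Write a triangulated surface as ASCII STL or PLY
#'
#' @param vessel a `vessel_geometry`.
#' @param path output file path.
#' @param include_caps include the end-cap triangles (default TRUE).
#' @return the path, invisibly.
#' @export
write_surface_stl <- function(vessel, path, include_caps = TRUE) {
  f <- vessel$faces
  if (!include_caps) f <- f[vessel$face_type == "wall", , drop = FALSE]
  v <- vessel$vertices
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- .row_unit(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                       e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                       e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel", con)
  txt <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                        "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                        "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                 n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
                 b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
  writeLines(txt, con)
  writeLines("endsolid vessel", con)
  invisible(path)
}

#' @rdname write_surface_stl
#' @export
write_surface_ply <- function(vessel, path, include_caps = TRUE) {
  f <- vessel$faces
  if (!include_caps) f <- f[vessel$face_type == "wall", , drop = FALSE]
  v <- vessel$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
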