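#' Parametric vessel centerlines
#'
#' Builds a smooth centerline for a synthetic vessel segment. Three shapes are
#' supported: a straight line, a constant-curvature circular arc (`curved`),
#' and an S-shaped pair of opposite arcs (`s_curve`). Arcs lie in the
#' axial (x--y) anatomical plane, which is where the horizontal segment of the
#' middle cerebral artery predominantly curves; the anatomical axes used by
#' the wall classifiers are +y = ventral (anterior) and +z = superior.
#'
#' The returned object carries, per point: position (m), cumulative arclength
#' (m), unit tangent, analytic curvature (1/m) and the unit vector toward the
#' local center of curvature, plus a rotation-minimizing orthonormal frame
#' `(n1, n2)` spanning the cross-sectional plane. A rotation-minimizing frame
#' (computed by the double-reflection method) is used instead of the Frenet
#' frame so the frame never flips at inflection points or straight runs.
#'
#' @param shape one of `"straight"`, `"curved"`, `"s_curve"`.
#' @param length total arclength in meters (> 0).
#' @param curve_radius radius of curvature in meters for curved shapes (> 0).
#' @param n_points number of points sampled along the centerline (>= 10).
#' @param seed optional seed controlling the (default zero) transverse jitter;
#'   kept as an explicit argument so generation is reproducible by contract.
#' @param jitter standard deviation (m) of smooth transverse perturbation;
#'   default 0 gives exact analytic shapes.
#' @return an object of class `centerline`.
#' @export
#' @examples
#' cl <- make_centerline("curved", length = 0.02, curve_radius = 0.012)
#' range(cl$curvature)   # constant 1/0.012
make_centerline <- function(shape = c("straight", "curved", "s_curve"),
                            length, curve_radius = NULL, n_points = 100L,
                            seed = 1L, jitter = 0) {
  shape <- match.arg(shape)
  .assert_positive(length, "length")
  if (n_points < 10L) stop("`n_points` must be >= 10", call. = FALSE)
  if (shape != "straight") {
    if (is.null(curve_radius)) stop("`curve_radius` required for curved shapes",
                                    call. = FALSE)
    .assert_positive(curve_radius, "curve_radius")
  }
  s <- seq(0, length, length.out = n_points)
  if (shape == "straight") {
    pts <- cbind(s, 0, 0)
    tan <- matrix(rep(c(1, 0, 0), each = n_points), ncol = 3)
    curv <- rep(0, n_points)
    cdir <- matrix(0, n_points, 3)
  } else if (shape == "curved") {
    # circular arc in the x-y plane, starting at the origin along +x,
    # bending toward +y; center of curvature at (0, R, 0)
    R <- curve_radius
    phi <- s / R
    pts <- cbind(R * sin(phi), R * (1 - cos(phi)), 0)
    tan <- cbind(cos(phi), sin(phi), 0)
    curv <- rep(1 / R, n_points)
    cdir <- cbind(-sin(phi), cos(phi), 0)
  } else { # s_curve: arc toward +y over first half, toward -y over second
    R <- curve_radius
    half <- length / 2
    phi1 <- pmin(s, half) / R
    pts1 <- cbind(R * sin(phi1), R * (1 - cos(phi1)), 0)
    tan1 <- cbind(cos(phi1), sin(phi1), 0)
    phim <- half / R
    pm <- c(R * sin(phim), R * (1 - cos(phim)), 0)
    tm <- c(cos(phim), sin(phim), 0)
    # second arc: center on the -normal side of the midpoint
    nm <- c(-sin(phim), cos(phim), 0)
    cen2 <- pm - R * nm
    s2 <- pmax(s - half, 0) / R
    # rotate (pm - cen2) about z by -s2 (opposite sense)
    v0 <- pm - cen2
    ct <- cos(-s2); st <- sin(-s2)
    pts2 <- cbind(cen2[1] + ct * v0[1] - st * v0[2],
                  cen2[2] + st * v0[1] + ct * v0[2],
                  0)
    tan2 <- cbind(ct * tm[1] - st * tm[2], st * tm[1] + ct * tm[2], 0)
    sel <- s > half
    pts <- pts1; pts[sel, ] <- pts2[sel, ]
    tan <- tan1; tan[sel, ] <- tan2[sel, ]
    curv <- rep(1 / R, n_points)
    cdir <- cbind(-tan[, 2], tan[, 1], 0)
    cdir[sel, ] <- -cdir[sel, , drop = FALSE]
  }
  if (jitter > 0) {
    pts <- pts + .with_seed(seed, {
      # smooth low-frequency transverse perturbation
      k <- 3
      ph <- stats::runif(2 * k, 0, 2 * pi)
      amp <- stats::rnorm(2 * k, 0, jitter / sqrt(k))
      dy <- dz <- rep(0, n_points)
      for (m in seq_len(k)) {
        dy <- dy + amp[m] * sin(m * pi * s / length + ph[m])
        dz <- dz + amp[k + m] * sin(m * pi * s / length + ph[k + m])
      }
      cbind(0, dy, dz)
    })
    tan <- .row_unit(rbind(pts[2, ] - pts[1, ],
                           (pts[-(1:2), ] - pts[1:(n_points - 2), ]) / 2,
                           pts[n_points, ] - pts[n_points - 1, ]))
  }
  fr <- .rmf_frames(pts, tan)
  structure(list(points = pts, arclengths = s, tangents = tan,
                 curvature = curv, curvature_dir = cdir,
                 n1 = fr$n1, n2 = fr$n2, shape = shape),
            class = "centerline")
}

# Rotation-minimizing frames by the double-reflection method
# (Wang et al. 2008). Returns unit normals n1, n2 per point.
.rmf_frames <- function(pts, tan) {
  n <- nrow(pts)
  t1 <- tan[1, ]
  # initial normal: any unit vector orthogonal to t1
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  r0 <- ref - sum(ref * t1) * t1
  r0 <- r0 / sqrt(sum(r0^2))
  n1 <- matrix(0, n, 3); n2 <- matrix(0, n, 3)
  n1[1, ] <- r0
  n2[1, ] <- .cross3(t1, r0)
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    if (c1 == 0) { n1[i + 1, ] <- n1[i, ]; n2[i + 1, ] <- n2[i, ]; next }
    rL <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tL <- tan[i, ] - (2 / c1) * sum(v1 * tan[i, ]) * v1
    v2 <- tan[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    r_next <- if (c2 == 0) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against the tangent to curb drift
    r_next <- r_next - sum(r_next * tan[i + 1, ]) * tan[i + 1, ]
    r_next <- r_next / sqrt(sum(r_next^2))
    n1[i + 1, ] <- r_next
    n2[i + 1, ] <- .cross3(tan[i + 1, ], r_next)
  }
  list(n1 = n1, n2 = n2)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %s, length %.4g m, %d points, max curvature %.3g 1/m>\n",
              x$shape, max(x$arclengths), nrow(x$points), max(x$curvature)))
  invisible(x)
}

# Resample a centerline at n uniformly spaced arclengths (cubic spline per
# coordinate; analytic fields re-interpolated).
.resample_centerline <- function(cl, n) {
  s_new <- seq(0, max(cl$arclengths), length.out = n)
  interp <- function(y) stats::spline(cl$arclengths, y, xout = s_new)$y
  pts <- cbind(interp(cl$points[, 1]), interp(cl$points[, 2]),
               interp(cl$points[, 3]))
  tan <- .row_unit(cbind(interp(cl$tangents[, 1]), interp(cl$tangents[, 2]),
                         interp(cl$tangents[, 3])))
  curv <- stats::approx(cl$arclengths, cl$curvature, xout = s_new)$y
  cdir <- cbind(stats::approx(cl$arclengths, cl$curvature_dir[, 1], xout = s_new)$y,
                stats::approx(cl$arclengths, cl$curvature_dir[, 2], xout = s_new)$y,
                stats::approx(cl$arclengths, cl$curvature_dir[, 3], xout = s_new)$y)
  # keep curvature_dir orthogonal to tangent
  cdir <- cdir - tan * rowSums(cdir * tan)
  nn <- .row_norm(cdir); cdir[nn > 1e-12, ] <- cdir[nn > 1e-12, , drop = FALSE] /
    nn[nn > 1e-12]
  fr <- .rmf_frames(pts, tan)
  structure(list(points = pts, arclengths = s_new, tangents = tan,
                 curvature = curv, curvature_dir = cdir,
                 n1 = fr$n1, n2 = fr$n2, shape = cl$shape),
            class = "centerline")
}

# Nearest centerline point for each row of `q` (k x 3). Returns index,
# arclength, and the perpendicular offset vector.
.nearest_centerline <- function(cl, q) {
  p <- cl$points
  # distance matrix in chunks to bound memory
  k <- nrow(q); n <- nrow(p)
  idx <- integer(k)
  chunk <- max(1L, floor(5e6 / n))
  for (start in seq(1L, k, by = chunk)) {
    end <- min(start + chunk - 1L, k)
    qq <- q[start:end, , drop = FALSE]
    d2 <- outer(rowSums(qq^2), rep(1, n)) - 2 * qq %*% t(p) +
      outer(rep(1, end - start + 1L), rowSums(p^2))
    idx[start:end] <- max.col(-d2, ties.method = "first")
  }
  off <- q - p[idx, , drop = FALSE]
  tanv <- cl$tangents[idx, , drop = FALSE]
  perp <- off - tanv * rowSums(off * tanv)
  list(index = idx, arclength = cl$arclengths[idx], offset = perp,
       axial = rowSums(off * tanv))
}
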