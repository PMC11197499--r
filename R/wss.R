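#' Cauchy stress on the wall faces
#'
#' Evaluates the incompressible Newtonian Cauchy stress
#' \eqn{\sigma = -p I + \mu(\nabla v + \nabla v^T)} on every wall boundary
#' face: the velocity gradient is recovered from the P1 basis on the
#' wall-adjacent element (where it is constant) and the pressure is the face
#' mean of the nodal values.
#'
#' @param sol a `flow_solution`.
#' @param mesh the `volume_mesh` it was computed on.
#' @param mu dynamic viscosity (defaults to the viscosity the solution was
#'   computed with).
#' @return an F x 6 matrix of stress components in Voigt order
#'   (xx, yy, zz, xy, xz, yz), one row per wall face, with attribute
#'   `face_ids` giving the wall-face row indices into the mesh boundary
#'   tables.
#' @export
cauchy_stress_at_wall <- function(sol, mesh, mu = sol$props$mu) {
  wall <- which(mesh$face_label == "wall")
  if (length(wall) == 0L) stop("mesh has no wall faces", call. = FALSE)
  gr <- .p1_gradients(mesh$nodes, mesh$tets)
  tet <- mesh$face_tet[wall]
  u <- sol$velocity
  # grad v on each adjacent tet: L[d,i] = dv_d/dx_i
  gradv <- array(0, c(length(wall), 3L, 3L))
  for (a in 1:4) {
    ua <- u[mesh$tets[tet, a], , drop = FALSE]
    ga <- gr$g[tet, a, , drop = FALSE]
    for (d in 1:3) for (i in 1:3)
      gradv[, d, i] <- gradv[, d, i] + ua[, d] * ga[, 1L, i]
  }
  f <- mesh$boundary_faces[wall, , drop = FALSE]
  pbar <- (sol$pressure[f[, 1]] + sol$pressure[f[, 2]] +
           sol$pressure[f[, 3]]) / 3
  sig <- cbind(xx = -pbar + 2 * mu * gradv[, 1, 1],
               yy = -pbar + 2 * mu * gradv[, 2, 2],
               zz = -pbar + 2 * mu * gradv[, 3, 3],
               xy = mu * (gradv[, 1, 2] + gradv[, 2, 1]),
               xz = mu * (gradv[, 1, 3] + gradv[, 3, 1]),
               yz = mu * (gradv[, 2, 3] + gradv[, 3, 2]))
  attr(sig, "face_ids") <- wall
  sig
}

#' Tangential wall traction (WSS vector) from stress and normal
#'
#' Implements \eqn{WSS = \sigma n - (\sigma n \cdot n) n}: the traction
#' vector \eqn{\sigma n} minus its normal component, leaving the tangential
#' (shearing) part. Non-unit normals are normalized with a warning.
#'
#' @param sigma stress rows in Voigt order (xx, yy, zz, xy, xz, yz), as from
#'   [cauchy_stress_at_wall()], or a single length-6 vector.
#' @param n outward unit normals (matching rows), or a single length-3
#'   vector.
#' @return list with `vector` (F x 3, Pa) and `magnitude` (Pa).
#' @export
#' @examples
#' # a pure-pressure state has no tangential traction
#' wss_vector(c(-100, -100, -100, 0, 0, 0), c(0, 1, 0))$magnitude  # 0
wss_vector <- function(sigma, n) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, 1L)
  if (is.null(dim(n))) n <- matrix(n, 1L)
  nn <- .row_norm(n)
  if (any(abs(nn - 1) > 1e-9)) {
    warning("non-unit normal(s) normalized")
    n <- n / nn
  }
  tx <- sigma[, 1] * n[, 1] + sigma[, 4] * n[, 2] + sigma[, 5] * n[, 3]
  ty <- sigma[, 4] * n[, 1] + sigma[, 2] * n[, 2] + sigma[, 6] * n[, 3]
  tz <- sigma[, 5] * n[, 1] + sigma[, 6] * n[, 2] + sigma[, 3] * n[, 3]
  tn <- tx * n[, 1] + ty * n[, 2] + tz * n[, 3]
  v <- cbind(tx - tn * n[, 1], ty - tn * n[, 2], tz - tn * n[, 3])
  list(vector = v, magnitude = .row_norm(v))
}

#' Wall shear stress field of a flow solution
#'
#' Full WSS extraction: Cauchy stress on every wall face, traction
#' projection, magnitudes, areas and outward normals, packaged with the
#' wall-face geometry needed by the anatomical classifiers. Faces within
#' `cap_exclusion` axial lengths of the inlet/outlet planes are flagged
#' `excluded` (cap boundary artifacts) and skipped by regional means.
#'
#' @param sol a `flow_solution`.
#' @param mesh the mesh.
#' @param cap_exclusion exclusion band at each end, in multiples of the
#'   axial mesh spacing.
#' @return object of class `wss_field`: `face_ids`, `sigma`, `normal`,
#'   `wss_vector`, `wss_magnitude`, `face_area`, `centroid`, `arclength`,
#'   `excluded`.
#' @export
compute_wss <- function(sol, mesh, cap_exclusion = 2) {
  sig <- cauchy_stress_at_wall(sol, mesh)
  wall <- attr(sig, "face_ids")
  n <- mesh$face_normal[wall, , drop = FALSE]
  w <- wss_vector(sig, n)
  cent <- mesh$face_centroid[wall, , drop = FALSE]
  cl <- mesh$meta$centerline
  nc <- .nearest_centerline(cl, cent)
  L <- max(cl$arclengths)
  band <- cap_exclusion * if (!is.null(mesh$meta$dz)) mesh$meta$dz else
    0.02 * L
  excluded <- nc$arclength < band | nc$arclength > L - band
  structure(list(face_ids = wall, sigma = sig, normal = n,
                 wss_vector = w$vector, wss_magnitude = w$magnitude,
                 face_area = mesh$face_area[wall],
                 centroid = cent, arclength = nc$arclength,
                 excluded = excluded),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field: %d wall faces, mean |WSS| %.3g Pa (range %.3g-%.3g)>\n",
              length(x$face_ids),
              regional_mean_wss(x, rep(TRUE, length(x$face_ids))),
              min(x$wss_magnitude), max(x$wss_magnitude)))
  invisible(x)
}

#' Regional mean wall shear stress
#'
#' The mean WSS magnitude over a region of wall faces, area-weighted by
#' default (each face contributes in proportion to its area); cap-adjacent
#' faces flagged in the field are excluded.
#'
#' @param field a `wss_field`.
#' @param region logical mask or integer indices over the field's faces.
#' @param weighting `"area"` (default) or `"uniform"`.
#' @param include_excluded also include cap-adjacent faces.
#' @return mean WSS in Pa.
#' @export
regional_mean_wss <- function(field, region,
                              weighting = c("area", "uniform"),
                              include_excluded = FALSE) {
  weighting <- match.arg(weighting)
  sel <- rep(FALSE, length(field$face_ids))
  sel[region] <- TRUE
  if (!include_excluded) sel <- sel & !field$excluded
  if (!any(sel)) stop("empty wall region", call. = FALSE)
  if (weighting == "area") {
    sum(field$wss_magnitude[sel] * field$face_area[sel]) /
      sum(field$face_area[sel])
  } else {
    mean(field$wss_magnitude[sel])
  }
}

#' Write a WSS field as a wall-surface VTU with cell data
#'
#' Emits the wall triangulation with `wss_vector` and `wss_magnitude` cell
#' arrays, readable in ParaView.
#'
#' @param field a `wss_field`.
#' @param mesh the mesh.
#' @param path output `.vtu` path.
#' @return the path, invisibly.
#' @export
write_wss_vtu <- function(field, mesh, path) {
  f <- mesh$boundary_faces[field$face_ids, , drop = FALSE]
  np <- nrow(mesh$nodes); nc <- nrow(f)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(t(mesh$nodes), collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(t(f) - 1L, collapse = " "), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nc) * 3L, collapse = " "), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(5L, nc), collapse = " "), con)
  w('</DataArray></Cells><CellData>')
  w('<DataArray type="Float64" Name="wss_vector" NumberOfComponents="3" format="ascii">')
  writeLines(paste(t(field$wss_vector), collapse = " "), con)
  w('</DataArray><DataArray type="Float64" Name="wss_magnitude" format="ascii">')
  writeLines(paste(field$wss_magnitude, collapse = " "), con)
  w('</DataArray></CellData></Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
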