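#' Tetrahedral volume mesh of a vessel lumen
#'
#' Fills the lumen of a swept-tube vessel with an unstructured-format (but
#' deterministically constructed) tetrahedral mesh. The cross-section is
#' discretized as a polar grid (center node plus rings of `n_theta` nodes)
#' whose radial spacing is graded toward the wall by `near_wall_factor`
#' (boundary-layer-style wall-normal refinement, where wall shear must be
#' resolved). The grid is swept along the centerline with its
#' rotation-minimizing frame; each triangular prism between consecutive
#' stations is split into 3 tetrahedra with a minimum-global-index diagonal
#' rule, which guarantees a conforming mesh.
#'
#' @param vessel a `vessel_geometry`.
#' @param target_edge target edge length (m) away from the wall.
#' @param near_wall_factor wall-adjacent radial spacing as a fraction of
#'   `target_edge`, in (0, 1].
#' @param growth geometric growth rate of radial spacing away from the wall.
#' @return an object of class `volume_mesh` with nodes (m), `tets` (1-based,
#'   positively oriented), labeled `boundary_faces` with outward unit
#'   normals, areas, centroids and the adjacent tet, per-tet volumes, and a
#'   `meta` list (resampled centerline, structured indices, sizes).
#' @export
#' @examples
#' cl <- make_centerline("straight", length = 0.01)
#' v <- make_vessel_surface(cl, base_radius = 0.002)
#' m <- tetrahedralize(v, target_edge = 8e-4)
#' mesh_quality(m)$n_cells
tetrahedralize <- function(vessel, target_edge, near_wall_factor = 0.5,
                           growth = 1.3) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  .assert_positive(target_edge, "target_edge")
  if (near_wall_factor <= 0 || near_wall_factor > 1)
    stop("`near_wall_factor` must lie in (0, 1]", call. = FALSE)
  r0 <- vessel$base_radius
  L <- max(vessel$centerline$arclengths)
  n_theta <- max(12L, as.integer(round(2 * pi * r0 / target_edge)))
  n_z <- max(4L, as.integer(round(L / target_edge)))
  cl <- .resample_centerline(vessel$centerline, n_z + 1L)
  vres <- vessel
  vres$centerline <- cl
  vres$radius_profile <- rep(r0, n_z + 1L)

  # radial spacings, wall inward: h_wall, h_wall*growth, ... capped at target
  sp <- target_edge * near_wall_factor
  spac <- numeric(0)
  while (sum(spac) < r0) {
    spac <- c(spac, min(sp, target_edge))
    sp <- sp * growth
  }
  spac <- spac / sum(spac)
  rho <- cumsum(rev(spac))            # normalized ring radii, center -> wall
  n_r <- length(rho)

  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  nodes_per_station <- 1L + n_r * n_theta
  n_station <- n_z + 1L
  N <- nodes_per_station * n_station
  nodes <- matrix(0, N, 3)
  node_station <- rep(seq_len(n_station), each = nodes_per_station)
  node_ring <- rep(c(0L, rep(seq_len(n_r), each = n_theta)), n_station)
  ct <- cos(theta); st <- sin(theta)
  for (i in seq_len(n_station)) {
    base <- (i - 1L) * nodes_per_station
    nodes[base + 1L, ] <- cl$points[i, ]
    rwall <- lumen_radius(vres, i, theta)   # may vary with theta (plaque)
    dirs <- outer(ct, cl$n1[i, ]) + outer(st, cl$n2[i, ])
    for (k in seq_len(n_r)) {
      idx <- base + 1L + (k - 1L) * n_theta + seq_len(n_theta)
      nodes[idx, ] <- matrix(cl$points[i, ], n_theta, 3, byrow = TRUE) +
        (rho[k] * rwall) * dirs
    }
  }

  # 2D cross-section triangulation (local, 1-based within a station)
  ring_id <- function(k, j) 1L + (k - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  tri <- matrix(0L, 0, 3)
  j <- seq_len(n_theta)
  tri <- rbind(tri, cbind(1L, ring_id(1L, j), ring_id(1L, j + 1L)))
  if (n_r > 1L) for (k in seq_len(n_r - 1L)) {
    a <- ring_id(k, j); b <- ring_id(k, j + 1L)
    c_ <- ring_id(k + 1L, j); d <- ring_id(k + 1L, j + 1L)
    tri <- rbind(tri, cbind(a, b, d), cbind(a, d, c_))
  }

  # sweep prisms -> 3 tets each with the min-global-index diagonal rule
  n_tri <- nrow(tri)
  tets <- matrix(0L, 3L * n_tri * n_z, 4L)
  row <- 1L
  for (iz in seq_len(n_z)) {
    off_b <- (iz - 1L) * nodes_per_station
    off_t <- iz * nodes_per_station
    vb <- tri + off_b
    vt <- tri + off_t
    for (t in seq_len(n_tri)) {
      v <- vb[t, ]; w <- vt[t, ]
      rot <- which.min(v) - 1L
      if (rot > 0L) {
        ord <- c((rot + 1L):3L, 1L:rot)[1:3]
        v <- v[ord]; w <- w[ord]
      }
      if (v[2] < v[3]) {
        tets[row, ] <- c(v[1], v[2], v[3], w[3])
        tets[row + 1L, ] <- c(v[1], v[2], w[3], w[2])
        tets[row + 2L, ] <- c(v[1], w[2], w[3], w[1])
      } else {
        tets[row, ] <- c(v[1], v[2], v[3], w[2])
        tets[row + 1L, ] <- c(v[1], w[2], v[3], w[3])
        tets[row + 2L, ] <- c(v[1], w[2], w[3], w[1])
      }
      row <- row + 3L
    }
  }

  # enforce positive orientation
  vol <- .tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0)) stop("meshing produced a degenerate (zero-volume) cell",
                          call. = FALSE)

  mesh <- structure(list(nodes = nodes, tets = tets, tet_volume = vol,
                         node_station = node_station, node_ring = node_ring,
                         meta = list(centerline = cl, n_theta = n_theta,
                                     n_r = n_r, n_z = n_z,
                                     rho = rho, target_edge = target_edge,
                                     near_wall_factor = near_wall_factor,
                                     dz = L / n_z,
                                     base_radius = r0)),
                    class = "volume_mesh")
  tag_boundaries(mesh, vessel)
}

# signed volumes of all tets (positive for right-handed ordering)
.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Label the boundary faces of a volume mesh
#'
#' Extracts the boundary (faces belonging to exactly one tet), computes
#' outward unit normals (oriented by the adjacent tet centroid) and labels
#' each face `inlet` (the planar cap at the start of the centerline, where
#' flow enters), `outlet_1` (end cap) or `wall`. Labels partition the
#' boundary: every face receives exactly one label.
#'
#' @param mesh a `volume_mesh`.
#' @param vessel the generating `vessel_geometry` (used for the end-plane
#'   geometry when the mesh was built externally; the structured metadata is
#'   used when present).
#' @return the mesh with `boundary_faces`, `face_label`, `face_normal`,
#'   `face_area`, `face_centroid`, `face_tet` fields filled.
#' @export
tag_boundaries <- function(mesh, vessel = NULL) {
  nodes <- mesh$nodes; tets <- mesh$tets
  M <- nrow(tets); N <- nrow(nodes)
  # four faces per tet, outward-ordered candidates
  fidx <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  faces <- matrix(0L, 4L * M, 3L)
  for (f in 1:4) faces[seq(f, by = 4L, length.out = M), ] <- cbind(
    tets[, fidx[f, 1]], tets[, fidx[f, 2]], tets[, fidx[f, 3]])
  face_tet <- rep(seq_len(M), each = 4L)
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  bnd <- which(key %in% names(tab)[tab == 1L])
  if (length(bnd) == 0L) stop("mesh has no boundary faces", call. = FALSE)
  bfaces <- faces[bnd, , drop = FALSE]
  btet <- face_tet[bnd]
  a <- nodes[bfaces[, 1], , drop = FALSE]
  b <- nodes[bfaces[, 2], , drop = FALSE]
  c_ <- nodes[bfaces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  area <- .row_norm(nrm)
  normal <- nrm / area
  centroid <- (a + b + c_) / 3
  # orient outward: away from the adjacent tet centroid
  tcent <- (nodes[tets[btet, 1], , drop = FALSE] +
            nodes[tets[btet, 2], , drop = FALSE] +
            nodes[tets[btet, 3], , drop = FALSE] +
            nodes[tets[btet, 4], , drop = FALSE]) / 4
  flip <- rowSums(normal * (centroid - tcent)) < 0
  normal[flip, ] <- -normal[flip, , drop = FALSE]

  # label caps by the end planes of the centerline
  cl <- if (!is.null(mesh$meta$centerline)) mesh$meta$centerline
        else vessel$centerline
  if (is.null(cl)) stop("no centerline available to locate the end caps",
                        call. = FALSE)
  p0 <- cl$points[1, ]; t0 <- cl$tangents[1, ]
  p1 <- cl$points[nrow(cl$points), ]; t1 <- cl$tangents[nrow(cl$points), ]
  tol <- 1e-6 * max(cl$arclengths) + 1e-12
  on_plane <- function(pl, tn) {
    d1 <- abs((a - matrix(pl, nrow(a), 3, byrow = TRUE)) %*% tn)
    d2 <- abs((b - matrix(pl, nrow(b), 3, byrow = TRUE)) %*% tn)
    d3 <- abs((c_ - matrix(pl, nrow(c_), 3, byrow = TRUE)) %*% tn)
    d1 < tol & d2 < tol & d3 < tol
  }
  lab <- rep("wall", nrow(bfaces))
  lab[on_plane(p0, t0)] <- "inlet"
  lab[on_plane(p1, t1)] <- "outlet_1"
  if (!any(lab == "inlet") || !any(lab == "outlet_1"))
    stop("cap detection failed: no inlet/outlet faces found", call. = FALSE)
  mesh$boundary_faces <- bfaces
  mesh$face_label <- lab
  mesh$face_normal <- normal
  mesh$face_area <- area
  mesh$face_centroid <- centroid
  mesh$face_tet <- btet
  mesh
}

#' Mesh quality report
#'
#' Reports the minimum cell volume, the maximum aspect ratio (longest edge
#' over shortest altitude), the cell count, and how many cells fall below a
#' configured minimum volume (default 1.0e-8 cm^3 = 1.0e-14 m^3, the scale
#' needed to capture microscale flow features near the wall).
#'
#' @param mesh a `volume_mesh`.
#' @param min_volume flag threshold in m^3.
#' @return list(min_volume, max_aspect, n_cells, n_below_min).
#' @export
mesh_quality <- function(mesh, min_volume = 1e-14) {
  if (is.null(mesh$tets) || nrow(mesh$tets) == 0L)
    stop("no cells", call. = FALSE)
  vol <- if (!is.null(mesh$tet_volume)) mesh$tet_volume
         else .tet_volumes(mesh$nodes, mesh$tets)
  tets <- mesh$tets; nodes <- mesh$nodes
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  emax <- rep(0, nrow(tets))
  for (pp in seq_len(6)) {
    e <- .row_norm(nodes[tets[, pairs[pp, 1]], , drop = FALSE] -
                   nodes[tets[, pairs[pp, 2]], , drop = FALSE])
    emax <- pmax(emax, e)
  }
  # largest face area per tet -> shortest altitude h = 3V / A_max
  amax <- rep(0, nrow(tets))
  fidx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  for (f in seq_len(4)) {
    a <- nodes[tets[, fidx[f, 1]], , drop = FALSE]
    b <- nodes[tets[, fidx[f, 2]], , drop = FALSE]
    c_ <- nodes[tets[, fidx[f, 3]], , drop = FALSE]
    e1 <- b - a; e2 <- c_ - a
    ar <- .row_norm(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])) / 2
    amax <- pmax(amax, ar)
  }
  aspect <- emax / (3 * vol / amax)
  list(min_volume = min(vol), max_aspect = max(aspect),
       n_cells = nrow(tets), n_below_min = sum(vol < min_volume))
}

#' Closed-surface divergence identity check
#'
#' For a closed boundary with outward normals, the surface integral of
#' \eqn{x \cdot n} equals three times the enclosed volume. The relative
#' mismatch validates face closure and normal orientation.
#'
#' @param mesh a labeled `volume_mesh`.
#' @return relative error `|oint x.n dA - 3V| / (3V)`.
#' @export
mesh_divergence_check <- function(mesh) {
  surf <- sum(rowSums(mesh$face_centroid * mesh$face_normal) * mesh$face_area)
  vol3 <- 3 * sum(mesh$tet_volume)
  abs(surf - vol3) / vol3
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("<volume_mesh: %d nodes, %d tets, %d boundary faces (%s)>\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_faces),
              paste(names(table(x$face_label)), collapse = "/")))
  invisible(x)
}

#' Write a mesh (plus optional cell/point data) as ASCII VTU
#'
#' Writes the tetrahedral mesh in VTK XML unstructured-grid format readable
#' by ParaView. Point data arrays (one row per node) and cell data arrays
#' are optional named lists of numeric vectors/matrices.
#'
#' @param mesh a `volume_mesh`.
#' @param path output `.vtu` path.
#' @param point_data named list; each element a vector (scalar per node) or
#'   matrix with one row per node.
#' @param boundary_ids write an integer `boundary_id` cell array on a surface
#'   export instead of the volume (used for labeled wall extractions).
#' @return the path, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list(),
                           boundary_ids = FALSE) {
  if (boundary_ids) {
    cells <- mesh$boundary_faces; ctype <- 5L   # VTK_TRIANGLE
    labs <- unique(mesh$face_label)
    id <- match(mesh$face_label, labs)
    cell_data <- list(boundary_id = id)
    legend <- as.list(stats::setNames(seq_along(labs), labs))
    jsonlite::write_json(legend, paste0(path, ".legend.json"),
                         auto_unbox = TRUE)
  } else {
    cells <- mesh$tets; ctype <- 10L            # VTK_TETRA
    cell_data <- list()
  }
  np <- nrow(mesh$nodes); nc <- nrow(cells); k <- ncol(cells)
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
  writeLines(paste(t(cells) - 1L, collapse = " "), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nc) * k, collapse = " "), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(ctype, nc), collapse = " "), con)
  w('</DataArray></Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      ncomp <- if (is.matrix(d)) ncol(d) else 1L
      w('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncomp)
      writeLines(paste(if (is.matrix(d)) t(d) else d, collapse = " "), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  if (length(cell_data)) {
    w('<CellData>')
    for (nm in names(cell_data)) {
      w('<DataArray type="Int32" Name="%s" format="ascii">', nm)
      writeLines(paste(cell_data[[nm]], collapse = " "), con)
      w('</DataArray>')
    }
    w('</CellData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
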