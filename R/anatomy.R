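#' Anatomical axes convention
#'
#' Wall quadrants are defined by image planes, so an explicit axes
#' convention must be declared and stored with every dataset. The default is
#' RAS-style: +y is anterior (ventral), +z is head-ward (superior); the
#' dorsal and inferior directions are their negatives.
#'
#' @param ventral_dir unit vector of the ventral (anterior) direction.
#' @param superior_dir unit vector of the superior (head-ward) direction.
#' @return object of class `anatomical_axes`.
#' @export
anatomical_axes <- function(ventral_dir = c(0, 1, 0),
                            superior_dir = c(0, 0, 1)) {
  v <- ventral_dir / sqrt(sum(ventral_dir^2))
  s <- superior_dir / sqrt(sum(superior_dir^2))
  if (abs(sum(v * s)) > 1e-6)
    stop("ventral and superior directions must be orthogonal", call. = FALSE)
  structure(list(ventral = v, superior = s), class = "anatomical_axes")
}

# wall-face geometry relative to the centerline: nearest station, arclength,
# radial offset (perpendicular to the local tangent)
.wall_face_geometry <- function(mesh) {
  wall <- which(mesh$face_label == "wall")
  cent <- mesh$face_centroid[wall, , drop = FALSE]
  cl <- mesh$meta$centerline
  nc <- .nearest_centerline(cl, cent)
  list(wall = wall, centroid = cent, cl = cl, nearest = nc)
}

#' Trisect a vessel segment and label wall faces
#'
#' Divides the span between an origin and a branch arclength into three
#' equal parts (proximal, middle, distal) and labels every wall face by the
#' arclength of its nearest centerline point. Cuts fall at origin + L/3 and
#' origin + 2L/3 with L the span length.
#'
#' @param mesh a labeled `volume_mesh`.
#' @param origin_arclength arclength (m) where the segment begins.
#' @param branch_arclength arclength (m) of the first branch point (segment
#'   end); defaults to the full centerline length.
#' @return list with `cuts` (the two cut arclengths) and `segment` (factor
#'   per wall face: proximal/middle/distal).
#' @export
#' @examples
#' # a 21 mm span is cut at 7 and 14 mm
trisect <- function(mesh, origin_arclength = 0,
                    branch_arclength = NULL) {
  geo <- .wall_face_geometry(mesh)
  if (is.null(branch_arclength))
    branch_arclength <- max(geo$cl$arclengths)
  if (branch_arclength <= origin_arclength)
    stop("branch arclength must exceed the origin arclength", call. = FALSE)
  L <- branch_arclength - origin_arclength
  cuts <- origin_arclength + c(L / 3, 2 * L / 3)
  s <- geo$nearest$arclength
  seg <- cut(s, breaks = c(-Inf, cuts, Inf),
             labels = c("proximal", "middle", "distal"))
  list(cuts = cuts, segment = seg)
}

#' Classify wall faces into ventral/dorsal/superior/inferior quadrants
#'
#' Each wall face is assigned by the angular position of its centroid around
#' the local centerline: the anatomical axes are projected onto the plane
#' perpendicular to the local tangent, and the face goes to the quadrant
#' whose (projected) direction its radial offset is most aligned with
#' (45-degree sectors around the four directions, which keeps the two
#' orthogonal image-plane splits consistent on oblique vessels).
#'
#' @param mesh a labeled `volume_mesh`.
#' @param axes an [anatomical_axes()] convention.
#' @return factor per wall face with levels ventral, dorsal, superior,
#'   inferior.
#' @export
classify_quadrant <- function(mesh, axes = anatomical_axes()) {
  geo <- .wall_face_geometry(mesh)
  tanv <- geo$cl$tangents[geo$nearest$index, , drop = FALSE]
  d <- .row_unit(geo$nearest$offset)
  proj <- function(ax) {
    m <- matrix(ax, nrow(tanv), 3, byrow = TRUE)
    .row_unit(m - tanv * rowSums(m * tanv))
  }
  vdir <- proj(axes$ventral)
  sdir <- proj(axes$superior)
  score <- cbind(ventral = rowSums(d * vdir),
                 dorsal = -rowSums(d * vdir),
                 superior = rowSums(d * sdir),
                 inferior = -rowSums(d * sdir))
  lab <- colnames(score)[max.col(score, ties.method = "first")]
  factor(lab, levels = c("ventral", "dorsal", "superior", "inferior"))
}

#' Classify wall faces into the inner and outer walls of the curve
#'
#' A face lies on the inner wall if its radial offset points toward the
#' local center of curvature (positive component along the curvature
#' direction), on the outer wall otherwise. Faces where the local curvature
#' is below `curvature_threshold` are `undefined` (straight vessel runs are
#' never labeled inner/outer).
#'
#' @param mesh a labeled `volume_mesh`.
#' @param curvature_threshold curvature (1/m) below which the side is
#'   undefined; default 5.
#' @return factor per wall face with levels inner, outer, undefined.
#' @export
classify_curve_side <- function(mesh, curvature_threshold = 5) {
  geo <- .wall_face_geometry(mesh)
  idx <- geo$nearest$index
  curv <- geo$cl$curvature[idx]
  cdir <- geo$cl$curvature_dir[idx, , drop = FALSE]
  side <- ifelse(curv < curvature_threshold, "undefined",
                 ifelse(rowSums(geo$nearest$offset * cdir) > 0,
                        "inner", "outer"))
  factor(side, levels = c("inner", "outer", "undefined"))
}

#' Full wall-region labeling
#'
#' Runs the trisection, quadrant and curve-side classifiers and bundles the
#' per-face labels with face areas and arclengths. The result indexes wall
#' faces in the same order as [compute_wss()] fields.
#'
#' @param mesh a labeled `volume_mesh`.
#' @param axes an [anatomical_axes()] convention.
#' @param origin_arclength,branch_arclength trisection span, as in
#'   [trisect()].
#' @param curvature_threshold as in [classify_curve_side()].
#' @return object of class `wall_labels`: data frame `labels` with columns
#'   `segment`, `quadrant`, `curve_side`, `area`, `arclength`, plus `cuts`
#'   and the mesh centerline for downstream use.
#' @export
wall_labels <- function(mesh, axes = anatomical_axes(),
                        origin_arclength = 0, branch_arclength = NULL,
                        curvature_threshold = 5) {
  tri <- trisect(mesh, origin_arclength, branch_arclength)
  quad <- classify_quadrant(mesh, axes)
  side <- classify_curve_side(mesh, curvature_threshold)
  geo <- .wall_face_geometry(mesh)
  structure(list(labels = data.frame(segment = tri$segment,
                                     quadrant = quad,
                                     curve_side = side,
                                     area = mesh$face_area[geo$wall],
                                     arclength = geo$nearest$arclength),
                 cuts = tri$cuts, wall_faces = geo$wall,
                 centerline = geo$cl, axes = axes),
            class = "wall_labels")
}

#' @export
print.wall_labels <- function(x, ...) {
  cat(sprintf("<wall_labels: %d wall faces; cuts at %s m>\n",
              nrow(x$labels), paste(signif(x$cuts, 4), collapse = ", ")))
  print(table(x$labels$segment, x$labels$quadrant))
  invisible(x)
}

#' Assign a plaque annotation to a wall and segment
#'
#' A plaque is annotated by 2--5 image points; its center (the arithmetic
#' centroid of the points) is snapped to the nearest wall face, whose
#' quadrant and segment labels are returned. An annotation whose centroid
#' lies farther than one local lumen diameter from the wall is rejected.
#'
#' @param points an n x 3 matrix of world coordinates (m), 2 <= n <= 5.
#' @param labels a [wall_labels()] object.
#' @param mesh the labeled `volume_mesh`.
#' @return list with `assigned_wall`, `assigned_segment`, `face` (index into
#'   wall faces), and `distance` (m).
#' @export
assign_plaque <- function(points, labels, mesh) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || nrow(points) > 5L)
    stop("a plaque annotation must have 2-5 points", call. = FALSE)
  ctr <- colMeans(points)
  wall <- labels$wall_faces
  cent <- mesh$face_centroid[wall, , drop = FALSE]
  d2 <- rowSums((cent - matrix(ctr, nrow(cent), 3, byrow = TRUE))^2)
  k <- which.min(d2)   # ties: lowest face index (deterministic)
  dist <- sqrt(d2[k])
  # local lumen diameter: twice the snapped face's distance to the
  # centerline (the wall radius there)
  nc <- .nearest_centerline(labels$centerline,
                            cent[k, , drop = FALSE])
  diam <- 2 * sqrt(sum(nc$offset^2))
  if (dist > max(diam, 1e-9))
    stop(sprintf(paste0("plaque centroid is %.3g m from the nearest wall ",
                        "face (> one local diameter %.3g m)"), dist, diam),
         call. = FALSE)
  list(assigned_wall = as.character(labels$labels$quadrant[k]),
       assigned_segment = as.character(labels$labels$segment[k]),
       face = k, distance = dist)
}

#' Read plaque annotations from CSV
#'
#' Expects columns `plaque_id,x_mm,y_mm,z_mm`; coordinates are converted
#' from mm to m.
#'
#' @param path CSV file path.
#' @return named list of point matrices (m), one per plaque id.
#' @export
read_plaque_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plaque_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("plaque CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$plaque_id), function(d)
    cbind(d$x_mm, d$y_mm, d$z_mm) * 1e-3)
}

#' Write wall labels as a surface VTU with integer cell arrays
#'
#' Emits `segment_id`, `quadrant_id` and `curve_side_id` cell arrays on the
#' wall triangulation plus a JSON legend mapping ids to names.
#'
#' @param labels a [wall_labels()] object.
#' @param mesh the mesh.
#' @param path output `.vtu` path.
#' @return the path, invisibly.
#' @export
write_labels_vtu <- function(labels, mesh, path) {
  f <- mesh$boundary_faces[labels$wall_faces, , drop = FALSE]
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
  for (nm in c("segment", "quadrant", "curve_side")) {
    w('<DataArray type="Int32" Name="%s_id" format="ascii">', nm)
    writeLines(paste(as.integer(labels$labels[[nm]]), collapse = " "), con)
    w('</DataArray>')
  }
  w('</CellData></Piece></UnstructuredGrid></VTKFile>')
  legend <- lapply(c(segment = "segment", quadrant = "quadrant",
                     curve_side = "curve_side"), function(nm)
    as.list(stats::setNames(seq_along(levels(labels$labels[[nm]])),
                            levels(labels$labels[[nm]]))))
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
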