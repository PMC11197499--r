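#' Voxel-grid transform
#'
#' Maps between world coordinates (mm) and 0-based voxel indices under the
#' voxel-center convention: the world position of voxel (0,0,0) is `origin`
#' and axes advance by `spacing` (with optional orientation signs). Models
#' are simulated in meters; the registration layer works in mm (the imaging
#' convention), so model coordinates are converted explicitly where they
#' enter.
#'
#' @param spacing length-3 positive spacing, mm.
#' @param origin world mm of the center of voxel (0,0,0).
#' @param signs orientation signs per axis (+1/-1).
#' @return object of class `grid_transform`.
#' @export
grid_transform <- function(spacing = c(0.4, 0.4, 0.8), origin = c(0, 0, 0),
                           signs = c(1, 1, 1)) {
  .assert_positive(spacing, "spacing")
  if (!all(signs %in% c(-1, 1)))
    stop("`signs` must be +1 or -1 per axis", call. = FALSE)
  structure(list(spacing = as.numeric(spacing), origin = as.numeric(origin),
                 signs = as.numeric(signs)),
            class = "grid_transform")
}

#' World (mm) to voxel indices
#'
#' Nearest-voxel-center projection: `index = floor((coord - origin) /
#' (sign * spacing) + 0.5)`, 0-based. Out-of-grid points are flagged, not
#' rejected.
#'
#' @param coords n x 3 world coordinates in mm (or a length-3 vector).
#' @param t a [grid_transform()].
#' @param shape optional grid dimensions for the in-bounds flag.
#' @return data.frame with columns i, j, k (0-based integer indices) and
#'   `in_bounds` (if `shape` given).
#' @export
#' @examples
#' t <- grid_transform(spacing = c(0.4, 0.4, 0.8))
#' world_to_voxel(c(0.4, 0.8, 1.6), t)   # (1, 2, 2)
world_to_voxel <- function(coords, t, shape = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, 1L)
  stopifnot(inherits(t, "grid_transform"))
  rel <- sweep(coords, 2L, t$origin, "-")
  rel <- sweep(rel, 2L, t$signs * t$spacing, "/")
  idx <- floor(rel + 0.5)
  out <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                    k = as.integer(idx[, 3]))
  if (!is.null(shape)) {
    out$in_bounds <- out$i >= 0L & out$i < shape[1] &
      out$j >= 0L & out$j < shape[2] & out$k >= 0L & out$k < shape[3]
  }
  out
}

#' Voxel indices to world coordinates (voxel centers, mm)
#'
#' Inverse projection `coord = origin + index * sign * spacing`; composed
#' with [world_to_voxel()] it is the identity on voxel centers.
#'
#' @param indices n x 3 matrix (or data.frame with i,j,k) of 0-based voxel
#'   indices.
#' @param t a [grid_transform()].
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(indices, t) {
  if (is.data.frame(indices))
    indices <- cbind(indices$i, indices$j, indices$k)
  if (is.null(dim(indices))) indices <- matrix(indices, 1L)
  sweep(sweep(indices, 2L, t$signs * t$spacing, "*"), 2L, t$origin, "+")
}

#' Locate an image point on the simulated wall
#'
#' Given voxel indices of an image point (e.g. a plaque annotation), finds
#' the nearest wall face of the model by Euclidean distance from the voxel
#' center's world coordinate. Ties break to the lowest face index.
#'
#' @param indices length-3 (or n x 3) 0-based voxel indices.
#' @param t a [grid_transform()].
#' @param mesh a labeled `volume_mesh` (model coordinates in m).
#' @return data.frame: `face` (index into the mesh's wall-face subset),
#'   `distance_mm`.
#' @export
locate_point_on_model <- function(indices, t, mesh) {
  wpt <- voxel_to_world(indices, t)            # mm
  wall <- which(mesh$face_label == "wall")
  cent <- mesh$face_centroid[wall, , drop = FALSE] * 1e3   # m -> mm
  out <- data.frame(face = integer(nrow(wpt)), distance_mm = numeric(nrow(wpt)))
  for (q in seq_len(nrow(wpt))) {
    d2 <- rowSums(sweep(cent, 2L, wpt[q, ], "-")^2)
    k <- which.min(d2)                          # lowest index on ties
    out$face[q] <- k
    out$distance_mm[q] <- sqrt(d2[k])
  }
  out
}

#' Project a WSS field onto a voxel grid
#'
#' Deposits each wall face's WSS magnitude into the voxel containing its
#' centroid; voxels receiving several faces take the area-weighted mean.
#' Voxels receiving nothing are 0 and marked invalid in the accompanying
#' mask.
#'
#' @param field a `wss_field` (model coordinates in m).
#' @param t a [grid_transform()].
#' @param shape grid dimensions.
#' @return list of two [voxel_grid()]s: `wss` (Pa) and `valid` (0/1 mask).
#' @export
project_wss_to_image <- function(field, t, shape) {
  cent_mm <- field$centroid * 1e3
  idx <- world_to_voxel(cent_mm, t, shape)
  keep <- idx$in_bounds
  lin <- 1L + idx$i[keep] + shape[1] * (idx$j[keep] + shape[2] * idx$k[keep])
  w <- field$face_area[keep]
  val <- field$wss_magnitude[keep]
  num <- tapply(val * w, lin, sum)
  den <- tapply(w, lin, sum)
  vals <- array(0, dim = shape)
  mask <- array(0, dim = shape)
  cells <- as.integer(names(num))
  vals[cells] <- as.numeric(num) / as.numeric(den)
  mask[cells] <- 1
  list(wss = voxel_grid(vals, t$spacing, t$origin),
       valid = voxel_grid(mask, t$spacing, t$origin))
}

#' Serialize / restore a grid transform as JSON
#'
#' @param t a [grid_transform()].
#' @param path JSON file path.
#' @return the path (writer) / a [grid_transform()] (reader).
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(unclass(t), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_transform(x$spacing, x$origin, x$signs)
}
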