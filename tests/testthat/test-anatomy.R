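test_that("trisection cuts a 21 mm span at 7 and 14 mm", {
  cl <- make_centerline("straight", length = 0.021, n_points = 50)
  v <- make_vessel_surface(cl, 0.0015, n_theta = 12)
  m <- tetrahedralize(v, target_edge = 1.2e-3)
  tri <- trisect(m)
  expect_equal(tri$cuts, c(0.007, 0.014), tolerance = 1e-12)
  expect_true(all(!is.na(tri$segment)))
  # labels change exactly twice walking down the tube
  geo <- hemowss:::.wall_face_geometry(m)
  ord <- order(geo$nearest$arclength)
  changes <- sum(diff(as.integer(tri$segment[ord])) != 0)
  expect_equal(changes, 2L)
  # a face at 10 mm arclength is in the middle segment
  mid_face <- which.min(abs(geo$nearest$arclength - 0.010))
  expect_equal(as.character(tri$segment[mid_face]), "middle")
  expect_error(trisect(m, origin_arclength = 0.02,
                       branch_arclength = 0.01), "exceed")
})

test_that("quadrants follow the declared anatomical convention", {
  fx <- tiny_straight()
  m <- fx$mesh
  quad <- classify_quadrant(m)
  geo <- hemowss:::.wall_face_geometry(m)
  d <- geo$nearest$offset
  # a face directly anterior (+y) of the centerline is ventral;
  # directly head-ward (+z) is superior
  ant <- which.max(d[, 2] / hemowss:::.row_norm(d))
  expect_equal(as.character(quad[ant]), "ventral")
  headward <- which.max(d[, 3] / hemowss:::.row_norm(d))
  expect_equal(as.character(quad[headward]), "superior")
  post <- which.min(d[, 2] / hemowss:::.row_norm(d))
  expect_equal(as.character(quad[post]), "dorsal")
})

test_that("quadrant areas on a symmetric straight tube are equal within 5%", {
  fx <- tiny_straight()
  lab <- wall_labels(fx$mesh)
  areas <- tapply(lab$labels$area, lab$labels$quadrant, sum)
  expect_lt(max(abs(areas / mean(areas) - 1)), 0.05)
  # labels partition the wall: quadrant areas and segment areas both sum to
  # the total wall area
  total <- sum(fx$mesh$face_area[fx$mesh$face_label == "wall"])
  expect_equal(sum(areas), total, tolerance = 1e-12)
  seg_areas <- tapply(lab$labels$area, lab$labels$segment, sum)
  expect_equal(sum(seg_areas), total, tolerance = 1e-12)
})

test_that("curve sides split a curved tube and vanish on a straight one", {
  fx <- tiny_curved()
  side <- classify_curve_side(fx$mesh)
  expect_true(all(side %in% c("inner", "outer")))
  # faces toward the arc center (at (0, Rc, 0)) are inner
  geo <- hemowss:::.wall_face_geometry(fx$mesh)
  arc_center <- c(0, 0.012, 0)
  d_face <- sqrt(rowSums(sweep(geo$centroid, 2, arc_center)^2))
  d_line <- sqrt(rowSums(sweep(
    geo$cl$points[geo$nearest$index, , drop = FALSE], 2, arc_center)^2))
  expect_true(all((d_face < d_line) == (side == "inner")))
  # inner and outer areas are each about half the wall
  areas <- tapply(fx$mesh$face_area[geo$wall], side, sum)
  expect_lt(abs(areas["inner"] / areas["outer"] - 1), 0.2)
  # straight tube: all undefined
  st <- tiny_straight()
  expect_true(all(classify_curve_side(st$mesh) == "undefined"))
})

test_that("labels are equivariant under a joint rotation of mesh and axes", {
  fx <- tiny_curved()
  lab0 <- wall_labels(fx$mesh)
  # rotate everything 40 degrees about x
  th <- 40 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- fx$mesh
  rot$nodes <- fx$mesh$nodes %*% t(R)
  rot$face_centroid <- fx$mesh$face_centroid %*% t(R)
  rot$face_normal <- fx$mesh$face_normal %*% t(R)
  cl <- fx$mesh$meta$centerline
  clr <- cl
  clr$points <- cl$points %*% t(R)
  clr$tangents <- cl$tangents %*% t(R)
  clr$curvature_dir <- cl$curvature_dir %*% t(R)
  clr$n1 <- cl$n1 %*% t(R)
  clr$n2 <- cl$n2 %*% t(R)
  rot$meta$centerline <- clr
  axes_r <- anatomical_axes(ventral_dir = as.numeric(R %*% c(0, 1, 0)),
                            superior_dir = as.numeric(R %*% c(0, 0, 1)))
  lab1 <- wall_labels(rot, axes = axes_r)
  expect_identical(lab0$labels$quadrant, lab1$labels$quadrant)
  expect_identical(lab0$labels$segment, lab1$labels$segment)
  expect_identical(lab0$labels$curve_side, lab1$labels$curve_side)
})

test_that("plaque annotations snap to the wall their centroid is nearest", {
  fx <- tiny_straight()
  lab <- wall_labels(fx$mesh)
  # pick an inferior-wall face centroid mid-vessel, jitter 3 points nearby
  inf_faces <- which(lab$labels$quadrant == "inferior" &
                     lab$labels$segment == "middle")
  ctr <- fx$mesh$face_centroid[lab$wall_faces[inf_faces[1]], ]
  pts <- rbind(ctr + c(1e-4, 0, -1e-4), ctr + c(-1e-4, 1e-4, 0),
               ctr + c(0, -1e-4, 0))
  res <- assign_plaque(pts, lab, fx$mesh)
  expect_equal(res$assigned_wall, "inferior")
  expect_equal(res$assigned_segment, "middle")
  # point-count validation: 2-5 points
  expect_error(assign_plaque(matrix(ctr, 1), lab, fx$mesh), "2-5")
  expect_error(assign_plaque(matrix(rep(ctr, 6), 6, byrow = TRUE), lab,
                             fx$mesh), "2-5")
  # a centroid far outside the vessel is rejected
  far <- matrix(rep(ctr + c(0, 0.05, 0), 2), 2, byrow = TRUE)
  expect_error(assign_plaque(far, lab, fx$mesh), "diameter")
})

test_that("plaque CSV reading converts mm to meters", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("plaque_id,x_mm,y_mm,z_mm",
               "p1,10,0,2", "p1,11,0,2", "p2,5,1,0", "p2,5,2,0"), path)
  ann <- read_plaque_csv(path)
  expect_length(ann, 2L)
  expect_equal(ann$p1[1, ], c(0.010, 0, 0.002))
  unlink(path)
})
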