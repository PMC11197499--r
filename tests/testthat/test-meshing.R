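test_that("tube meshes fill the analytic volume within 2%", {
  cl <- make_centerline("straight", length = 0.03)
  v <- make_vessel_surface(cl, 0.002)
  m <- tetrahedralize(v, target_edge = 6e-4)
  va <- pi * 0.002^2 * 0.03
  expect_lt(abs(sum(m$tet_volume) - va) / va, 0.02)
  expect_gt(min(m$tet_volume), 0)
})

test_that("refining the mesh reduces the volume error monotonically", {
  cl <- make_centerline("straight", length = 0.015, n_points = 40)
  v <- make_vessel_surface(cl, 0.002)
  va <- pi * 0.002^2 * 0.015
  err <- vapply(c(1.0e-3, 5e-4), function(e) {
    m <- tetrahedralize(v, target_edge = e)
    abs(sum(m$tet_volume) - va) / va
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("near-wall grading shortens the wall-normal spacing", {
  fx <- tiny_straight()
  m <- fx$mesh
  # radial ring positions (normalized): wall gap vs mean interior gap
  gaps <- diff(c(0, m$meta$rho))
  wall_gap <- gaps[length(gaps)]
  interior <- mean(gaps[-length(gaps)])
  expect_lte(wall_gap / interior, 0.7)
})

test_that("boundary labels partition the closed surface", {
  fx <- tiny_straight()
  m <- fx$mesh
  expect_setequal(unique(m$face_label), c("inlet", "outlet_1", "wall"))
  # every boundary face has exactly one label by construction; closure:
  nsum <- colSums(m$face_normal * m$face_area)
  expect_lt(max(abs(nsum)), 1e-12)
  # divergence identity: oint x.n dA = 3V
  expect_lt(mesh_divergence_check(m), 1e-6)
  # inlet area approaches pi r^2: 2% at production resolution, polygonal
  # deficit dominates the coarse fixture
  a_in <- sum(m$face_area[m$face_label == "inlet"])
  expect_lt(abs(a_in - pi * fx$r^2) / (pi * fx$r^2), 0.05)
  pc <- poiseuille_case()
  a_in2 <- sum(pc$mesh$face_area[pc$mesh$face_label == "inlet"])
  expect_lt(abs(a_in2 - pi * pc$r^2) / (pi * pc$r^2), 0.02)
})

test_that("tag_boundaries relabels a stripped mesh identically", {
  fx <- tiny_straight()
  m2 <- fx$mesh
  m2$face_label <- NULL
  m2 <- tag_boundaries(m2, fx$vessel)
  expect_identical(m2$face_label, fx$mesh$face_label)
})

test_that("mesh_quality reports the hand-computable cube decomposition", {
  # unit cube split into 6 tetrahedra around the main diagonal
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  cube <- structure(list(nodes = nodes, tets = tets), class = "volume_mesh")
  q <- mesh_quality(cube, min_volume = 1e-14)
  expect_equal(q$n_cells, 6L)
  expect_equal(abs(q$min_volume), 1 / 6, tolerance = 1e-12)
  expect_error(mesh_quality(structure(list(nodes = nodes,
                                           tets = tets[0, , drop = FALSE]),
                                      class = "volume_mesh")), "no cells")
})

test_that("desk-scale default meshes stay in the intended cell-count band", {
  fx <- poiseuille_case()
  q <- mesh_quality(fx$mesh)
  expect_gte(q$n_cells, 1e4)
  expect_lte(q$n_cells, 2e5)
  expect_equal(q$n_below_min, 0)
})

test_that("mesh VTU output is well-formed XML with matching counts", {
  fx <- tiny_straight()
  path <- tempfile(fileext = ".vtu")
  write_mesh_vtu(fx$mesh, path)
  x <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(x, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(fx$mesh$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(fx$mesh$tets))
  unlink(path)
})
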