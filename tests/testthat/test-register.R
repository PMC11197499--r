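test_that("world to voxel projection rounds to the nearest voxel center", {
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8))
  idx <- world_to_voxel(c(0.4, 0.8, 1.6), t)
  expect_equal(unlist(idx[1, c("i", "j", "k")], use.names = FALSE),
               c(1L, 2L, 2L))
  expect_equal(unlist(world_to_voxel(c(0, 0, 0), t)[1, c("i", "j", "k")],
                      use.names = FALSE), c(0L, 0L, 0L))
  # out-of-grid points are flagged, not rejected
  idx2 <- world_to_voxel(c(-5, 0, 0), t, shape = c(10, 10, 10))
  expect_false(idx2$in_bounds)
})

test_that("voxel to world returns voxel centers and inverts the projection", {
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8), origin = c(1, 2, 3))
  expect_equal(voxel_to_world(c(0, 0, 0), t)[1, ], c(1, 2, 3))
  expect_equal(voxel_to_world(c(1, 2, 2),
                              grid_transform(c(0.4, 0.4, 0.8)))[1, ],
               c(0.4, 0.8, 1.6))
  # identity on voxel centers
  ijk <- cbind(3, 7, 2)
  expect_equal(unlist(world_to_voxel(voxel_to_world(ijk, t),
                                     t)[1, c("i", "j", "k")],
                      use.names = FALSE), as.integer(ijk))
})

test_that("round-trip error is at most half a voxel on random points", {
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8), origin = c(-3, 1, 0))
  set.seed(20)
  pts <- cbind(runif(1000, -2, 12), runif(1000, 2, 15), runif(1000, 1, 20))
  back <- voxel_to_world(world_to_voxel(pts, t), t)
  err <- abs(back - pts)
  expect_true(all(err[, 1] <= 0.2 + 1e-12))
  expect_true(all(err[, 2] <= 0.2 + 1e-12))
  expect_true(all(err[, 3] <= 0.4 + 1e-12))
})

test_that("image points localize the nearest wall face on the model", {
  fx <- tiny_straight()
  m <- fx$mesh
  wall <- which(m$face_label == "wall")
  target <- 5L
  ctr_mm <- m$face_centroid[wall[target], ] * 1e3
  # grid whose voxel (0,0,0) center sits exactly on the face centroid
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8), origin = ctr_mm)
  hit <- locate_point_on_model(c(0, 0, 0), t, m)
  expect_equal(hit$face, target)
  expect_lt(hit$distance_mm, 1e-9)
})

test_that("perturbed wall points are recovered at fine voxel spacing", {
  fx <- tiny_straight()
  m <- fx$mesh
  wall <- which(m$face_label == "wall")
  set.seed(7)
  pick <- sample(length(wall), 100)
  t <- grid_transform(spacing = c(0.05, 0.05, 0.05),
                      origin = apply(m$face_centroid[wall, ], 2, min) * 1e3)
  ok <- 0L
  for (q in seq_along(pick)) {
    ctr_mm <- m$face_centroid[wall[pick[q]], ] * 1e3
    jit <- runif(3, -0.0125, 0.0125)         # < spacing/4
    idx <- world_to_voxel(ctr_mm + jit, t)
    hit <- locate_point_on_model(as.matrix(idx[, 1:3]), t, m)
    if (hit$face == pick[q]) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("WSS projection deposits area-weighted means per voxel", {
  # uniform field: every valid voxel carries the field value
  f <- fake_wss_field(rep(3.7, 12),
                      centroid = cbind(seq(0, 0.0044, length.out = 12),
                                       0, 0))
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8))
  pr <- project_wss_to_image(f, t, shape = c(16, 3, 3))
  vals <- pr$wss$values[pr$valid$values == 1]
  expect_true(all(abs(vals - 3.7) < 1e-12))
  expect_true(all(pr$wss$values[pr$valid$values == 0] == 0))
  # single face: exactly one nonzero voxel
  f1 <- fake_wss_field(5, centroid = cbind(0.0008, 0, 0))
  pr1 <- project_wss_to_image(f1, t, shape = c(8, 2, 2))
  expect_equal(sum(pr1$valid$values), 1)
  # two faces in one voxel, areas 1 and 3, values 4 and 8 -> 7
  f2 <- fake_wss_field(c(4, 8), area = c(1, 3),
                       centroid = rbind(c(1e-5, 0, 0), c(2e-5, 0, 0)))
  pr2 <- project_wss_to_image(f2, t, shape = c(4, 2, 2))
  expect_equal(max(pr2$wss$values), 7)
})

test_that("projection conserves the area-weighted field mean", {
  fx <- tiny_curved()
  field <- compute_wss(fx$sol, fx$mesh)
  lo <- apply(field$centroid, 2, min) * 1e3 - 1
  hi <- apply(field$centroid, 2, max) * 1e3 + 1
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8), origin = lo)
  shape <- as.integer(ceiling((hi - lo) / t$spacing)) + 1L
  pr <- project_wss_to_image(field, t, shape)
  # voxel means weighted by deposited area equal the field mean
  idx <- world_to_voxel(field$centroid * 1e3, t, shape)
  lin <- 1L + idx$i + shape[1] * (idx$j + shape[2] * idx$k)
  dep_area <- tapply(field$face_area, lin, sum)
  vox_mean <- pr$wss$values[as.integer(names(dep_area))]
  lhs <- sum(vox_mean * as.numeric(dep_area)) / sum(dep_area)
  rhs <- sum(field$wss_magnitude * field$face_area) / sum(field$face_area)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("grid transforms round-trip through JSON", {
  t <- grid_transform(spacing = c(0.4, 0.4, 0.8), origin = c(-1, 2, 0.5),
                      signs = c(1, -1, 1))
  path <- tempfile(fileext = ".json")
  write_transform_json(t, path)
  back <- read_transform_json(path)
  expect_equal(unclass(back), unclass(t))
  unlink(path)
})
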