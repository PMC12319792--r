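test_that("trilinear sampling reproduces voxel centers and midpoints", {
  set.seed(1)
  vol <- scalar_volume(array(runif(5 * 6 * 7), c(5, 6, 7)))
  expect_equal(trilinear_sample(vol, rbind(c(2, 3, 4)))[1], vol$data[3, 4, 5])
  mid <- trilinear_sample(vol, rbind(c(2.5, 3, 4)))[1]
  expect_equal(mid, (vol$data[3, 4, 5] + vol$data[4, 4, 5]) / 2)
})

test_that("trilinear interpolation is exact on affine fields", {
  g <- c(8, 9, 10)
  idx <- as.matrix(expand.grid(x = 0:(g[1] - 1), y = 0:(g[2] - 1), z = 0:(g[3] - 1)))
  a <- c(0.3, -1.2, 0.7); b <- 2.5
  vol <- scalar_volume(array(idx %*% a + b, g))
  set.seed(2)
  pts <- cbind(runif(100, 0, g[1] - 1), runif(100, 0, g[2] - 1),
               runif(100, 0, g[3] - 1))
  got <- trilinear_sample(vol, pts)[, 1]
  expect_equal(got, as.numeric(pts %*% a + b), tolerance = 1e-6)
})

test_that("trilinear sampling is linear in the volume and continuous in points", {
  set.seed(3)
  v1 <- array(runif(4^3), c(4, 4, 4)); v2 <- array(runif(4^3), c(4, 4, 4))
  pts <- cbind(runif(20, 0, 3), runif(20, 0, 3), runif(20, 0, 3))
  s <- function(d) trilinear_sample(scalar_volume(d), pts)[, 1]
  expect_equal(s(2 * v1 + 3 * v2), 2 * s(v1) + 3 * s(v2), tolerance = 1e-10)
  # continuity: small point perturbation gives a small value change
  vol <- scalar_volume(v1)
  base <- trilinear_sample(vol, pts)[, 1]
  pert <- trilinear_sample(vol, pts + 1e-7)[, 1]
  expect_lt(max(abs(pert - base)), 1e-5)
})

test_that("out-of-grid points clamp and are counted", {
  vol <- scalar_volume(array(1:8, c(2, 2, 2)))
  out <- trilinear_sample(vol, rbind(c(-5, 0, 0), c(0.5, 0.5, 0.5)))
  expect_equal(out[1], vol$data[1, 1, 1])
  expect_equal(attr(out, "n_clamped"), 1)
  expect_error(scalar_volume(array(0, c(2, 2, 2)), affine = matrix(0, 4, 4)),
               "invertible")
})

test_that("occupancy rasterization recovers the analytic ball volume", {
  # radii chosen away from Pythagorean shells (e.g. r = 5 has 30 lattice
  # points exactly on the sphere), where lattice counts track the volume
  g <- c(32, 32, 32); ctr <- c(16, 16, 16)
  inner <- icosphere(5, 5.6, ctr)
  outer <- icosphere(5, 8.2, ctr)
  lab <- rasterize_occupancy(inner, outer, g)
  white <- sum(lab$data == 2)
  expect_equal(white, 4 / 3 * pi * 5.6^3, tolerance = 0.05)
  total_in <- sum(lab$data >= 1)
  expect_equal(total_in, 4 / 3 * pi * 8.2^3, tolerance = 0.05)
  expect_equal(length(lab$data), prod(g))  # labels partition the grid
  # and the count agrees exactly with an independent lattice-point count of
  # the ball (the icosphere is fine enough that no point falls in the gap)
  idx <- as.matrix(expand.grid(0:31, 0:31, 0:31))
  d2 <- rowSums(sweep(idx, 2, ctr, "-")^2)
  expect_equal(white, sum(d2 < 5.6^2))
})

test_that("identical inner and outer surfaces give zero gray voxels", {
  g <- c(24, 24, 24); ctr <- (g - 1) / 2
  m <- icosphere(2, 6, ctr)
  lab <- rasterize_occupancy(m, m, g)
  expect_equal(sum(lab$data == 1), 0)
  expect_error(rasterize_occupancy(one_triangle(), m, g), "closed")
})

test_that("rasterization is invariant to rigid motion of meshes and affine", {
  g <- c(20, 20, 20)
  inner <- icosphere(2, 4, (g - 1) / 2)
  outer <- icosphere(2, 6, (g - 1) / 2)
  base <- rasterize_occupancy(inner, outer, g)
  # rotate both meshes and the grid frame by the same rigid motion
  th <- 0.6
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(3, -2, 1)
  mv <- function(m) triangle_mesh(sweep(m$vertices %*% t(rot), 2, shift, "+"),
                                  m$faces, validate = FALSE)
  aff <- diag(4); aff[1:3, 1:3] <- rot; aff[1:3, 4] <- shift
  moved <- rasterize_occupancy(mv(inner), mv(outer), g, aff)
  expect_identical(moved$data, base$data)
})

test_that("MGH (.mgz) volumes are read with the correct data and affine", {
  # write an MGH file by hand (big-endian, 284-byte header, float32 data)
  dims <- c(4L, 3L, 2L)
  set.seed(6)
  dat <- array(round(rnorm(prod(dims)), 3), dims)
  spacing <- c(1, 1, 1)
  mdc <- diag(3)
  c_ras <- c(2, -1, 3)
  path <- tempfile(fileext = ".mgz")
  con <- gzfile(path, "wb")
  writeBin(as.integer(c(1, dims, 1, 3, 0)), con, size = 4, endian = "big")
  writeBin(1L, con, size = 2, endian = "big")
  writeBin(as.numeric(c(spacing, as.vector(mdc), c_ras)), con, size = 4,
           endian = "big")
  writeBin(raw(284 - 30 - 60), con)
  writeBin(as.numeric(dat), con, size = 4, endian = "big")
  close(con)
  vol <- read_volume(path)
  expect_equal(vol$data, dat, tolerance = 1e-6)
  # world position of the grid center equals c_ras under the MGH convention
  ctr_world <- cortexflow:::voxel_to_world(rbind(dims / 2), vol$affine)
  expect_equal(as.numeric(ctr_world), c_ras, tolerance = 1e-5)
  unlink(path)
})

test_that("NIfTI volumes round-trip with their affine", {
  set.seed(4)
  aff <- diag(4); aff[1:3, 4] <- c(-10, 5, 2)
  vol <- scalar_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), aff)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  v2 <- read_volume(path)
  expect_equal(v2$data, vol$data, tolerance = 1e-6)
  expect_equal(v2$affine, vol$affine, tolerance = 1e-5)
  unlink(path)
})
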