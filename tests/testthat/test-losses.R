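test_that("chamfer loss is zero for identical point sets and matches the oracle", {
  m <- icosphere(2)
  pts <- sample_surface_points(m, 200, rng_seed = 3)
  # pred points == ref points: place ref points exactly at a sample draw
  loss <- curvature_weighted_chamfer(m, pts, rep(1, 200), n_points = 200,
                                     rng_seed = 3)
  expect_lt(loss, 1e-12)
  set.seed(10)
  for (rep in 1:5) {
    pred <- random_bumpy_sphere(rep, sd = 0.1)
    refp <- matrix(rnorm(600, 0, 1), 200, 3)
    got <- curvature_weighted_chamfer(pred, refp, rep(1, 200), n_points = 200,
                                      rng_seed = rep)
    pp <- sample_surface_points(pred, 200, rng_seed = rep)
    expect_lt(abs(got - oracle_chamfer(pp, refp)), 1e-9)
    # weighted case against the oracle
    w <- runif(200, 0.2, 3)
    gotw <- curvature_weighted_chamfer(pred, refp, w, n_points = 200,
                                       rng_seed = rep)
    expect_lt(abs(gotw - oracle_chamfer(pp, refp, w)), 1e-9)
  }
})

test_that("upweighting a reference point increases the loss iff it is off-surface", {
  tri <- one_triangle()
  refp <- rbind(c(0.2, 0.2, 0), c(0.3, 0.3, 0.7))  # on-surface, off-surface
  base_w <- c(1, 1)
  l0 <- curvature_weighted_chamfer(tri, refp, base_w, n_points = 50, rng_seed = 1)
  l_on <- curvature_weighted_chamfer(tri, refp, c(4, 1), n_points = 50, rng_seed = 1)
  l_off <- curvature_weighted_chamfer(tri, refp, c(1, 4), n_points = 50, rng_seed = 1)
  expect_lt(l_on, l0)   # weight mass moves to a zero-distance point
  expect_gt(l_off, l0)  # doubling an off-surface point raises the loss
})

test_that("edge loss equals L^2 on uniform meshes and scales quadratically", {
  m <- icosphere(1)
  e <- mesh_edges(m)
  lens <- sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2))
  expect_equal(edge_loss(m), mean(lens^2), tolerance = 1e-12)
  m2 <- triangle_mesh(m$vertices * 3, m$faces)
  expect_equal(edge_loss(m2), 9 * edge_loss(m), tolerance = 1e-10)
  # direct per-edge oracle on a random mesh
  r <- random_bumpy_sphere(4, sd = 0.1)
  er <- mesh_edges(r)
  oracle <- mean(rowSums((r$vertices[er[, 1], ] - r$vertices[er[, 2], ])^2))
  expect_equal(edge_loss(r), oracle, tolerance = 1e-12)
})

test_that("normal consistency is zero on a plane, 1 for a right-angle fold, and decreases under refinement", {
  flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(normal_consistency_loss(flat), 0, tolerance = 1e-12)
  fold <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 1)),
                        rbind(c(1, 2, 3), c(2, 1, 4)))
  expect_equal(normal_consistency_loss(fold), 1, tolerance = 1e-12)
  vals <- vapply(1:3, function(l) normal_consistency_loss(icosphere(l)), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("voxel cross-entropy hits its closed-form anchors and the oracle", {
  lab <- array(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, 1L), c(2, 2, 2))
  onehot <- array(0, c(2, 2, 2, 3))
  for (i in 1:8) onehot[((i - 1) %% 2) + 1, (((i - 1) %/% 2) %% 2) + 1,
                        ((i - 1) %/% 4) + 1, lab[i] + 1] <- 50
  expect_lt(voxel_cross_entropy(onehot, lab), 1e-12)
  expect_equal(voxel_cross_entropy(array(0, c(2, 2, 2, 3)), lab), log(3),
               tolerance = 1e-12)
  set.seed(5)
  logits <- array(rnorm(24), c(2, 2, 2, 3))
  z <- matrix(logits, 8, 3)
  p <- exp(z) / rowSums(exp(z))
  oracle <- -mean(log(p[cbind(1:8, as.integer(lab) + 1)]))
  expect_equal(voxel_cross_entropy(logits, lab), oracle, tolerance = 1e-12)
})

test_that("the total loss is linear in each weight and zero at zero weights", {
  m <- random_bumpy_sphere(6, sd = 0.08)
  ref <- icosphere(1)
  rp <- reference_point_set(ref, 300, rng_seed = 2)
  set.seed(6)
  logits <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  lab <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  term <- function(w) total_loss(m, m, rp, rp, logits, lab, weights = w,
                                 rng_seed = 4)$loss
  zero <- loss_weights(0, 0, 0, 0, 300)
  expect_equal(term(zero), 0)
  only_ch <- total_loss(m, m, rp, rp, logits, lab,
                        weights = loss_weights(1, 0, 0, 0, 300), rng_seed = 4)
  expect_equal(only_ch$loss,
               only_ch$breakdown[["chamfer_white"]] + only_ch$breakdown[["chamfer_pial"]])
  # numeric linearity in each weight
  for (wn in c("w_chamfer", "w_edge", "w_normal", "w_voxel")) {
    w1 <- zero; w1[[wn]] <- 1
    w2 <- zero; w2[[wn]] <- 2
    l1 <- term(w1); l2 <- term(w2)
    expect_equal(l2, 2 * l1, tolerance = 1e-9)
    expect_gte(l1, 0)  # every term nonnegative
  }
})

test_that("mesh-term gradients match finite differences and are nonzero on a perturbed sphere", {
  m <- random_bumpy_sphere(7, sd = 0.05)
  fd_grad <- function(f, v0, eps = 1e-6) {
    g <- matrix(0, nrow(v0), 3)
    for (i in seq_len(nrow(v0))) for (k in 1:3) {
      vp <- v0; vp[i, k] <- vp[i, k] + eps
      vm <- v0; vm[i, k] <- vm[i, k] - eps
      g[i, k] <- (f(vp) - f(vm)) / (2 * eps)
    }
    g
  }
  ge <- edge_loss(m, with_grad = TRUE)$grad_vertices
  ge_fd <- fd_grad(function(v) edge_loss(triangle_mesh(v, m$faces, validate = FALSE)),
                   m$vertices)
  expect_lt(max(abs(ge - ge_fd)) / max(abs(ge)), 1e-5)
  gn <- normal_consistency_loss(m, with_grad = TRUE)$grad_vertices
  gn_fd <- fd_grad(function(v)
    normal_consistency_loss(triangle_mesh(v, m$faces, validate = FALSE)),
    m$vertices)
  expect_lt(max(abs(gn - gn_fd)) / max(abs(gn)), 1e-4)
  # chamfer gradient on a single triangle (face sampling fixed by seed)
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0.2)),
                       matrix(1:3, 1, 3), validate = FALSE)
  set.seed(8)
  refp <- matrix(rnorm(45, 0.3, 0.5), 15, 3)
  w <- runif(15, 0.5, 2)
  gc <- curvature_weighted_chamfer(tri, refp, w, n_points = 50, rng_seed = 11,
                                   with_grad = TRUE)
  gc_fd <- fd_grad(function(v)
    curvature_weighted_chamfer(triangle_mesh(v, tri$faces, validate = FALSE),
                               refp, w, n_points = 50, rng_seed = 11),
    tri$vertices)
  expect_lt(max(abs(gc$grad_vertices - gc_fd)) / max(abs(gc_fd)), 1e-5)
  # gradients actually flow (nonzero) for all three mesh terms
  expect_gt(max(abs(ge)), 0)
  expect_gt(max(abs(gn)), 0)
  expect_gt(max(abs(gc$grad_vertices)), 0)
})
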