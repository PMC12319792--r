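test_that("ASSD anchors: identical meshes, concentric spheres, symmetry, rigid invariance", {
  m <- icosphere(3)
  expect_lt(assd(m, m, n = 5000, rng_seed = 1), 1e-6)
  # concentric spheres r = 1.0 / 1.1 -> ~0.1
  a <- icosphere(4, 1.0); b <- icosphere(4, 1.1)
  d <- assd(a, b, n = 20000, rng_seed = 2)
  expect_equal(d, 0.1, tolerance = 0.05)
  # symmetric by construction (same seed drives both directions)
  expect_identical(assd(a, b, n = 5000, rng_seed = 3),
                   assd(b, a, n = 5000, rng_seed = 3))
  # rigid motion applied to both meshes
  th <- 0.8
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  mv <- function(m) triangle_mesh(sweep(m$vertices %*% t(rot), 2, c(5, -3, 2), "+"),
                                  m$faces, validate = FALSE)
  expect_equal(assd(mv(a), mv(b), n = 5000, rng_seed = 4),
               assd(a, b, n = 5000, rng_seed = 4), tolerance = 1e-6)
})

test_that("ASSD equals the exhaustive brute-force oracle on small instances", {
  set.seed(20)
  for (rep in 1:5) {
    pred <- random_bumpy_sphere(rep, level = 1, sd = 0.1)
    ref <- random_bumpy_sphere(rep + 50, level = 1, sd = 0.1)
    pp <- sample_surface_points(pred, 200, rng_seed = rep)
    pr <- sample_surface_points(ref, 200, rng_seed = rep)
    oracle <- (sum(oracle_point_mesh_dist(pp, ref)) +
                 sum(oracle_point_mesh_dist(pr, pred))) / 400
    expect_lt(abs(assd(pred, ref, n = 200, rng_seed = rep) - oracle), 1e-9)
  }
})

test_that("ASSD is stable across sampling seeds", {
  a <- icosphere(3, 1.0); b <- icosphere(3, 1.1)
  vals <- vapply(1:10, function(s) assd(a, b, n = 10000, rng_seed = s), 0)
  expect_lt(sd(vals) / mean(vals), 0.01)
})

test_that("percentile Hausdorff follows the interpolation rule and is monotone", {
  m <- icosphere(2)
  expect_equal(hdx(m, m, 90, n = 2000, rng_seed = 1), 0, tolerance = 1e-9)
  # hand-computed type-7 quantiles on the documented example
  d <- c(rep(0.1, 9), 1.0)
  expect_equal(percentile_hd(d, 0, 100), 1.0)
  expect_equal(percentile_hd(d, 0, 90), 0.1 + 0.1 * (1.0 - 0.1))  # 0.19
  a <- random_bumpy_sphere(3, sd = 0.1); b <- icosphere(2, 1.05)
  h90 <- hdx(a, b, 90, n = 5000, rng_seed = 5)
  h99 <- hdx(a, b, 99, n = 5000, rng_seed = 5)
  h100 <- hdx(a, b, 100, n = 5000, rng_seed = 5)
  expect_lte(h90, h99)
  expect_lte(h99, h100)
})

test_that("self-intersection fraction: convex meshes are clean, a piercing triangle is found", {
  expect_equal(self_intersection_fraction(icosphere(2)), 0)
  tetra <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                         rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_equal(self_intersection_fraction(tetra), 0)
  # 9 disjoint triangles + one triangle stabbing through the first
  strip_v <- NULL; strip_f <- NULL
  for (i in 0:8) {  # gaps of 1 between triangles: no touching
    strip_v <- rbind(strip_v, c(2 * i, 0, 0), c(2 * i + 1, 0, 0), c(2 * i, 1, 0))
    strip_f <- rbind(strip_f, c(3 * i + 1, 3 * i + 2, 3 * i + 3))
  }
  pierce_v <- rbind(c(0.3, 0.3, -0.5), c(0.5, 0.2, 0.5), c(0.2, 0.5, 0.5))
  mesh <- triangle_mesh(rbind(strip_v, pierce_v), rbind(strip_f, 27 + c(1, 2, 3)))
  expect_equal(self_intersection_fraction(mesh), 2 / 10)
})

test_that("self-intersections agree with the all-pairs oracle on random instances", {
  found_some <- FALSE
  for (rep in 1:8) {
    m <- random_bumpy_sphere(rep + 100, level = 1, sd = 0.25)
    fast <- cortexflow:::cpp_self_intersections(m$vertices, m$faces - 1L)
    slow <- oracle_self_intersections(m)
    expect_identical(as.logical(fast), slow, label = paste("instance", rep))
    if (any(slow)) found_some <- TRUE
  }
  expect_true(found_some)  # the perturbation level does produce intersections
})

test_that("cortical thickness matches shells, zero case, and per-vertex brute force", {
  w <- icosphere(4, 1.0); p <- icosphere(4, 1.5)
  th <- cortical_thickness(w, p)$values
  expect_equal(mean(th), 0.5, tolerance = 0.03)
  expect_lt(max(abs(th - 0.5)) / 0.5, 0.03)
  expect_equal(max(cortical_thickness(w, w)$values), 0, tolerance = 1e-12)
  ws <- random_bumpy_sphere(9, level = 1, sd = 0.05)
  ps <- triangle_mesh(ws$vertices * 1.4, ws$faces)
  got <- cortical_thickness(ws, ps)$values
  oracle <- (oracle_point_mesh_dist(ws$vertices, ps) +
               oracle_point_mesh_dist(ps$vertices, ws)) / 2
  expect_lt(max(abs(got - oracle)), 1e-9)
})

test_that("longitudinal variance reproduces the unbiased-variance hand cases", {
  expect_equal(longitudinal_variance(list(c(1, 5), c(3, 5)))$per_vertex, c(2, 0))
  expect_equal(longitudinal_variance(list(1, 2, 3))$per_vertex, 1)
  ident <- longitudinal_variance(list(c(2, 3, 4), c(2, 3, 4), c(2, 3, 4)))
  expect_equal(ident$per_vertex, c(0, 0, 0))
  expect_equal(ident$subject_median, 0)
  expect_error(longitudinal_variance(list(c(1, 2))), "single visit")
})

test_that("MCVar and CThVar are zero for identical visits and positive otherwise", {
  m <- icosphere(2); p <- icosphere(2, 1.4)
  sw <- surface_sequence("s", list(m, m, m), "white")
  sp <- surface_sequence("s", list(p, p, p), "pial")
  expect_equal(as.numeric(mcvar(sw)), 0)
  expect_equal(as.numeric(cthvar(sw, sp)), 0)
  m2 <- triangle_mesh(m$vertices * 1.05, m$faces)
  sw2 <- surface_sequence("s", list(m, m2), "white")
  expect_gt(as.numeric(mcvar(sw2)), 0)
})

test_that("ParcF1 is 1 for identical visits, bounded, and matches a hand-computed toy", {
  m <- icosphere(2)
  labs <- generate_parcellation(m, 4, rng_seed = 2)
  seq_id <- surface_sequence("s", list(m, m, m), "white")
  expect_equal(parc_f1(seq_id, labs), 1.0)
  # 8-vertex toy: an octahedron-like pair with one vertex pushed across a
  # label boundary so its nearest neighbor in the other visit has another label
  v1 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0),
              c(0, -1, 0), c(0, 0, -1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
             c(6, 3, 2), c(6, 4, 3), c(6, 5, 4), c(6, 2, 5))
  lab <- c(1L, 1L, 2L, 2L, 1L, 2L)
  m1 <- triangle_mesh(v1, f)
  v2 <- v1; v2[2, ] <- c(0.1, 0.95, 0.05)  # vertex 2 moves next to vertex 3
  m2 <- triangle_mesh(v2, f, validate = FALSE)
  sq <- surface_sequence("s", list(m1, m2), "white")
  # independent oracle: enumerate NN matches from the full distance matrix
  # and build the weighted F1 table longhand, for both ordered pairs
  oracle_pair <- function(ma, mb) {
    dmat <- as.matrix(dist(rbind(ma$vertices, mb$vertices)))[1:6, 7:12]
    pred <- lab[apply(dmat, 1, which.min)]
    truth <- lab
    f1c <- function(c) {
      tp <- sum(truth == c & pred == c); fp <- sum(truth != c & pred == c)
      fn <- sum(truth == c & pred != c)
      2 * tp / (2 * tp + fp + fn)
    }
    sup <- c(sum(truth == 1), sum(truth == 2))
    sum(c(f1c(1), f1c(2)) * sup) / sum(sup)
  }
  hand <- mean(c(oracle_pair(m1, m2), oracle_pair(m2, m1)))
  expect_equal(parc_f1(sq, lab), hand)
  expect_lt(parc_f1(sq, lab), 1)  # the displaced vertex does cross a boundary
  expect_gte(parc_f1(sq, lab), 0)
  expect_lte(parc_f1(sq, lab), 1)
  expect_error(parc_f1(surface_sequence("s", list(m1), "white"), lab),
               "at least two visits")
})
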