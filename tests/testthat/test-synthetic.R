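small_cfg <- function(...) {
  base <- list(n_subjects = 3, grid_shape = c(20, 20, 20),
               mesh_subdivisions = 2, visits_mean = 3,
               visits_sd = 1, visits_min = 2, visits_max = 4, rng_seed = 5)
  do.call(synthetic_cohort_config, utils::modifyList(base, list(...)))
}

test_that("subjects are bitwise reproducible given the seed", {
  cfg <- small_cfg()
  a <- generate_subject(cfg, 123, "s")
  b <- generate_subject(cfg, 123, "s")
  expect_identical(a, b)
  c2 <- generate_subject(cfg, 124, "s")
  expect_false(identical(a$pial[[1]]$vertices, c2$pial[[1]]$vertices))
})

test_that("ground-truth surfaces are closed, intersection-free, nested, and share connectivity", {
  cfg <- small_cfg()
  s <- generate_subject(cfg, 77, "s")
  for (j in seq_along(s$times)) {
    expect_true(is_closed_manifold(s$white[[j]]))
    expect_true(is_closed_manifold(s$pial[[j]]))
    expect_equal(self_intersection_fraction(s$white[[j]]), 0)
    expect_equal(self_intersection_fraction(s$pial[[j]]), 0)
    expect_identical(s$white[[j]]$faces, s$faces)
    expect_identical(s$pial[[j]]$faces, s$faces)
    # strict nesting: white vertices inside the pial surface
    ctr <- colMeans(s$pial[[j]]$vertices)
    rw <- sqrt(rowSums(sweep(s$white[[j]]$vertices, 2, ctr, "-")^2))
    rp <- sqrt(rowSums(sweep(s$pial[[j]]$vertices, 2, ctr, "-")^2))
    expect_true(all(rw < rp))
  }
})

test_that("zero atrophy and drift give identical visits with zero variance metrics", {
  cfg <- small_cfg(atrophy_rate = c(control = 0, ad = 0), drift_sd = 0)
  s <- generate_subject(cfg, 9, "s")
  for (j in 2:length(s$times)) {
    expect_identical(s$white[[j]]$vertices, s$white[[1]]$vertices)
    expect_identical(s$pial[[j]]$vertices, s$pial[[1]]$vertices)
  }
  sw <- surface_sequence("s", s$white, "white")
  sp <- surface_sequence("s", s$pial, "pial")
  expect_equal(as.numeric(mcvar(sw)), 0)
  expect_equal(as.numeric(cthvar(sw, sp)), 0)
})

test_that("injected atrophy is recoverable from measured thickness on ground truth", {
  cfg <- synthetic_cohort_config(n_subjects = 1, grid_shape = c(24, 24, 24),
                                 mesh_subdivisions = 3, drift_sd = 0,
                                 atrophy_rate = c(control = 0.1, ad = 0.1),
                                 rng_seed = 3)
  s <- generate_subject(cfg, 11, "s")
  # regress measured mean thickness on time: slope ~ -0.1/yr within 5%
  th <- vapply(seq_along(s$times), function(j)
    mean(cortical_thickness(s$white[[j]], s$pial[[j]])$values), 0)
  slope <- coef(lm(th ~ s$times))[2]
  expect_equal(as.numeric(slope), -0.1, tolerance = 0.05)
})

test_that("visit counts follow the configured truncated-normal distribution", {
  cfg <- small_cfg(n_subjects = 60)
  cohort <- generate_cohort(cfg)
  nv <- vapply(cohort$subjects, function(s) length(s$times), 0)
  expect_true(all(nv >= cfg$visits_min & nv <= cfg$visits_max))
  # cohort mean within 3 sigma of the truncated-distribution expectation,
  # estimated here by direct simulation of the same truncation rule
  set.seed(99)
  draws <- rnorm(40000, cfg$visits_mean, cfg$visits_sd)
  draws <- round(draws)
  draws <- draws[draws >= cfg$visits_min & draws <= cfg$visits_max]
  expect_lt(abs(mean(nv) - mean(draws)), 3 * sd(draws) / sqrt(length(nv)))
})

test_that("parcellations partition the vertices into contiguous nonempty regions", {
  m <- icosphere(3)
  p1 <- generate_parcellation(m, 1)
  expect_true(all(p1$values == 1L))
  p8 <- generate_parcellation(m, 8, rng_seed = 4)
  expect_length(p8$values, nrow(m$vertices))
  sizes <- table(factor(p8$values, levels = 1:8))
  expect_true(all(sizes > 0))
  expect_lt(sd(sizes) / mean(sizes), 0.5)  # roughly balanced
  # determinism
  expect_identical(generate_parcellation(m, 8, rng_seed = 4)$values, p8$values)
})

test_that("cohorts export to disk and re-import with resolving paths", {
  cfg <- small_cfg(n_subjects = 2)
  cohort <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort-export-test")
  manifest <- export_cohort(cohort, dir)
  expect_equal(nrow(manifest),
               sum(vapply(cohort$subjects, function(s) length(s$times), 0)))
  imp <- import_cohort(dir)
  expect_equal(nrow(imp$manifest), nrow(manifest))
  expect_identical(imp$template_white$faces, cohort$template_white$faces)
  v1 <- imp$load_volume(1)
  expect_equal(v1$data, cohort$subjects[[1]]$volume[[1]]$data, tolerance = 1e-6)
  w1 <- imp$load_white(1)
  expect_equal(w1$vertices, cohort$subjects[[1]]$white[[1]]$vertices,
               tolerance = 1e-5)
  expect_identical(imp$parcellation$values, cohort$parcellation$values)
  unlink(dir, recursive = TRUE)
})

test_that("impossible geometry parameters are rejected", {
  cfg <- small_cfg(thickness_mean = 20)  # thicker than the outer radius
  expect_error(generate_subject(cfg, 1, "s"), "crossing")
})
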