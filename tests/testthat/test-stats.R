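test_that("noise-free data generated from the regression model is recovered exactly", {
  # all random terms zero: the fixed effects are exactly identifiable
  recs <- simulate_subject_records(n_subjects = 16, n_vertices = 6,
                                   n_visits = 4,
                                   beta = c(2.5, -0.004, -0.03, -0.3),
                                   sd_b0 = 0, sd_b1 = 0, sd_eps = 0,
                                   rng_seed = 2)
  fit <- vertexwise_lme(recs)
  expect_true(all(fit$converged))
  expect_equal(fit$beta3, rep(-0.3, 6), tolerance = 1e-6)
})

test_that("a vertex mask restricts the fitted vertices without renumbering", {
  recs <- simulate_subject_records(n_subjects = 10, n_vertices = 5,
                                   sd_eps = 0.05, rng_seed = 3)
  fit <- vertexwise_lme(recs, vertex_mask = c(2, 4))
  expect_equal(fit$vertex, c(2L, 4L))
})

test_that("type-I error is calibrated under the null", {
  # beta3 = 0: fraction of p < 0.05 within 3 sigma of 0.05
  recs <- simulate_subject_records(n_subjects = 30, n_vertices = 60,
                                   n_visits = 3,
                                   beta = c(2.5, -0.004, -0.02, 0),
                                   sd_b0 = 0.08, sd_b1 = 0.02, sd_eps = 0.05,
                                   rng_seed = 7)
  fit <- vertexwise_lme(recs)
  frac <- mean(fit$p < 0.05, na.rm = TRUE)
  se3 <- 3 * sqrt(0.05 * 0.95 / nrow(fit))
  expect_lt(abs(frac - 0.05), se3 + 0.05)  # wide but bounded: vertices share subjects
})

test_that("an injected diagnosis effect is detected far above the permuted baseline", {
  recs <- simulate_subject_records(n_subjects = 30, n_vertices = 40,
                                   n_visits = 3,
                                   beta = c(2.5, -0.004, -0.02, -0.3),
                                   sd_b0 = 0.08, sd_b1 = 0.02, sd_eps = 0.05,
                                   rng_seed = 8)
  fit <- vertexwise_lme(recs)
  frac_true <- mean(fit$p < 0.05)
  # permute diagnosis labels across subjects
  set.seed(9)
  d_perm <- sample(vapply(recs, `[[`, 0L, "diagnosis"))
  recs_perm <- mapply(function(r, d) { r$diagnosis <- d; r }, recs, d_perm,
                      SIMPLIFY = FALSE)
  frac_perm <- mean(vertexwise_lme(recs_perm)$p < 0.05)
  expect_gt(frac_true, frac_perm)
  expect_gt(frac_true, 0.9)  # strong effect at this contrast
})

test_that("beta3 estimates are nearly unbiased across repeated cohorts", {
  est <- vapply(1:12, function(s) {
    recs <- simulate_subject_records(n_subjects = 40, n_vertices = 2,
                                     n_visits = 3, beta = c(2.5, -0.004, -0.02, -0.3),
                                     sd_b0 = 0.08, sd_b1 = 0.02, sd_eps = 0.05,
                                     rng_seed = 100 + s)
    mean(vertexwise_lme(recs)$beta3)
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.3)) / 0.3, 0.1)
})

test_that("normative Z-scores hit their closed-form anchors", {
  nv <- 8
  mk <- function(id, age, th, d) subject_record(id, age, 0, list(th), d)
  base <- rnorm(nv, 2.5, 0.1)
  refs <- lapply(1:6, function(i)
    mk(sprintf("c%d", i), 64 + i %% 3, base + rnorm(nv, 0, 0.1), 0))
  ref_ids <- vapply(refs, `[[`, "", "subject_id")
  ref_mat <- t(vapply(refs, function(r) r$thickness[[1]], numeric(nv)))
  mu <- colMeans(ref_mat); sdv <- apply(ref_mat, 2, sd)
  probe_mean <- mk("p1", 65, mu, 1)
  probe_plus <- mk("p2", 65, mu + sdv, 1)
  z <- normative_zscores(c(refs, list(probe_mean, probe_plus)), ref_ids)
  expect_equal(z$mean_z[z$subject == "p1"], 0, tolerance = 1e-10)
  expect_equal(z$mean_z[z$subject == "p2"], 1, tolerance = 1e-10)
  # a vertex mask excludes the designated region from the average
  mask <- rep(TRUE, nv); mask[1:2] <- FALSE
  probe_odd <- mk("p3", 65, { t2 <- mu; t2[1] <- t2[1] + 50; t2 }, 1)
  z2 <- normative_zscores(c(refs, list(probe_odd)), ref_ids, vertex_mask = mask)
  expect_equal(z2$mean_z[z2$subject == "p3"], 0, tolerance = 1e-10)
  # empty brackets are reported by name
  lone <- mk("c9", 95, base, 0)
  expect_error(normative_zscores(c(refs, list(lone)),
                                 c(ref_ids, "c9")), "bracket")
})

test_that("thinner synthetic patients score below controls and separate by AUC", {
  set.seed(11)
  nv <- 10
  mk <- function(id, age, th, d) subject_record(id, age, 0, list(th), d)
  controls <- lapply(1:12, function(i)
    mk(sprintf("c%d", i), runif(1, 60, 79), rnorm(nv, 2.5, 0.05), 0))
  patients <- lapply(1:12, function(i)
    mk(sprintf("a%d", i), runif(1, 60, 79), rnorm(nv, 2.2, 0.05), 1))
  z <- normative_zscores(c(controls, patients),
                         vapply(controls, `[[`, "", "subject_id"))
  expect_lt(mean(z$mean_z[z$diagnosis == 1]), mean(z$mean_z[z$diagnosis == 0]))
  a <- auc(-z$mean_z, z$diagnosis)  # lower Z = more atrophic = patient
  expect_gt(a, 0.9)
})

test_that("AUC follows the Mann-Whitney enumeration and its symmetries", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  set.seed(12)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  expect_equal(auc(s, 1 - l), 1 - auc(s, l), tolerance = 1e-12)
  # ties get midranks: all-equal scores give 0.5
  expect_equal(auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
})
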