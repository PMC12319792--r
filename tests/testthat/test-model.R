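# shared tiny fixtures for model tests
tiny_setup <- function(level = 1, grid = 12, seed = 2) {
  ctr <- rep((grid - 1) / 2, 3)
  set.seed(seed)
  vol <- scalar_volume(array(runif(grid^3), rep(grid, 3)))
  list(white = icosphere(level, grid * 0.18, ctr),
       pial = icosphere(level, grid * 0.28, ctr),
       volume = vol, ctr = ctr)
}

test_that("config invariants are enforced", {
  expect_error(deform_config(n_integration_steps = 4, step_size = 0.2),
               "must equal 1")
  expect_silent(deform_config(n_integration_steps = 10, step_size = 0.1))
})

test_that("the joint graph has the expected structure", {
  w <- icosphere(1); p <- icosphere(1, 1.5)
  g_on <- build_graph(w, p, virtual_edges = TRUE)
  nv <- nrow(w$vertices)
  expect_equal(g_on$n_nodes, 2 * nv)
  expect_equal(g_on$n_virtual, nv)
  g_off <- build_graph(w, p, virtual_edges = FALSE)
  e_mesh <- nrow(mesh_edges(w))
  expect_equal(nrow(g_off$edges), 2 * e_mesh)
  expect_equal(nrow(g_on$edges), 2 * e_mesh + nv)
  # per-node degree = mesh degree (+1 when virtual edges are on)
  mesh_deg <- tabulate(as.vector(rbind(mesh_edges(w)[, 1], mesh_edges(w)[, 2])), nv)
  expect_equal(g_on$degree[seq_len(nv)], mesh_deg + 1L)
  expect_equal(g_off$degree[seq_len(nv)], mesh_deg)
  expect_error(build_graph(w, icosphere(2)), "share vertex count")
})

test_that("an untrained model is the identity deformation", {
  s <- tiny_setup()
  cfg <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  params <- init_deform_params(cfg)
  out <- integrate_flow(s$white, s$pial, s$volume, params, cfg)
  expect_identical(out$white$vertices, s$white$vertices)
  expect_identical(out$pial$vertices, s$pial$vertices)
  expect_identical(out$white$faces, s$white$faces)
})

test_that("Euler integration matches closed forms for stub fields", {
  s <- tiny_setup()
  cfg <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  params <- init_deform_params(cfg)
  v0 <- rbind(s$white$vertices, s$pial$vertices)
  # constant field: V(1) = T + c
  cvec <- c(0.3, -0.2, 0.5)
  out <- integrate_flow(s$white, s$pial, s$volume, params, cfg,
                        flow_override = function(t, v)
                          matrix(cvec, nrow(v), 3, byrow = TRUE))
  got <- rbind(out$white$vertices, out$pial$vertices)
  expect_lt(max(abs(got - sweep(v0, 2, cvec, "+"))), 1e-5)
  # linear field f(V) = V A^T: V(1) = T ((I + hA)^5)^T
  a <- matrix(c(0.1, 0.05, 0, -0.02, 0.08, 0.01, 0, 0.03, -0.06), 3, 3)
  out2 <- integrate_flow(s$white, s$pial, s$volume, params, cfg,
                         flow_override = function(t, v) v %*% t(a))
  step <- diag(3) + 0.2 * a
  m5 <- step %*% step %*% step %*% step %*% step
  expected <- v0 %*% t(m5)
  got2 <- rbind(out2$white$vertices, out2$pial$vertices)
  expect_lt(max(abs(got2 - expected)), 1e-5)
})

test_that("the flow field is equivariant under vertex permutation", {
  s <- tiny_setup()
  cfg <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  params <- init_deform_params(cfg)
  params$head_w <- matrix(rnorm(length(params$head_w), 0, 0.05),
                          nrow(params$head_w), 3)
  graph <- build_graph(s$white, s$pial, TRUE)
  pyr <- encode_volume(params, s$volume, cfg)
  attr(pyr, "frame") <- cortexflow:::volume_frame(s$volume)
  nv <- nrow(s$white$vertices)
  v <- rbind(s$white$vertices, s$pial$vertices)
  feats0 <- matrix(0, 2 * nv, cfg$graph_feature_dim * cfg$n_graph_blocks)
  base <- flow_field(v, feats0, pyr, graph, params, cfg, t = 0.2)
  # permute within each surface block so surface membership is preserved
  set.seed(9)
  perm_half <- sample(nv)
  perm <- c(perm_half, perm_half + nv)
  pw <- triangle_mesh(s$white$vertices[perm_half, ],
                      matrix(match(s$white$faces, perm_half), ncol = 3),
                      validate = FALSE)
  pp <- triangle_mesh(s$pial$vertices[perm_half, ],
                      matrix(match(s$pial$faces, perm_half), ncol = 3),
                      validate = FALSE)
  graph_p <- build_graph(pw, pp, TRUE)
  got <- flow_field(v[perm, ], feats0, pyr, graph_p, params, cfg, t = 0.2)
  expect_equal(got$velocity, base$velocity[perm, ], tolerance = 1e-10)
})

test_that("velocities respond to the image content", {
  s <- tiny_setup()
  cfg <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  params <- init_deform_params(cfg)
  params$head_w <- matrix(rnorm(length(params$head_w), 0, 0.05),
                          nrow(params$head_w), 3)
  out1 <- integrate_flow(s$white, s$pial, s$volume, params, cfg)
  vol2 <- scalar_volume(s$volume$data * 0 + 1, s$volume$affine)
  out2 <- integrate_flow(s$white, s$pial, vol2, params, cfg)
  expect_gt(max(abs(out1$white$vertices - out2$white$vertices)), 1e-8)
})

test_that("integration is deterministic and aborts on divergence", {
  s <- tiny_setup()
  cfg <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  params <- init_deform_params(cfg)
  params$head_w <- matrix(rnorm(length(params$head_w), 0, 0.05),
                          nrow(params$head_w), 3)
  a <- integrate_flow(s$white, s$pial, s$volume, params, cfg)
  b <- integrate_flow(s$white, s$pial, s$volume, params, cfg)
  expect_identical(a$white$vertices, b$white$vertices)
  expect_error(
    integrate_flow(s$white, s$pial, s$volume, params, cfg,
                   flow_override = function(t, v) v * 1e4),
    "diverged")
})

test_that("stage-2 initialization copies everything except input layers", {
  cfg1 <- deform_config(encoder_channels = c(3, 4), rng_seed = 5)
  p1 <- init_deform_params(cfg1)
  cfg2 <- deform_config(encoder_channels = c(3, 4), rng_seed = 6,
                        template_feature_dim = 128)
  p2 <- init_stage2_from_stage1(p1, cfg2)
  for (nm in setdiff(names(p1), c("gnn1_w_self", "gnn1_w_nbr")))
    expect_identical(p2[[nm]], p1[[nm]], label = nm)
  expect_false(identical(dim(p2$gnn1_w_self), dim(p1$gnn1_w_self)))
  # degenerate case: no extra features -> full copy
  cfg2b <- deform_config(encoder_channels = c(3, 4), rng_seed = 7)
  p2b <- init_stage2_from_stage1(p1, cfg2b)
  expect_identical(p2b, p1)
  # shape mismatch outside input layers is an error
  p_bad <- p1
  p_bad$conv_c_w <- array(0, c(3, 3, 3, 2, 2))
  expect_error(init_stage2_from_stage1(p_bad, cfg2), "shape mismatch")
})

test_that("configurations round-trip through YAML", {
  cfg <- deform_config(encoder_channels = c(5, 7), n_integration_steps = 10,
                       step_size = 0.1, virtual_edges = FALSE, rng_seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  cfg2 <- read_config_yaml(path)
  expect_equal(cfg2, cfg)
  unlink(path)
})

test_that("checkpoints verify the template fingerprint", {
  cfg <- deform_config(encoder_channels = c(3, 4))
  p <- init_deform_params(cfg)
  m <- icosphere(1)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(p, cfg, m$faces, path)
  ck <- load_checkpoint(path, m$faces)
  expect_equal(ck$params$conv_a_w, p$conv_a_w)
  expect_equal(ck$config$encoder_channels, cfg$encoder_channels)
  expect_error(load_checkpoint(path, icosphere(2)$faces), "fingerprint")
  unlink(path)
})
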