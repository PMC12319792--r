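# Template-deformation network: a small 3D convolutional encoder-decoder
# extracts multi-resolution image features; trilinear interpolation pulls
# them onto the template vertices; graph-convolution blocks over the joint
# white+pial graph predict a velocity field; explicit Euler integration on
# t in [0,1] deforms the template to the image.

#' Deformation model configuration
#'
#' @param encoder_channels length-2 integer: channels of the full-resolution
#'   and half-resolution feature levels.
#' @param n_graph_blocks number of graph-convolution blocks (features from
#'   all blocks are concatenated into the velocity head input and exported
#'   as the per-vertex deep features).
#' @param graph_feature_dim width of each graph block (default 64).
#' @param n_integration_steps,step_size Euler scheme on `t` in `[0,1]`;
#'   their product must equal 1 (default 5 steps of 0.2).
#' @param virtual_edges connect white vertex `v` to pial vertex `v` in the
#'   joint graph to discourage surface crossings.
#' @param template_feature_dim dimension `D_f` of static per-vertex features
#'   carried by the input template (0 in stage 1; `graph_feature_dim *
#'   n_graph_blocks` when deforming a feature-enriched within-subject
#'   template in stage 2).
#' @param rng_seed seed for weight initialization.
#' @return a `deform_config` list.
#' @export
deform_config <- function(encoder_channels = c(8, 16),
                          n_graph_blocks = 2,
                          graph_feature_dim = 64,
                          n_integration_steps = 5,
                          step_size = 0.2,
                          virtual_edges = TRUE,
                          template_feature_dim = 0,
                          rng_seed = 1) {
  if (abs(n_integration_steps * step_size - 1) > 1e-9)
    stop("n_integration_steps * step_size must equal 1 (integration on t in [0,1])")
  if (graph_feature_dim < 1) stop("graph_feature_dim must be >= 1")
  structure(list(encoder_channels = as.integer(encoder_channels),
                 n_graph_blocks = as.integer(n_graph_blocks),
                 graph_feature_dim = as.integer(graph_feature_dim),
                 n_integration_steps = as.integer(n_integration_steps),
                 step_size = step_size,
                 virtual_edges = isTRUE(virtual_edges),
                 template_feature_dim = as.integer(template_feature_dim),
                 rng_seed = as.integer(rng_seed)),
            class = "deform_config")
}

#' Joint deformation graph over white and pial templates
#'
#' Nodes are the vertices of both surfaces; edges come from the mesh faces,
#' plus (optionally) a virtual edge joining white vertex `v` to pial vertex
#' `v` for every `v`.
#'
#' @param white,pial template [triangle_mesh()] objects with equal vertex
#'   count and identical connectivity.
#' @param virtual_edges add white-pial virtual edges.
#' @return a `deform_graph` list with the edge list, per-node neighbor
#'   structure, and surface membership.
#' @export
build_graph <- function(white, pial, virtual_edges = TRUE) {
  nv <- nrow(white$vertices)
  if (nrow(pial$vertices) != nv || !identical(white$faces, pial$faces))
    stop("white and pial templates must share vertex count and connectivity")
  e1 <- mesh_edges(white)
  edges <- rbind(e1, e1 + nv)
  n_virtual <- 0L
  if (virtual_edges) {
    edges <- rbind(edges, cbind(seq_len(nv), seq_len(nv) + nv))
    n_virtual <- nv
  }
  # directed neighbor lists (both directions of each undirected edge)
  src <- as.integer(c(edges[, 1], edges[, 2]))
  dst <- as.integer(c(edges[, 2], edges[, 1]))
  ord <- order(src)
  src <- src[ord]; dst <- dst[ord]
  deg <- tabulate(src, 2L * nv)
  # sparse neighborhood-mean operator and its adjoint, built once
  m <- Matrix::sparseMatrix(i = src, j = dst,
                            x = 1 / pmax(deg, 1)[src],
                            dims = c(2L * nv, 2L * nv))
  structure(list(n_nodes = 2L * nv, n_per_surface = nv,
                 edges = edges, n_virtual = n_virtual,
                 nbr_center = src, nbr_neighbor = dst, degree = deg,
                 mean_op = m, mean_op_t = Matrix::t(m),
                 surface_id = rep(c(1L, 2L), each = nv)),
            class = "deform_graph")
}

# neighbor-mean aggregation  (M X)[i] = mean_{j in N(i)} X[j]
neighbor_mean <- function(x, graph) {
  as.matrix(graph$mean_op %*% x)
}

# adjoint of neighbor_mean: (M^T G)[j] = sum_{i : j in N(i)} G[i] / deg(i)
neighbor_mean_t <- function(g, graph) {
  as.matrix(graph$mean_op_t %*% g)
}

# ---- parameters ------------------------------------------------------------

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

# width of the node input vector of the first graph block
gnn_input_dim <- function(config) {
  c1 <- config$encoder_channels[1]; c2 <- config$encoder_channels[2]
  fd <- config$graph_feature_dim * config$n_graph_blocks
  c1 + c2 + 3L + 2L + 1L + fd + config$template_feature_dim
  # image feats | coords | surface one-hot | t | recurrent feats | static feats
}

#' Initialize deformation model parameters
#'
#' All layers use scaled-normal (He) initialization except the velocity
#' head, which is zero-initialized so that an untrained model is exactly the
#' identity deformation.
#'
#' @param config a [deform_config()].
#' @return named list of parameter arrays.
#' @export
init_deform_params <- function(config) {
  with_seed(config$rng_seed, {
    c1 <- config$encoder_channels[1]; c2 <- config$encoder_channels[2]
    gd <- config$graph_feature_dim
    din <- gnn_input_dim(config)
    p <- list(
      conv_a_w = he_init(c(3, 3, 3, 1, c1), 27),
      conv_a_b = numeric(c1),
      conv_b_w = he_init(c(3, 3, 3, c1, c1), 27 * c1),
      conv_b_b = numeric(c1),
      conv_down_w = he_init(c(3, 3, 3, c1, c2), 27 * c1),
      conv_down_b = numeric(c2),
      conv_c_w = he_init(c(3, 3, 3, c2, c2), 27 * c2),
      conv_c_b = numeric(c2),
      conv_up_w = he_init(c(3, 3, 3, c1 + c2, c1), 27 * (c1 + c2)),
      conv_up_b = numeric(c1),
      seg_w = he_init(c(c1, 3), c1),
      seg_b = numeric(3))
    for (b in seq_len(config$n_graph_blocks)) {
      d_in <- if (b == 1) din else gd
      p[[paste0("gnn", b, "_w_self")]] <- he_init(c(d_in, gd), d_in)
      p[[paste0("gnn", b, "_w_nbr")]] <- he_init(c(d_in, gd), d_in)
      p[[paste0("gnn", b, "_b1")]] <- numeric(gd)
      p[[paste0("gnn", b, "_w2_self")]] <- he_init(c(gd, gd), gd)
      p[[paste0("gnn", b, "_w2_nbr")]] <- he_init(c(gd, gd), gd)
      p[[paste0("gnn", b, "_b2")]] <- numeric(gd)
    }
    p$head_w <- matrix(0, gd * config$n_graph_blocks, 3)  # zero-init: identity flow
    p$head_b <- numeric(3)
    p
  })
}

#' Initialize stage-2 parameters from a trained stage-1 model
#'
#' Copies every parameter tensor except the input layer of the first graph
#' block, whose width changes when the within-subject template carries
#' static vertex features; those are freshly (seeded) initialized.
#'
#' @param params_stage1 trained stage-1 parameter list.
#' @param config_stage2 a [deform_config()] with the stage-2
#'   `template_feature_dim`.
#' @return stage-2 parameter list.
#' @export
init_stage2_from_stage1 <- function(params_stage1, config_stage2) {
  p2 <- init_deform_params(config_stage2)
  input_layers <- c("gnn1_w_self", "gnn1_w_nbr")
  for (nm in names(p2)) {
    if (nm %in% input_layers) {
      if (identical(dim(params_stage1[[nm]]), dim(p2[[nm]])))
        p2[[nm]] <- params_stage1[[nm]]  # degenerate case: same width, copy
      next
    }
    if (!identical(dim(params_stage1[[nm]]), dim(p2[[nm]])) &&
        !identical(length(params_stage1[[nm]]), length(p2[[nm]])))
      stop("parameter shape mismatch outside input layers: ", nm)
    p2[[nm]] <- params_stage1[[nm]]
  }
  p2
}

# ---- encoder ---------------------------------------------------------------

conv3d <- function(x, w, b, stride = 1L) {
  d <- dim(x)
  cout <- dim(w)[5]
  out <- cpp_conv3d_fwd(as.numeric(x), as.integer(d), as.numeric(w),
                        as.numeric(b), cout, as.integer(stride))
  dim(out) <- c(ceiling(d[1:3] / stride), cout)
  out
}

# leaky rectifier (slope 0.1): keeps gradient alive in rarely-active units
relu <- function(x) {
  out <- cpp_leaky(as.numeric(x))
  dim(out) <- dim(x)
  out
}

# gradient through the leaky rectifier from the post-activation sign
relu_grad <- function(act, g) {
  out <- cpp_leaky_grad(as.numeric(act), as.numeric(g))
  dim(out) <- dim(g)
  out
}

#' Encode a volume into a multi-resolution feature pyramid
#'
#' Small convolutional encoder-decoder with a skip connection: a
#' full-resolution feature level, a half-resolution level, and an auxiliary
#' per-voxel 3-class segmentation head (background / gray / white) used only
#' by the voxel cross-entropy loss.
#'
#' @param params parameter list from [init_deform_params()].
#' @param volume a [scalar_volume()].
#' @param config a [deform_config()].
#' @param keep_cache retain intermediate activations for the backward pass.
#' @return a `feature_pyramid`: list of levels (each `data` `H x W x D x C`
#'   plus `affine`), segmentation logits, and optional cache.
#' @export
encode_volume <- function(params, volume, config, keep_cache = FALSE) {
  x <- array(volume$data, c(dim(volume$data), 1))
  if (any(!is.finite(x))) stop("NaN in encoder input volume")
  a1 <- relu(conv3d(x, params$conv_a_w, params$conv_a_b))
  a2 <- relu(conv3d(a1, params$conv_b_w, params$conv_b_b))
  d1 <- relu(conv3d(a2, params$conv_down_w, params$conv_down_b, stride = 2L))
  c1 <- relu(conv3d(d1, params$conv_c_w, params$conv_c_b))
  up <- cpp_upsample_nearest(as.numeric(c1), as.integer(dim(c1)),
                             as.integer(c(dim(a2)[1:3], dim(c1)[4])))
  dim(up) <- c(dim(a2)[1:3], dim(c1)[4])
  cat_in <- array(c(a2, up), c(dim(a2)[1:3], dim(a2)[4] + dim(up)[4]))
  f0 <- relu(conv3d(cat_in, params$conv_up_w, params$conv_up_b))
  # per-voxel linear segmentation head on the full-resolution features
  nvox <- prod(dim(f0)[1:3])
  f0m <- matrix(f0, nvox, dim(f0)[4])
  seg <- sweep(f0m %*% params$seg_w, 2, params$seg_b, "+")
  if (any(!is.finite(f0))) stop("NaN in encoder features at level 1")
  if (any(!is.finite(c1))) stop("NaN in encoder features at level 2")
  lvl2_affine <- volume$affine %*% diag(c(2, 2, 2, 1))
  structure(list(
    levels = list(list(data = f0, affine = volume$affine),
                  list(data = c1, affine = lvl2_affine)),
    seg_logits = array(seg, c(dim(f0)[1:3], 3)),
    cache = if (keep_cache) list(x = x, a1 = a1, a2 = a2, d1 = d1, c1 = c1,
                                 up = up, cat_in = cat_in, f0 = f0) else NULL),
    class = "feature_pyramid")
}

# backward through the encoder given gradients on the two feature levels and
# the segmentation logits; returns parameter gradients
encode_volume_backward <- function(params, pyr, g_f0, g_c1, g_seg) {
  cc <- pyr$cache
  grads <- list()
  dims_f0 <- dim(cc$f0)
  nvox <- prod(dims_f0[1:3])
  f0m <- matrix(cc$f0, nvox, dims_f0[4])
  gsegm <- matrix(g_seg, nvox, 3)
  grads$seg_w <- crossprod(f0m, gsegm)
  grads$seg_b <- colSums(gsegm)
  g_f0 <- g_f0 + array(gsegm %*% t(params$seg_w), dims_f0)
  g_f0 <- relu_grad(cc$f0, g_f0)
  bw <- cpp_conv3d_bwd(as.numeric(cc$cat_in), as.integer(dim(cc$cat_in)),
                       as.numeric(params$conv_up_w), dim(params$conv_up_w)[5],
                       1L, as.numeric(g_f0))
  grads$conv_up_w <- array(bw$grad_weights, dim(params$conv_up_w))
  grads$conv_up_b <- bw$grad_bias
  g_cat <- array(bw$grad_input, dim(cc$cat_in))
  ca <- dim(cc$a2)[4]
  g_a2 <- g_cat[, , , seq_len(ca), drop = FALSE]
  g_up <- g_cat[, , , ca + seq_len(dim(cc$c1)[4]), drop = FALSE]
  g_c1 <- g_c1 + array(
    cpp_upsample_nearest_adjoint(as.numeric(g_up), as.integer(dim(cc$c1)),
                                 as.integer(dim(cc$up))), dim(cc$c1))
  g_c1 <- relu_grad(cc$c1, g_c1)
  bw <- cpp_conv3d_bwd(as.numeric(cc$d1), as.integer(dim(cc$d1)),
                       as.numeric(params$conv_c_w), dim(params$conv_c_w)[5],
                       1L, as.numeric(g_c1))
  grads$conv_c_w <- array(bw$grad_weights, dim(params$conv_c_w))
  grads$conv_c_b <- bw$grad_bias
  g_d1 <- relu_grad(cc$d1, array(bw$grad_input, dim(cc$d1)))
  bw <- cpp_conv3d_bwd(as.numeric(cc$a2), as.integer(dim(cc$a2)),
                       as.numeric(params$conv_down_w), dim(params$conv_down_w)[5],
                       2L, as.numeric(g_d1))
  grads$conv_down_w <- array(bw$grad_weights, dim(params$conv_down_w))
  grads$conv_down_b <- bw$grad_bias
  g_a2 <- relu_grad(cc$a2, g_a2 + array(bw$grad_input, dim(cc$a2)))
  bw <- cpp_conv3d_bwd(as.numeric(cc$a1), as.integer(dim(cc$a1)),
                       as.numeric(params$conv_b_w), dim(params$conv_b_w)[5],
                       1L, as.numeric(g_a2))
  grads$conv_b_w <- array(bw$grad_weights, dim(params$conv_b_w))
  grads$conv_b_b <- bw$grad_bias
  g_a1 <- relu_grad(cc$a1, array(bw$grad_input, dim(cc$a1)))
  bw <- cpp_conv3d_bwd(as.numeric(cc$x), as.integer(dim(cc$x)),
                       as.numeric(params$conv_a_w), dim(params$conv_a_w)[5],
                       1L, as.numeric(g_a1))
  grads$conv_a_w <- array(bw$grad_weights, dim(params$conv_a_w))
  grads$conv_a_b <- bw$grad_bias
  grads
}

# ---- flow field ------------------------------------------------------------

# normalize world coordinates to roughly [-1, 1] given the volume frame
normalize_coords <- function(vertices, frame) {
  sweep(vertices, 2, frame$center, "-") / frame$half_extent
}

volume_frame <- function(volume) {
  d <- dim(volume$data)[1:3]
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  w <- voxel_to_world(corners, volume$affine)
  center <- colMeans(apply(w, 2, range))
  list(center = center, half_extent = max(apply(w, 2, function(x) diff(range(x)))) / 2)
}

# neighbor aggregation commutes with the per-node linear map, so the mean
# is taken after the (cheap, BLAS) transform: M(x) W == M(x W)
gnn_layer_forward <- function(x, graph, w_self, w_nbr, b) {
  pre <- cpp_add_bias(x %*% w_self + neighbor_mean(x %*% w_nbr, graph), b)
  list(out = relu(pre), pre = pre, x = x)
}

gnn_layer_backward <- function(cache, g_out, graph, w_self, w_nbr) {
  g_pre <- relu_grad(cache$pre, g_out)
  mt_g <- neighbor_mean_t(g_pre, graph)
  list(g_w_self = crossprod(cache$x, g_pre),
       g_w_nbr = crossprod(cache$x, mt_g),
       g_b = colSums(g_pre),
       g_x = g_pre %*% t(w_self) + mt_g %*% t(w_nbr))
}

#' Velocity field at one integration state
#'
#' Samples the feature pyramid at the current vertex positions, assembles
#' the node input (image features, normalized coordinates, surface one-hot,
#' time, recurrent block features, static template features) and runs the
#' graph-convolution blocks; the zero-initialized linear head maps the
#' concatenated block features to per-vertex velocities.
#'
#' @param vertices `N x 3` current positions of all graph nodes (world mm).
#' @param features_prev `N x (graph_feature_dim * n_graph_blocks)` recurrent
#'   features from the previous step (zeros at `t = 0`).
#' @param pyramid a `feature_pyramid` from [encode_volume()].
#' @param graph a [build_graph()] result.
#' @param params parameter list.
#' @param config a [deform_config()].
#' @param t scalar time in `[0, 1]`.
#' @param static_features optional `N x D_f` template feature matrix.
#' @param keep_cache retain intermediates for the backward pass.
#' @return list with `velocity` (`N x 3`), `features` (per-block outputs,
#'   concatenated), and optional `cache`.
#' @export
flow_field <- function(vertices, features_prev, pyramid, graph, params, config,
                       t = 0, static_features = NULL, keep_cache = FALSE) {
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates in flow state")
  sampled <- lapply(seq_along(pyramid$levels), function(l) {
    s <- trilinear_sample(pyramid$levels[[l]], vertices)
    if (any(!is.finite(s))) stop("NaN in sampled features at level ", l)
    s
  })
  frame <- attr(pyramid, "frame")
  coords <- normalize_coords(vertices, frame)
  onehot <- cbind(as.numeric(graph$surface_id == 1L),
                  as.numeric(graph$surface_id == 2L))
  x <- do.call(cbind, c(sampled, list(coords, onehot,
                                      matrix(t, graph$n_nodes, 1),
                                      features_prev)))
  if (!is.null(static_features)) x <- cbind(x, static_features)
  block_caches <- vector("list", config$n_graph_blocks)
  block_outs <- vector("list", config$n_graph_blocks)
  h <- x
  for (b in seq_len(config$n_graph_blocks)) {
    l1 <- gnn_layer_forward(h, graph, params[[paste0("gnn", b, "_w_self")]],
                            params[[paste0("gnn", b, "_w_nbr")]],
                            params[[paste0("gnn", b, "_b1")]])
    l2 <- gnn_layer_forward(l1$out, graph, params[[paste0("gnn", b, "_w2_self")]],
                            params[[paste0("gnn", b, "_w2_nbr")]],
                            params[[paste0("gnn", b, "_b2")]])
    block_caches[[b]] <- list(l1 = l1, l2 = l2)
    block_outs[[b]] <- l2$out
    h <- l2$out
  }
  feats <- do.call(cbind, block_outs)
  velocity <- cpp_add_bias(feats %*% params$head_w, params$head_b)
  list(velocity = velocity, features = feats,
       cache = if (keep_cache) list(blocks = block_caches, feats = feats,
                                    n_image_feats = sum(vapply(sampled, ncol, 1L)),
                                    vertices = vertices) else NULL)
}

# backward through flow_field for one step: returns parameter gradient
# increments and the gradient on the sampled image features (per level)
flow_field_backward <- function(cache, g_velocity, graph, params, config, pyramid) {
  grads <- list()
  grads$head_w <- crossprod(cache$feats, g_velocity)
  grads$head_b <- colSums(g_velocity)
  g_feats <- g_velocity %*% t(params$head_w)
  gd <- config$graph_feature_dim
  g_block_out <- vector("list", config$n_graph_blocks)
  for (b in seq_len(config$n_graph_blocks))
    g_block_out[[b]] <- g_feats[, (b - 1) * gd + seq_len(gd), drop = FALSE]
  g_x <- NULL
  for (b in rev(seq_len(config$n_graph_blocks))) {
    g_out <- g_block_out[[b]]
    if (!is.null(g_x)) g_out <- g_out + g_x  # chained input of next block
    bc <- cache$blocks[[b]]
    bw2 <- gnn_layer_backward(bc$l2, g_out, graph,
                              params[[paste0("gnn", b, "_w2_self")]],
                              params[[paste0("gnn", b, "_w2_nbr")]])
    grads[[paste0("gnn", b, "_w2_self")]] <- bw2$g_w_self
    grads[[paste0("gnn", b, "_w2_nbr")]] <- bw2$g_w_nbr
    grads[[paste0("gnn", b, "_b2")]] <- bw2$g_b
    bw1 <- gnn_layer_backward(bc$l1, bw2$g_x, graph,
                              params[[paste0("gnn", b, "_w_self")]],
                              params[[paste0("gnn", b, "_w_nbr")]])
    grads[[paste0("gnn", b, "_w_self")]] <- bw1$g_w_self
    grads[[paste0("gnn", b, "_w_nbr")]] <- bw1$g_w_nbr
    grads[[paste0("gnn", b, "_b1")]] <- bw1$g_b
    g_x <- bw1$g_x
  }
  # g_input columns: [image feats | coords | one-hot | t | recurrent | static];
  # only the image-feature block is propagated further (into the encoder)
  list(grads = grads, g_input = g_x)
}

#' Integrate the deformation flow
#'
#' Explicit Euler scheme `V_{k+1} = V_k + h f(t_k, X, V_k)` with
#' `h = step_size` over `n_integration_steps` steps; the reconstruction is
#' `V(1)` with the template connectivity, together with the final per-block
#' vertex features (the "generalized vertices").
#'
#' @param white,pial input template meshes (population template in stage 1,
#'   within-subject template in stage 2).
#' @param volume the visit's [scalar_volume()].
#' @param params,config model parameters and [deform_config()].
#' @param graph optional prebuilt [build_graph()].
#' @param pyramid optional precomputed [encode_volume()] result.
#' @param static_features optional `N x D_f` template features (stage 2).
#' @param keep_cache retain per-step caches (training).
#' @param flow_override optional function `f(t, V)` returning `N x 3`
#'   velocities, integrated in place of the learned field (analytic
#'   stub for verifying the Euler scheme against closed forms).
#' @return list with deformed `white` and `pial` meshes, `features`
#'   (`N x (64 * n_blocks)`), and training caches when requested.
#' @export
integrate_flow <- function(white, pial, volume, params, config,
                           graph = NULL, pyramid = NULL,
                           static_features = NULL, keep_cache = FALSE,
                           flow_override = NULL) {
  if (is.null(graph)) graph <- build_graph(white, pial, config$virtual_edges)
  if (is.null(pyramid)) pyramid <- encode_volume(params, volume, config)
  if (is.null(attr(pyramid, "frame"))) attr(pyramid, "frame") <- volume_frame(volume)
  v <- rbind(white$vertices, pial$vertices)
  feats <- matrix(0, graph$n_nodes, config$graph_feature_dim * config$n_graph_blocks)
  h <- config$step_size
  frame <- attr(pyramid, "frame")
  diverge_r <- 10 * 2 * frame$half_extent
  caches <- if (keep_cache) vector("list", config$n_integration_steps) else NULL
  ff <- NULL
  for (k in seq_len(config$n_integration_steps)) {
    t_k <- (k - 1) * h
    if (is.null(flow_override)) {
      ff <- flow_field(v, feats, pyramid, graph, params, config, t = t_k,
                       static_features = static_features, keep_cache = keep_cache)
      v <- v + h * ff$velocity
      feats <- ff$features
    } else {
      v <- v + h * flow_override(t_k, v)
    }
    if (max(abs(sweep(v, 2, frame$center, "-"))) > diverge_r)
      stop(sprintf("flow diverged at step %d: vertex norm exceeds 10x grid diameter", k))
    if (keep_cache) caches[[k]] <- ff$cache
  }
  nv <- graph$n_per_surface
  list(white = triangle_mesh(v[seq_len(nv), , drop = FALSE], white$faces, validate = FALSE),
       pial = triangle_mesh(v[nv + seq_len(nv), , drop = FALSE], pial$faces, validate = FALSE),
       features = feats, graph = graph, pyramid = pyramid,
       caches = caches)
}

#' Read / write a model configuration as YAML
#'
#' @param config a [deform_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(deform_config, vals[names(vals) %in% names(formals(deform_config))])
}

# ---- checkpoints -----------------------------------------------------------

# stable fingerprint of mesh connectivity
faces_fingerprint <- function(faces) {
  f <- as.numeric(faces)
  sprintf("%dx3-%.0f-%.0f", nrow(faces), sum(f), sum(f * seq_along(f)) %% 1e9)
}

#' Save / load a model checkpoint
#'
#' Stores parameters, configuration and a fingerprint of the template
#' connectivity so that a checkpoint cannot silently be applied to a
#' different template.
#'
#' @param params,config model parameters and [deform_config()].
#' @param template_faces faces matrix of the template the model was trained
#'   on.
#' @param path file path (`.rds`).
#' @param extra optional named list stored verbatim (e.g. training log).
#' @export
save_checkpoint <- function(params, config, template_faces, path, extra = list()) {
  saveRDS(list(params = params, config = unclass(config),
               fingerprint = faces_fingerprint(template_faces),
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param template_faces_expected faces to verify against (NULL skips the
#'   check).
#' @export
load_checkpoint <- function(path, template_faces_expected = NULL) {
  ck <- readRDS(path)
  ck$config <- do.call(deform_config, ck$config[names(ck$config) %in%
    names(formals(deform_config))])
  if (!is.null(template_faces_expected) &&
      !identical(ck$fingerprint, faces_fingerprint(template_faces_expected)))
    stop("checkpoint/template fingerprint mismatch")
  ck
}
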