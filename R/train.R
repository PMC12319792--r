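# Training loop: Adam on the hand-written gradients of the combined loss.
# Backpropagation through the Euler flow is truncated step-wise: every
# integration step's velocity receives the upstream gradient h * dL/dV(1),
# and the coordinate/feature recurrence between steps is detached. Forward
# integration is exact Euler; the truncation only affects the direction of
# the training signal (a first-order approximation that keeps the cost of
# one iteration linear in the number of steps).

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr = 2e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# global-norm gradient clipping: rescale all gradients when their joint
# norm exceeds `max_norm` (guards against occasional loss spikes)
clip_grads <- function(grads, max_norm = 5) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# forward + backward + loss for one visit; returns loss, breakdown, grads
train_step <- function(scan, template_white, template_pial, params, config,
                       graph, weights, rng_seed, static_features = NULL) {
  pyramid <- encode_volume(params, scan$volume, config, keep_cache = TRUE)
  attr(pyramid, "frame") <- volume_frame(scan$volume)
  out <- integrate_flow(template_white, template_pial, scan$volume, params,
                        config, graph = graph, pyramid = pyramid,
                        static_features = static_features, keep_cache = TRUE)
  tl <- total_loss(out$white, out$pial, scan$ref_points_white,
                   scan$ref_points_pial, pyramid$seg_logits, scan$ref_labels,
                   weights, rng_seed = rng_seed, with_grad = TRUE)
  g_v1 <- rbind(tl$grad_white, tl$grad_pial)
  h <- config$step_size
  grads <- NULL
  c1 <- dim(pyramid$levels[[1]]$data)[4]
  c2 <- dim(pyramid$levels[[2]]$data)[4]
  g_f0 <- array(0, dim(pyramid$levels[[1]]$data))
  g_c1 <- array(0, dim(pyramid$levels[[2]]$data))
  for (k in seq_len(config$n_integration_steps)) {
    fb <- flow_field_backward(out$caches[[k]], h * g_v1, graph, params, config,
                              pyramid)
    grads <- add_grads(grads, fb$grads)
    gi <- fb$g_input
    vox1 <- world_to_voxel(out$caches[[k]]$vertices, pyramid$levels[[1]]$affine)
    vox2 <- world_to_voxel(out$caches[[k]]$vertices, pyramid$levels[[2]]$affine)
    g_f0 <- g_f0 + array(cpp_trilinear_adjoint(
      as.integer(dim(pyramid$levels[[1]]$data)), vox1,
      gi[, seq_len(c1), drop = FALSE]), dim(g_f0))
    g_c1 <- g_c1 + array(cpp_trilinear_adjoint(
      as.integer(dim(pyramid$levels[[2]]$data)), vox2,
      gi[, c1 + seq_len(c2), drop = FALSE]), dim(g_c1))
  }
  g_seg <- if (is.null(tl$grad_logits)) array(0, dim(pyramid$seg_logits))
  else tl$grad_logits
  enc_grads <- encode_volume_backward(params, pyramid, g_f0, g_c1, g_seg)
  grads <- add_grads(grads, enc_grads)
  list(loss = tl$loss, breakdown = tl$breakdown, grads = grads,
       pred_white = out$white, pred_pial = out$pial)
}

# quick validation ASSD (mean of white+pial over scans)
validation_assd <- function(scans, template_white, template_pial, params,
                            config, graph, subject_templates = NULL,
                            n = 4000, rng_seed = 7) {
  vals <- vapply(scans, function(scan) {
    st <- scan_template(scan, template_white, template_pial, subject_templates)
    out <- integrate_flow(st$white, st$pial, scan$volume, params, config,
                          graph = graph, static_features = st$features)
    (assd(out$white, scan$ref_white, n, rng_seed) +
       assd(out$pial, scan$ref_pial, n, rng_seed + 1L)) / 2
  }, numeric(1))
  mean(vals)
}

# resolve the input template of a scan (population in stage 1, the subject's
# feature-enriched template in stage 2)
scan_template <- function(scan, template_white, template_pial, subject_templates) {
  if (is.null(subject_templates))
    return(list(white = template_white, pial = template_pial, features = NULL))
  st <- subject_templates[[scan$subject_id]]
  if (is.null(st)) stop("missing within-subject template for subject: ",
                        scan$subject_id)
  nv <- nrow(template_white$vertices)
  list(white = triangle_mesh(st$white$coordinates, template_white$faces, validate = FALSE),
       pial = triangle_mesh(st$pial$coordinates, template_pial$faces, validate = FALSE),
       features = rbind(st$white$features, st$pial$features))
}

#' Train a deformation stage
#'
#' Optimizes the combined loss over the training scans with Adam; keeps the
#' parameters with the lowest validation ASSD when validation scans are
#' given, otherwise the final parameters.
#'
#' @param scans list of scan records: each a list with `volume`
#'   ([scalar_volume()]), `ref_white`, `ref_pial` (reference meshes),
#'   `subject_id`. Reference point sets and label volumes are derived here
#'   once per scan.
#' @param template_white,template_pial population template meshes.
#' @param config a [deform_config()] (stage 2: set `template_feature_dim`).
#' @param weights a [loss_weights()].
#' @param epochs passes over the scans.
#' @param lr Adam learning rate.
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 = none).
#' @param params_init optional initial parameters (stage 2 warm start from
#'   [init_stage2_from_stage1()]).
#' @param subject_templates stage 2: named list (by subject) of
#'   within-subject templates with `white`/`pial` [generalized_vertices()].
#' @param val_scans optional validation scan list (same record format).
#' @param rng_seed seed controlling shuffling and point sampling.
#' @param verbose print per-epoch losses.
#' @return list with `params`, `config`, and a training `log` data.frame.
#' @export
train_stage <- function(scans, template_white, template_pial, config,
                        weights = loss_weights(n_loss_points = 2000),
                        epochs = 8, lr = 2e-3, lr_decay = 1,
                        params_init = NULL,
                        subject_templates = NULL, val_scans = NULL,
                        rng_seed = 1, verbose = FALSE) {
  if (!is.null(subject_templates)) {
    missing_t <- setdiff(unique(vapply(scans, `[[`, "", "subject_id")),
                         names(subject_templates))
    if (length(missing_t))
      stop("missing within-subject template(s) for subject(s): ",
           paste(missing_t, collapse = ", "))
  }
  graph <- build_graph(template_white, template_pial, config$virtual_edges)
  params <- params_init %||% init_deform_params(config)
  scans <- prepare_scans(scans, weights, rng_seed)
  if (!is.null(val_scans)) val_scans <- prepare_scans(val_scans, weights, rng_seed + 500L)
  state <- adam_init(params)
  log <- list()
  best <- list(assd = Inf, params = params)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(rng_seed + ep, sample(seq_along(scans)))
    ep_loss <- 0
    bk <- NULL
    for (i in ord) {
      st <- scan_template(scans[[i]], template_white, template_pial, subject_templates)
      ts <- train_step(scans[[i]], st$white, st$pial, params, config, graph,
                       weights, rng_seed = rng_seed * 1000L + ep * 100L + i,
                       static_features = st$features)
      up <- adam_step(params, clip_grads(ts$grads), state,
                      lr * lr_decay^(ep - 1))
      params <- up$params
      state <- up$state
      ep_loss <- ep_loss + ts$loss
      bk <- if (is.null(bk)) ts$breakdown else bk + ts$breakdown
    }
    va <- NA_real_
    if (!is.null(val_scans)) {
      va <- validation_assd(val_scans, template_white, template_pial, params,
                            config, graph, subject_templates)
      if (va < best$assd) best <- list(assd = va, params = params)
    }
    log[[ep]] <- data.frame(epoch = ep, loss = ep_loss / length(scans),
                            val_assd = va,
                            t(bk / length(scans)))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val ASSD %.3f", ep,
                      ep_loss / length(scans), va))
  }
  final_params <- if (is.finite(best$assd)) best$params else params
  list(params = final_params, config = config, log = do.call(rbind, log))
}

# attach reference point sets (with curvature weights) and label volumes
prepare_scans <- function(scans, weights, rng_seed) {
  n_pts <- weights$n_loss_points
  lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    if (is.null(s$ref_points_white))
      s$ref_points_white <- reference_point_set(s$ref_white, n_pts, rng_seed + 2L * i)
    if (is.null(s$ref_points_pial))
      s$ref_points_pial <- reference_point_set(s$ref_pial, n_pts, rng_seed + 2L * i + 1L)
    if (is.null(s$ref_labels) && weights$w_voxel > 0)
      s$ref_labels <- rasterize_occupancy(s$ref_white, s$ref_pial,
                                          dim(s$volume$data), s$volume$affine)
    s
  })
}
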