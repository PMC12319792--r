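# Training losses: curvature-weighted symmetric Chamfer on sampled point
# sets, edge-length and normal-consistency mesh regularizers, and the voxel
# cross-entropy on the auxiliary segmentation head. Each term also exposes
# its gradient with respect to the predicted vertices (mesh terms) or the
# logits (voxel term) for the hand-written training loop.

#' Loss weights
#'
#' @param w_chamfer,w_edge,w_normal,w_voxel nonnegative term weights.
#' @param n_loss_points points sampled per surface for the Chamfer term.
#' @export
loss_weights <- function(w_chamfer = 1, w_edge = 0.1, w_normal = 0.1,
                         w_voxel = 1, n_loss_points = 100000) {
  if (any(c(w_chamfer, w_edge, w_normal, w_voxel) < 0))
    stop("loss weights must be nonnegative")
  list(w_chamfer = w_chamfer, w_edge = w_edge, w_normal = w_normal,
       w_voxel = w_voxel, n_loss_points = as.integer(n_loss_points))
}

#' Curvature weights for reference points
#'
#' Samples `n` points from a reference mesh and attaches the weight
#' `1 + |kappa| / mean(|kappa|)` interpolated barycentrically from the
#' vertex mean curvature, so high-curvature (tightly folded) regions count
#' more in the Chamfer target. On a constant-curvature reference the weights
#' are uniform and the loss reduces to the plain symmetric Chamfer.
#'
#' @param ref_mesh reference [triangle_mesh()].
#' @param n number of points.
#' @param rng_seed sampling seed.
#' @return `n x 3` point matrix with a `weights` attribute.
#' @export
reference_point_set <- function(ref_mesh, n, rng_seed = NULL) {
  pts <- sample_surface_points(ref_mesh, n, rng_seed)
  kappa <- abs(mean_curvature(ref_mesh)$values)
  mk <- mean(kappa)
  wv <- if (mk > 0) 1 + kappa / mk else rep(1, length(kappa))
  fi <- attr(pts, "face_index")
  bc <- attr(pts, "barycentric")
  f <- ref_mesh$faces[fi, , drop = FALSE]
  w <- wv[f[, 1]] * bc[, 1] + wv[f[, 2]] * bc[, 2] + wv[f[, 3]] * bc[, 3]
  attr(pts, "weights") <- w
  pts
}

#' Curvature-weighted symmetric Chamfer loss
#'
#' Mean squared nearest-neighbor distance from sampled predicted points to
#' the reference points plus the reverse direction, where each reference
#' point's contribution is scaled by its curvature-derived weight
#' (normalized to mean 1). Differentiable in the predicted vertices.
#'
#' @param pred predicted [triangle_mesh()].
#' @param ref_points `n x 3` reference point matrix.
#' @param ref_weights per-reference-point nonnegative weights (default
#'   uniform).
#' @param n_points number of points sampled from the predicted mesh.
#' @param rng_seed sampling seed.
#' @param with_grad also return the gradient with respect to `pred` vertices.
#' @return scalar loss (list with `loss` and `grad_vertices` when
#'   `with_grad`).
#' @export
curvature_weighted_chamfer <- function(pred, ref_points, ref_weights = NULL,
                                       n_points = nrow(ref_points),
                                       rng_seed = NULL, with_grad = FALSE) {
  ref_points <- matrix(as.numeric(ref_points), ncol = 3)
  n_ref <- nrow(ref_points)
  if (n_ref < 1) stop("need at least one reference point")
  if (is.null(ref_weights)) ref_weights <- attr(ref_points, "weights") %||% rep(1, n_ref)
  if (any(ref_weights < 0)) stop("reference weights must be nonnegative")
  w <- ref_weights / mean(ref_weights)
  pp <- sample_surface_points(pred, n_points, rng_seed)
  fi <- attr(pp, "face_index"); bc <- attr(pp, "barycentric")
  fwd <- cpp_nn(pp, ref_points)           # pred -> ref
  bwd <- cpp_nn(ref_points, pp)           # ref -> pred
  loss_fwd <- mean(fwd$distance^2)
  loss_bwd <- mean(w * bwd$distance^2)
  loss <- loss_fwd + loss_bwd
  if (!with_grad) return(loss)
  np <- nrow(pp)
  # d/dp of mean ||p - q||^2 terms; both directions land on predicted points
  g_pts <- 2 * (pp - ref_points[fwd$index, , drop = FALSE]) / np
  g_bwd <- -2 * (ref_points - pp[bwd$index, , drop = FALSE]) * (w / n_ref)
  g_pts_b <- accum_index(bwd$index, g_bwd, np)
  g_pts <- g_pts + g_pts_b
  # chain through barycentric sampling onto the vertices
  f <- pred$faces[fi, , drop = FALSE]
  nv <- nrow(pred$vertices)
  gv <- accum_index(f[, 1], g_pts * bc[, 1], nv) +
    accum_index(f[, 2], g_pts * bc[, 2], nv) +
    accum_index(f[, 3], g_pts * bc[, 3], nv)
  list(loss = loss, grad_vertices = gv)
}

#' Edge-length loss
#'
#' Mean squared edge length over the mesh edge set; regularizes toward
#' short, uniform edges.
#'
#' @param mesh a [triangle_mesh()].
#' @param with_grad also return the vertex gradient.
#' @export
edge_loss <- function(mesh, with_grad = FALSE) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  l2 <- rowSums(d^2)
  loss <- mean(l2)
  if (!with_grad) return(loss)
  nv <- nrow(mesh$vertices)
  g <- 2 * d / nrow(e)
  gv <- accum_index(e[, 1], g, nv) - accum_index(e[, 2], g, nv)
  list(loss = loss, grad_vertices = gv)
}

# adjacency of face pairs sharing an edge (closed manifold: one pair per edge)
face_pairs <- function(mesh) {
  conn_cached(mesh$faces, "fpairs", function(f) {
    nv <- max(f)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
    fid <- rep(seq_len(nrow(f)), 3)
    o <- order(key)
    key <- key[o]; fid <- fid[o]
    same <- key[-1] == key[-length(key)]
    cbind(fid[c(same, FALSE)], fid[c(FALSE, same)])
  })
}

#' Normal-consistency loss
#'
#' Mean over adjacent face pairs of `1 - cos(angle between face normals)`;
#' zero on planar patches, decreasing under refinement of a smooth surface.
#'
#' @inheritParams edge_loss
#' @export
normal_consistency_loss <- function(mesh, with_grad = FALSE) {
  fp <- face_pairs(mesh)
  fn <- face_normals(mesh)
  na <- fn$normals[fp[, 1], , drop = FALSE]
  nb <- fn$normals[fp[, 2], , drop = FALSE]
  loss <- mean(1 - rowSums(na * nb))
  if (!with_grad) return(loss)
  npair <- nrow(fp)
  # accumulate dL/dn per face
  g_n <- accum_index(fp[, 1], -nb / npair, nrow(mesh$faces)) +
    accum_index(fp[, 2], -na / npair, nrow(mesh$faces))
  # through the normalization n = N / |N|
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  crossm <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nvec <- crossm(e1, e2)
  len <- pmax(sqrt(rowSums(nvec^2)), .Machine$double.eps)
  nhat <- nvec / len
  g_nvec <- (g_n - nhat * rowSums(g_n * nhat)) / len
  g_v1 <- crossm(e2, g_nvec)
  g_v2 <- crossm(g_nvec, e1)
  g_v0 <- -(g_v1 + g_v2)
  nv <- nrow(v)
  gv <- accum_index(f[, 1], g_v0, nv) + accum_index(f[, 2], g_v1, nv) +
    accum_index(f[, 3], g_v2, nv)
  list(loss = loss, grad_vertices = gv)
}

#' Voxel cross-entropy loss
#'
#' Mean multiclass cross-entropy of the segmentation logits against a
#' reference label volume (0 background, 1 gray, 2 white).
#'
#' @param logits `H x W x D x 3` array of class scores.
#' @param labels integer array/[scalar_volume()] of reference labels.
#' @param with_grad also return the gradient on the logits.
#' @export
voxel_cross_entropy <- function(logits, labels, with_grad = FALSE) {
  if (inherits(labels, "scalar_volume")) labels <- labels$data
  d <- dim(logits)
  nvox <- prod(d[1:3])
  z <- matrix(logits, nvox, d[4])
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  lab <- as.integer(labels) + 1L
  ll <- -log(pmax(p[cbind(seq_len(nvox), lab)], 1e-300))
  loss <- mean(ll)
  if (!with_grad) return(loss)
  onehot <- matrix(0, nvox, d[4])
  onehot[cbind(seq_len(nvox), lab)] <- 1
  list(loss = loss, grad_logits = array((p - onehot) / nvox, d))
}

#' Combined training loss for one visit
#'
#' Weighted sum of the four terms over both surfaces, with a per-term
#' breakdown.
#'
#' @param pred_white,pred_pial predicted meshes (`V(1)`).
#' @param ref_points_white,ref_points_pial reference point sets from
#'   [reference_point_set()] (weights attached).
#' @param seg_logits encoder segmentation logits.
#' @param ref_labels reference label volume.
#' @param weights a [loss_weights()] list.
#' @param rng_seed sampling seed for the Chamfer term.
#' @param with_grad also return vertex / logit gradients.
#' @return list with `loss`, `breakdown`, and gradients when requested.
#' @export
total_loss <- function(pred_white, pred_pial, ref_points_white, ref_points_pial,
                       seg_logits = NULL, ref_labels = NULL,
                       weights = loss_weights(), rng_seed = NULL,
                       with_grad = FALSE) {
  n_pts <- min(weights$n_loss_points, nrow(ref_points_white))
  eval_surface <- function(pred, ref_pts, seed_off) {
    out <- list(breakdown = c(), grad = NULL)
    gv <- matrix(0, nrow(pred$vertices), 3)
    ch <- ed <- no <- 0
    if (weights$w_chamfer > 0) {
      r <- curvature_weighted_chamfer(pred, ref_pts, attr(ref_pts, "weights"),
                                      n_points = n_pts,
                                      rng_seed = if (is.null(rng_seed)) NULL else rng_seed + seed_off,
                                      with_grad = with_grad)
      if (with_grad) { ch <- r$loss; gv <- gv + weights$w_chamfer * r$grad_vertices }
      else ch <- r
    }
    if (weights$w_edge > 0) {
      r <- edge_loss(pred, with_grad)
      if (with_grad) { ed <- r$loss; gv <- gv + weights$w_edge * r$grad_vertices }
      else ed <- r
    }
    if (weights$w_normal > 0) {
      r <- normal_consistency_loss(pred, with_grad)
      if (with_grad) { no <- r$loss; gv <- gv + weights$w_normal * r$grad_vertices }
      else no <- r
    }
    list(breakdown = c(chamfer = ch, edge = ed, normal = no), grad = gv)
  }
  sw <- eval_surface(pred_white, ref_points_white, 101L)
  sp <- eval_surface(pred_pial, ref_points_pial, 202L)
  vx <- 0; g_logits <- NULL
  if (weights$w_voxel > 0 && !is.null(seg_logits) && !is.null(ref_labels)) {
    r <- voxel_cross_entropy(seg_logits, ref_labels, with_grad)
    if (with_grad) { vx <- r$loss; g_logits <- weights$w_voxel * r$grad_logits }
    else vx <- r
  }
  breakdown <- c(chamfer_white = unname(sw$breakdown["chamfer"]),
                 chamfer_pial = unname(sp$breakdown["chamfer"]),
                 edge_white = unname(sw$breakdown["edge"]),
                 edge_pial = unname(sp$breakdown["edge"]),
                 normal_white = unname(sw$breakdown["normal"]),
                 normal_pial = unname(sp$breakdown["normal"]),
                 voxel = vx)
  loss <- weights$w_chamfer * (breakdown[["chamfer_white"]] + breakdown[["chamfer_pial"]]) +
    weights$w_edge * (breakdown[["edge_white"]] + breakdown[["edge_pial"]]) +
    weights$w_normal * (breakdown[["normal_white"]] + breakdown[["normal_pial"]]) +
    weights$w_voxel * vx
  out <- list(loss = loss, breakdown = breakdown)
  if (with_grad) {
    out$grad_white <- sw$grad
    out$grad_pial <- sp$grad
    out$grad_logits <- g_logits
  }
  out
}
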