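# Surface-quality metrics (ASSD, percentile Hausdorff, self-intersecting
# face fraction) and longitudinal-consistency metrics (mean-curvature
# variance, cortical-thickness variance, parcellation F1).

#' Average symmetric surface distance (ASSD)
#'
#' Points are sampled uniformly by area from both meshes; the metric is the
#' mean of all point-to-surface distances in both directions, in mm.
#'
#' @param pred,ref [triangle_mesh()] objects.
#' @param n points sampled per mesh.
#' @param rng_seed sampling seed.
#' @return scalar distance (mm).
#' @export
assd <- function(pred, ref, n = 100000, rng_seed = NULL) {
  if (nrow(pred$faces) == 0 || nrow(ref$faces) == 0) stop("empty mesh")
  # both meshes draw from the same seed so the metric is exactly symmetric
  p_pred <- sample_surface_points(pred, n, rng_seed)
  p_ref <- sample_surface_points(ref, n, rng_seed)
  d1 <- point_to_mesh_distance(p_pred, ref)
  d2 <- point_to_mesh_distance(p_ref, pred)
  (sum(d1) + sum(d2)) / (length(d1) + length(d2))
}

#' Percentile (robust) Hausdorff distance
#'
#' The maximum over both directions of the X-th percentile of the
#' point-to-surface distance distribution (type-7 linear-interpolation
#' quantile); `x = 100` is the standard symmetric Hausdorff distance of the
#' sampled point sets.
#'
#' @inheritParams assd
#' @param x percentile in `(0, 100]`.
#' @export
hdx <- function(pred, ref, x = 90, n = 100000, rng_seed = NULL) {
  if (x <= 0 || x > 100) stop("percentile must lie in (0, 100]")
  d1 <- point_to_mesh_distance(sample_surface_points(pred, n, rng_seed), ref)
  d2 <- point_to_mesh_distance(sample_surface_points(ref, n, rng_seed), pred)
  percentile_hd(d1, d2, x)
}

#' Percentile rule of the robust Hausdorff distance
#'
#' Max over both directions of the type-7 (linear interpolation) empirical
#' quantile of the directed distance samples; exposed so reported values
#' are reproducible bit for bit.
#'
#' @param d1,d2 directed point-to-surface distance samples.
#' @param x percentile in `(0, 100]`.
#' @export
percentile_hd <- function(d1, d2, x) {
  max(quantile(d1, x / 100, type = 7, names = FALSE),
      quantile(d2, x / 100, type = 7, names = FALSE))
}

#' Self-intersecting face fraction (SIF)
#'
#' Fraction of faces with a proper geometric intersection against any
#' non-adjacent face of the same mesh (faces sharing a vertex are never
#' counted, which excludes the shared-edge contact of neighboring faces).
#'
#' @param mesh a [triangle_mesh()].
#' @return fraction in `[0, 1]`.
#' @export
self_intersection_fraction <- function(mesh) {
  hit <- cpp_self_intersections(mesh$vertices, mesh$faces - 1L)
  mean(hit)
}

#' Bilateral cortical thickness
#'
#' Per corresponding vertex pair: the average of the shortest distance from
#' the white vertex to the pial surface and from the pial vertex to the
#' white surface.
#'
#' @param white,pial meshes with equal vertex count and shared vertex order.
#' @return a [vertex_scalar_field()] named `"thickness"` (mm).
#' @export
cortical_thickness <- function(white, pial) {
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("white and pial meshes must share the vertex order")
  d_wp <- point_to_mesh_distance(white$vertices, pial)
  d_pw <- point_to_mesh_distance(pial$vertices, white)
  vertex_scalar_field((d_wp + d_pw) / 2, "thickness")
}

#' Across-visit per-vertex variance with subject-level median
#'
#' Unbiased sample variance of a per-vertex descriptor over the visits of
#' one subject (requires at least two visits), plus the robust subject
#' score: the median of the per-vertex variances. Used with `|kappa|` for
#' the mean-curvature variance (MCVar) and with cortical thickness for
#' CThVar.
#'
#' @param fields list of [vertex_scalar_field()] or numeric vectors, one per
#'   visit, equal lengths.
#' @return list with `per_vertex` variances and `subject_median`.
#' @export
longitudinal_variance <- function(fields) {
  vals <- lapply(fields, function(f) if (inherits(f, "vertex_scalar_field")) f$values else f)
  if (length(vals) < 2)
    stop("longitudinal variance is undefined for a single visit")
  nv <- length(vals[[1]])
  if (any(vapply(vals, length, 1L) != nv)) stop("field lengths differ across visits")
  m <- do.call(cbind, vals)
  v <- apply(m, 1, var)  # unbiased: divides by K_i
  list(per_vertex = v, subject_median = median(v))
}

#' Mean-curvature variance of a surface sequence
#'
#' `|kappa|` is used internally so the result is invariant to the sign
#' convention of the curvature estimator.
#'
#' @param sequence a [surface_sequence()] with >= 2 visits.
#' @return subject-level median MCVar (with per-vertex values attached).
#' @export
mcvar <- function(sequence) {
  ks <- lapply(sequence$meshes, function(m) abs(mean_curvature(m)$values))
  lv <- longitudinal_variance(ks)
  structure(lv$subject_median, per_vertex = lv$per_vertex)
}

#' Cortical-thickness variance across visits
#'
#' @param white_seq,pial_seq [surface_sequence()] objects of the two surface
#'   classes, same visits.
#' @return subject-level median CThVar (per-vertex values attached).
#' @export
cthvar <- function(white_seq, pial_seq) {
  if (length(white_seq$meshes) != length(pial_seq$meshes))
    stop("white and pial sequences must have the same number of visits")
  ths <- mapply(function(w, p) cortical_thickness(w, p)$values,
                white_seq$meshes, pial_seq$meshes, SIMPLIFY = FALSE)
  lv <- longitudinal_variance(ths)
  structure(lv$subject_median, per_vertex = lv$per_vertex)
}

#' Longitudinal parcellation consistency (ParcF1)
#'
#' Atlas labels live on the template and propagate to every visit by vertex
#' identity. For every ordered visit pair `(j, k)`, each vertex of visit `j`
#' is matched to the spatially nearest vertex of visit `k`; the per-class F1
#' of `(label(v), label(NN(v)))` is weighted by class support and averaged
#' over all ordered pairs.
#'
#' @param sequence a [surface_sequence()] with >= 2 visits.
#' @param labels integer [vertex_scalar_field()] (or vector) on the template
#'   vertex order.
#' @return score in `[0, 1]`.
#' @export
parc_f1 <- function(sequence, labels) {
  if (length(sequence$meshes) < 2)
    stop("parcellation consistency needs at least two visits")
  lab <- if (inherits(labels, "vertex_scalar_field")) labels$values else labels
  lab <- as.integer(lab)
  nv <- nrow(sequence$meshes[[1]]$vertices)
  if (length(lab) != nv) stop("label field length does not match the meshes")
  k <- length(sequence$meshes)
  scores <- c()
  for (j in seq_len(k)) for (kk in seq_len(k)) {
    if (j == kk) next
    nn <- cpp_nn(sequence$meshes[[j]]$vertices, sequence$meshes[[kk]]$vertices)
    scores <- c(scores, weighted_f1(lab, lab[nn$index]))
  }
  mean(scores)
}

# support-weighted multiclass F1 of (truth, prediction)
weighted_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  n <- length(truth)
  f1s <- vapply(classes, function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    if (2 * tp + fp + fn == 0) return(1)  # absent class, vacuously consistent
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(classes, function(c) sum(truth == c), numeric(1))
  sum(f1s * support) / sum(support)
}

#' Metric report for a reconstructed cohort
#'
#' Per-scan surface quality (ASSD, HD90, HD99, SIF against references, when
#' given) and per-subject longitudinal consistency (MCVar per surface,
#' CThVar, ParcF1 per surface).
#'
#' @param recon named list per subject: list with `white`, `pial`
#'   [surface_sequence()] objects.
#' @param refs optional matching list of reference sequences.
#' @param labels optional parcellation labels on the template.
#' @param n_points sample count for distance metrics.
#' @param rng_seed seed.
#' @return list of data.frames `per_scan` and `per_subject`.
#' @export
metric_report <- function(recon, refs = NULL, labels = NULL,
                          n_points = 25000, rng_seed = 1) {
  per_scan <- list()
  per_subject <- list()
  for (sid in names(recon)) {
    rw <- recon[[sid]]$white; rp <- recon[[sid]]$pial
    kv <- length(rw$meshes)
    for (j in seq_len(kv)) {
      row <- data.frame(subject = sid, visit = j,
                        sif_white = self_intersection_fraction(rw$meshes[[j]]),
                        sif_pial = self_intersection_fraction(rp$meshes[[j]]))
      if (!is.null(refs)) {
        row$assd_white <- assd(rw$meshes[[j]], refs[[sid]]$white$meshes[[j]],
                               n_points, rng_seed)
        row$assd_pial <- assd(rp$meshes[[j]], refs[[sid]]$pial$meshes[[j]],
                              n_points, rng_seed + 1L)
        row$hd90_white <- hdx(rw$meshes[[j]], refs[[sid]]$white$meshes[[j]], 90,
                              n_points, rng_seed)
        row$hd90_pial <- hdx(rp$meshes[[j]], refs[[sid]]$pial$meshes[[j]], 90,
                             n_points, rng_seed + 1L)
      }
      per_scan[[length(per_scan) + 1]] <- row
    }
    srow <- data.frame(subject = sid, n_visits = kv,
                       mcvar_white = NA_real_, mcvar_pial = NA_real_,
                       cthvar = NA_real_, parcf1_white = NA_real_,
                       parcf1_pial = NA_real_)
    if (kv >= 2) {
      srow$mcvar_white <- as.numeric(mcvar(rw))
      srow$mcvar_pial <- as.numeric(mcvar(rp))
      srow$cthvar <- as.numeric(cthvar(rw, rp))
      if (!is.null(labels)) {
        srow$parcf1_white <- parc_f1(rw, labels)
        srow$parcf1_pial <- parc_f1(rp, labels)
      }
    }
    per_subject[[length(per_subject) + 1]] <- srow
  }
  list(per_scan = do.call(rbind, per_scan),
       per_subject = do.call(rbind, per_subject),
       meta = list(n_points = n_points, rng_seed = rng_seed))
}
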