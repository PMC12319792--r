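# Orchestration of the two-stage longitudinal procedure: stage-1 training /
# inference from the population template, mesh-space within-subject template
# aggregation (with feature enrichment), stage-2 training / inference from
# the subject templates.

#' Stage-1 inference and within-subject template aggregation
#'
#' Runs the stage-1 model on every visit of every subject (deforming the
#' population template), then averages each subject's generalized vertices
#' (coordinates and the final per-block GNN features) into a within-subject
#' template. A single-visit subject's template is its stage-1
#' reconstruction.
#'
#' @param params,config trained stage-1 parameters and [deform_config()].
#' @param subjects list; each element needs `subject_id` and a list
#'   `volume` of per-visit [scalar_volume()] objects.
#' @param template_white,template_pial population template meshes.
#' @param aggregation `"mean"` (default) or `"median"`.
#' @return named list (by subject) with `white` / `pial`
#'   [generalized_vertices()] templates and the stage-1 per-visit meshes.
#' @export
run_stage1_and_aggregate <- function(params, config, subjects,
                                     template_white, template_pial,
                                     aggregation = "mean") {
  graph <- build_graph(template_white, template_pial, config$virtual_edges)
  nv <- nrow(template_white$vertices)
  out <- list()
  for (s in subjects) {
    gw <- list(); gp <- list(); mw <- list(); mp <- list()
    for (j in seq_along(s$volume)) {
      r <- integrate_flow(template_white, template_pial, s$volume[[j]],
                          params, config, graph = graph)
      gw[[j]] <- generalized_vertices(r$white$vertices,
                                      r$features[seq_len(nv), , drop = FALSE])
      gp[[j]] <- generalized_vertices(r$pial$vertices,
                                      r$features[nv + seq_len(nv), , drop = FALSE])
      mw[[j]] <- r$white; mp[[j]] <- r$pial
    }
    out[[s$subject_id]] <- list(
      white = aggregate_template(gw, aggregation),
      pial = aggregate_template(gp, aggregation),
      stage1_white = surface_sequence(s$subject_id, mw, "white"),
      stage1_pial = surface_sequence(s$subject_id, mp, "pial"))
  }
  out
}

#' Reconstruct a subject sequence with the full two-stage model
#'
#' Stage 1 deforms the population template to every visit; the visits are
#' aggregated into a feature-enriched within-subject template; stage 2
#' deforms that template to every visit again. All outputs share the
#' population template connectivity, across visits and subjects.
#'
#' @param stage1,stage2 lists with `params` and `config` (as returned by
#'   [train_stage()] or [load_checkpoint()]).
#' @param subjects as in [run_stage1_and_aggregate()].
#' @param template_white,template_pial population templates.
#' @param aggregation template aggregation method.
#' @return named list per subject: `white` / `pial` stage-2
#'   [surface_sequence()]s, the `template` pair, and the stage-1 sequences.
#' @export
reconstruct <- function(stage1, stage2, subjects, template_white,
                        template_pial, aggregation = "mean") {
  templates <- run_stage1_and_aggregate(stage1$params, stage1$config, subjects,
                                        template_white, template_pial,
                                        aggregation)
  graph <- build_graph(template_white, template_pial,
                       stage2$config$virtual_edges)
  out <- list()
  for (s in subjects) {
    st <- templates[[s$subject_id]]
    tw <- triangle_mesh(st$white$coordinates, template_white$faces, validate = FALSE)
    tp <- triangle_mesh(st$pial$coordinates, template_pial$faces, validate = FALSE)
    feats <- rbind(st$white$features, st$pial$features)
    if (ncol(feats) != stage2$config$template_feature_dim)
      stop("stage-2 config expects template_feature_dim = ", ncol(feats))
    mw <- list(); mp <- list()
    for (j in seq_along(s$volume)) {
      r <- integrate_flow(tw, tp, s$volume[[j]], stage2$params, stage2$config,
                          graph = graph, static_features = feats)
      mw[[j]] <- r$white; mp[[j]] <- r$pial
    }
    out[[s$subject_id]] <- list(
      white = surface_sequence(s$subject_id, mw, "white"),
      pial = surface_sequence(s$subject_id, mp, "pial"),
      template = st,
      stage1_white = st$stage1_white, stage1_pial = st$stage1_pial)
  }
  out
}

#' Train the full two-stage pipeline on a synthetic cohort
#'
#' Convenience wrapper used by the examples and the acceptance script:
#' trains stage 1 on the training subjects, builds within-subject templates,
#' warm-starts and trains stage 2 on the same scans, and returns both
#' checkpoints.
#'
#' @param cohort a [generate_cohort()] result.
#' @param train_idx,val_idx subject indices used for training / validation.
#' @param config a [deform_config()] (stage 1; stage 2 derives from it).
#' @param weights a [loss_weights()].
#' @param epochs_stage1,epochs_stage2 training epochs per stage.
#' @param lr Adam learning rate.
#' @param lr_decay per-epoch learning-rate decay factor.
#' @param rng_seed seed.
#' @param verbose print progress.
#' @return list with `stage1`, `stage2` (params + config) and the
#'   within-subject `templates` of the training subjects.
#' @export
train_pipeline <- function(cohort, train_idx, val_idx = NULL,
                           config = deform_config(),
                           weights = loss_weights(n_loss_points = 2000),
                           epochs_stage1 = 8, epochs_stage2 = 6, lr = 2e-3,
                           lr_decay = 1, rng_seed = 1, verbose = FALSE) {
  scans_of <- function(idx) {
    out <- list()
    for (i in idx) {
      s <- cohort$subjects[[i]]
      for (j in seq_along(s$volume))
        out[[length(out) + 1]] <- list(subject_id = s$subject_id,
                                       visit = j, volume = s$volume[[j]],
                                       ref_white = s$white[[j]],
                                       ref_pial = s$pial[[j]])
    }
    out
  }
  tw <- cohort$template_white; tp <- cohort$template_pial
  stage1 <- train_stage(scans_of(train_idx), tw, tp, config, weights,
                        epochs = epochs_stage1, lr = lr, lr_decay = lr_decay,
                        val_scans = if (length(val_idx)) scans_of(val_idx),
                        rng_seed = rng_seed, verbose = verbose)
  templates <- run_stage1_and_aggregate(stage1$params, stage1$config,
                                        cohort$subjects[c(train_idx, val_idx)],
                                        tw, tp)
  cfg2 <- deform_config(
    encoder_channels = config$encoder_channels,
    n_graph_blocks = config$n_graph_blocks,
    graph_feature_dim = config$graph_feature_dim,
    n_integration_steps = config$n_integration_steps,
    step_size = config$step_size,
    virtual_edges = config$virtual_edges,
    template_feature_dim = config$graph_feature_dim * config$n_graph_blocks,
    rng_seed = config$rng_seed + 1L)
  params2 <- init_stage2_from_stage1(stage1$params, cfg2)
  stage2 <- train_stage(scans_of(train_idx), tw, tp, cfg2, weights,
                        epochs = epochs_stage2, lr = lr, lr_decay = lr_decay,
                        params_init = params2,
                        subject_templates = templates,
                        val_scans = if (length(val_idx)) scans_of(val_idx),
                        rng_seed = rng_seed + 1L, verbose = verbose)
  list(stage1 = stage1, stage2 = stage2, templates = templates)
}
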