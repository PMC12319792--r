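# Synthetic longitudinal cohort: nested "cortex-like" white/pial surface
# pairs with known vertex correspondence across visits, controllable
# atrophy trajectories, a parcellation, covariates, and rasterized noisy
# volumes. The generator gives the package a fully self-contained
# end-to-end benchmark: training, template aggregation, metrics and group
# analysis all run on it without any download.

# real spherical harmonics basis up to l = 3 at unit directions (n x 16)
sh_basis <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(
    1,                                   # l=0
    y, z, x,                             # l=1
    x * y, y * z, 3 * z^2 - 1, x * z, x^2 - y^2,                       # l=2
    y * (3 * x^2 - y^2), x * y * z, y * (5 * z^2 - 1), z * (5 * z^2 - 3),
    x * (5 * z^2 - 1), z * (x^2 - y^2), x * (x^2 - 3 * y^2))           # l=3
}

# per-degree decay so low-order shape dominates
sh_scale <- c(0, rep(1, 3), rep(1 / 2, 5), rep(1 / 3, 7))

#' Synthetic cohort configuration
#'
#' The defaults define the study conditions of the synthetic benchmark:
#' visit counts follow the truncated-normal analogue of a typical
#' longitudinal aging cohort (mean 4.4, SD 1.9 visits, at least 2), the
#' cortical ribbon is 2.5 mm thick on a smoothly bumpy sphere filling about
#' 60% of the grid, the diseased group thins at 0.10 mm/yr against
#' 0.01 mm/yr for controls, and volumes are piecewise-constant occupancy
#' images (CSF 0, gray 0.5, white 1) with Gaussian noise.
#'
#' @param n_subjects number of subjects.
#' @param visits_mean,visits_sd,visits_min,visits_max truncated-normal visit
#'   count per subject.
#' @param grid_shape volume grid (voxels are 1 mm, world = voxel frame).
#' @param mesh_subdivisions icosphere level of the ground-truth surfaces.
#' @param outer_radius_frac outer sphere radius as a fraction of grid size.
#' @param bump_amplitude SD (mm) of the spherical-harmonic radial bumps that
#'   individualize the outer shape.
#' @param thickness_mean,thickness_spatial_sd mean cortical thickness (mm)
#'   and SD of its smooth spatial variation.
#' @param drift_sd SD (mm) of the per-visit smooth radial drift
#'   (diagnosis-independent; emulates positioning/scan variability).
#' @param atrophy_rate named thickness-loss rates (mm per year) per
#'   diagnosis group.
#' @param group_proportions named sampling proportions of the groups.
#' @param noise_sd Gaussian intensity noise SD.
#' @param baseline_age_range years; sampled uniformly.
#' @param visit_spacing_range years between consecutive visits (uniform).
#' @param n_regions parcellation regions on the template.
#' @param rng_seed master seed; every subject derives its own stream.
#' @export
synthetic_cohort_config <- function(n_subjects = 20,
                                    visits_mean = 4.4, visits_sd = 1.9,
                                    visits_min = 2, visits_max = 8,
                                    grid_shape = c(48, 48, 48),
                                    mesh_subdivisions = 3,
                                    outer_radius_frac = 0.30,
                                    bump_amplitude = 0.8,
                                    thickness_mean = 2.5,
                                    thickness_spatial_sd = 0.25,
                                    drift_sd = 0.1,
                                    atrophy_rate = c(control = 0.01, ad = 0.10),
                                    group_proportions = c(control = 0.5, ad = 0.5),
                                    noise_sd = 0.1,
                                    baseline_age_range = c(60, 85),
                                    visit_spacing_range = c(0.5, 1.5),
                                    n_regions = 8,
                                    rng_seed = 1) {
  stopifnot(all(is.finite(atrophy_rate)), length(grid_shape) == 3)
  as.list(environment())
}

# derive a deterministic 31-bit per-subject seed from the master seed
subject_seed <- function(rng_seed, idx) {
  as.integer((as.numeric(rng_seed) * 10007 + idx * 7919) %% 2147483647)
}

#' Generate one synthetic longitudinal subject
#'
#' The outer (pial-like) base shape is a sphere with smooth random radial
#' bumps (low-order spherical harmonics); the inner (white-like) surface is
#' the outer one eroded radially inward by a smooth positive thickness
#' field. Each visit applies a small smooth radial drift and, on top,
#' diagnosis-dependent thinning proportional to `atrophy_rate * time`
#' (the inner surface moves outward toward the pial surface). Volumes are
#' occupancy rasterizations with Gaussian noise. Fully reproducible per
#' seed.
#'
#' @param config a [synthetic_cohort_config()].
#' @param seed integer seed for this subject.
#' @param subject_id identifier.
#' @return a `synthetic_subject` list: shared `faces`, per-visit `white`,
#'   `pial`, `volume`, `thickness`, plus `diagnosis`, `baseline_age`,
#'   `times`.
#' @export
generate_subject <- function(config, seed, subject_id = "sub") {
  with_seed(seed, {
    g <- config$grid_shape
    center <- (g - 1) / 2
    r0 <- config$outer_radius_frac * min(g)
    tmpl <- icosphere(config$mesh_subdivisions, 1)
    u <- tmpl$vertices  # unit directions
    basis <- sh_basis(u)

    shape_c <- rnorm(16, 0, config$bump_amplitude) * sh_scale
    r_outer_base <- r0 + as.numeric(basis %*% shape_c)
    th_c <- rnorm(16, 0, config$thickness_spatial_sd) * sh_scale
    thickness_base <- config$thickness_mean + as.numeric(basis %*% th_c)

    groups <- names(config$group_proportions)
    diagnosis <- sample(groups, 1, prob = config$group_proportions)
    rate <- config$atrophy_rate[[diagnosis]]
    baseline_age <- runif(1, config$baseline_age_range[1], config$baseline_age_range[2])

    k <- 0
    repeat {
      k <- round(rnorm(1, config$visits_mean, config$visits_sd))
      if (k >= config$visits_min && k <= config$visits_max) break
    }
    times <- c(0, cumsum(runif(k - 1, config$visit_spacing_range[1],
                               config$visit_spacing_range[2])))

    white <- pial <- volumes <- thickness <- vector("list", k)
    for (j in seq_len(k)) {
      drift_c <- rnorm(16, 0, config$drift_sd) * sh_scale
      r_out_j <- r_outer_base + as.numeric(basis %*% drift_c)
      th_j <- pmax(thickness_base - rate * times[j], 0.3)
      pial_j <- triangle_mesh(sweep(u * r_out_j, 2, center, "+"), tmpl$faces,
                              validate = FALSE)
      # erode along outward normals: white and pial are parallel offsets, so
      # the bilateral thickness of the pair equals the field (up to faceting)
      nrm <- vertex_normals(pial_j)
      white_j <- triangle_mesh(pial_j$vertices - nrm * th_j, tmpl$faces,
                               validate = FALSE)
      r_in_j <- sqrt(rowSums(sweep(white_j$vertices, 2, center, "-")^2))
      if (any(r_in_j <= 0) || any(th_j <= 0) || any(r_in_j >= r_out_j))
        stop("parameters produce inner/outer surface crossing; reduce bump or atrophy")
      lab <- rasterize_occupancy(white_j, pial_j, g)
      vol <- array(c(0, 0.5, 1)[lab$data + 1L], g) +
        array(rnorm(prod(g), 0, config$noise_sd), g)
      white[[j]] <- white_j
      pial[[j]] <- pial_j
      volumes[[j]] <- scalar_volume(vol, lab$affine)
      thickness[[j]] <- vertex_scalar_field(th_j, "thickness")
    }
    structure(list(subject_id = subject_id, faces = tmpl$faces,
                   white = white, pial = pial, volume = volumes,
                   thickness = thickness, labels = NULL,
                   diagnosis = diagnosis, baseline_age = baseline_age,
                   times = times),
              class = "synthetic_subject")
  })
}

#' Synthetic parcellation by farthest-point seeding
#'
#' Seeds are chosen by farthest-point traversal of the mesh graph
#' (edge-length weighted Dijkstra distances) and every vertex is assigned
#' to its geodesically nearest seed, giving contiguous, roughly balanced
#' regions. Region 1 doubles as the designated "unknown" medial mask in the
#' group analyses.
#'
#' @param template a [triangle_mesh()].
#' @param n_regions number of regions (>= 1).
#' @param rng_seed seed for the initial vertex choice.
#' @return integer [vertex_scalar_field()] of labels `1..n_regions`.
#' @export
generate_parcellation <- function(template, n_regions, rng_seed = 1) {
  nv <- nrow(template$vertices)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_regions == 1) return(vertex_scalar_field(rep(1L, nv), "parcellation"))
  e <- mesh_edges(template)
  w <- sqrt(rowSums((template$vertices[e[, 1], ] - template$vertices[e[, 2], ])^2))
  adj_n <- c(e[, 2], e[, 1])
  adj_c <- c(e[, 1], e[, 2])
  adj_w <- c(w, w)
  ord <- order(adj_c)
  adj_c <- adj_c[ord]; adj_n <- adj_n[ord]; adj_w <- adj_w[ord]
  ptr <- c(0, cumsum(tabulate(adj_c, nv)))
  dijkstra <- function(sources) {
    d <- rep(Inf, nv)
    d[sources] <- 0
    # simple queue-based relaxation (small meshes)
    active <- sources
    while (length(active)) {
      nxt <- integer(0)
      for (v in active) {
        idx <- seq.int(ptr[v] + 1, ptr[v + 1])
        nb <- adj_n[idx]
        nd <- d[v] + adj_w[idx]
        upd <- nd < d[nb]
        if (any(upd)) {
          d[nb[upd]] <- nd[upd]
          nxt <- c(nxt, nb[upd])
        }
      }
      active <- unique(nxt)
    }
    d
  }
  seeds <- with_seed(rng_seed, sample.int(nv, 1))
  dmin <- dijkstra(seeds)
  for (i in seq_len(n_regions - 1)) {
    seeds <- c(seeds, which.max(dmin))
    dmin <- pmin(dmin, dijkstra(seeds[length(seeds)]))
  }
  dmat <- vapply(seeds, function(s) dijkstra(s), numeric(nv))
  lab <- max.col(-dmat, ties.method = "first")
  vertex_scalar_field(as.integer(lab), "parcellation")
}

#' Generate a synthetic longitudinal cohort
#'
#' @param config a [synthetic_cohort_config()].
#' @return a `synthetic_cohort`: subjects, the population template pair
#'   (white/pial icospheres at the cohort mean radii), and a parcellation.
#' @export
generate_cohort <- function(config) {
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, subject_seed(config$rng_seed, i),
                     sprintf("sub-%03d", i)))
  g <- config$grid_shape
  center <- (g - 1) / 2
  r0 <- config$outer_radius_frac * min(g)
  tmpl_pial <- icosphere(config$mesh_subdivisions, r0, center)
  tmpl_white <- icosphere(config$mesh_subdivisions, r0 - config$thickness_mean, center)
  parc <- generate_parcellation(tmpl_white, config$n_regions,
                                rng_seed = config$rng_seed)
  structure(list(subjects = subjects, template_white = tmpl_white,
                 template_pial = tmpl_pial, parcellation = parc,
                 config = config),
            class = "synthetic_cohort")
}

#' Export a cohort to disk
#'
#' NIfTI volumes, FreeSurfer surface files, a covariate CSV and a manifest
#' CSV that the pipeline consumes unchanged.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created).
#' @return the manifest data.frame, invisibly written to
#'   `<out_dir>/manifest.csv`.
#' @export
export_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  cov <- list()
  for (s in cohort$subjects) {
    for (j in seq_along(s$times)) {
      base <- file.path(out_dir, sprintf("%s_visit-%02d", s$subject_id, j))
      write_volume(s$volume[[j]], paste0(base, ".nii.gz"))
      write_mesh(s$white[[j]], paste0(base, ".white"), "freesurfer_surface")
      write_mesh(s$pial[[j]], paste0(base, ".pial"), "freesurfer_surface")
      rows[[length(rows) + 1]] <- data.frame(
        subject = s$subject_id, visit = j, time = s$times[j],
        volume = paste0(base, ".nii.gz"),
        white = paste0(base, ".white"), pial = paste0(base, ".pial"))
    }
    cov[[length(cov) + 1]] <- data.frame(
      subject = s$subject_id, diagnosis = s$diagnosis,
      baseline_age = s$baseline_age, n_visits = length(s$times))
  }
  write_mesh(cohort$template_white, file.path(out_dir, "template.white"))
  write_mesh(cohort$template_pial, file.path(out_dir, "template.pial"))
  write_field_csv(cohort$parcellation, file.path(out_dir, "parcellation.csv"))
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(do.call(rbind, cov), file.path(out_dir, "covariates.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Re-import an exported cohort
#'
#' @param out_dir directory written by [export_cohort()].
#' @return list with `manifest`, `covariates`, loaded `template_white`,
#'   `template_pial`, `parcellation`, and per-row loader closures.
#' @export
import_cohort <- function(out_dir) {
  manifest <- read.csv(file.path(out_dir, "manifest.csv"))
  covariates <- read.csv(file.path(out_dir, "covariates.csv"))
  missing <- !file.exists(manifest$volume)
  if (any(missing)) stop("manifest paths do not resolve: ",
                         paste(head(manifest$volume[missing], 3), collapse = ", "))
  list(manifest = manifest, covariates = covariates,
       template_white = read_mesh(file.path(out_dir, "template.white")),
       template_pial = read_mesh(file.path(out_dir, "template.pial")),
       parcellation = read_field_csv(file.path(out_dir, "parcellation.csv")),
       load_volume = function(i) read_volume(manifest$volume[i]),
       load_white = function(i) read_mesh(manifest$white[i]),
       load_pial = function(i) read_mesh(manifest$pial[i]))
}
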