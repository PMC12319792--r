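#' Triangle mesh
#'
#' The universal surface representation of the package: a list with a
#' numeric `V x 3` matrix of vertex coordinates (world space, mm) and an
#' integer `F x 3` matrix of 1-based vertex indices with counter-clockwise
#' orientation (normals point outward for closed surfaces).
#'
#' @param vertices numeric matrix, one vertex per row.
#' @param faces integer matrix, one triangle per row (1-based indices).
#' @param validate check index bounds and face degeneracy.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_closed_manifold(x)) " (closed 2-manifold)" else ""))
  invisible(x)
}

#' Validate a triangle mesh
#'
#' Checks that all face indices are within `[1, V]` and that no face repeats
#' a vertex index.
#'
#' @param mesh a [triangle_mesh()].
#' @return the mesh, invisibly; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- nrow(mesh$vertices)
  f <- mesh$faces
  if (nrow(f) > 0) {
    if (any(f < 1L) || any(f > v))
      stop(sprintf("face indices out of bounds [1, %d]", v))
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen))
      stop(sprintf("degenerate face(s) with repeated vertex: %s",
                   paste(which(degen)[seq_len(min(5, sum(degen)))], collapse = ", ")))
  }
  if (any(!is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  invisible(mesh)
}

# connectivity-derived structures are cached per faces array: during
# training the same template connectivity is queried thousands of times
.conn_cache <- new.env(parent = emptyenv())

conn_cached <- function(faces, what, compute) {
  key <- paste0(what, "-", nrow(faces), "-", sum(as.numeric(faces)), "-",
                sum(as.numeric(faces) * seq_along(faces)) %% 1e15)
  hit <- .conn_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- compute(faces)
  .conn_cache[[key]] <- val
  val
}

#' Edge set of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return integer `E x 2` matrix of unique undirected edges (rows sorted).
#' @export
mesh_edges <- function(mesh) {
  conn_cached(mesh$faces, "edges", function(f) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    unique(e)
  })
}

#' Test for a closed 2-manifold
#'
#' @param mesh a [triangle_mesh()].
#' @return TRUE when every undirected edge is shared by exactly two faces.
#' @export
is_closed_manifold <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Per-face normals and areas
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `normals` (`F x 3`, unit where the face is non-degenerate)
#'   and `areas` (length-`F`).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  areas <- len / 2
  nz <- len > 0
  n[nz, ] <- n[nz, , drop = FALSE] / len[nz]
  list(normals = n, areas = areas)
}

#' Vertex scalar field
#'
#' A named per-vertex value vector aligned to a mesh's vertex order
#' (curvature, thickness, Z-scores, or integer parcellation labels).
#'
#' @param values numeric or integer vector, one value per vertex.
#' @param name label for the field.
#' @param mesh optional mesh to check the length against.
#' @export
vertex_scalar_field <- function(values, name = "field", mesh = NULL) {
  if (!is.null(mesh) && length(values) != nrow(mesh$vertices))
    stop("field length does not match the mesh vertex count")
  structure(list(values = values, name = name), class = "vertex_scalar_field")
}

#' Longitudinal surface sequence
#'
#' Ordered per-visit meshes of one subject and one surface class, all sharing
#' a single connectivity so that vertex row `v` denotes the same anatomical
#' point at every visit.
#'
#' @param subject_id identifier.
#' @param meshes list of [triangle_mesh()] objects with bitwise-equal faces.
#' @param surface_class `"white"` or `"pial"`.
#' @export
surface_sequence <- function(subject_id, meshes, surface_class = c("white", "pial")) {
  surface_class <- match.arg(surface_class)
  if (length(meshes) < 1) stop("a surface sequence needs at least one visit")
  f0 <- meshes[[1]]$faces
  for (m in meshes)
    if (!identical(m$faces, f0))
      stop("all meshes in a sequence must share identical faces")
  structure(list(subject_id = subject_id, meshes = meshes,
                 surface_class = surface_class),
            class = "surface_sequence")
}

# ---- template construction -------------------------------------------------

#' Icosphere template mesh
#'
#' Subdivided icosahedron projected onto a sphere; the desk-scale analogue of
#' a spherical population template. Level 0 has 12 vertices / 20 faces; each
#' level quadruples the face count (level 3: 642 vertices, 1280 faces).
#'
#' @param subdivisions number of 1-to-4 face subdivisions.
#' @param radius sphere radius (mm).
#' @param center length-3 numeric center.
#' @return a closed, outward-oriented [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    res <- subdivide_midpoint(v, f)
    v <- res$vertices / sqrt(rowSums(res$vertices^2))
    f <- res$faces
  }
  # enforce outward orientation (normal . centroid > 0)
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(n * ctr) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

# one round of midpoint (1-to-4) subdivision with shared-edge midpoints
subdivide_midpoint <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ek <- key(e[, 1], e[, 2])
  uk <- unique(ek)
  mid_idx <- match(ek, uk) + nrow(v)
  ue <- e[!duplicated(ek), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_idx[seq_len(nf)]
  m23 <- mid_idx[nf + seq_len(nf)]
  m31 <- mid_idx[2 * nf + seq_len(nf)]
  newf <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = newf)
}
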